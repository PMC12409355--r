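#' Family catalogue for type III CRISPR locus annotation
#'
#' The catalogue declares which profile names in a HMM hit table correspond
#' to Cas10, cas accessory genes, cyclic-oligoadenylate effectors and ring
#' nuclease (RN) families, and how profile names map onto families. The one
#' non-identity mapping shipped by default folds the predicted RN Csx14 into
#' the Crn1 family, which it belongs to by homology.
#'
#' @param rn_families character vector of RN family names.
#' @param effector_families character vector of effector family names.
#' @param cas10_profiles profile names that identify the Cas10 anchor.
#' @param cas_accessory_profiles profile names of non-Cas10 cas-core genes
#'   used when chaining the cas operon span.
#' @param profile_to_family named character vector mapping profile names to
#'   family names for profiles whose name differs from their family
#'   (e.g. `c(Csx14 = "Crn1")`). Profiles absent from the map are their own
#'   family.
#'
#' @return An object of class `rn_catalogue`.
#' @examples
#' cat <- family_catalogue()
#' map_profile_family(cat, c("Csx14", "Crn3", "Csx1"))
#' @export
family_catalogue <- function(
    rn_families = c("Crn1", "Crn2", "Crn3", "Csx15", "Csx16", "Csx20"),
    effector_families = c("Csx1", "Csm6", "Csm6-2", "Can1", "Can2",
                          "Cami1", "Cam1", "CalpL", "NucC", "Csx23",
                          "TIR-SAVED", "CorA"),
    cas10_profiles = "Cas10",
    cas_accessory_profiles = c("Cas5", "Cas7", "Cas11", "Csm3", "Csm4",
                               "Csm5", "Cmr1", "Cmr4", "Cmr5", "Cas6"),
    profile_to_family = c(Csx14 = "Crn1")) {
  if (length(intersect(rn_families, effector_families)) > 0L)
    stop_fmt("RN and effector family sets must be disjoint: %s",
             paste(intersect(rn_families, effector_families), collapse = ", "))
  bad <- setdiff(unname(profile_to_family),
                 c(rn_families, effector_families))
  if (length(bad) > 0L)
    stop_fmt("profile_to_family maps onto unknown families: %s",
             paste(bad, collapse = ", "))
  structure(
    list(rn_families = rn_families,
         effector_families = effector_families,
         cas10_profiles = cas10_profiles,
         cas_accessory_profiles = cas_accessory_profiles,
         profile_to_family = profile_to_family),
    class = "rn_catalogue")
}

#' Map profile names to family names
#'
#' Applies the catalogue's profile-to-family map; profiles without an
#' explicit entry are returned unchanged (profile name == family name).
#'
#' @param catalogue an `rn_catalogue`.
#' @param profiles character vector of profile names.
#' @return character vector of family names, same length as `profiles`.
#' @export
map_profile_family <- function(catalogue, profiles) {
  out <- profiles
  hit <- profiles %in% names(catalogue$profile_to_family)
  out[hit] <- unname(catalogue$profile_to_family[profiles[hit]])
  out
}

# Profile names that resolve to an RN family (family names themselves plus
# aliases such as Csx14).
rn_profiles <- function(catalogue) {
  aliases <- names(catalogue$profile_to_family)[
    catalogue$profile_to_family %in% catalogue$rn_families]
  unique(c(catalogue$rn_families, aliases))
}

effector_profiles <- function(catalogue) {
  aliases <- names(catalogue$profile_to_family)[
    catalogue$profile_to_family %in% catalogue$effector_families]
  unique(c(catalogue$effector_families, aliases))
}

#' Default effector-to-signal mapping
#'
#' Maps each effector family to the second messenger that activates it:
#' cA3, cA4 or cA6 (cyclic tri-, tetra- or hexa-adenylate) or SAM-AMP.
#' Csx1, Can1, Can2, Cami1, Cam1 and CalpL are cA4-activated; Csm6 and
#' Csm6-2 are cA6-activated; NucC and TIR-SAVED respond to cA3; CorA-fused
#' systems signal via SAM-AMP. Assignments for families characterized
#' elsewhere (e.g. Csx23) are provisional and can be overridden.
#'
#' @param overrides named character vector of `family = signal` overrides or
#'   additions; signals must be one of `cA3`, `cA4`, `cA6`, `SAM-AMP`,
#'   `unknown`.
#' @return named character vector: effector family -> signal.
#' @export
default_signal_mapping <- function(overrides = NULL) {
  m <- c(Csx1 = "cA4", Can1 = "cA4", Can2 = "cA4", Cami1 = "cA4",
         Cam1 = "cA4", CalpL = "cA4", Csx23 = "cA4",
         Csm6 = "cA6", `Csm6-2` = "cA6",
         NucC = "cA3", `TIR-SAVED` = "cA3",
         CorA = "SAM-AMP")
  if (!is.null(overrides)) {
    ok <- c("cA3", "cA4", "cA6", "SAM-AMP", "unknown")
    if (!all(overrides %in% ok))
      stop_fmt("unknown signal label(s): %s",
               paste(setdiff(overrides, ok), collapse = ", "))
    m[names(overrides)] <- overrides
  }
  m
}
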