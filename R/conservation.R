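#' Build a conservation profile from a reference alignment
#'
#' Reduces a reference multiple sequence alignment of a ring-nuclease
#' family to the two things the screen needs: a consensus sequence over the
#' well-occupied columns, and the set of absolutely conserved columns whose
#' residue every genuine family member is expected to carry.
#'
#' A column is *retained* when its gap fraction is at most `g_max`
#' (alignments are ragged at their ends; fully gapped columns carry no
#' signal). A retained column is *conserved* when its modal residue
#' accounts for at least `t_cons` of the non-gap characters; the default
#' `t_cons = 1` is the literal reading of "absolutely conserved".
#'
#' @param msa an aligned protein set: `AAStringSet`, named character vector,
#'   or path to an aligned FASTA. All sequences must have equal aligned
#'   length; gaps are `-` or `.`.
#' @param family family name stored on the profile.
#' @param t_cons minimum modal-residue frequency (over non-gap characters)
#'   for a column to count as conserved; in (0, 1], default 1.
#' @param g_max maximum gap fraction for a column to be retained in the
#'   consensus; default 0.2.
#' @return object of class `conservation_profile` with fields `family`,
#'   `consensus` (character scalar over retained columns),
#'   `retained_columns` (alignment column indices of the consensus
#'   positions), `conserved_columns` (alignment column indices),
#'   `conserved_residues` (expected residue per conserved column) and
#'   `conserved_consensus_pos` (position of each conserved column within
#'   the consensus string).
#' @export
build_conservation_profile <- function(msa, family = "family",
                                       t_cons = 1.0, g_max = 0.2) {
  if (is.character(msa) && length(msa) == 1L && file.exists(msa))
    msa <- Biostrings::readAAStringSet(msa)
  if (inherits(msa, "AAStringSet")) msa <- as.character(msa)
  if (length(msa) < 2L)
    stop_fmt("reference alignment for %s needs >=2 sequences", family)
  if (length(unique(nchar(msa))) != 1L)
    stop_fmt("ragged alignment for %s: aligned lengths %s", family,
             paste(sort(unique(nchar(msa))), collapse = ", "))
  if (t_cons <= 0 || t_cons > 1) stop_fmt("t_cons must be in (0, 1]")
  mat <- do.call(rbind, strsplit(toupper(msa), ""))
  mat[mat == "."] <- "-"
  ncol_aln <- ncol(mat)
  gap_frac <- colMeans(mat == "-")
  retained <- which(gap_frac <= g_max)
  if (length(retained) == 0L)
    stop_fmt("no column of the %s alignment passes g_max = %g", family, g_max)
  modal <- character(ncol_aln); modal_freq <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    res <- mat[, j]; res <- res[res != "-"]
    if (length(res) == 0L) { modal[j] <- NA_character_; next }
    tab <- sort(table(res), decreasing = TRUE)
    modal[j] <- names(tab)[1]
    modal_freq[j] <- tab[1] / length(res)
  }
  conserved <- intersect(
    which(modal_freq >= t_cons & !is.na(modal)), retained)
  structure(
    list(family = family,
         consensus = paste(modal[retained], collapse = ""),
         retained_columns = retained,
         conserved_columns = conserved,
         conserved_residues = modal[conserved],
         conserved_consensus_pos = match(conserved, retained),
         t_cons = t_cons, g_max = g_max,
         n_sequences = length(msa)),
    class = "conservation_profile")
}

#' Screen an RN candidate for absolutely conserved residues
#'
#' Automated equivalent of inspecting a candidate against the family
#' alignment: the candidate is globally aligned to the profile consensus
#' (BLOSUM62, affine gaps), each conserved column is mapped through the
#' alignment, and the candidate passes only when it carries the expected
#' residue at every conserved column. A conserved column whose consensus
#' position is deleted in the candidate counts as missing.
#'
#' @param protein_seq candidate amino-acid sequence (character scalar).
#' @param profile a `conservation_profile`.
#' @param gap_opening,gap_extension affine gap penalties for the global
#'   alignment (defaults 10 and 1).
#' @return list with `status` (`"pass"` or `"fail"`) and
#'   `missing_positions`, a data frame (`column`, `expected`, `observed`)
#'   of conserved alignment columns where the candidate deviates
#'   (`observed` is `"-"` for a deletion). `missing_positions` has zero
#'   rows iff `status == "pass"`.
#' @export
screen_candidate <- function(protein_seq, profile,
                             gap_opening = 10, gap_extension = 1) {
  if (!inherits(profile, "conservation_profile"))
    stop_fmt("profile must be a conservation_profile")
  if (length(profile$conserved_columns) == 0L)
    stop_fmt("profile %s has no conserved columns; cannot screen",
             profile$family)
  if (!nzchar(protein_seq)) stop_fmt("empty candidate sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_seq),
    Biostrings::AAString(profile$consensus),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # residue of the candidate aligned against each consensus position
  cons_len <- nchar(profile$consensus)
  at_cons <- character(cons_len)
  jpos <- 0L
  for (k in seq_along(sub)) {
    if (sub[k] != "-") {
      jpos <- jpos + 1L
      at_cons[jpos] <- pat[k]
    }
  }
  obs <- at_cons[profile$conserved_consensus_pos]
  bad <- obs != profile$conserved_residues
  missing <- data.frame(
    column = profile$conserved_columns[bad],
    expected = profile$conserved_residues[bad],
    observed = obs[bad],
    stringsAsFactors = FALSE)
  list(status = if (nrow(missing) == 0L) "pass" else "fail",
       missing_positions = missing)
}

#' Read per-family reference alignments from a directory
#'
#' Loads every `<family>.afa` aligned FASTA under `dir` and builds one
#' [conservation profile][build_conservation_profile] per family.
#'
#' @param dir directory of `<family>.afa` files.
#' @param t_cons,g_max passed to [build_conservation_profile()].
#' @return named list of `conservation_profile` objects.
#' @export
read_reference_profiles <- function(dir, t_cons = 1.0, g_max = 0.2) {
  files <- list.files(dir, pattern = "\\.afa$", full.names = TRUE)
  profs <- lapply(files, function(f)
    build_conservation_profile(f, family = sub("\\.afa$", "", basename(f)),
                               t_cons = t_cons, g_max = g_max))
  setNames(profs, vapply(profs, `[[`, "", "family"))
}
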