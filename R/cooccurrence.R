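#' Summarize RN content and RN/effector co-occurrence across loci
#'
#' Computes the descriptive statistics of the survey: per-RN-family gene
#' instance counts and locus counts, the number of RN-positive loci, the
#' multi-RN locus report, the RN-by-effector co-occurrence matrix, and the
#' number of RN-positive loci carrying no effector. An RN counts as
#' "associated" only when its conserved-residue screen did not fail
#' (`screen_status != "fail"`): screen failures were removed as false
#' positives. A locus counts once per family even when it carries two
#' genes of the same family.
#'
#' @param annotated an `rn_annotated_loci` from [annotate_loci()].
#' @return list of class `rn_cooccurrence_summary`: `family_counts`
#'   (`family`, `n_instances`, `n_loci`), `n_rn_positive_loci`,
#'   `n_multi_rn_loci`, `multi_rn` (`locus_id`, `n_rn`, `families`),
#'   `rn_by_effector` (matrix, RN families x effector families, locus
#'   counts), `n_rn_loci_without_effector`, and instance/locus totals.
#' @export
summarize_cooccurrence <- function(annotated) {
  rns <- annotated$rns[annotated$rns$screen_status != "fail", , drop = FALSE]
  eff <- annotated$effectors
  fams <- sort(unique(rns$family))
  family_counts <- data.frame(
    family = fams,
    n_instances = vapply(fams, function(f) sum(rns$family == f), 0L),
    n_loci = vapply(fams, function(f)
      length(unique(rns$locus_id[rns$family == f])), 0L),
    stringsAsFactors = FALSE)
  rownames(family_counts) <- NULL
  per_locus_k <- if (nrow(rns) > 0L)
    tapply(rns$family, rns$locus_id, function(x) length(x)) else integer()
  rn_pos <- names(per_locus_k)
  multi <- rn_pos[per_locus_k > 1L]
  multi_rn <- data.frame(
    locus_id = multi,
    n_rn = as.integer(per_locus_k[multi]),
    families = vapply(multi, function(l)
      paste(sort(rns$family[rns$locus_id == l]), collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  rownames(multi_rn) <- NULL
  eff_fams <- sort(unique(eff$family))
  mat <- matrix(0L, nrow = length(fams), ncol = length(eff_fams),
                dimnames = list(fams, eff_fams))
  for (r in fams) for (e in eff_fams) {
    mat[r, e] <- length(intersect(unique(rns$locus_id[rns$family == r]),
                                  unique(eff$locus_id[eff$family == e])))
  }
  no_eff <- setdiff(rn_pos, unique(eff$locus_id))
  structure(list(
    family_counts = family_counts,
    n_rn_instances = nrow(rns),
    n_rn_positive_loci = length(rn_pos),
    n_multi_rn_loci = length(multi),
    multi_rn = multi_rn,
    rn_by_effector = mat,
    n_rn_loci_without_effector = length(no_eff),
    n_loci = nrow(annotated$loci)),
    class = "rn_cooccurrence_summary")
}

#' @export
print.rn_cooccurrence_summary <- function(x, ...) {
  cat(sprintf(
    "<rn_cooccurrence_summary> %d loci; %d RN instances in %d RN-positive loci (%d multi-RN, %d without effector)\n",
    x$n_loci, x$n_rn_instances, x$n_rn_positive_loci, x$n_multi_rn_loci,
    x$n_rn_loci_without_effector))
  print(x$family_counts)
  invisible(x)
}

#' Restricted RN-effector association proportions
#'
#' For each effector family, the proportion of its loci that also carry an
#' RN, computed over the restricted locus set: loci with exactly one
#' effector annotation and at most one (screen-passing) RN annotation.
#' Restricting removes ambiguity about which effector an RN is associated
#' with. Families whose restricted locus count is zero are reported with
#' denominator 0 and `NA` proportion rather than dropped.
#'
#' @param annotated an `rn_annotated_loci`.
#' @param families optional effector families to report; default all seen.
#' @return data frame (`family`, `n_with_rn`, `n_loci`, `proportion`).
#' @export
restricted_association <- function(annotated, families = NULL) {
  eff <- annotated$effectors
  rns <- annotated$rns[annotated$rns$screen_status != "fail", , drop = FALSE]
  eff_per_locus <- table(eff$locus_id)
  rn_per_locus <- table(rns$locus_id)
  rn_count <- function(l) {
    v <- rn_per_locus[l]; ifelse(is.na(v), 0L, as.integer(v))
  }
  restricted <- names(eff_per_locus)[eff_per_locus == 1L]
  restricted <- restricted[rn_count(restricted) <= 1L]
  if (is.null(families)) families <- sort(unique(eff$family))
  rows <- lapply(families, function(f) {
    fl <- intersect(restricted, eff$locus_id[eff$family == f])
    n <- length(fl)
    k <- sum(rn_count(fl) >= 1L)
    data.frame(family = f, n_with_rn = k, n_loci = n,
               proportion = if (n > 0L) k / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the RN-effector co-occurrence network
#'
#' Bipartite network with one node per RN family and per effector family,
#' and an edge weighted by the number of loci containing both families.
#' Edges between two RNs or two effectors are never created — removing
#' same-type co-occurrences is what exposes the RN-effector structure.
#' Zero-weight pairs are omitted. Effector nodes carry their signal as an
#' attribute.
#'
#' @param annotated an `rn_annotated_loci`.
#' @param signal_mapping named vector from [default_signal_mapping()].
#' @return list of class `rn_bipartite_network`: `nodes` (`id`, `type`
#'   in RN/effector, `signal`) and `edges` (`rn`, `effector`, `weight`).
#' @export
build_network <- function(annotated,
                          signal_mapping = default_signal_mapping()) {
  summ <- summarize_cooccurrence(annotated)
  mat <- summ$rn_by_effector
  nodes <- rbind(
    data.frame(id = rownames(mat),
               type = rep("RN", nrow(mat)),
               signal = rep(NA_character_, nrow(mat)),
               stringsAsFactors = FALSE),
    data.frame(id = colnames(mat),
               type = rep("effector", ncol(mat)),
               signal = unname(signal_mapping[colnames(mat)]),
               stringsAsFactors = FALSE))
  nodes$signal[is.na(nodes$signal) & nodes$type == "effector"] <- "unknown"
  idx <- which(mat > 0L, arr.ind = TRUE)
  edges <- if (nrow(idx) > 0L) data.frame(
    rn = rownames(mat)[idx[, 1]],
    effector = colnames(mat)[idx[, 2]],
    weight = as.integer(mat[idx]),
    stringsAsFactors = FALSE)
  else data.frame(rn = character(), effector = character(),
                  weight = integer(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$rn, edges$effector), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "rn_bipartite_network")
}

#' Genome-level background frequency of an RN family
#'
#' Among genomes carrying at least one screened (non-failing) instance of
#' the family anywhere in the genome, the fraction that carry no type III
#' CRISPR locus at all. A high value flags a family whose presence does
#' not depend on type III CRISPR, arguing against a dedicated RN role.
#'
#' @param genome_rns output of [screen_proteome_rns()] over all genomes.
#' @param annotated an `rn_annotated_loci` (its `loci` define which
#'   genomes have a type III locus).
#' @param family RN family name.
#' @return list with `n_genomes_with_family`, `n_without_locus`,
#'   `fraction` (`NA` when the family is absent genome-wide).
#' @export
background_frequency <- function(genome_rns, annotated, family) {
  ok <- genome_rns$family == family & genome_rns$screen_status != "fail"
  carriers <- unique(genome_rns$genome_id[ok])
  if (length(carriers) == 0L)
    return(list(n_genomes_with_family = 0L, n_without_locus = 0L,
                fraction = NA_real_))
  locus_genomes <- unique(annotated$loci$genome_id)
  n_wo <- sum(!carriers %in% locus_genomes)
  list(n_genomes_with_family = length(carriers),
       n_without_locus = n_wo,
       fraction = n_wo / length(carriers))
}

#' Count phage genomes carrying each RN family
#'
#' Per family, the number of distinct phage genomes with at least one
#' screen-passing RN instance (genome-level deduplication: a phage with
#' two Crn2 genes counts once).
#'
#' @param phage_rns output of [screen_proteome_rns()] on phage proteomes.
#' @return data frame (`family`, `n_genomes`), sorted by decreasing count.
#' @export
phage_family_counts <- function(phage_rns) {
  ok <- phage_rns[phage_rns$screen_status != "fail", , drop = FALSE]
  if (nrow(ok) == 0L)
    return(data.frame(family = character(), n_genomes = integer(),
                      stringsAsFactors = FALSE))
  tab <- tapply(ok$genome_id, ok$family,
                function(g) length(unique(g)))
  out <- data.frame(family = names(tab), n_genomes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_genomes, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate the leaves of a Cas10 tree with locus content
#'
#' Produces the ring-annotation table behind a Cas10 phylogeny figure: one
#' row per leaf (leaf labels are Cas10 anchor gene ids), with the locus
#' subtype, the inferred signal(s), one presence column per RN family
#' (screen-passing instances only), and a flag for Cas10s lacking a clear
#' active cyclase domain. Leaves without a matching locus get explicit
#' `NA` values, never dropped.
#'
#' @param tree an `ape::phylo` object or path to a newick file.
#' @param annotated an `rn_annotated_loci`.
#' @param rn_families RN family columns to emit (default: the catalogue
#'   default set).
#' @return data frame, one row per leaf.
#' @export
tree_annotation <- function(tree, annotated,
                            rn_families = family_catalogue()$rn_families) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  labs <- tree$tip.label
  if (anyDuplicated(labs))
    stop_fmt("duplicate leaf labels: %s",
             paste(unique(labs[duplicated(labs)]), collapse = ", "))
  loci <- annotated$loci
  rns <- annotated$rns[annotated$rns$screen_status != "fail", , drop = FALSE]
  m <- match(labs, loci$anchor_gene)
  out <- data.frame(
    leaf = labs,
    locus_id = loci$locus_id[m],
    subtype = loci$subtype[m],
    signals = loci$signals[m],
    cyclase_absent = !loci$has_cyclase[m],
    stringsAsFactors = FALSE)
  for (f in rn_families) {
    fl <- unique(rns$locus_id[rns$family == f])
    out[[f]] <- ifelse(is.na(out$locus_id), NA_integer_,
                       as.integer(out$locus_id %in% fl))
  }
  out
}
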