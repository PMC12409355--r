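#' Classify a gene as a ring-nuclease candidate
#'
#' Returns the best RN-family call for one gene, or `NULL`. A gene
#' qualifies only if it has at least one RN-profile hit at or below the
#' e-value ceiling *and* is at most `max_len` amino acids long — the
#' length cutoff that keeps CARF-containing effectors, which share the
#' sensor domain, from being mis-called as RNs. Among qualifying hits the
#' highest bit score wins; ties break by smaller e-value, then
#' alphabetical family name. Profile names are mapped to families
#' (Csx14 hits become Crn1 calls).
#'
#' @param gene single-row gene table.
#' @param hits hit table (may contain hits for other genes).
#' @param catalogue an `rn_catalogue`.
#' @param evalue_ceiling maximum e-value (default 1e-4).
#' @param max_len maximum RN length in amino acids (default 250).
#' @return `NULL`, or a list with `family`, `bitscore`, `evalue`.
#' @export
classify_rn <- function(gene, hits, catalogue, evalue_ceiling = 1e-4,
                        max_len = 250) {
  if (gene$length_aa > max_len) return(NULL)
  h <- hits[hits$protein_id == gene$gene_id &
              hits$family_id %in% rn_profiles(catalogue) &
              hits$evalue <= evalue_ceiling, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h$family <- map_profile_family(catalogue, h$family_id)
  h <- h[order(-h$bitscore, h$evalue, h$family), , drop = FALSE]
  list(family = h$family[1], bitscore = h$bitscore[1], evalue = h$evalue[1])
}

best_effector_hit <- function(gene_id, hits, catalogue, evalue_ceiling) {
  h <- hits[hits$protein_id == gene_id &
              hits$family_id %in% effector_profiles(catalogue) &
              hits$evalue <= evalue_ceiling, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h$family <- map_profile_family(catalogue, h$family_id)
  h <- h[order(-h$bitscore, h$evalue, h$family), , drop = FALSE]
  list(family = h$family[1], bitscore = h$bitscore[1], evalue = h$evalue[1])
}

# Cross-annotation arbitration for a gene qualifying as both effector and
# RN: the effector call wins when the protein exceeds the RN length cutoff;
# the RN call wins when the protein is within the cutoff AND the RN bit
# score beats the effector bit score; otherwise effector.
resolve_cross_annotation <- function(gene, rn_call, eff_call,
                                     max_len = 250) {
  if (is.null(rn_call) && is.null(eff_call)) return("none")
  if (is.null(eff_call)) return("rn")
  if (is.null(rn_call)) return("effector")
  if (gene$length_aa > max_len) return("effector")
  if (rn_call$bitscore > eff_call$bitscore) return("rn") else
    return("effector")
}

#' Annotate effectors (and arbitrate RN/effector conflicts) on locus members
#'
#' Per member gene, the best effector-family hit is taken; when the gene
#' also qualifies as an RN the cross-annotation rule of
#' [classify_rn()]/[resolve_cross_annotation()] decides which call stands.
#'
#' @param members gene table of locus members.
#' @param hits hit table.
#' @param catalogue an `rn_catalogue`.
#' @param evalue_ceiling maximum e-value.
#' @param signal_mapping named vector from [default_signal_mapping()].
#' @param max_rn_len RN length cutoff in aa.
#' @return data frame (`gene_id`, `family`, `bitscore`, `evalue`,
#'   `signal`), one row per effector call.
#' @export
annotate_effectors <- function(members, hits, catalogue,
                               evalue_ceiling = 1e-4,
                               signal_mapping = default_signal_mapping(),
                               max_rn_len = 250) {
  calls <- annotate_members(members, hits, catalogue, evalue_ceiling,
                            max_rn_len)
  eff <- calls$effectors
  if (nrow(eff) > 0L) {
    eff$signal <- unname(signal_mapping[eff$family])
    miss <- is.na(eff$signal)
    if (any(miss)) {
      warn_fmt("effector families with no signal mapping: %s",
               paste(unique(eff$family[miss]), collapse = ", "))
      eff$signal[miss] <- "unknown"
    }
  } else eff$signal <- character()
  eff
}

# Shared per-gene call logic: returns both annotation tables, before
# conserved-residue screening.
annotate_members <- function(members, hits, catalogue, evalue_ceiling,
                             max_rn_len = 250) {
  rn_rows <- list(); eff_rows <- list()
  for (i in seq_len(nrow(members))) {
    g <- members[i, ]
    rn <- classify_rn(g, hits, catalogue, evalue_ceiling, max_rn_len)
    ef <- best_effector_hit(g$gene_id, hits, catalogue, evalue_ceiling)
    verdict <- resolve_cross_annotation(g, rn, ef, max_rn_len)
    if (verdict == "rn")
      rn_rows[[length(rn_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, family = rn$family, bitscore = rn$bitscore,
        evalue = rn$evalue, stringsAsFactors = FALSE)
    else if (verdict == "effector")
      eff_rows[[length(eff_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id, family = ef$family, bitscore = ef$bitscore,
        evalue = ef$evalue, stringsAsFactors = FALSE)
  }
  list(
    rns = if (length(rn_rows)) do.call(rbind, rn_rows) else
      data.frame(gene_id = character(), family = character(),
                 bitscore = numeric(), evalue = numeric(),
                 stringsAsFactors = FALSE),
    effectors = if (length(eff_rows)) do.call(rbind, eff_rows) else
      data.frame(gene_id = character(), family = character(),
                 bitscore = numeric(), evalue = numeric(),
                 stringsAsFactors = FALSE))
}

#' Annotate a Cas10 protein for cyclase and HD nuclease motifs
#'
#' The Palm/cyclase domain is called by a GGDD-type tetrad
#' (`GGDD`/`GGDE`/`SGDD` by default); the HD nuclease domain by a
#' histidine followed by an aspartate within 4 residues, in the N-terminal
#' third of the protein. Both rules are plain motif patterns and
#' configurable; they are heuristics, not structure-based calls.
#'
#' @param cas10_seq Cas10 amino-acid sequence.
#' @param cyclase_motifs character vector of cyclase tetrad motifs.
#' @param hd_pattern regular expression for the HD motif.
#' @return list with `has_cyclase`, `has_hd` (logicals).
#' @export
annotate_cas10 <- function(cas10_seq,
                           cyclase_motifs = c("GGDD", "GGDE", "SGDD"),
                           hd_pattern = "H.{0,3}D") {
  has_cyclase <- any(vapply(cyclase_motifs, grepl, logical(1),
                            x = cas10_seq, fixed = TRUE))
  n_third <- substr(cas10_seq, 1L, max(1L, nchar(cas10_seq) %/% 3L))
  list(has_cyclase = has_cyclase,
       has_hd = grepl(hd_pattern, n_third))
}

#' Infer the signalling molecule(s) of a locus from its effectors
#'
#' The signal repertoire of a locus is the union of the signals its
#' effector families respond to; a locus with no effector has an empty
#' signal set. Families absent from the mapping trigger a warning and map
#' to `"unknown"`.
#'
#' @param effector_families character vector of effector family names.
#' @param signal_mapping named vector from [default_signal_mapping()].
#' @return sorted character vector of signal labels.
#' @export
infer_signals <- function(effector_families,
                          signal_mapping = default_signal_mapping()) {
  if (length(effector_families) == 0L) return(character())
  sig <- signal_mapping[effector_families]
  miss <- is.na(sig)
  if (any(miss)) {
    warn_fmt("no signal mapping for effector families: %s",
             paste(unique(effector_families[miss]), collapse = ", "))
    sig[miss] <- "unknown"
  }
  sort(unique(unname(sig)))
}

#' Annotate an assembled locus set
#'
#' Runs the full annotation stage over the member genes of every locus:
#' RN calling with the length cutoff, effector calling with
#' cross-annotation arbitration, conserved-residue screening of RN
#' candidates against the family reference profiles, Cas10
#' cyclase/HD motif flags on the anchor, and per-locus signal inference
#' from effector content.
#'
#' @param locus_set an `rn_locus_set` from [build_loci()].
#' @param genes gene table.
#' @param hits hit table.
#' @param catalogue an `rn_catalogue`.
#' @param profiles named list of `conservation_profile` objects keyed by
#'   RN family; families without a profile get `screen_status =
#'   "not_screened"`.
#' @param signal_mapping named vector from [default_signal_mapping()].
#' @param evalue_ceiling maximum hit e-value (default 1e-4).
#' @param max_rn_len RN length cutoff in aa (default 250).
#' @return object of class `rn_annotated_loci`: the input `loci` and
#'   `members` plus `rns` (`locus_id`, `gene_id`, `family`, `bitscore`,
#'   `evalue`, `screen_status`, `missing_positions` as a
#'   semicolon-separated `column:expected` string), `effectors`
#'   (`locus_id`, `gene_id`, `family`, `bitscore`, `evalue`, `signal`),
#'   and per-locus columns `has_cyclase`, `has_hd`, `signals`
#'   (comma-separated) added to `loci`.
#' @export
annotate_loci <- function(locus_set, genes, hits, catalogue,
                          profiles = list(),
                          signal_mapping = default_signal_mapping(),
                          evalue_ceiling = 1e-4, max_rn_len = 250) {
  loci <- locus_set$loci
  members <- locus_set$members
  gidx <- match(members$gene_id, genes$gene_id)
  rn_all <- NULL; eff_all <- NULL
  for (lid in loci$locus_id) {
    mg <- genes[gidx[members$locus_id == lid], , drop = FALSE]
    calls <- annotate_members(mg, hits, catalogue, evalue_ceiling,
                              max_rn_len)
    if (nrow(calls$rns) > 0L) {
      calls$rns$locus_id <- lid
      rn_all <- rbind(rn_all, calls$rns)
    }
    if (nrow(calls$effectors) > 0L) {
      calls$effectors$locus_id <- lid
      eff_all <- rbind(eff_all, calls$effectors)
    }
  }
  rns <- rn_all %||% data.frame(
    gene_id = character(), family = character(), bitscore = numeric(),
    evalue = numeric(), locus_id = character(), stringsAsFactors = FALSE)
  effectors <- eff_all %||% data.frame(
    gene_id = character(), family = character(), bitscore = numeric(),
    evalue = numeric(), locus_id = character(), stringsAsFactors = FALSE)
  # conserved-residue screen
  rns$screen_status <- rep("not_screened", nrow(rns))
  rns$missing_positions <- rep("", nrow(rns))
  if (nrow(rns) > 0L) {
    seqs <- genes$protein_seq[match(rns$gene_id, genes$gene_id)]
    for (i in seq_len(nrow(rns))) {
      prof <- profiles[[rns$family[i]]]
      if (is.null(prof)) next
      sc <- screen_candidate(seqs[i], prof)
      rns$screen_status[i] <- sc$status
      if (nrow(sc$missing_positions) > 0L)
        rns$missing_positions[i] <- paste(
          sprintf("%d:%s", sc$missing_positions$column,
                  sc$missing_positions$expected), collapse = ";")
    }
  }
  # effector signals
  if (nrow(effectors) > 0L) {
    effectors$signal <- unname(signal_mapping[effectors$family])
    effectors$signal[is.na(effectors$signal)] <- "unknown"
  } else effectors$signal <- character()
  # per-locus cas10 motifs and signal set
  anchor_seq <- genes$protein_seq[match(loci$anchor_gene, genes$gene_id)]
  c10 <- lapply(anchor_seq, annotate_cas10)
  loci$has_cyclase <- vapply(c10, `[[`, logical(1), "has_cyclase")
  loci$has_hd <- vapply(c10, `[[`, logical(1), "has_hd")
  loci$signals <- vapply(loci$locus_id, function(lid) {
    fam <- effectors$family[effectors$locus_id == lid]
    paste(infer_signals(fam, signal_mapping), collapse = ",")
  }, character(1))
  structure(list(loci = loci, members = members,
                 rns = rns[, c("locus_id", "gene_id", "family", "bitscore",
                               "evalue", "screen_status",
                               "missing_positions")],
                 effectors = effectors[, c("locus_id", "gene_id", "family",
                                           "bitscore", "evalue", "signal")]),
            class = "rn_annotated_loci")
}

#' @export
print.rn_annotated_loci <- function(x, ...) {
  cat(sprintf(
    "<rn_annotated_loci> %d loci, %d RN annotations (%d pass), %d effectors\n",
    nrow(x$loci), nrow(x$rns), sum(x$rns$screen_status == "pass"),
    nrow(x$effectors)))
  invisible(x)
}

#' Screen a whole proteome for ring nucleases, ignoring locus context
#'
#' Applies the same per-gene RN call (length cutoff, e-value ceiling,
#' cross-annotation against effector hits) and conserved-residue screen as
#' the locus pipeline, but over every gene. Used for genome-wide background
#' frequencies and for phage proteome scans.
#'
#' @inheritParams annotate_loci
#' @param genes gene table (any genomes/proteomes).
#' @return data frame (`genome_id`, `gene_id`, `family`, `bitscore`,
#'   `evalue`, `screen_status`).
#' @export
screen_proteome_rns <- function(genes, hits, catalogue, profiles = list(),
                                evalue_ceiling = 1e-4, max_rn_len = 250) {
  calls <- annotate_members(genes, hits, catalogue, evalue_ceiling,
                            max_rn_len)
  rns <- calls$rns
  rns$genome_id <- genes$genome_id[match(rns$gene_id, genes$gene_id)]
  rns$screen_status <- rep("not_screened", nrow(rns))
  if (nrow(rns) > 0L) {
    seqs <- genes$protein_seq[match(rns$gene_id, genes$gene_id)]
    for (i in seq_len(nrow(rns))) {
      prof <- profiles[[rns$family[i]]]
      if (is.null(prof)) next
      rns$screen_status[i] <- screen_candidate(seqs[i], prof)$status
    }
  }
  rns[, c("genome_id", "gene_id", "family", "bitscore", "evalue",
          "screen_status")]
}
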