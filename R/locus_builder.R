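#' Find Cas10 anchor genes
#'
#' A gene anchors a type III CRISPR locus when it carries at least one hit
#' from a Cas10 profile at or below the e-value ceiling. Each gene is
#' reported once however many Cas10-profile hits it has.
#'
#' @param genes gene table.
#' @param hits hit table ([parse_domtbl()] layout).
#' @param catalogue an `rn_catalogue`.
#' @param evalue_ceiling maximum e-value for a hit to count (default 1e-4).
#' @return subset of `genes` rows that anchor a locus, with an extra
#'   `cas10_bitscore` column (best Cas10-profile bit score).
#' @export
find_cas10_anchors <- function(genes, hits, catalogue,
                               evalue_ceiling = 1e-4) {
  h <- hits[hits$family_id %in% catalogue$cas10_profiles &
              hits$evalue <= evalue_ceiling, , drop = FALSE]
  if (nrow(h) == 0L || nrow(genes) == 0L) {
    out <- genes[0, , drop = FALSE]; out$cas10_bitscore <- numeric()
    return(out)
  }
  best <- tapply(h$bitscore, h$protein_id, max)
  out <- genes[genes$gene_id %in% names(best), , drop = FALSE]
  out$cas10_bitscore <- as.numeric(best[out$gene_id])
  out[order(out$genome_id, out$contig_id, out$start), , drop = FALSE]
}

#' Chain the cas operon span around a Cas10 anchor
#'
#' The cas span is the smallest interval covering the anchor and every gene
#' with a cas-core-profile hit reachable from the anchor by steps of
#' intergenic gap at most `chain_gap`: the span is grown to a fixpoint,
#' absorbing any cas gene within `chain_gap` of the current extent, which
#' for interval proximity equals the transitive closure of the pairwise
#' gap graph.
#'
#' @param anchor single-row gene table (the Cas10 gene).
#' @param genes gene table for the same contig set.
#' @param hits hit table.
#' @param catalogue an `rn_catalogue`.
#' @param chain_gap maximum intergenic gap in bp between chained cas genes
#'   (default 500).
#' @param evalue_ceiling maximum hit e-value.
#' @return named integer vector `c(start =, end =)` in bp.
#' @export
build_cas_span <- function(anchor, genes, hits, catalogue,
                           chain_gap = 500, evalue_ceiling = 1e-4) {
  cas_profiles <- unique(c(catalogue$cas10_profiles,
                           catalogue$cas_accessory_profiles))
  h <- hits[hits$family_id %in% cas_profiles &
              hits$evalue <= evalue_ceiling, , drop = FALSE]
  cand <- genes[genes$gene_id %in% h$protein_id &
                  genes$genome_id == anchor$genome_id &
                  genes$contig_id == anchor$contig_id, , drop = FALSE]
  if (!anchor$gene_id %in% cand$gene_id)
    cand <- rbind(cand, genes[genes$gene_id == anchor$gene_id, ,
                              drop = FALSE])
  # grow the span to a fixpoint: absorb any cas gene within chain_gap of
  # the current extent; for interval-proximity graphs this equals the
  # transitive closure of the pairwise gap relation
  in_set <- cand$gene_id == anchor$gene_id
  lo <- min(cand$start[in_set]); hi <- max(cand$end[in_set])
  repeat {
    gaps <- interval_gap(cand$start, cand$end, lo, hi)
    add <- !in_set & gaps <= chain_gap
    if (!any(add)) break
    in_set <- in_set | add
    lo <- min(cand$start[in_set]); hi <- max(cand$end[in_set])
  }
  c(start = as.integer(lo), end = as.integer(hi))
}

#' Extend a cas span into its search neighborhood
#'
#' The neighborhood is the cas span widened by `window` bp on each side,
#' clipped to the contig; every protein-coding gene overlapping it is a
#' candidate RN/effector carrier.
#'
#' @param cas_span named vector `c(start =, end =)`.
#' @param contig_length contig length in bp.
#' @param window extension in bp each side (default 6000).
#' @return named integer vector `c(start =, end =)`.
#' @export
build_neighborhood <- function(cas_span, contig_length, window = 6000) {
  c(start = as.integer(max(1L, cas_span[["start"]] - window)),
    end = as.integer(min(contig_length, cas_span[["end"]] + window)))
}

#' Merge loci whose cas spans overlap
#'
#' Two Cas10 anchors inside one chained operon produce overlapping spans;
#' these are collapsed into a single locus covering the union span, whose
#' anchor is the Cas10 with the best bit score. Merging is transitive.
#'
#' @param loci locus table (`build_loci()` layout, before membership).
#' @return locus table with overlapping-span loci merged.
#' @export
merge_overlapping_loci <- function(loci) {
  if (nrow(loci) <= 1L) return(loci)
  out <- NULL
  for (key in unique(paste(loci$genome_id, loci$contig_id, sep = "\r"))) {
    sub <- loci[paste(loci$genome_id, loci$contig_id, sep = "\r") == key, ,
                drop = FALSE]
    sub <- sub[order(sub$span_start, sub$span_end), , drop = FALSE]
    grp <- integer(nrow(sub)); g <- 1L; grp[1] <- 1L
    hi <- sub$span_end[1]
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      if (sub$span_start[i] <= hi) grp[i] <- g
      else { g <- g + 1L; grp[i] <- g }
      hi <- max(hi, sub$span_end[i])
    }
    merged <- do.call(rbind, lapply(split(sub, grp), function(d) {
      best <- which.max(d$cas10_bitscore)
      r <- d[best, , drop = FALSE]
      r$span_start <- min(d$span_start); r$span_end <- max(d$span_end)
      r
    }))
    out <- rbind(out, merged)
  }
  rownames(out) <- NULL
  out[order(out$genome_id, out$contig_id, out$span_start), , drop = FALSE]
}

#' Assign genes to locus neighborhoods
#'
#' A gene is a member of a locus when its interval overlaps the locus
#' neighborhood by at least 1 bp. A gene overlapping several neighborhoods
#' goes to the locus with the smaller gap to its cas span (gap 0 when the
#' gene overlaps the span itself); ties break toward the lexicographically
#' smaller `locus_id`. Strand is ignored. Genes inside a cas span are
#' always members of that locus.
#'
#' @param loci locus table with `nb_start`/`nb_end` columns.
#' @param genes gene table.
#' @return data frame (`locus_id`, `gene_id`) of memberships.
#' @export
assign_members <- function(loci, genes) {
  if (nrow(loci) == 0L || nrow(genes) == 0L)
    return(data.frame(locus_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  res <- vector("list", nrow(genes)); n <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cand <- loci[loci$genome_id == g$genome_id &
                   loci$contig_id == g$contig_id &
                   intervals_overlap(loci$nb_start, loci$nb_end,
                                     g$start, g$end), , drop = FALSE]
    if (nrow(cand) == 0L) next
    gap <- interval_gap(cand$span_start, cand$span_end, g$start, g$end)
    cand <- cand[order(gap, cand$locus_id), , drop = FALSE]
    n <- n + 1L
    res[[n]] <- data.frame(locus_id = cand$locus_id[1], gene_id = g$gene_id,
                           stringsAsFactors = FALSE)
  }
  if (n == 0L)
    return(data.frame(locus_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, res[seq_len(n)])
}

#' Build Cas10-anchored loci from genes and hits
#'
#' End-to-end locus discovery: find Cas10 anchors, chain each cas span,
#' merge overlapping spans, derive the 6 kbp neighborhood (clipped at
#' contig ends) and assign member genes.
#'
#' @param genes gene table.
#' @param hits hit table.
#' @param catalogue an `rn_catalogue`.
#' @param contig_lengths named integer vector, contig id -> length in bp.
#' @param window neighborhood half-width in bp (default 6000).
#' @param chain_gap cas-operon chaining gap in bp (default 500).
#' @param evalue_ceiling maximum hit e-value (default 1e-4).
#' @param subtype_table optional data frame (`genome_id`, `contig_id`,
#'   `start`, `end`, `subtype`): a locus takes the subtype of an interval
#'   overlapping its cas span.
#' @param subtype_overrides optional data frame (`locus_id`, `subtype`) of
#'   manual corrections applied last.
#' @return list of class `rn_locus_set`: `loci` (one row per locus:
#'   `locus_id`, `genome_id`, `contig_id`, `anchor_gene`,
#'   `cas10_bitscore`, `span_start`, `span_end`, `nb_start`, `nb_end`,
#'   `subtype`) and `members` (`locus_id`, `gene_id`).
#' @export
build_loci <- function(genes, hits, catalogue, contig_lengths,
                       window = 6000, chain_gap = 500,
                       evalue_ceiling = 1e-4,
                       subtype_table = NULL, subtype_overrides = NULL) {
  anchors <- find_cas10_anchors(genes, hits, catalogue, evalue_ceiling)
  if (nrow(anchors) == 0L) {
    loci <- data.frame(locus_id = character(), genome_id = character(),
                       contig_id = character(), anchor_gene = character(),
                       cas10_bitscore = numeric(),
                       span_start = integer(), span_end = integer(),
                       nb_start = integer(), nb_end = integer(),
                       subtype = character(), stringsAsFactors = FALSE)
    return(structure(list(loci = loci,
                          members = assign_members(loci, genes)),
                     class = "rn_locus_set"))
  }
  spans <- t(vapply(seq_len(nrow(anchors)), function(i)
    build_cas_span(anchors[i, ], genes, hits, catalogue,
                   chain_gap, evalue_ceiling),
    integer(2)))
  loci <- data.frame(
    locus_id = NA_character_,
    genome_id = anchors$genome_id, contig_id = anchors$contig_id,
    anchor_gene = anchors$gene_id, cas10_bitscore = anchors$cas10_bitscore,
    span_start = spans[, "start"], span_end = spans[, "end"],
    stringsAsFactors = FALSE)
  loci <- merge_overlapping_loci(loci)
  # stable ids: per genome, ordered by contig then span start
  ord <- order(loci$genome_id, loci$contig_id, loci$span_start)
  loci <- loci[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(loci)), loci$genome_id, FUN = seq_along)
  loci$locus_id <- sprintf("%s_L%02d", loci$genome_id, idx)
  cl <- contig_lengths[loci$contig_id]
  if (anyNA(cl))
    stop_fmt("missing contig length for: %s",
             paste(unique(loci$contig_id[is.na(cl)]), collapse = ", "))
  loci$nb_start <- pmax(1L, loci$span_start - as.integer(window))
  loci$nb_end <- pmin(as.integer(cl), loci$span_end + as.integer(window))
  loci$subtype <- NA_character_
  if (!is.null(subtype_table) && nrow(subtype_table) > 0L) {
    for (i in seq_len(nrow(loci))) {
      st <- subtype_table[
        subtype_table$genome_id == loci$genome_id[i] &
          subtype_table$contig_id == loci$contig_id[i] &
          intervals_overlap(subtype_table$start, subtype_table$end,
                            loci$span_start[i], loci$span_end[i]), ,
        drop = FALSE]
      if (nrow(st) > 0L) loci$subtype[i] <- st$subtype[1]
    }
  }
  if (!is.null(subtype_overrides) && nrow(subtype_overrides) > 0L) {
    m <- match(loci$locus_id, subtype_overrides$locus_id)
    loci$subtype[!is.na(m)] <- subtype_overrides$subtype[m[!is.na(m)]]
  }
  structure(list(loci = loci, members = assign_members(loci, genes)),
            class = "rn_locus_set")
}

#' @export
print.rn_locus_set <- function(x, ...) {
  cat(sprintf("<rn_locus_set> %d loci, %d member genes\n",
              nrow(x$loci), nrow(x$members)))
  invisible(x)
}

#' Write the locus table as TSV
#'
#' @param locus_set an `rn_locus_set`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_locus_table <- function(locus_set, path) {
  write_tsv_table(locus_set$loci, path)
}
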