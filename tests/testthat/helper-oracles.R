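# Independent brute-force oracles and fixture builders. These deliberately
# re-derive results by the most direct route available (pairwise graph
# closure, per-gene scans, exhaustive DP) so they share no code with the
# implementation they check.

# --- affine-gap global alignment score, Gotoh three-state DP -------------
# gap of length L costs open + L * ext (matches the package's aligner
# convention)
gotoh_score <- function(p, s, open = 10, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62
  a <- strsplit(p, "")[[1]]; b <- strsplit(s, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in substitution
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in subject (deletion in s)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in pattern
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      sub <- B[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sub
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- cas-span via explicit transitive closure of the pairwise gap graph --
bf_cas_span <- function(anchor_id, cand, chain_gap) {
  n <- nrow(cand)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    gap <- max(0L, max(cand$start[i], cand$start[j]) -
                 min(cand$end[i], cand$end[j]) - 1L)
    adj[i, j] <- gap <= chain_gap
  }
  seen <- cand$gene_id == anchor_id
  repeat {
    new <- seen
    for (i in which(seen)) new <- new | adj[i, ]
    if (identical(new, seen)) break
    seen <- new
  }
  c(start = min(cand$start[seen]), end = max(cand$end[seen]))
}

# --- per-gene membership scan -------------------------------------------
bf_members <- function(loci, genes) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    best <- NULL; best_gap <- Inf
    for (k in seq_len(nrow(loci))) {
      l <- loci[k, ]
      if (l$genome_id != g$genome_id || l$contig_id != g$contig_id) next
      if (g$start > l$nb_end || g$end < l$nb_start) next
      gap <- if (g$start <= l$span_end && g$end >= l$span_start) 0 else
        max(l$span_start - g$end, g$start - l$span_end) - 1
      if (gap < best_gap ||
          (gap == best_gap && !is.null(best) && l$locus_id < best)) {
        best <- l$locus_id; best_gap <- gap
      }
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(locus_id = best,
                                            gene_id = g$gene_id)
  }
  if (length(out) == 0L)
    return(data.frame(locus_id = character(), gene_id = character()))
  do.call(rbind, out)
}

# --- pairwise locus-count of RN/effector family co-occurrence -----------
bf_edge_weights <- function(rns, effectors) {
  rns <- rns[rns$screen_status != "fail", , drop = FALSE]
  out <- list()
  for (r in unique(rns$family)) for (e in unique(effectors$family)) {
    w <- 0L
    for (l in unique(c(rns$locus_id, effectors$locus_id))) {
      if (any(rns$family == r & rns$locus_id == l) &&
          any(effectors$family == e & effectors$locus_id == l))
        w <- w + 1L
    }
    if (w > 0L)
      out[[length(out) + 1L]] <- data.frame(rn = r, effector = e,
                                            weight = w)
  }
  if (length(out) == 0L)
    return(data.frame(rn = character(), effector = character(),
                      weight = integer()))
  df <- do.call(rbind, out)
  df[order(df$rn, df$effector), , drop = FALSE]
}

# --- independent minimal domtbl line parser ------------------------------
bf_parse_domtbl <- function(path) {
  out <- NULL
  for (ln in readLines(path)) {
    if (grepl("^#", ln) || !nzchar(trimws(ln))) next
    f <- scan(text = ln, what = "character", quiet = TRUE)
    out <- rbind(out, data.frame(
      protein_id = f[1], family_id = f[4],
      evalue = as.numeric(f[13]), bitscore = as.numeric(f[14])))
  }
  out
}

# --- fixture builders ----------------------------------------------------
make_profiles <- function(ds, t_cons = 1.0, g_max = 0.2) {
  setNames(
    lapply(names(ds$msas), function(f)
      build_conservation_profile(ds$msas[[f]], family = f,
                                 t_cons = t_cons, g_max = g_max)),
    names(ds$msas))
}

run_full <- function(ds, ...) {
  catalogue <- family_catalogue()
  ls <- build_loci(ds$genes, ds$hits, catalogue, ds$contig_lengths,
                   subtype_table = ds$subtype_table, ...)
  annotate_loci(ls, ds$genes, ds$hits, catalogue,
                profiles = make_profiles(ds))
}

# hand-built annotated-locus object for the co-occurrence stage
make_annotated <- function(loci_ids, rns, effectors,
                           genome_ids = sub("_L.*", "", loci_ids)) {
  n <- length(loci_ids)
  loci <- data.frame(
    locus_id = loci_ids, genome_id = genome_ids,
    contig_id = sprintf("%s_c1", genome_ids),
    anchor_gene = sprintf("%s_cas10", loci_ids),
    subtype = rep("III-A", n), has_cyclase = rep(TRUE, n),
    has_hd = rep(FALSE, n), signals = rep("", n),
    stringsAsFactors = FALSE)
  if (is.null(rns$screen_status)) rns$screen_status <- "pass"
  if (is.null(rns$gene_id) && nrow(rns) > 0)
    rns$gene_id <- sprintf("rn_g%03d", seq_len(nrow(rns)))
  if (is.null(effectors$gene_id) && nrow(effectors) > 0)
    effectors$gene_id <- sprintf("eff_g%03d", seq_len(nrow(effectors)))
  if (is.null(effectors$signal) && nrow(effectors) > 0)
    effectors$signal <- unname(default_signal_mapping()[effectors$family])
  structure(list(loci = loci,
                 members = data.frame(locus_id = character(),
                                      gene_id = character()),
                 rns = rns, effectors = effectors),
            class = "rn_annotated_loci")
}

empty_rns <- function() data.frame(locus_id = character(),
                                   gene_id = character(),
                                   family = character(),
                                   screen_status = character(),
                                   stringsAsFactors = FALSE)
empty_effs <- function() data.frame(locus_id = character(),
                                    gene_id = character(),
                                    family = character(),
                                    signal = character(),
                                    stringsAsFactors = FALSE)

random_aa <- function(n) paste(sample(c("A","C","D","E","F","G","H","I",
                                        "K","L","M","N","P","Q","R","S",
                                        "T","V","W","Y"), n, replace = TRUE),
                               collapse = "")
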