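#' Parse a HMMER per-domain hit table (domtblout)
#'
#' Reads the whitespace-delimited per-domain tabular output of a profile
#' search, one row per domain hit, skipping `#`-prefixed comment lines.
#' The search-direction convention is that of `hmmsearch`: the target is
#' the protein, the query is the profile. Per row the parser keeps the
#' protein id (column 1), the profile name (column 4), the
#' per-domain independent e-value (column 13), the per-domain bit score
#' (column 14) and the alignment coordinates on the protein
#' (columns 18-19). Profile names are kept raw; mapping onto families is a
#' downstream concern ([map_profile_family()]).
#'
#' @param path path to a domtblout file.
#' @return data frame with columns `protein_id`, `family_id`, `bitscore`,
#'   `evalue`, `ali_start`, `ali_end`.
#' @export
parse_domtbl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (length(keep) == 0L) return(empty_hit_table())
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 19L)
      stop_fmt("%s line %d: expected >=19 fields, found %d",
               path, i, length(f))
    num <- suppressWarnings(as.numeric(f[c(13, 14, 18, 19)]))
    if (anyNA(num))
      stop_fmt("%s line %d: non-numeric score/e-value/coordinate field",
               path, i)
    data.frame(protein_id = f[1], family_id = f[4],
               bitscore = num[2], evalue = num[1],
               ali_start = as.integer(num[3]), ali_end = as.integer(num[4]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bad <- out$evalue < 0
  if (any(bad))
    stop_fmt("%s: negative e-value on data row %d", path, which(bad)[1])
  out
}

empty_hit_table <- function() {
  data.frame(protein_id = character(), family_id = character(),
             bitscore = numeric(), evalue = numeric(),
             ali_start = integer(), ali_end = integer(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in HMMER per-domain tabular format
#'
#' Emits the 23-column `domtblout` layout that [parse_domtbl()] reads
#' (protein as target, profile as query); unused numeric columns are
#' filled with neutral values. Round-tripping preserves the parsed fields.
#'
#' @param hits hit table (`protein_id`, `family_id`, `bitscore`, `evalue`,
#'   `ali_start`, `ali_end`).
#' @param path output path.
#' @param target_lengths optional named integer vector of protein lengths.
#' @return invisibly, `path`.
#' @export
write_domtbl <- function(hits, path, target_lengths = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
    con)
  if (nrow(hits) > 0L) {
    tlen <- if (is.null(target_lengths)) rep(0L, nrow(hits)) else
      as.integer(target_lengths[hits$protein_id])
    tlen[is.na(tlen)] <- 0L
    writeLines(sprintf(
      "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.99 -",
      hits$protein_id, tlen, hits$family_id,
      pmax(1L, hits$ali_end - hits$ali_start + 1L),
      hits$evalue, hits$bitscore, hits$evalue, hits$evalue, hits$bitscore,
      pmax(1L, hits$ali_end - hits$ali_start + 1L),
      hits$ali_start, hits$ali_end, hits$ali_start, hits$ali_end), con)
  }
  invisible(path)
}
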