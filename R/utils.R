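#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.delim write.table head
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Intergenic gap between two 1-based inclusive intervals (0 when they touch
# or overlap).
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1, s2) - pmin(e1, e2) - 1L)
}

intervals_overlap <- function(s1, e1, s2, e2) {
  s1 <= e2 & s2 <= e1
}

#' Write a result table as tab-separated text
#'
#' All pipeline writers emit UTF-8 TSV with a single header row and no
#' quoting or row names.
#'
#' @param df data frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated result table
#'
#' @param path path to a TSV with a single header row.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
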