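#' Read protein-coding genes from GFF3 + protein FASTA
#'
#' Builds the gene table the pipeline operates on: one row per CDS feature,
#' with 1-based inclusive coordinates taken verbatim from the GFF3 and the
#' translated sequence looked up in a paired protein FASTA keyed by the
#' feature `ID` (or `locus_tag`). Genome translation is deliberately out of
#' scope: proteome + GFF archives ship the translations.
#'
#' Features whose ID has no entry in the FASTA are reported with a warning
#' and dropped. Records with start > end or an unknown strand symbol raise
#' an error naming the offending line number.
#'
#' @param gff_path path to a GFF3 file.
#' @param faa_path path to a protein FASTA whose names are CDS IDs.
#' @param genome_id genome identifier stored on every returned row; defaults
#'   to the GFF file name without extension.
#' @return data frame with columns `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `protein_seq`, `length_aa`.
#' @export
read_genome_annotation <- function(gff_path, faa_path,
                                   genome_id = sub("\\.gff3?$", "",
                                                   basename(gff_path))) {
  validate_gff_records(gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) return(empty_gene_table())
  ids <- as.character(gr$ID)
  if (anyNA(ids) && !is.null(gr$locus_tag))
    ids[is.na(ids)] <- as.character(gr$locus_tag)[is.na(ids)]
  if (anyNA(ids))
    stop_fmt("%d CDS feature(s) in %s lack an ID/locus_tag attribute",
             sum(is.na(ids)), gff_path)
  if (anyDuplicated(ids))
    stop_fmt("duplicate CDS IDs in %s: %s", gff_path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  prot <- Biostrings::readAAStringSet(faa_path)
  names(prot) <- sub("\\s.*$", "", names(prot))
  seqs <- as.character(prot)[ids]
  missing <- is.na(seqs)
  if (any(missing)) {
    warn_fmt("dropping %d CDS feature(s) without a protein sequence: %s",
             sum(missing),
             paste(head(ids[missing], 5L), collapse = ", "))
    gr <- gr[!missing]; ids <- ids[!missing]; seqs <- seqs[!missing]
  }
  if (length(gr) == 0L) return(empty_gene_table())
  data.frame(
    gene_id = ids,
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_seq = unname(seqs),
    length_aa = nchar(unname(seqs)),
    stringsAsFactors = FALSE)
}

# Light record-level validation pass over the raw GFF3 lines so that
# malformed coordinates and strand symbols are reported with line numbers,
# which the structured importer cannot do.
validate_gff_records <- function(gff_path) {
  lines <- readLines(gff_path, warn = FALSE)
  data_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in data_idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) next
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (!is.na(s) && !is.na(e) && s > e)
      stop_fmt("%s line %d: start (%d) > end (%d)", gff_path, i, s, e)
    if (!f[7] %in% c("+", "-", ".", "?"))
      stop_fmt("%s line %d: unknown strand symbol '%s'", gff_path, i, f[7])
  }
  invisible(TRUE)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), genome_id = character(),
             contig_id = character(), start = integer(), end = integer(),
             strand = character(), protein_seq = character(),
             length_aa = integer(), stringsAsFactors = FALSE)
}

#' Write a gene table as GFF3 + protein FASTA
#'
#' Inverse of [read_genome_annotation()]; round-tripping preserves every
#' field. One pair of files per call (one genome).
#'
#' @param genes gene table (one genome).
#' @param gff_path output GFF3 path.
#' @param faa_path output protein FASTA path.
#' @param contig_lengths optional named integer vector of contig lengths,
#'   written as `##sequence-region` directives.
#' @return invisibly, `gff_path`.
#' @export
write_genome_annotation <- function(genes, gff_path, faa_path,
                                    contig_lengths = NULL) {
  if (nrow(genes) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$contig_id,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      strand = genes$strand)
    gr$type <- "CDS"
    gr$ID <- genes$gene_id
    gr$phase <- 0L
    if (!is.null(contig_lengths))
      GenomeInfoDb::seqlengths(gr) <- contig_lengths[
        GenomeInfoDb::seqlevels(gr)]
    rtracklayer::export(gr, gff_path, format = "gff3")
    aa <- Biostrings::AAStringSet(genes$protein_seq)
    names(aa) <- genes$gene_id
    Biostrings::writeXStringSet(aa, faa_path)
  } else {
    writeLines("##gff-version 3", gff_path)
    file.create(faa_path)
  }
  invisible(gff_path)
}
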