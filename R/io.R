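# Plain-text interchange: FASTA, BED, TSV truth tables.

#' Write and read chromosome sequences
#' @param seqs a `Biostrings::DNAStringSet`.
#' @param path FASTA path.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write gene models or segments as BED6
#'
#' Intervals are already 0-based half-open internally, so they are written
#' as-is.  For segments the score column is mean coverage x 10, rounded.
#'
#' @param x data.frame with `chrom`, `start`, `end`, `strand` and either
#'   `gene_id` or `name` (+ optional `mean_cov`).
#' @param path output path.
#' @export
write_bed6 <- function(x, path) {
  name <- if ("gene_id" %in% names(x)) x$gene_id
          else if ("name" %in% names(x)) x$name else "."
  score <- if ("mean_cov" %in% names(x)) round(x$mean_cov * 10) else 0L
  data.table::fwrite(data.table::data.table(x$chrom, x$start, x$end, name,
                                            score, x$strand),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  b <- data.table::fread(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "name",
                                       "score", "strand"))
  as.data.frame(b)
}

#' Write / read the simulation truth table
#'
#' One TSV per entity class under `dir`; [read_truth()] restores all fields
#' exactly (the round-trip is covered by the test suite).
#'
#' @param truth list with any of `genes`, `sites`, `lsvs` data.frames.
#' @param dir output directory (created).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in intersect(c("genes", "sites", "lsvs"), names(truth)))
    data.table::fwrite(truth[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t")
  invisible(dir)
}

#' @rdname write_truth
#' @export
read_truth <- function(dir) {
  out <- list()
  for (nm in c("genes", "sites", "lsvs")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (file.exists(p))
      out[[nm]] <- as.data.frame(data.table::fread(p, sep = "\t"))
  }
  out
}

#' Write / read a count matrix with row names
#' @param counts matrix with gene rownames and sample colnames.
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  dt <- data.table::data.table(gene_id = rownames(counts))
  for (cn in colnames(counts)) dt[[cn]] <- counts[, cn]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}
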