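#' Strand-specific coverage tracks
#'
#' A `coverage_track` holds non-negative, base-resolution coverage over a set
#' of chromosomes, one run-length-encoded vector per chromosome per strand.
#' Coordinates are 0-based half-open: the value for base `i` (0-based) is
#' element `i + 1` of the decoded vector.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bases).
#' @return an object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_lengths) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0))
  empty <- lapply(chrom_lengths, function(n) S4Vectors::Rle(0, n))
  structure(list(chroms = chrom_lengths,
                 cov = list(`+` = empty, `-` = empty)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$chroms), "chromosome(s),",
      format(sum(as.numeric(x$chroms)), big.mark = ","), "bases\n")
  for (ch in names(x$chroms)) {
    cat(sprintf("  %s (%d nt): total + %.0f / - %.0f\n", ch, x$chroms[[ch]],
                sum(x$cov[["+"]][[ch]]), sum(x$cov[["-"]][[ch]])))
  }
  invisible(x)
}

#' Get or set per-chromosome coverage
#'
#' @param track a `coverage_track`.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param value numeric vector or `Rle` of length equal to the chromosome.
#' @return `cov_get` returns an `S4Vectors::Rle`; `cov_set` the updated track.
#' @export
cov_get <- function(track, chrom, strand) {
  stopifnot(inherits(track, "coverage_track"), strand %in% c("+", "-"),
            chrom %in% names(track$chroms))
  track$cov[[strand]][[chrom]]
}

#' @rdname cov_get
#' @export
cov_set <- function(track, chrom, strand, value) {
  stopifnot(inherits(track, "coverage_track"), strand %in% c("+", "-"),
            chrom %in% names(track$chroms))
  if (!is(value, "Rle")) value <- S4Vectors::Rle(value)
  if (length(value) != track$chroms[[chrom]])
    stop("coverage length does not match chromosome length")
  track$cov[[strand]][[chrom]] <- value
  track
}

#' Sum coverage over a 0-based half-open interval
#'
#' @inheritParams cov_get
#' @param start,end 0-based half-open interval bounds.
#' @export
cov_window_sum <- function(track, chrom, strand, start, end) {
  stopifnot(start < end, start >= 0, end <= track$chroms[[chrom]])
  sum(S4Vectors::window(cov_get(track, chrom, strand), start + 1L, end))
}

#' Decode a window of coverage as a plain numeric vector
#'
#' @inheritParams cov_window_sum
#' @export
cov_window <- function(track, chrom, strand, start, end) {
  stopifnot(start < end, start >= 0, end <= track$chroms[[chrom]])
  as.numeric(S4Vectors::window(cov_get(track, chrom, strand), start + 1L, end))
}

#' Total coverage of a track (library-size proxy)
#' @param track a `coverage_track`.
#' @export
cov_total <- function(track) {
  tot <- 0
  for (s in c("+", "-")) for (ch in names(track$chroms))
    tot <- tot + sum(track$cov[[s]][[ch]])
  tot
}

#' Base-wise sum of coverage tracks
#'
#' Used to pool replicates of one state before segmentation.
#'
#' @param tracks list of `coverage_track` objects on the same chromosomes.
#' @return a `coverage_track` with the base-wise sum.
#' @export
sum_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  out <- tracks[[1]]
  if (length(tracks) == 1) return(out)
  for (tr in tracks[-1]) {
    if (!identical(tr$chroms, out$chroms))
      stop("coverage tracks have mismatched chromosome lengths")
    for (s in c("+", "-")) for (ch in names(out$chroms))
      out$cov[[s]][[ch]] <- out$cov[[s]][[ch]] + tr$cov[[s]][[ch]]
  }
  out
}

#' Scale a track by a positive constant
#' @param track a `coverage_track`.
#' @param k positive scalar.
#' @export
scale_track <- function(track, k) {
  stopifnot(k > 0)
  for (s in c("+", "-")) for (ch in names(track$chroms))
    track$cov[[s]][[ch]] <- track$cov[[s]][[ch]] * k
  track
}

#' Write / read a strand pair of bedGraph files
#'
#' One file per strand, 0-based half-open intervals, zero runs omitted.
#'
#' @param track a `coverage_track`.
#' @param prefix file prefix; files `<prefix>.plus.bedGraph` and
#'   `<prefix>.minus.bedGraph` are written.
#' @return `write_bedgraph_pair` returns the two paths invisibly;
#'   `read_bedgraph_pair` returns a `coverage_track`.
#' @export
write_bedgraph_pair <- function(track, prefix) {
  paths <- c(`+` = paste0(prefix, ".plus.bedGraph"),
             `-` = paste0(prefix, ".minus.bedGraph"))
  for (s in c("+", "-")) {
    rows <- lapply(names(track$chroms), function(ch) {
      r <- track$cov[[s]][[ch]]
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- ends - S4Vectors::runLength(r)
      vals <- S4Vectors::runValue(r)
      keep <- vals != 0
      data.table::data.table(chrom = ch, start = starts[keep],
                             end = ends[keep], value = vals[keep])
    })
    data.table::fwrite(data.table::rbindlist(rows), paths[[s]], sep = "\t",
                       col.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_bedgraph_pair
#' @param chrom_lengths named integer vector giving the chromosome space of
#'   the track being read.
#' @export
read_bedgraph_pair <- function(prefix, chrom_lengths) {
  track <- coverage_track(chrom_lengths)
  paths <- c(`+` = paste0(prefix, ".plus.bedGraph"),
             `-` = paste0(prefix, ".minus.bedGraph"))
  for (s in c("+", "-")) {
    bg <- data.table::fread(paths[[s]], header = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    if (nrow(bg) == 0) next
    for (ch in unique(bg$chrom)) {
      v <- numeric(chrom_lengths[[ch]])
      sub <- bg[bg$chrom == ch, ]
      for (i in seq_len(nrow(sub)))
        v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
      track <- cov_set(track, ch, s, v)
    }
  }
  track
}
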