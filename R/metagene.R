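# Metagene profiles of nascent coverage anchored at the TSS or TTS.

# strand-oriented genome window around a gene's anchor; NULL if out of range
anchor_window <- function(gene, anchor, w1, w2, chrom_len) {
  if (gene$strand == "+") {
    a <- if (anchor == "TTS") gene$end else gene$start
    lo <- a + w1; hi <- a + w2
  } else {
    a <- if (anchor == "TTS") gene$start else gene$end
    lo <- a - w2; hi <- a - w1
  }
  if (lo < 0 || hi > chrom_len) return(NULL)
  c(lo, hi)
}

#' Metagene coverage profile per state
#'
#' Builds the average scaled nascent-coverage profile around the TSS or TTS.
#' Gene filters (each optional input enables its filter): windows extended
#' around the anchor must not overlap any other gene's extended window; no
#' N-run longer than 20 bases in the window; expression of at least
#' `min_tpm` TPM in one of `tpm_states`; and at least `min_bin_frac` of
#' the gene-body-side bins (upstream of a TTS anchor, downstream of a TSS
#' anchor) non-zero in at least `min_samples` samples.  Per gene,
#' library-size-normalized coverage is averaged per bin across a state's
#' samples, scaled by the gene's maximal bin, then averaged across genes;
#' minus-strand windows are orientation-flipped so positive offsets are
#' always downstream.
#'
#' @param tracks named list of [coverage_track()] per sample.
#' @param design design matching `tracks`.
#' @param genes gene annotation.
#' @param anchor `"TTS"` (window -1/+5 kb, 50-bp bins) or `"TSS"` (window
#'   -1/+1 kb, 10-bp bins).
#' @param window length-2 window (nt relative to anchor); default by anchor.
#' @param bin bin width (nt); default by anchor.
#' @param seqs optional `DNAStringSet` enabling the N-gap filter.
#' @param tpm optional TPM matrix (genes x samples) enabling the
#'   expression filter.
#' @param min_tpm,tpm_states expression filter parameters.
#' @param min_bin_frac,min_samples coverage-breadth filter parameters.
#' @return object of class `metagene_profile`: list with `profile` (matrix
#'   states x bins, values in `[0, 1]`), `bin_start` (offsets), `n_genes`,
#'   `anchor`, `filter_counts`.
#' @export
metagene_profile <- function(tracks, design, genes,
                             anchor = c("TTS", "TSS"), window = NULL,
                             bin = NULL, seqs = NULL, tpm = NULL,
                             min_tpm = 25, tpm_states = c("SA", "IBA"),
                             min_bin_frac = 1 / 3, min_samples = 3L) {
  anchor <- match.arg(anchor)
  if (is.null(window)) window <- if (anchor == "TTS") c(-1000L, 5000L)
                                 else c(-1000L, 1000L)
  if (is.null(bin)) bin <- if (anchor == "TTS") 50L else 10L
  w1 <- window[1]; w2 <- window[2]
  stopifnot((w2 - w1) %% bin == 0)
  nbin <- (w2 - w1) %/% bin
  chrom_len <- tracks[[1]]$chroms

  wins <- lapply(seq_len(nrow(genes)), function(i)
    anchor_window(genes[i, ], anchor, w1, w2,
                  chrom_len[[genes$chrom[i]]]))
  in_range <- !vapply(wins, is.null, logical(1))

  # extended-interval overlap filter (gene body union window, any strand)
  no_overlap <- rep(TRUE, nrow(genes))
  for (ch in unique(genes$chrom)) {
    sel <- which(genes$chrom == ch & in_range)
    if (length(sel) < 2) next
    lo <- vapply(sel, function(i) min(wins[[i]][1], genes$start[i]),
                 numeric(1))
    hi <- vapply(sel, function(i) max(wins[[i]][2], genes$end[i]),
                 numeric(1))
    ir <- IRanges::IRanges(lo + 1, hi)
    ov <- IRanges::countOverlaps(ir, ir)
    no_overlap[sel] <- ov == 1
  }

  no_ngap <- rep(TRUE, nrow(genes))
  if (!is.null(seqs)) {
    for (i in which(in_range)) {
      sq <- as.character(Biostrings::subseq(seqs[[genes$chrom[i]]],
                                            wins[[i]][1] + 1, wins[[i]][2]))
      if (grepl("N{21,}", sq)) no_ngap[i] <- FALSE
    }
  }

  expressed <- rep(TRUE, nrow(genes))
  if (!is.null(tpm)) {
    st_means <- vapply(tpm_states, function(st)
      rowMeans(tpm[, design$sample[design$state == st], drop = FALSE]),
      numeric(nrow(tpm)))
    expressed <- apply(st_means >= min_tpm, 1, any)[genes$gene_id]
    expressed[is.na(expressed)] <- FALSE
  }

  cand <- which(in_range & no_overlap & no_ngap & expressed)
  norm <- 1e6 / vapply(tracks, cov_total, numeric(1))

  # binned, oriented, normalized coverage per candidate gene per sample
  binned <- array(NA_real_, c(length(cand), length(tracks), nbin))
  for (gi in seq_along(cand)) {
    i <- cand[gi]
    for (j in seq_along(tracks)) {
      v <- cov_window(tracks[[j]], genes$chrom[i], genes$strand[i],
                      wins[[i]][1], wins[[i]][2])
      if (genes$strand[i] == "-") v <- rev(v)
      binned[gi, j, ] <- colMeans(matrix(v * norm[j], nrow = bin))
    }
  }

  # coverage-breadth filter evaluated on the gene-body side of the window
  # (upstream of a TTS anchor, downstream of a TSS anchor): a gene without
  # readthrough legitimately has an empty downstream TTS window, and must
  # not be excluded for it
  offs <- seq(w1, w2 - bin, by = bin)
  body_bins <- if (anchor == "TTS") offs < 0 else offs >= 0
  if (!any(body_bins)) body_bins <- rep(TRUE, nbin)
  covered <- apply(binned[, , body_bins, drop = FALSE] > 0, c(1, 2),
                   mean) >= min_bin_frac
  breadth_ok <- rowSums(covered) >= min_samples
  use <- which(breadth_ok)
  filter_counts <- c(total = nrow(genes), in_range = sum(in_range),
                     non_overlapping = sum(in_range & no_overlap),
                     no_ngap = sum(in_range & no_overlap & no_ngap),
                     expressed = length(cand), breadth = length(use))
  if (!length(use))
    stop("no genes pass the metagene filters; counts: ",
         paste(names(filter_counts), filter_counts, sep = "=",
               collapse = ", "))

  states <- levels(design$state)
  prof <- matrix(NA_real_, length(states), nbin,
                 dimnames = list(states, NULL))
  for (st in states) {
    js <- which(design$state == st)
    per_gene <- t(vapply(use, function(gi) {
      m <- matrix(binned[gi, js, ], nrow = length(js))
      v <- colMeans(m)
      mx <- max(v)
      if (mx > 0) v / mx else rep(NA_real_, nbin)
    }, numeric(nbin)))
    prof[st, ] <- colMeans(per_gene, na.rm = TRUE)
  }
  structure(list(profile = prof, bin_start = seq(w1, w2 - bin, by = bin),
                 n_genes = length(use), anchor = anchor, bin = bin,
                 filter_counts = filter_counts),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: anchor %s, %d genes, %d bins of %d nt\n",
              x$anchor, x$n_genes, ncol(x$profile), x$bin))
  invisible(x)
}
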