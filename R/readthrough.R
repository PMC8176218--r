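# 3' readthrough quantification and annotation revision.
# TTS coordinate: interval end for plus-strand genes, interval start for
# minus-strand genes (0-based half-open throughout).

gene_tts <- function(genes) ifelse(genes$strand == "+", genes$end, genes$start)

# index of the segment (same chrom/strand) covering each gene's 3'-end base,
# NA when none
match_tts_segment <- function(genes, segments) {
  idx <- rep(NA_integer_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sub <- which(segments$chrom == g$chrom & segments$strand == g$strand)
    if (!length(sub)) next
    if (g$strand == "+") {
      hit <- sub[segments$start[sub] <= g$end - 1L &
                 segments$end[sub] >= g$end]
    } else {
      hit <- sub[segments$start[sub] <= g$start &
                 segments$end[sub] > g$start]
    }
    if (length(hit)) idx[i] <- hit[1]
  }
  idx
}

#' Per-gene 3' extension beyond the annotated TTS
#'
#' A gene is eligible in a state iff a called segment overlaps its annotated
#' 3' end; the extension is the strand-aware distance from the TTS to the
#' segment's downstream boundary, floored at 0.
#'
#' @param genes gene annotation data.frame.
#' @param segments segment data.frame for one state
#'   ([call_transcribed_segments()]).
#' @param state optional label copied to the output (defaults to the
#'   segments' own label).
#' @return data.frame: `gene_id`, `state`, `eligible`, `extension`.
#' @export
compute_tts_extension <- function(genes, segments, state = NULL) {
  if (is.null(state))
    state <- if (nrow(segments)) segments$state[1] else NA_character_
  idx <- match_tts_segment(genes, segments)
  ext <- rep(NA_real_, nrow(genes))
  ok <- !is.na(idx)
  plus <- genes$strand == "+"
  ext[ok & plus] <- pmax(0, segments$end[idx[ok & plus]] -
                              genes$end[ok & plus])
  ext[ok & !plus] <- pmax(0, genes$start[ok & !plus] -
                               segments$start[idx[ok & !plus]])
  data.frame(gene_id = genes$gene_id, state = state, eligible = ok,
             extension = ext, stringsAsFactors = FALSE)
}

#' Distribution of segment 3' boundaries around the TTS
#'
#' Uses only genes whose 3' end is overlapped by a segment in EVERY state,
#' then bins the signed, strand-aware offset (downstream positive) of the
#' covering segment's 3' boundary from the annotated TTS.
#'
#' @param segments_by_state named list of per-state segment data.frames.
#' @param genes gene annotation.
#' @param window half-window in nt (default 20000, i.e. +/- 20 kb).
#' @param bin bin width in nt.
#' @return data.frame: `state`, `bin_start`, `bin_mid`, `count`; attribute
#'   `genes_used` lists the qualifying gene ids.
#' @export
tts_offset_distribution <- function(segments_by_state, genes,
                                    window = 20000L, bin = 50L) {
  stopifnot(length(segments_by_state) >= 2)
  recs <- lapply(names(segments_by_state), function(st)
    compute_tts_extension(genes, segments_by_state[[st]], state = st))
  names(recs) <- names(segments_by_state)
  elig <- Reduce(`&`, lapply(recs, `[[`, "eligible"))
  used <- genes$gene_id[elig]
  breaks <- seq(-window, window, by = bin)
  if (!any(elig)) {
    warning("no genes have segments covering the 3' end in every state")
    out <- data.frame(state = character(0), bin_start = numeric(0),
                      bin_mid = numeric(0), count = integer(0))
    attr(out, "genes_used") <- character(0)
    return(out)
  }
  rows <- lapply(names(recs), function(st) {
    off <- pmin(pmax(recs[[st]]$extension[elig], -window), window - 1e-9)
    cnt <- tabulate(findInterval(off, breaks), nbins = length(breaks) - 1)
    data.frame(state = st, bin_start = head(breaks, -1),
               bin_mid = head(breaks, -1) + bin / 2, count = cnt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "genes_used") <- used
  out
}

#' Mean extension difference between two states
#'
#' Restricted to genes eligible in both states; the standard error comes
#' from a nonparametric bootstrap over genes (paired resampling).
#'
#' @param records_a,records_b outputs of [compute_tts_extension()].
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return list: `delta_nt` (mean B - mean A), `se`, `n_genes`.
#' @export
mean_extension_difference <- function(records_a, records_b, n_boot = 1000L,
                                      seed = 1L) {
  common <- merge(records_a[records_a$eligible, c("gene_id", "extension")],
                  records_b[records_b$eligible, c("gene_id", "extension")],
                  by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(common) < 2)
    stop("insufficient data: fewer than 2 genes eligible in both states")
  d <- common$extension_b - common$extension_a
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i)
    mean(d[sample.int(length(d), replace = TRUE)]), numeric(1))
  list(delta_nt = mean(d), se = sd(boots), n_genes = nrow(common))
}

#' Elongation rate from a 3' shift over elapsed time
#'
#' Divides the polymerase displacement (nt) by the elapsed time (days) and
#' reports kb/min, both raw and rounded to one significant figure; a 2000 nt
#' shift over 5 days gives 0.000278, rounding to 0.0003 kb/min.
#'
#' @param delta_nt displacement in nt.
#' @param delta_days elapsed days (> 0).
#' @return list: `kb_per_min`, `rounded` (1 significant figure).
#' @export
elongation_rate <- function(delta_nt, delta_days) {
  if (delta_days <= 0) stop("delta_days must be positive")
  r <- (delta_nt / 1000) / (delta_days * 1440)
  list(kb_per_min = r, rounded = signif(r, 1))
}

#' Difference in mean days below the Tb threshold
#'
#' @param design_a,design_b design rows for the two states; each must carry
#'   `days_below8` (days with body temperature below 8 degrees C).
#' @return mean(B) - mean(A) in days.
#' @export
delta_days_below_threshold <- function(design_a, design_b) {
  if (!"days_below8" %in% names(design_a) ||
      !"days_below8" %in% names(design_b))
    stop("designs must carry a days_below8 column")
  mean(design_b$days_below8) - mean(design_a$days_below8)
}

#' Revise gene annotation using maximal called segments
#'
#' Per gene, if a segment overlapping the annotated 3' end extends further
#' 3', that boundary replaces the gene's; overlapping same-strand bodies are
#' then merged (names joined with `":"`); finally `tss_trim` nt are removed
#' downstream of each body's 5' end.  Bodies no longer than `min_len` are
#' dropped and logged.  Bodies containing more than one original gene are
#' kept but flagged `de_eligible = FALSE`.
#'
#' @param genes gene annotation.
#' @param max_segments maximal segments from
#'   [merge_segments_across_states()].
#' @param tss_trim nt removed at the 5' end (default 500).
#' @param min_len minimum body length retained (default 50).
#' @return data.frame: `name`, `chrom`, `start`, `end`, `strand`,
#'   `n_members`, `de_eligible`; attribute `dropped` lists dropped body
#'   names.
#' @export
revise_annotation <- function(genes, max_segments, tss_trim = 500L,
                              min_len = 50L) {
  g <- genes
  idx <- match_tts_segment(g, max_segments)
  ok <- !is.na(idx)
  plus <- g$strand == "+"
  ext_end <- ifelse(ok & plus, pmax(g$end, max_segments$end[idx]), g$end)
  ext_start <- ifelse(ok & !plus, pmin(g$start, max_segments$start[idx]),
                      g$start)
  bodies <- list()
  for (ch in unique(g$chrom)) {
    for (s in c("+", "-")) {
      sel <- which(g$chrom == ch & g$strand == s)
      if (!length(sel)) next
      ir <- IRanges::IRanges(ext_start[sel] + 1L, ext_end[sel])
      red <- IRanges::reduce(ir, with.revmap = TRUE)
      revmap <- S4Vectors::mcols(red)$revmap
      for (k in seq_along(red)) {
        members <- g$gene_id[sel[revmap[[k]]]]
        members <- members[order(ext_start[sel[revmap[[k]]]])]
        bodies[[length(bodies) + 1]] <- data.frame(
          name = paste(members, collapse = ":"), chrom = ch,
          start = IRanges::start(red)[k] - 1L, end = IRanges::end(red)[k],
          strand = s, n_members = length(members),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, bodies)
  # strand-aware 5' trim
  out$start <- ifelse(out$strand == "+", out$start + tss_trim, out$start)
  out$end <- ifelse(out$strand == "-", out$end - tss_trim, out$end)
  short <- out$end - out$start <= min_len
  dropped <- out$name[short]
  out <- out[!short, , drop = FALSE]
  out$de_eligible <- out$n_members == 1
  out <- out[order(out$chrom, out$strand, out$start), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Coverage-sum quantification over revised gene bodies
#'
#' @param bodies revised bodies from [revise_annotation()].
#' @param tracks named list of [coverage_track()] per sample.
#' @return numeric matrix, bodies x samples, of strand-matched coverage
#'   sums.
#' @export
quantify_gene_bodies <- function(bodies, tracks) {
  m <- matrix(0, nrow(bodies), length(tracks),
              dimnames = list(bodies$name, names(tracks)))
  for (j in seq_along(tracks)) {
    for (i in seq_len(nrow(bodies))) {
      m[i, j] <- cov_window_sum(tracks[[j]], bodies$chrom[i],
                                bodies$strand[i], bodies$start[i],
                                bodies$end[i])
    }
  }
  m
}

#' Transcripts per million
#'
#' @param counts matrix, features x samples.
#' @param lengths feature lengths in nt.
#' @return TPM matrix; every non-degenerate column sums to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  stopifnot(all(lengths > 0), nrow(counts) == length(lengths))
  rate <- counts / (lengths / 1000)
  cs <- colSums(rate)
  if (any(cs == 0)) {
    warning("all-zero column(s) in TPM input: ",
            paste(colnames(counts)[cs == 0], collapse = ", "))
    cs[cs == 0] <- 1
  }
  sweep(rate, 2, cs, "/") * 1e6
}
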