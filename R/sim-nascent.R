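# Nascent (run-on) coverage simulation.

# expected (noise-free) coverage for one sample on one chrom/strand
expected_strand_coverage <- function(L, genes_sub, truth_genes, state,
                                     plateau, background, dynamic_range) {
  v <- rep(background, L)
  if (nrow(genes_sub) == 0) return(v)
  lib <- pattern_library_rna()
  tg <- truth_genes[match(genes_sub$gene_id, truth_genes$gene_id), ]
  for (i in seq_len(nrow(genes_sub))) {
    g <- genes_sub[i, ]
    pat <- if ("pattern" %in% names(tg)) tg$pattern[i] else "flat"
    h <- plateau * pattern_level(pat, state, lib, dynamic_range)
    idx <- (g$start + 1):g$end
    v[idx] <- v[idx] + h
    # promoter-proximal (5') and TTS (3') polymerase accumulation peaks
    p5 <- min(150L, g$end - g$start)
    p3 <- min(200L, g$end - g$start)
    if (g$strand == "+") {
      v[(g$start + 1):(g$start + p5)] <- v[(g$start + 1):(g$start + p5)] + 2 * h
      v[(g$end - p3 + 1):g$end] <- v[(g$end - p3 + 1):g$end] + 1.5 * h
    } else {
      v[(g$end - p5 + 1):g$end] <- v[(g$end - p5 + 1):g$end] + 2 * h
      v[(g$start + 1):(g$start + p3)] <- v[(g$start + 1):(g$start + p3)] + 1.5 * h
    }
    # exponential readthrough tail, half-distance extension/3, truncated at
    # the true extension
    ext_col <- paste0("ext_", state)
    E <- if (ext_col %in% names(tg)) tg[[ext_col]][i] else 0
    if (!is.null(E) && !is.na(E) && E > 0) {
      d <- 0:(E - 1)
      tailv <- h * 2^(-3 * d / E)
      if (g$strand == "+") {
        v[(g$end + 1):(g$end + E)] <- v[(g$end + 1):(g$end + E)] + tailv
      } else {
        v[g$start:(g$start - E + 1)] <- v[g$start:(g$start - E + 1)] + tailv
      }
    }
  }
  v
}

#' Simulate strand-specific nascent coverage tracks
#'
#' Each sample's track is built gene by gene as a body plateau (height set by
#' the gene's pattern and the sample's state), a promoter-proximal 5' peak, a
#' 3' peak at the TTS, an exponentially decaying readthrough tail whose
#' length is the gene's true per-state extension, and Poisson intergenic
#' background.  With `noise = FALSE` the deterministic expected coverage is
#' emitted (the zero-noise oracle mode); with `noise = TRUE` every base is a
#' Poisson draw with that expectation.
#'
#' @param genes,truth from [build_genome()].
#' @param design a [state_design()]; one track per row.
#' @param seed integer seed.
#' @param background,plateau,noise,dynamic_range override the values stored
#'   in `truth$config`.
#' @return list with `tracks` (named list of [coverage_track()] per sample)
#'   and `design`.
#' @export
simulate_nascent <- function(genes, truth, design, seed = 1L,
                             background = NULL, plateau = NULL, noise = NULL,
                             dynamic_range = NULL) {
  cfg <- truth$config
  if (is.null(background)) background <- cfg$background
  if (is.null(plateau)) plateau <- cfg$plateau
  if (is.null(noise)) noise <- cfg$noise
  if (is.null(dynamic_range)) dynamic_range <- cfg$dynamic_range
  chrom_lengths <- setNames(rep(as.integer(cfg$chrom_length),
                                cfg$n_chromosomes),
                            sprintf("chr%d", seq_len(cfg$n_chromosomes)))
  if (is.null(genes))
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
  set.seed(seed)
  tracks <- vector("list", nrow(design))
  names(tracks) <- design$sample
  for (k in seq_len(nrow(design))) {
    tr <- coverage_track(chrom_lengths)
    st <- as.character(design$state[k])
    for (ch in names(chrom_lengths)) {
      for (s in c("+", "-")) {
        sub <- genes[genes$chrom == ch & genes$strand == s, , drop = FALSE]
        mu <- expected_strand_coverage(chrom_lengths[[ch]], sub,
                                       truth$genes, st, plateau, background,
                                       dynamic_range)
        v <- if (noise) rpois(length(mu), mu) else mu
        tr <- cov_set(tr, ch, s, v)
      }
    }
    tracks[[k]] <- tr
  }
  list(tracks = tracks, design = design)
}
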