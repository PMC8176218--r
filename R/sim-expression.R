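#' Simulate a gene-level count matrix
#'
#' Counts are negative binomial with mean `size_factor x sex_effect x
#' pattern-scaled expression level` and configured dispersion (dispersion 0
#' falls back to Poisson).  The pattern template is mapped onto
#' `[1/dynamic_range, 1]` of the gene's baseline expression, so a dynamic
#' gene spans an eight-fold range by default.  The sex effect multiplies
#' male samples.
#'
#' @param genes,truth from [build_genome()].
#' @param design a [state_design()].
#' @param seed integer seed.
#' @param dispersion,sex_effect,dynamic_range override `truth$config`.
#' @param patterns optional named character vector (per gene id) overriding
#'   the truth patterns, e.g. to decouple nascent from steady-state
#'   dynamics.
#' @return integer matrix, genes x samples.
#' @export
simulate_expression <- function(genes, truth, design, seed = 1L,
                                dispersion = NULL, sex_effect = NULL,
                                dynamic_range = NULL, patterns = NULL) {
  cfg <- truth$config
  if (is.null(dispersion)) dispersion <- cfg$nb_dispersion
  if (is.null(sex_effect)) sex_effect <- cfg$sex_effect
  if (is.null(dynamic_range)) dynamic_range <- cfg$dynamic_range
  tg <- truth$genes
  if (is.null(patterns)) {
    patterns <- setNames(tg$pattern, tg$gene_id)
  } else {
    stopifnot(all(tg$gene_id %in% names(patterns)))
    bad <- setdiff(unique(patterns),
                   c("flat", rownames(pattern_library_rna())))
    if (length(bad)) stop("unknown pattern name(s): ",
                          paste(bad, collapse = ", "))
  }
  lib <- pattern_library_rna()
  set.seed(seed)
  n <- nrow(tg)
  m <- nrow(design)
  counts <- matrix(0L, n, m, dimnames = list(tg$gene_id, design$sample))
  sex_mult <- ifelse(design$sex == "M", sex_effect, 1)
  for (j in seq_len(m)) {
    st <- as.character(design$state[j])
    lev <- vapply(seq_len(n), function(i)
      pattern_level(patterns[[tg$gene_id[i]]], st, lib, dynamic_range),
      numeric(1))
    mu <- design$size_factor[j] * sex_mult[j] * tg$expr_level * lev
    counts[, j] <- if (dispersion < 1e-12) rpois(n, mu)
                   else rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  counts
}

#' Simulate paired steady-state and nascent count matrices
#'
#' Two generator modes probe the transcription-vs-stability question.  In
#' `"transcription"` mode nascent dynamics share the steady-state patterns,
#' so fold changes across a seasonal transition correlate strongly between
#' assays.  In `"stability"` mode nascent patterns are drawn independently,
#' except that genes whose steady-state pattern peaks in the cold
#' (`Cold_high_*`) are forced to the mirrored `Cold_low_*` nascent pattern:
#' their RNA accumulates while transcription falls, the signature of
#' cold-stabilised transcripts (class `stable_RNA`).
#'
#' @param genome result of [build_genome()].
#' @param design_rna,design_nascent designs for the two assays.
#' @param mode `"transcription"` or `"stability"`.
#' @param seed integer seed.
#' @return list with `counts_rna`, `counts_nascent`, and `truth`
#'   (data.frame: `gene_id`, `pattern_rna`, `pattern_nascent`, `class`).
#' @export
simulate_concordance <- function(genome, design_rna, design_nascent,
                                 mode = c("transcription", "stability"),
                                 seed = 1L) {
  mode <- match.arg(mode)
  tg <- genome$truth$genes
  cfg <- genome$truth$config
  pat_rna <- setNames(tg$pattern, tg$gene_id)
  if (mode == "transcription") {
    pat_nas <- pat_rna
    cls <- ifelse(pat_rna == "flat", "flat", "concordant")
  } else {
    set.seed(seed + 104729L)
    pat_nas <- setNames(
      sample(names(cfg$pattern_mix), nrow(tg), replace = TRUE,
             prob = cfg$pattern_mix), tg$gene_id)
    stable <- startsWith(pat_rna, "Cold_high")
    pat_nas[stable] <- sub("Cold_high", "Cold_low", pat_rna[stable])
    cls <- ifelse(stable, "stable_RNA",
                  ifelse(pat_rna == "flat", "flat", "independent"))
  }
  counts_rna <- simulate_expression(genome$genes, genome$truth, design_rna,
                                    seed = seed, patterns = pat_rna)
  counts_nascent <- simulate_expression(genome$genes, genome$truth,
                                        design_nascent, seed = seed + 1L,
                                        patterns = pat_nas)
  list(counts_rna = counts_rna, counts_nascent = counts_nascent,
       truth = data.frame(gene_id = tg$gene_id,
                          pattern_rna = unname(pat_rna),
                          pattern_nascent = unname(pat_nas),
                          class = cls, stringsAsFactors = FALSE))
}
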