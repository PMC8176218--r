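#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator and validates it.
#' Defaults encode the study design being emulated: five physiological states
#' with five animals each for steady-state RNA and three each for nascent
#' transcription; per-state mean 3' readthrough extensions growing through
#' the torpor bout (Ent 300 < ET 600 < LT 2500 nt, so the injected ET to LT
#' shift is 1900 nt); negative-binomial counts (dispersion 0.05) following
#' the 14 reference patterns with ~30% of genes dynamic; A-to-G editing
#' elevated in arousal (rate 0.3 vs 0.05 elsewhere) plus genomic A/G
#' polymorphisms visible in both assays; and cold-shifted splicing.
#'
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_genes number of genes, distributed over chromosomes.
#' @param gene_length_range,intergenic_gap_range sampling ranges (bases).
#' @param strand_balance fraction of genes on the plus strand.
#' @param states ordered state labels of the steady-state design.
#' @param replicates_per_state animals per state (steady-state design).
#' @param seed integer seed used by [build_genome()].
#' @param extension_truth list with `mean` (named per-state readthrough in
#'   nt) and `sd` (per-gene jitter; states with mean 0 get exactly 0).
#' @param nb_dispersion negative-binomial dispersion of simulated counts.
#' @param pattern_mix named fractions per pattern (must include `flat` and
#'   sum to 1); `NULL` gives flat 0.70 and the rest split over the library.
#' @param editing list: `n_sites`, `n_polymorphic`, `rates` (named per-state
#'   editing rate), `depth` (mean per-sample depth).
#' @param splicing list: `n_lsv`, `junctions_per_lsv`, `cold_dpsi`,
#'   `ir_fraction`, `depth`.
#' @param motif list: `motif` (DNA-sense AU-rich core, default `"TATTTAT"`,
#'   i.e. UAUUUAU on the RNA), `density` named counts per gene class
#'   (`high`, `low`).
#' @param gc named per-class mean GC fraction (`high`, `low`).
#' @param utr5_length,utr3_length,intron_length,intron_fraction gene
#'   sub-structure used for editing-site region annotation.
#' @param tandem_pair,tandem_gap place the first two genes as a same-strand
#'   tandem pair separated by `tandem_gap` nt (readthrough-into-neighbour
#'   scenario).
#' @param n_gap_loci optional data.frame (`chrom`, `start`, `length`) of
#'   N-runs to insert (lengths must exceed 20).
#' @param background Poisson intergenic background rate for nascent
#'   coverage (reads/base).
#' @param plateau mean gene-body nascent coverage at full expression.
#' @param noise logical; `FALSE` emits deterministic expected coverage and
#'   is the zero-noise oracle mode.
#' @param expression_level lognormal `meanlog`/`sdlog` of per-gene baseline
#'   expression.
#' @param sex_effect multiplicative offset applied to male samples.
#' @param dynamic_range fold range between a pattern's low and high states.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 600000L,
                       n_genes = 60L,
                       gene_length_range = c(2000L, 4000L),
                       intergenic_gap_range = c(4000L, 8000L),
                       strand_balance = 0.5,
                       states = c("SA", "IBA", "Ent", "Ar", "SpD"),
                       replicates_per_state = 5L,
                       seed = 1L,
                       extension_truth = list(
                         mean = c(SA = 0, IBA = 0, Ent = 300, ET = 600,
                                  LT = 2500),
                         sd = 50),
                       nb_dispersion = 0.05,
                       pattern_mix = NULL,
                       editing = list(n_sites = 200L, n_polymorphic = 20L,
                                      rates = c(SA = 0.05, IBA = 0.05,
                                                Ent = 0.05, Ar = 0.3,
                                                SpD = 0.05),
                                      depth = 50),
                       splicing = list(n_lsv = 50L, junctions_per_lsv = 2L,
                                       cold_dpsi = 0.3, ir_fraction = 0.2,
                                       depth = 200),
                       motif = list(motif = "TATTTAT",
                                    density = c(high = 6, low = 1)),
                       gc = c(high = 0.60, low = 0.45),
                       utr5_length = 200L, utr3_length = 500L,
                       intron_length = 300L, intron_fraction = 0.5,
                       tandem_pair = FALSE, tandem_gap = 500L,
                       n_gap_loci = NULL,
                       background = 0.1,
                       plateau = 10,
                       noise = TRUE,
                       expression_level = c(meanlog = log(300), sdlog = 1),
                       sex_effect = 1.3,
                       dynamic_range = 8) {
  cfg <- as.list(environment())
  if (is.null(cfg$pattern_mix)) {
    pats <- rownames(pattern_library_rna())
    cfg$pattern_mix <- c(flat = 0.70,
                         setNames(rep(0.30 / length(pats), length(pats)),
                                  pats))
  }
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 0,
              length(gene_length_range) == 2,
              gene_length_range[1] <= gene_length_range[2],
              gene_length_range[1] > 0,
              length(intergenic_gap_range) == 2,
              intergenic_gap_range[1] <= intergenic_gap_range[2],
              intergenic_gap_range[1] >= 0,
              strand_balance >= 0, strand_balance <= 1,
              !anyDuplicated(states), replicates_per_state >= 1,
              nb_dispersion > 0 || nb_dispersion == 0,
              all(extension_truth$mean >= 0), extension_truth$sd >= 0,
              background >= 0, plateau > 0, dynamic_range >= 1,
              utr5_length >= 0, utr3_length >= 0,
              intron_fraction >= 0, intron_fraction <= 1)
  })
  if (abs(sum(cfg$pattern_mix) - 1) > 1e-8)
    stop("pattern_mix must sum to 1")
  if (any(cfg$pattern_mix < 0) || any(cfg$pattern_mix > 1))
    stop("pattern_mix fractions must lie in [0, 1]")
  bad <- setdiff(names(cfg$pattern_mix),
                 c("flat", rownames(pattern_library_rna())))
  if (length(bad)) stop("unknown pattern(s) in pattern_mix: ",
                        paste(bad, collapse = ", "))
  if (any(cfg$editing$rates < 0) || any(cfg$editing$rates > 1))
    stop("editing rates must lie in [0, 1]")
  if (!is.null(cfg$n_gap_loci) && any(cfg$n_gap_loci$length <= 20))
    stop("N-gap runs must be longer than 20 bases")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes on", x$n_chromosomes,
      "chromosome(s) of", x$chrom_length, "nt;",
      length(x$states), "states x", x$replicates_per_state, "replicates\n")
  invisible(x)
}
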