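# hibernaseq

Analysis of liver transcription and steady-state RNA dynamics across the
torpor-arousal cycle of a hibernating mammal, built as a tested, reusable
pipeline for anyone comparing nascent (run-on) and steady-state
transcriptomes across physiological states.

Hibernators alternate multi-day torpor bouts at body temperatures (Tb) of
4-8 °C with brief euthermic arousals. Steady-state RNA (RNA-seq)
confounds transcription with RNA stability, while run-on coverage
(GRO-seq) maps elongating RNA polymerase directly. This package
implements the analyses that exploit that contrast:

* **Segmentation** of strand-specific nascent coverage into transcribed
  units, per state, by a threshold caller or an unsupervised two-state
  Poisson-emission HMM (EM + Viterbi, Rcpp).
* **Readthrough**: per-gene 3' extension past the annotated TTS,
  TTS-offset distributions, revised gene annotations (3' substitution,
  `:`-joined merging, 500-nt TSS trim), metagene profiles, and the torpor
  elongation rate — for a 3' shift of Δ nt over Δd days,
  rate = (Δ/1000)/(1440·Δd) kb/min.
* **Expression**: median-of-ratios normalization, a `log2(norm + 8) ≥ 7
  in ≥ 4/5 animals of ≥ 1 state` pass filter, per-gene fixed-dispersion
  negative-binomial LRT (`~ state + sex` vs `~ sex`, χ², BH, DE at
  q ≤ 0.001), reference-pattern assignment by Pearson r ≥ 0.8 against 14
  state templates, and GC-content comparisons.
* **Concordance**: DE-set intersection between assays (nascent LT
  matched to steady-state Ar), fold-change correlations, quadrant
  classification (`stable_RNA` = RNA up / transcription down), and
  AU-rich-element k-mer enrichment (binomial test, BH).
* **Editing**: A-to-I (A/G) site statistics via G-tests across states and
  pairwise, a cross-assay polymorphism filter (candidates also variant in
  the nascent assay are removed), region annotation and overlap tests.
* **Splicing**: PSI per junction, summer-dominant junction,
  Dirichlet-posterior dPSI with the `P(|dPSI| ≥ 0.2) ≥ 0.999` rule, and
  temperature-pattern classification of significant events.
* **Synthetic data**: a generator with a written truth table (genome,
  gene models, coverage, counts, allele and junction tables) so every
  stage is testable end to end with known answers.

## Worked example: the torpor elongation rate

Simulate a zero-noise genome whose true per-state 3' extensions grow
through the torpor bout (ET 600, LT 2500 nt, per-gene jitter 50 nt), call
transcribed segments, and recover the polymerase shift:

```r
library(hibernaseq)

cfg <- sim_config(n_genes = 60, chrom_length = 700000L, seed = 1,
                  background = 0, noise = FALSE)
g      <- build_genome(cfg)
design <- state_design("nascent", 1)
nas    <- simulate_nascent(g$genes, g$truth, design, seed = 2)

recs <- lapply(c(ET = "ET", LT = "LT"), function(st) {
  pooled <- pool_state_coverage(nas$tracks, design, st)
  segs   <- call_transcribed_segments(pooled, "threshold", smooth_bp = 1,
                                      threshold = 0.1, state = st)
  compute_tts_extension(g$genes, segs, st)
})
shift <- mean_extension_difference(recs$ET, recs$LT, seed = 3)
str(shift)
#> List of 3
#>  $ delta_nt: num 1887
#>  $ se      : num 8.34
#>  $ n_genes : int 60

dd <- delta_days_below_threshold(design[design$state == "ET", ],
                                 design[design$state == "LT", ])
dd
#> [1] 7.3
str(elongation_rate(shift$delta_nt, dd))
#> List of 2
#>  $ kb_per_min: num 0.000179
#>  $ rounded   : num 2e-04
```

The recovered shift (1887 ± 8 nt over 60 genes) matches the injected
1900-nt truth within the bootstrap SE; dividing ~2 kb by the 7.3-day
difference in time spent below 8 °C gives a torpor elongation rate on the
order of 1e-4 kb/min — three to four orders of magnitude below the
typical 1-6 kb/min of warm-body Pol II, the central quantitative claim
this pipeline reproduces. (Rounding 2 kb over 5 days instead gives the
coarser 0.0003 kb/min figure; `elongation_rate()` reports both raw and
rounded values.)

## A command-line entry point

```sh
Rscript -e 'hibernaseq::hibernaseq_cli()' simulate --out sim_out --seed 1
Rscript -e 'hibernaseq::hibernaseq_cli()' segment  --out sim_out --method hmm
```

writes a full synthetic dataset (FASTA, BED6, per-strand bedGraph, TSV
tables, truth directory) and per-state segment BED files.
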