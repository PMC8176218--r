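#' Simulate allele-count tables for both assays
#'
#' Places candidate A/G variant sites inside genes.  True editing sites show
#' the alternative allele only in the steady-state RNA assay, at a
#' state-dependent rate (highest in arousal by default, emulating cold
#' accumulation of A-to-I edits); polymorphic sites show allele frequency
#' ~0.5 in BOTH assays.  The reference base is `A` on the host gene's strand
#' (so `T>C` in genome coordinates for minus-strand genes).  Per-sample
#' depth is Poisson around the configured mean; allele counts are binomial.
#'
#' @param genes,truth from [build_genome()].
#' @param design_rna,design_nascent designs for the two assays.
#' @param seed integer seed.
#' @param n_sites,n_polymorphic,rates,depth override `truth$config$editing`.
#' @return list with `rna` and `nascent` long tables (`site_id`, `chrom`,
#'   `pos0`, `strand`, `ref`, `alt`, `sample`, `state`, `ref_count`,
#'   `alt_count`) and `truth_sites` (per-site truth incl. `polymorphic` and
#'   per-state `rate_*` columns).
#' @export
simulate_editing <- function(genes, truth, design_rna, design_nascent,
                             seed = 1L, n_sites = NULL, n_polymorphic = NULL,
                             rates = NULL, depth = NULL) {
  ecfg <- truth$config$editing
  if (is.null(n_sites)) n_sites <- ecfg$n_sites
  if (is.null(n_polymorphic)) n_polymorphic <- ecfg$n_polymorphic
  if (is.null(rates)) rates <- ecfg$rates
  if (is.null(depth)) depth <- ecfg$depth
  stopifnot(n_polymorphic <= n_sites, nrow(genes) >= 1,
            all(rates >= 0 & rates <= 1))
  set.seed(seed)
  gi <- sample(nrow(genes), n_sites, replace = TRUE)
  pos <- genes$start[gi] +
    floor(runif(n_sites) * (genes$end[gi] - genes$start[gi]))
  strand <- genes$strand[gi]
  sites <- data.frame(
    site_id = sprintf("s%04d", seq_len(n_sites)),
    chrom = genes$chrom[gi], pos0 = as.integer(pos),
    gene_id = genes$gene_id[gi], strand = strand,
    ref = ifelse(strand == "+", "A", "T"),
    alt = ifelse(strand == "+", "G", "C"),
    polymorphic = c(rep(TRUE, n_polymorphic),
                    rep(FALSE, n_sites - n_polymorphic)),
    stringsAsFactors = FALSE)
  states <- levels(design_rna$state)
  for (st in states) {
    r <- if (st %in% names(rates)) rates[[st]] else 0
    sites[[paste0("rate_", st)]] <- ifelse(sites$polymorphic, 0.5, r)
  }

  draw_assay <- function(design, is_rna) {
    rows <- vector("list", nrow(design))
    for (j in seq_len(nrow(design))) {
      st <- as.character(design$state[j])
      rc <- paste0("rate_", st)
      p <- if (rc %in% names(sites)) sites[[rc]] else {
        # nascent-only states (ET/LT) borrow the Ar rate for edited sites
        alt_st <- if (st %in% c("ET", "LT")) "Ar" else st
        ac <- paste0("rate_", alt_st)
        if (ac %in% names(sites)) sites[[ac]] else rep(0, nrow(sites))
      }
      # only polymorphisms are visible in the nascent assay
      if (!is_rna) p <- ifelse(sites$polymorphic, 0.5, 0)
      dp <- rpois(nrow(sites), depth)
      ac <- rbinom(nrow(sites), dp, p)
      rows[[j]] <- data.frame(
        site_id = sites$site_id, chrom = sites$chrom, pos0 = sites$pos0,
        strand = sites$strand, ref = sites$ref, alt = sites$alt,
        sample = design$sample[j], state = st,
        ref_count = dp - ac, alt_count = ac, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  list(rna = draw_assay(design_rna, TRUE),
       nascent = draw_assay(design_nascent, FALSE),
       truth_sites = sites)
}
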