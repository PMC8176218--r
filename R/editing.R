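# A-to-I (A/G) editing-site statistics with a cross-assay polymorphism
# filter.  Site tables are long: one row per site per sample with
# ref_count / alt_count.

site_key <- function(tab) paste(tab$chrom, tab$pos0, sep = ":")

#' Coverage filter for editing-site tables
#'
#' Keeps sites with depth (`ref_count + alt_count`) of at least `min_depth`
#' in at least `min_samples` samples (default: more than six samples).
#'
#' @param tab long site table.
#' @param min_depth per-sample depth threshold (default 10).
#' @param min_samples samples required at depth (default 7).
#' @return filtered table (all rows of passing sites).
#' @export
filter_sites_by_coverage <- function(tab, min_depth = 10L,
                                     min_samples = 7L) {
  depth <- tab$ref_count + tab$alt_count
  ok_n <- tapply(depth >= min_depth, tab$site_id, sum)
  keep <- names(ok_n)[ok_n >= min_samples]
  tab[tab$site_id %in% keep, , drop = FALSE]
}

# G statistic (likelihood-ratio chi-square) for a 2 x k count table;
# 0.5 pseudocount only when a margin is zero
g_stat <- function(m) {
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) m <- m + 0.5
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  keep <- m > 0
  2 * sum(m[keep] * log(m[keep] / e[keep]))
}

#' Test per-site editing-frequency variability across states
#'
#' G-test on the state-pooled ref/alt table per site
#' (`df = n_states - 1`), BH-adjusted across sites; sites with all counts
#' on one allele get `p = 1`.
#'
#' @param tab long site table with a `state` column (or supply `design`).
#' @param design optional design used to map `sample` to `state`.
#' @param q_thresh significance threshold (default 0.05).
#' @return data.frame: `site_id`, `g`, `p`, `q`, `significant`, plus
#'   per-state pooled editing frequencies `ef_<state>`.
#' @export
test_state_variability <- function(tab, design = NULL, q_thresh = 0.05) {
  if (!"state" %in% names(tab)) {
    stopifnot(!is.null(design))
    tab$state <- design$state[match(tab$sample, design$sample)]
  }
  states <- if (is.factor(tab$state)) levels(factor(tab$state))
            else unique(tab$state)
  sites <- unique(tab$site_id)
  res <- data.frame(site_id = sites, g = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  ef <- matrix(NA_real_, length(sites), length(states),
               dimnames = list(sites, states))
  for (i in seq_along(sites)) {
    sub <- tab[tab$site_id == sites[i], ]
    refs <- tapply(sub$ref_count, factor(sub$state, levels = states), sum)
    alts <- tapply(sub$alt_count, factor(sub$state, levels = states), sum)
    refs[is.na(refs)] <- 0; alts[is.na(alts)] <- 0
    m <- rbind(ref = refs, alt = alts)
    nz <- colSums(m) > 0
    if (sum(nz) < 2 || sum(m["alt", ]) == 0 || sum(m["ref", ]) == 0) {
      res$g[i] <- 0; res$p[i] <- 1
    } else {
      res$g[i] <- g_stat(m[, nz, drop = FALSE])
      res$p[i] <- pchisq(res$g[i], sum(nz) - 1, lower.tail = FALSE)
    }
    ef[i, ] <- ifelse(colSums(m) > 0, m["alt", ] / colSums(m), NA_real_)
  }
  res$q <- p.adjust(res$p, "BH")
  res$significant <- res$q < q_thresh
  for (st in states) res[[paste0("ef_", st)]] <- ef[, st]
  res
}

#' Substitution spectrum in gene-strand orientation
#'
#' Tallies the 12 possible ref>alt substitution classes after flipping
#' sites hosted on minus-strand genes to the transcribed strand (so a
#' genomic `T>C` in a minus-strand gene counts as `A>G`).  Ambiguous bases
#' are excluded and counted.
#'
#' @param sites one row per site with `ref`, `alt`, `strand`.
#' @return named integer vector over the 12 classes; attribute `excluded`.
#' @export
substitution_spectrum <- function(sites) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(sites$ref); alt <- toupper(sites$alt)
  flip <- sites$strand == "-"
  ok <- ref %in% names(comp) & alt %in% names(comp) & ref != alt
  ref[flip & ok] <- comp[ref[flip & ok]]
  alt[flip & ok] <- comp[alt[flip & ok]]
  classes <- c(t(outer(names(comp), names(comp), paste, sep = ">")))
  classes <- classes[!classes %in% paste(names(comp), names(comp),
                                         sep = ">")]
  out <- table(factor(paste(ref[ok], alt[ok], sep = ">"),
                      levels = classes))
  res <- setNames(as.integer(out), names(out))
  attr(res, "excluded") <- sum(!ok)
  res
}

#' Cross-assay polymorphism filter
#'
#' Candidate edited sites found among the variants of the nascent
#' (run-on) assay are treated as genomic polymorphisms and removed;
#' `retained + excluded = input` always.
#'
#' @param rna_sites data.frame of candidate sites (`chrom`, `pos0`).
#' @param nascent_variants data.frame of variants seen in the nascent
#'   assay (`chrom`, `pos0`).
#' @return list: `retained` (data.frame), `n_input`, `n_excluded`,
#'   `n_retained`.
#' @export
cross_assay_filter <- function(rna_sites, nascent_variants) {
  shared <- site_key(rna_sites) %in% site_key(nascent_variants)
  list(retained = rna_sites[!shared, , drop = FALSE],
       n_input = nrow(rna_sites), n_excluded = sum(shared),
       n_retained = sum(!shared))
}

#' Call variant sites from an allele-count table
#'
#' A site is a variant if its pooled alternative-allele frequency reaches
#' `min_alt_frac` with at least `min_alt_count` alternative reads.
#'
#' @param tab long site table.
#' @param min_alt_frac,min_alt_count detection thresholds.
#' @return data.frame of unique variant sites (`site_id`, `chrom`, `pos0`).
#' @export
detect_variant_sites <- function(tab, min_alt_frac = 0.1,
                                 min_alt_count = 2L) {
  alt <- tapply(tab$alt_count, tab$site_id, sum)
  tot <- tapply(tab$ref_count + tab$alt_count, tab$site_id, sum)
  hit <- names(alt)[tot > 0 & alt >= min_alt_count &
                      alt / pmax(tot, 1) >= min_alt_frac]
  unique(tab[tab$site_id %in% hit, c("site_id", "chrom", "pos0")])
}

#' Pairwise differential editing between two states
#'
#' Two-proportion G-test on pooled ref/alt counts per site, BH-adjusted
#' across sites.
#'
#' @param tab long site table with `state`.
#' @param state_a,state_b states to compare.
#' @param q_thresh significance threshold (default 0.05).
#' @return data.frame: `site_id`, `ef_a`, `ef_b`, `def` (ef_b - ef_a),
#'   `g`, `p`, `q`, `significant`; zero total depth in a state gives `NA`.
#' @export
pairwise_differential_editing <- function(tab, state_a, state_b,
                                          q_thresh = 0.05) {
  sub <- tab[tab$state %in% c(state_a, state_b), ]
  sites <- unique(sub$site_id)
  out <- data.frame(site_id = sites, ef_a = NA_real_, ef_b = NA_real_,
                    def = NA_real_, g = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(sites)) {
    ss <- sub[sub$site_id == sites[i], ]
    ra <- sum(ss$ref_count[ss$state == state_a])
    aa <- sum(ss$alt_count[ss$state == state_a])
    rb <- sum(ss$ref_count[ss$state == state_b])
    ab <- sum(ss$alt_count[ss$state == state_b])
    if (ra + aa == 0 || rb + ab == 0) next
    out$ef_a[i] <- aa / (ra + aa)
    out$ef_b[i] <- ab / (rb + ab)
    out$def[i] <- out$ef_b[i] - out$ef_a[i]
    m <- rbind(c(ra, aa), c(rb, ab))
    if (aa + ab == 0 || ra + rb == 0) {
      out$g[i] <- 0; out$p[i] <- 1
    } else {
      out$g[i] <- g_stat(m)
      out$p[i] <- pchisq(out$g[i], 1, lower.tail = FALSE)
    }
  }
  ok <- !is.na(out$p)
  out$q <- NA_real_
  out$q[ok] <- p.adjust(out$p[ok], "BH")
  out$significant <- !is.na(out$q) & out$q < q_thresh
  out
}

#' Sites with editing enriched in a cold state
#'
#' A site is cold-enriched when its pooled editing frequency in
#' `cold_state` exceeds that of every other state at `q < q_thresh` in the
#' corresponding pairwise test.
#'
#' @param tab long site table with `state`.
#' @param cold_state the state expected to accumulate edits (default Ar).
#' @param q_thresh per-pair significance threshold.
#' @return character vector of site ids.
#' @export
cold_enriched_sites <- function(tab, cold_state = "Ar", q_thresh = 0.05) {
  states <- setdiff(unique(as.character(tab$state)), cold_state)
  hits <- NULL
  for (st in states) {
    pr <- pairwise_differential_editing(tab, st, cold_state, q_thresh)
    ok <- pr$site_id[pr$significant & !is.na(pr$def) & pr$def > 0]
    hits <- if (is.null(hits)) ok else intersect(hits, ok)
  }
  hits
}

#' Classify sites by genomic region
#'
#' Interval containment against the gene sub-feature table with precedence
#' CDS > UTR > intron > intergenic; sites on chromosomes absent from the
#' models are intergenic.
#'
#' @param sites data.frame with `chrom`, `pos0`.
#' @param features sub-feature table from [gene_features()].
#' @return character vector of classes (`CDS`, `utr5`, `utr3`, `intron`,
#'   `intergenic`).
#' @export
annotate_region <- function(sites, features) {
  prec <- c(cds = 1, utr5 = 2, utr3 = 2, intron = 3)
  label <- c(cds = "CDS", utr5 = "5'UTR", utr3 = "3'UTR",
             intron = "intron")
  out <- rep("intergenic", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- features[features$chrom == sites$chrom[i] &
                      features$start <= sites$pos0[i] &
                      features$end > sites$pos0[i], , drop = FALSE]
    if (nrow(hit) == 0) next
    best <- hit$type[order(prec[hit$type])][1]
    out[i] <- label[[best]]
  }
  out
}

#' Overlap of a site set with a reference set
#'
#' Hypergeometric upper-tail probability of observing at least the overlap
#' given the universe size.
#'
#' @param sites,reference data.frames with `chrom`, `pos0` (or character
#'   key vectors).
#' @param universe_size number of candidate sites in the universe.
#' @return list: `n_overlap`, `p`.
#' @export
overlap_reference <- function(sites, reference, universe_size) {
  ks <- if (is.data.frame(sites)) unique(site_key(sites)) else unique(sites)
  kr <- if (is.data.frame(reference)) unique(site_key(reference))
        else unique(reference)
  n_ov <- length(intersect(ks, kr))
  stopifnot(universe_size >= length(union(ks, kr)))
  p <- phyper(n_ov - 1, length(kr), universe_size - length(kr),
              length(ks), lower.tail = FALSE)
  list(n_overlap = n_ov, p = p)
}
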