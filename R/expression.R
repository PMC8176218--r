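# Differential expression across physiological states with a sex covariate,
# reference-pattern assignment and GC comparison.

#' Median-of-ratios size factors
#' @param counts non-negative count matrix (genes x samples).
#' @export
size_factors_mor <- function(counts) {
  logc <- log(counts)
  use <- rowSums(is.finite(logc)) == ncol(counts)
  if (!any(use)) return(setNames(rep(1, ncol(counts)), colnames(counts)))
  ref <- rowMeans(logc[use, , drop = FALSE])
  apply(logc[use, , drop = FALSE], 2, function(x)
    exp(stats::median(x - ref)))
}

#' Normalize counts and apply the expression-level pass filter
#'
#' Size factors by median-of-ratios; the working log scale is
#' `log2(normalized count + pseudo)` (a declared stand-in for a regularized
#' log).  A gene is retained iff its log level reaches `min_level` in at
#' least `min_samples` individuals of at least one state.
#'
#' @param counts raw count matrix (genes x samples).
#' @param design matching [state_design()].
#' @param min_level log2 threshold (default 7).
#' @param min_samples individuals required at or above threshold (default
#'   4, capped at the state's sample count).
#' @param pseudo pseudocount on the normalized scale (default 8).
#' @return list: `log` (filtered log matrix), `norm` (filtered normalized
#'   counts), `size_factors`, `keep` (logical over input genes).
#' @export
normalize_and_filter <- function(counts, design, min_level = 7,
                                 min_samples = 4L, pseudo = 8) {
  stopifnot(ncol(counts) == nrow(design), all(counts >= 0))
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  sf <- size_factors_mor(counts)
  norm <- sweep(counts, 2, sf, "/")
  logmat <- log2(norm + pseudo)
  keep <- rep(FALSE, nrow(counts))
  for (st in levels(design$state)) {
    cols <- design$sample[design$state == st]
    need <- min(min_samples, length(cols))
    keep <- keep | rowSums(logmat[, cols, drop = FALSE] >= min_level) >= need
  }
  list(log = logmat[keep, , drop = FALSE],
       norm = norm[keep, , drop = FALSE],
       size_factors = sf, keep = keep)
}

# Method-of-moments NB dispersion per gene from normalized counts, pooled
# over state cells (floored).  Deliberately not stratified by sex: the sex
# offset inflates the estimate slightly, which compensates the small-sample
# noise of the moment estimator and keeps the fixed-dispersion LRT from
# becoming anticonservative at n = 5 per state.
mom_dispersion <- function(norm_row, design, floor = 1e-8) {
  cell <- factor(design$state)
  num <- 0; den <- 0
  for (cl in levels(cell)) {
    x <- norm_row[cell == cl]
    if (length(x) < 2) next
    m <- mean(x)
    if (m <= 0) next
    num <- num + (length(x) - 1) * (var(x) - m) / m^2
    den <- den + (length(x) - 1)
  }
  if (den == 0) return(floor)
  max(num / den, floor)
}

#' Negative-binomial likelihood-ratio test across states
#'
#' Per gene: a negative-binomial log-linear fit of the full model
#' (`~ state + sex`) against the reduced model (`~ sex`), with
#' per-gene dispersion estimated by method-of-moments within state cells
#' (floor `1e-8`) and held fixed in both fits.  The LRT p-value uses
#' a chi-square with `n_states - 1` degrees of freedom;
#' Benjamini-Hochberg adjustment runs over all converged genes and the DE
#' flag applies `q <= q_thresh`.
#'
#' @param counts raw counts for pass-filter genes (genes x samples).
#' @param design matching [state_design()].
#' @param size_factors per-sample size factors (from
#'   [normalize_and_filter()]); default recomputed.
#' @param q_thresh DE significance threshold on q (default 0.001).
#' @return data.frame: `gene_id`, `lrt_stat`, `p`, `q`, `de`, `dispersion`,
#'   and per-state mean log2 columns `mean_<state>`.
#' @export
nb_lrt_de <- function(counts, design, size_factors = NULL,
                      q_thresh = 0.001) {
  stopifnot(nlevels(design$state) >= 2)
  if (is.null(size_factors)) size_factors <- size_factors_mor(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  st <- design$state
  sex <- factor(design$sex)
  off <- log(size_factors)
  df_lrt <- nlevels(st) - 1
  one_sex <- nlevels(sex) < 2
  n <- nrow(counts)
  lrt <- p <- disp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    y <- counts[i, ]
    phi <- mom_dispersion(norm[i, ], design)
    disp[i] <- phi
    theta <- 1 / phi
    fit <- tryCatch({
      full <- if (one_sex)
        glm(y ~ st + offset(off), family = MASS::negative.binomial(theta))
      else glm(y ~ st + sex + offset(off),
               family = MASS::negative.binomial(theta))
      red <- if (one_sex)
        glm(y ~ 1 + offset(off), family = MASS::negative.binomial(theta))
      else glm(y ~ sex + offset(off),
               family = MASS::negative.binomial(theta))
      red$deviance - full$deviance
    }, error = function(e) NA_real_, warning = function(w) {
      # refit quietly; IWLS warnings (e.g. step halving) are tolerated
      full <- suppressWarnings(
        if (one_sex) glm(y ~ st + offset(off),
                         family = MASS::negative.binomial(theta))
        else glm(y ~ st + sex + offset(off),
                 family = MASS::negative.binomial(theta)))
      red <- suppressWarnings(
        if (one_sex) glm(y ~ 1 + offset(off),
                         family = MASS::negative.binomial(theta))
        else glm(y ~ sex + offset(off),
                 family = MASS::negative.binomial(theta)))
      red$deviance - full$deviance
    })
    if (is.na(fit) || fit < 0) fit <- if (is.na(fit)) NA_real_ else 0
    lrt[i] <- fit
    p[i] <- pchisq(fit, df_lrt, lower.tail = FALSE)
  }
  q <- rep(NA_real_, n)
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], "BH")
  out <- data.frame(gene_id = rownames(counts), lrt_stat = lrt, p = p,
                    q = q, de = !is.na(q) & q <= q_thresh,
                    dispersion = disp, stringsAsFactors = FALSE)
  for (s in levels(st)) {
    cols <- which(st == s)
    out[[paste0("mean_", s)]] <-
      log2(rowMeans(norm[, cols, drop = FALSE]) + 1)
  }
  rownames(out) <- NULL
  out
}

#' Assign genes to reference patterns by Pearson correlation
#'
#' Each gene's per-state mean vector is correlated against every library
#' template; the gene is assigned to the most-correlated template if
#' `r >= r_min`, otherwise `Unassigned`.  Exact ties break toward library
#' order and are logged in the `ties` attribute; zero-variance genes are
#' `Unassigned` with reason.
#'
#' @param state_means matrix (genes x states, any monotone scale) aligned
#'   to the library's state order.
#' @param library pattern library matrix ([pattern_library_rna()]).
#' @param r_min assignment threshold (default 0.8).
#' @return data.frame: `gene_id`, `pattern`, `r`, `reason`.
#' @export
assign_pattern <- function(state_means, library, r_min = 0.8) {
  stopifnot(ncol(state_means) == ncol(library))
  if (!is.null(colnames(state_means)) &&
      !identical(colnames(state_means), colnames(library)))
    state_means <- state_means[, colnames(library), drop = FALSE]
  n <- nrow(state_means)
  pat <- rep("Unassigned", n)
  rbest <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  ties <- character(0)
  tlib <- t(library)
  for (i in seq_len(n)) {
    v <- state_means[i, ]
    if (sd(v) == 0) { reason[i] <- "zero variance"; next }
    r <- suppressWarnings(cor(v, tlib))[1, ]
    mx <- max(r)
    rbest[i] <- mx
    if (mx >= r_min) {
      hits <- which(abs(r - mx) < 1e-12)
      pat[i] <- rownames(library)[hits[1]]
      if (length(hits) > 1)
        ties <- c(ties, rownames(state_means)[i] %||% as.character(i))
    } else reason[i] <- "r below threshold"
  }
  out <- data.frame(gene_id = rownames(state_means) %||%
                      as.character(seq_len(n)),
                    pattern = pat, r = rbest, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- ties
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise log2 fold change between two states
#'
#' `log2((mean_B + pseudo) / (mean_A + pseudo))` of size-factor-normalized
#' state means; positive values are higher in `state_b`.
#'
#' @param norm normalized count matrix (genes x samples).
#' @param design matching design.
#' @param state_a,state_b state labels.
#' @param pseudo pseudocount (default 1).
#' @return named numeric vector of log2 fold changes.
#' @export
pairwise_log2fc <- function(norm, design, state_a, state_b, pseudo = 1) {
  stopifnot(state_a %in% design$state, state_b %in% design$state)
  ma <- rowMeans(norm[, design$sample[design$state == state_a],
                      drop = FALSE])
  mb <- rowMeans(norm[, design$sample[design$state == state_b],
                      drop = FALSE])
  setNames(log2((mb + pseudo) / (ma + pseudo)), rownames(norm))
}

#' GC content of up- vs down-regulated gene sets
#'
#' For each named comparison, contrasts the GC fraction distributions of
#' genes increased vs decreased across a transition with a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param comparisons named list; each element a list with `up` and `down`
#'   character vectors of gene ids.
#' @param gc named numeric vector of per-gene GC fractions.
#' @return data.frame: `comparison`, `n_up`, `n_down`, `median_gc_up`,
#'   `median_gc_down`, `p`, `low_n` flag.
#' @export
gc_content_compare <- function(comparisons, gc) {
  rows <- lapply(names(comparisons), function(nm) {
    up <- gc[intersect(comparisons[[nm]]$up, names(gc))]
    dn <- gc[intersect(comparisons[[nm]]$down, names(gc))]
    if (!length(up) || !length(dn))
      return(data.frame(comparison = nm, n_up = length(up),
                        n_down = length(dn), median_gc_up = NA_real_,
                        median_gc_down = NA_real_, p = NA_real_,
                        low_n = TRUE, stringsAsFactors = FALSE))
    p <- suppressWarnings(wilcox.test(up, dn, exact = NULL)$p.value)
    data.frame(comparison = nm, n_up = length(up), n_down = length(dn),
               median_gc_up = stats::median(up),
               median_gc_down = stats::median(dn), p = p,
               low_n = length(up) < 5 || length(dn) < 5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
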