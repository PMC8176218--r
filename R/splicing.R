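# PSI / dPSI splicing analysis with a Dirichlet posterior decision rule.

#' Percent-spliced-in per sample
#'
#' `PSI_j = count_j / sum(counts)`; a zero total yields an NA vector with a
#' flag attribute.
#'
#' @param counts junction count vector for one LSV in one sample.
#' @return numeric PSI vector summing to 1 (or NA with attribute
#'   `zero_total`).
#' @export
compute_psi <- function(counts) {
  stopifnot(all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) {
    out <- rep(NA_real_, length(counts))
    attr(out, "zero_total") <- TRUE
    return(out)
  }
  counts / tot
}

# long LSV table -> junction x sample count matrix for one LSV
lsv_count_matrix <- function(tab, lsv) {
  sub <- tab[tab$lsv_id == lsv, ]
  juncs <- sort(unique(sub$junction_id))
  samples <- unique(sub$sample)
  m <- matrix(0, length(juncs), length(samples),
              dimnames = list(juncs, samples))
  m[cbind(match(sub$junction_id, juncs), match(sub$sample, samples))] <-
    sub$count
  m
}

#' Per-sample PSI matrix for one LSV
#' @param tab long junction table (`lsv_id`, `junction_id`, `sample`,
#'   `count`).
#' @param lsv LSV id.
#' @return matrix junctions x samples of PSI values (NA columns for
#'   zero-total samples).
#' @export
psi_matrix <- function(tab, lsv) {
  m <- lsv_count_matrix(tab, lsv)
  apply(m, 2, compute_psi)
}

#' Most common junction in the reference (summer) state
#'
#' The junction with the highest pooled count over the reference state's
#' samples; ties break to the lowest junction index and are flagged.
#'
#' @param tab long junction table with `state`.
#' @param lsv LSV id.
#' @param ref_state reference state (default `"SA"`).
#' @return integer junction id (attribute `tie` if tied); `NA` when the
#'   reference state has no counts.
#' @export
summer_dominant_junction <- function(tab, lsv, ref_state = "SA") {
  sub <- tab[tab$lsv_id == lsv & tab$state == ref_state, ]
  if (nrow(sub) == 0 || sum(sub$count) == 0) return(NA_integer_)
  pooled <- tapply(sub$count, sub$junction_id, sum)
  mx <- max(pooled)
  hits <- as.integer(names(pooled)[pooled == mx])
  out <- min(hits)
  if (length(hits) > 1) attr(out, "tie") <- TRUE
  out
}

#' Posterior dPSI significance between two states
#'
#' Counts are pooled within each state; the posterior over each state's
#' PSI vector is `Dirichlet(1 + pooled counts)`.  Monte-Carlo draws of the
#' per-junction dPSI (state B minus state A) estimate
#' `P(|dPSI| >= threshold)`; a junction is significant when that
#' probability reaches `prob` (default: 99.9% probability of at least
#' 0.2).  `one_sided = TRUE` uses `P(dPSI >= threshold)` instead.
#'
#' @param tab long junction table with `state`.
#' @param lsv LSV id.
#' @param state_a,state_b states to compare.
#' @param threshold dPSI magnitude threshold (default 0.2).
#' @param prob posterior probability required (default 0.999).
#' @param draws Monte-Carlo sample size (default 2000).
#' @param seed RNG seed.
#' @param one_sided if `TRUE`, only increases in B count.
#' @return data.frame: `lsv_id`, `junction_id`, `mean_dpsi`,
#'   `p_dpsi_ge_threshold`, `significant`.
#' @export
dpsi_significance <- function(tab, lsv, state_a, state_b, threshold = 0.2,
                              prob = 0.999, draws = 2000L, seed = 1L,
                              one_sided = FALSE) {
  m <- lsv_count_matrix(tab[tab$state %in% c(state_a, state_b), ], lsv)
  sub <- tab[tab$lsv_id == lsv, ]
  samp_a <- unique(sub$sample[sub$state == state_a])
  samp_b <- unique(sub$sample[sub$state == state_b])
  ca <- rowSums(m[, colnames(m) %in% samp_a, drop = FALSE])
  cb <- rowSums(m[, colnames(m) %in% samp_b, drop = FALSE])
  J <- length(ca)
  stopifnot(J >= 2)
  set.seed(seed)
  ga <- matrix(rgamma(draws * J, shape = rep(1 + ca, each = draws)),
               draws, J)
  gb <- matrix(rgamma(draws * J, shape = rep(1 + cb, each = draws)),
               draws, J)
  psi_a <- ga / rowSums(ga)
  psi_b <- gb / rowSums(gb)
  dpsi <- psi_b - psi_a
  pge <- if (one_sided) colMeans(dpsi >= threshold)
         else colMeans(abs(dpsi) >= threshold)
  data.frame(lsv_id = lsv, junction_id = as.integer(rownames(m)),
             mean_dpsi = colMeans(dpsi), p_dpsi_ge_threshold = pge,
             significant = pge >= prob, stringsAsFactors = FALSE)
}

#' Per-state mean alternative-junction PSI for an LSV
#'
#' The alternative-junction PSI of a sample is the summed PSI of all
#' junctions other than the summer-dominant one (or the IR junction's own
#' PSI for intron-retention events).  Samples with zero totals are
#' ignored.
#'
#' @param tab long junction table with `state` and `ir_flag`.
#' @param lsv LSV id.
#' @param states ordered state labels.
#' @param use_ir if `TRUE` and the LSV has an IR junction, track that
#'   junction's PSI instead.
#' @return named numeric vector of state means (NA where no sample has
#'   counts).
#' @export
alt_junction_psi <- function(tab, lsv, states, use_ir = FALSE) {
  sub <- tab[tab$lsv_id == lsv, ]
  dom <- summer_dominant_junction(tab, lsv)
  if (is.na(dom)) return(setNames(rep(NA_real_, length(states)), states))
  psim <- psi_matrix(tab, lsv)
  juncs <- as.integer(rownames(psim))
  ir_j <- unique(sub$junction_id[sub$ir_flag])
  track <- if (use_ir && length(ir_j))
    colSums(psim[juncs %in% ir_j, , drop = FALSE])
  else colSums(psim[juncs != dom, , drop = FALSE])
  st_of <- sub$state[match(colnames(psim), sub$sample)]
  vapply(states, function(s)
    mean(track[st_of == s], na.rm = TRUE), numeric(1))
}

#' Assign splicing events to temperature patterns
#'
#' For every LSV significant in at least one pairwise comparison, the
#' per-state mean alternative-junction PSI (IR junction PSI for IR
#' events) is correlated against the pattern library with the same
#' `r >= r_min` rule used for expression clusters.
#'
#' @param tab long junction table with `state` and `ir_flag`.
#' @param lsv_ids LSVs to classify (e.g. the significant ones).
#' @param library pattern library whose states match the design.
#' @param r_min assignment threshold (default 0.8).
#' @return data.frame: `lsv_id`, `is_ir`, `pattern`, `r`.
#' @export
classify_splicing_patterns <- function(tab, lsv_ids, library,
                                       r_min = 0.8) {
  states <- colnames(library)
  rows <- lapply(lsv_ids, function(l) {
    is_ir <- any(tab$ir_flag[tab$lsv_id == l])
    v <- alt_junction_psi(tab, l, states, use_ir = is_ir)
    if (anyNA(v)) return(data.frame(lsv_id = l, is_ir = is_ir,
                                    pattern = "Unassigned", r = NA_real_,
                                    stringsAsFactors = FALSE))
    asn <- assign_pattern(matrix(v, 1, dimnames = list(l, states)),
                          library, r_min)
    data.frame(lsv_id = l, is_ir = is_ir, pattern = asn$pattern,
               r = asn$r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
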