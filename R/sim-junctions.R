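#' Simulate junction-count tables grouped into local splicing variations
#'
#' Each LSV gets a per-state PSI vector: in warm states one junction
#' dominates; in the cold states (Ent, Ar, ET, LT) PSI shifts by
#' `cold_dpsi` toward the alternative junctions.  A configurable fraction of
#' LSVs carry an intron-retention (IR) junction whose PSI instead drops in
#' the cold, emulating the observation that IR events fall into the cold-low
#' patterns.  Per sample, junction counts are multinomial at the configured
#' depth with the state's PSI vector.
#'
#' @param genes,truth from [build_genome()].
#' @param design a [state_design()].
#' @param seed integer seed.
#' @param n_lsv,junctions_per_lsv,cold_dpsi,ir_fraction,depth override
#'   `truth$config$splicing`.
#' @return list with `counts` (long table: `lsv_id`, `gene_id`,
#'   `junction_id`, `ir_flag`, `sample`, `state`, `count`) and `truth_lsvs`
#'   (per LSV x junction truth with per-state `psi_*` columns).
#' @export
simulate_junctions <- function(genes, truth, design, seed = 1L,
                               n_lsv = NULL, junctions_per_lsv = NULL,
                               cold_dpsi = NULL, ir_fraction = NULL,
                               depth = NULL) {
  scfg <- truth$config$splicing
  if (is.null(n_lsv)) n_lsv <- scfg$n_lsv
  if (is.null(junctions_per_lsv)) junctions_per_lsv <- scfg$junctions_per_lsv
  if (is.null(cold_dpsi)) cold_dpsi <- scfg$cold_dpsi
  if (is.null(ir_fraction)) ir_fraction <- scfg$ir_fraction
  if (is.null(depth)) depth <- scfg$depth
  J <- junctions_per_lsv
  stopifnot(J >= 2, cold_dpsi >= 0, cold_dpsi <= 0.5)
  set.seed(seed)
  states <- levels(design$state)
  cold <- states %in% c("Ent", "Ar", "ET", "LT")
  gi <- sample(nrow(genes), n_lsv, replace = TRUE)
  is_ir <- runif(n_lsv) < ir_fraction

  truth_rows <- vector("list", n_lsv)
  count_rows <- vector("list", n_lsv)
  for (l in seq_len(n_lsv)) {
    if (is_ir[l]) {
      # junction J is the retained intron; high in warm, falls in cold
      warm_psi <- c(rep(0.6 / (J - 1), J - 1), 0.4)
      cold_psi <- warm_psi
      cold_psi[J] <- warm_psi[J] - cold_dpsi
      cold_psi[seq_len(J - 1)] <- cold_psi[seq_len(J - 1)] +
        cold_dpsi / (J - 1)
    } else {
      # junction 1 dominates in warm states, loses PSI in the cold
      warm_psi <- c(0.7, rep(0.3 / (J - 1), J - 1))
      cold_psi <- warm_psi
      cold_psi[1] <- warm_psi[1] - cold_dpsi
      cold_psi[-1] <- cold_psi[-1] + cold_dpsi / (J - 1)
    }
    psi <- vapply(seq_along(states), function(s)
      if (cold[s]) cold_psi else warm_psi, numeric(J))
    colnames(psi) <- states
    stopifnot(abs(colSums(psi) - 1) < 1e-9, all(psi >= 0))

    tr <- data.frame(lsv_id = sprintf("lsv%03d", l),
                     gene_id = genes$gene_id[gi[l]],
                     junction_id = seq_len(J),
                     ir_flag = c(rep(FALSE, J - 1), is_ir[l]),
                     stringsAsFactors = FALSE)
    for (st in states) tr[[paste0("psi_", st)]] <- psi[, st]
    truth_rows[[l]] <- tr

    cr <- vector("list", nrow(design))
    for (k in seq_len(nrow(design))) {
      st <- as.character(design$state[k])
      cnt <- as.vector(rmultinom(1, depth, psi[, st]))
      cr[[k]] <- data.frame(lsv_id = tr$lsv_id[1],
                            gene_id = tr$gene_id[1],
                            junction_id = seq_len(J),
                            ir_flag = tr$ir_flag,
                            sample = design$sample[k], state = st,
                            count = cnt, stringsAsFactors = FALSE)
    }
    count_rows[[l]] <- do.call(rbind, cr)
  }
  list(counts = do.call(rbind, count_rows),
       truth_lsvs = do.call(rbind, truth_rows))
}
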