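# Shared small fixtures.  Everything is generated in code; the tiny genome
# is cached per test run because several files reuse it.

tiny_config <- function(...) {
  sim_config(n_genes = 8L, chrom_length = 200000L, seed = 42L, ...)
}

tiny_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome(tiny_config())
    cache
  }
})

# brute-force interval union oracle on a small base space
base_set_union <- function(segs, n_bases) {
  covered <- rep(FALSE, n_bases)
  for (i in seq_len(nrow(segs)))
    covered[(segs$start[i] + 1):segs$end[i]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# closed-form P(|X - Y| >= t) for X ~ Beta(a1, a2), Y ~ Beta(b1, b2),
# by numerical integration over the density of X (independent oracle for
# the Monte-Carlo Dirichlet posterior on 2-junction LSVs)
beta_diff_prob <- function(a1, a2, b1, b2, t) {
  f <- function(x) dbeta(x, a1, a2) *
    (pbeta(x - t, b1, b2) + (1 - pbeta(x + t, b1, b2)))
  integrate(f, 0, 1, rel.tol = 1e-9)$value
}
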