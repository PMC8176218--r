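# transcribed-segment calling

test_that("pooling replicates is a base-wise sum", {
  tr1 <- cov_set(coverage_track(c(c1 = 1000L)), "c1", "+",
                 rpois(1000, 0.5))
  tr2 <- cov_set(coverage_track(c(c1 = 1000L)), "c1", "+",
                 rpois(1000, 0.5))
  tr3 <- cov_set(coverage_track(c(c1 = 1000L)), "c1", "+", rep(1, 1000))
  expect_identical(pool_state_coverage(list(tr1))$cov, tr1$cov)
  pooled <- pool_state_coverage(list(tr1, tr2, tr3))
  expect_equal(as.numeric(cov_get(pooled, "c1", "+")),
               as.numeric(cov_get(tr1, "c1", "+")) +
                 as.numeric(cov_get(tr2, "c1", "+")) + 1)
  expect_error(pool_state_coverage(list(tr1,
    coverage_track(c(c1 = 500L)))), "mismatch")
})

test_that("constant-3 pooling of three unit tracks", {
  tr <- cov_set(coverage_track(c(c1 = 100L)), "c1", "-", rep(1, 100))
  p <- pool_state_coverage(list(tr, tr, tr))
  expect_true(all(as.numeric(cov_get(p, "c1", "-")) == 3))
})

test_that("threshold caller recovers a clean block exactly", {
  v <- numeric(5000)
  v[1001:3000] <- 10   # 0-based [1000, 3000)
  tr <- cov_set(coverage_track(c(c1 = 5000L)), "c1", "+", v)
  segs <- call_transcribed_segments(tr, "threshold", smooth_bp = 1,
                                    threshold = 1, state = "SA")
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 1000L)
  expect_equal(segs$end, 3000L)
  expect_equal(segs$mean_cov, 10)
  expect_equal(segs$state, "SA")
})

test_that("all-zero coverage yields no segments (not an error)", {
  tr <- coverage_track(c(c1 = 2000L))
  segs <- call_transcribed_segments(tr, "threshold")
  expect_equal(nrow(segs), 0L)
  segs <- call_transcribed_segments(tr, "hmm")
  expect_equal(nrow(segs), 0L)
})

test_that("gap joining and min_len filtering behave as configured", {
  v <- numeric(3000)
  v[101:400] <- 5; v[451:800] <- 5   # 50-nt gap
  v[2001:2100] <- 5                  # 100-nt run
  tr <- cov_set(coverage_track(c(c1 = 3000L)), "c1", "+", v)
  segs <- call_transcribed_segments(tr, "threshold", smooth_bp = 1,
                                    threshold = 1, max_gap = 100,
                                    min_len = 200)
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$start, segs$end), c(100, 800))
  segs2 <- call_transcribed_segments(tr, "threshold", smooth_bp = 1,
                                     threshold = 1, max_gap = 10,
                                     min_len = 200)
  expect_equal(nrow(segs2), 2L)
})

test_that("threshold 0 with infinite gap gives one segment per covered
           chromosome-strand", {
  v <- numeric(1000); v[500:600] <- 2
  tr <- cov_set(coverage_track(c(c1 = 1000L)), "c1", "+", v)
  segs <- call_transcribed_segments(tr, "threshold", smooth_bp = 1,
                                    threshold = 0, max_gap = Inf,
                                    min_len = 1)
  expect_equal(nrow(segs), 1L)  # minus strand uncovered: no segment
  expect_equal(c(segs$start, segs$end), c(0, 1000))
})

test_that("hmm calls boundaries matching truth on zero-noise readthrough", {
  cfg <- sim_config(n_genes = 4L, chrom_length = 80000L, seed = 5L,
                    background = 0, noise = FALSE)
  g <- build_genome(cfg)
  d <- state_design("nascent", 1L)
  nas <- simulate_nascent(g$genes, g$truth, d, seed = 9)
  segs <- call_transcribed_segments(nas$tracks[["LT_1"]], "hmm")
  ext <- compute_tts_extension(g$genes, segs, "LT")
  expect_true(all(ext$eligible))
  expect_true(all(abs(ext$extension - g$truth$genes$ext_LT) <= 50))
})

test_that("hmm boundary is within ~100 nt of truth on Poisson data", {
  cfg <- sim_config(n_genes = 4L, chrom_length = 80000L, seed = 5L,
                    background = 0, noise = TRUE)
  g <- build_genome(cfg)
  d <- state_design("nascent", 3L)
  nas <- simulate_nascent(g$genes, g$truth, d, seed = 9)
  pooled <- pool_state_coverage(nas$tracks, d, "LT")
  segs <- call_transcribed_segments(pooled, "hmm")
  ext <- compute_tts_extension(g$genes, segs, "LT")
  expect_true(all(abs(ext$extension - g$truth$genes$ext_LT) <= 100))
})

test_that("merge across states equals the base-set union oracle", {
  set.seed(31)
  mk <- function() {
    s <- sort(sample(0:1900, 6))
    data.frame(chrom = "c1", start = s[c(1, 3, 5)],
               end = s[c(1, 3, 5)] + sample(30:80, 3), strand = "+",
               state = "x", mean_cov = 1)
  }
  for (rep in 1:10) {
    sets <- list(mk(), mk(), mk())
    merged <- merge_segments_across_states(sets)
    oracle <- base_set_union(do.call(rbind, sets), 2000)
    expect_equal(merged$start, oracle$start)
    expect_equal(merged$end, oracle$end)
    # idempotence
    again <- merge_segments_across_states(merged)
    expect_equal(again[, c("start", "end")], merged[, c("start", "end")])
  }
})

test_that("simple overlap union: [100,200) + [150,300) -> [100,300)", {
  a <- data.frame(chrom = "c1", start = 100L, end = 200L, strand = "+",
                  state = "A", mean_cov = 1)
  b <- data.frame(chrom = "c1", start = 150L, end = 300L, strand = "+",
                  state = "B", mean_cov = 1)
  m <- merge_segments_across_states(list(a, b))
  expect_equal(c(m$start, m$end), c(100L, 300L))
  # opposite strands do not merge
  b$strand <- "-"
  m2 <- merge_segments_across_states(list(a, b))
  expect_equal(nrow(m2), 2L)
})

test_that("segments are sorted, non-overlapping, with positive mean", {
  g <- tiny_genome()
  d <- state_design("nascent", 2L)
  nas <- simulate_nascent(g$genes, g$truth, d, seed = 13)
  pooled <- pool_state_coverage(nas$tracks, d, "Ent")
  for (method in c("threshold", "hmm")) {
    segs <- call_transcribed_segments(pooled, method, state = "Ent")
    expect_true(all(segs$start < segs$end))
    expect_true(all(segs$mean_cov > 0))
    for (s in c("+", "-")) {
      sub <- segs[segs$strand == s, ]
      if (nrow(sub) > 1)
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
})
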