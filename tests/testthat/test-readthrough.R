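# readthrough quantification, annotation revision, elongation arithmetic

seg_row <- function(start, end, strand = "+", state = "LT", chrom = "c1")
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             state = state, mean_cov = 1, stringsAsFactors = FALSE)

gene_row <- function(start, end, strand = "+", id = "g1", chrom = "c1")
  data.frame(gene_id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)

test_that("TTS extension arithmetic is strand-aware", {
  # segment ending exactly at the TTS: extension 0
  r <- compute_tts_extension(gene_row(1000, 5000), seg_row(900, 5000))
  expect_true(r$eligible)
  expect_equal(r$extension, 0)
  # plus strand, TTS 5000, segment [3000, 7500): 2500 nt
  r <- compute_tts_extension(gene_row(1000, 5000), seg_row(3000, 7500))
  expect_equal(r$extension, 2500)
  # minus strand, TTS = start = 4000, segment [1800, 6000): 2200 nt
  r <- compute_tts_extension(gene_row(4000, 9000, "-"),
                             seg_row(1800, 6000, "-"))
  expect_equal(r$extension, 2200)
  # mirror-image of the plus-strand case (strand-flip oracle)
  L <- 10000
  rp <- compute_tts_extension(gene_row(1000, 5000), seg_row(3000, 7500))
  rm <- compute_tts_extension(gene_row(L - 5000, L - 1000, "-"),
                              seg_row(L - 7500, L - 3000, "-"))
  expect_equal(rm$extension, rp$extension)
  # no overlap of the 3' end: ineligible, not an error
  r <- compute_tts_extension(gene_row(1000, 5000), seg_row(6000, 8000))
  expect_false(r$eligible)
})

test_that("TTS offset distribution uses only genes called in every state", {
  genes <- rbind(gene_row(1000, 3000, id = "a"),
                 gene_row(6000, 9000, id = "b"))
  segs <- list(
    ET = rbind(seg_row(900, 3600, state = "ET"),
               seg_row(5900, 9600, state = "ET")),
    LT = rbind(seg_row(900, 5500, state = "LT")))  # gene b missing in LT
  h <- tts_offset_distribution(segs, genes, window = 20000, bin = 50)
  expect_equal(attr(h, "genes_used"), "a")
  for (st in c("ET", "LT"))
    expect_equal(sum(h$count[h$state == st]), 1L)
  # modes at the per-state offsets
  expect_equal(h$bin_start[h$state == "ET" & h$count > 0], 600)
  expect_equal(h$bin_start[h$state == "LT" & h$count > 0], 2500)
  # all segments at the TTS: spike in the zero bin
  segs0 <- list(ET = rbind(seg_row(900, 3000, state = "ET"),
                           seg_row(5900, 9000, state = "ET")),
                LT = rbind(seg_row(900, 3000, state = "LT"),
                           seg_row(5900, 9000, state = "LT")))
  h0 <- tts_offset_distribution(segs0, genes, window = 1000, bin = 50)
  expect_true(all(h0$bin_start[h0$count > 0] == 0))
  expect_warning(
    tts_offset_distribution(list(ET = seg_row(1, 2), LT = seg_row(1, 2)),
                            genes), "no genes")
})

test_that("mean extension difference and its bootstrap SE", {
  recs <- function(ids, ext) data.frame(gene_id = ids, state = "x",
                                        eligible = TRUE, extension = ext)
  ident <- recs(c("a", "b", "c"), c(5, 10, 15))
  r <- mean_extension_difference(ident, ident, n_boot = 200)
  expect_equal(r$delta_nt, 0)
  expect_equal(r$se, 0)
  r <- mean_extension_difference(recs(c("a", "b"), c(100, 200)),
                                 recs(c("a", "b"), c(400, 500)))
  expect_equal(r$delta_nt, 300)
  expect_error(mean_extension_difference(recs("a", 1), recs("a", 1)),
               "insufficient")
})

test_that("elongation-rate arithmetic and properties", {
  r <- elongation_rate(2000, 5)
  expect_equal(r$kb_per_min, 2 / (5 * 1440))
  expect_equal(r$rounded, 3e-4)
  expect_equal(elongation_rate(0, 5)$kb_per_min, 0)
  expect_equal(elongation_rate(1890, 7.3)$kb_per_min, 0.00018, tolerance = 0.01)
  expect_error(elongation_rate(100, 0), "positive")
  # linear in delta_nt, inverse in delta_days
  set.seed(1)
  for (i in 1:20) {
    nt <- runif(1, 10, 5000); dd <- runif(1, 0.5, 20); k <- runif(1, 1, 9)
    expect_equal(elongation_rate(k * nt, dd)$kb_per_min,
                 k * elongation_rate(nt, dd)$kb_per_min)
    expect_equal(elongation_rate(nt, k * dd)$kb_per_min,
                 elongation_rate(nt, dd)$kb_per_min / k)
  }
})

test_that("days-below-threshold difference matches hand computation", {
  d <- state_design("nascent", 3L)
  expect_equal(delta_days_below_threshold(d[d$state == "ET", ],
                                          d[d$state == "LT", ]), 7.3)
  expect_equal(delta_days_below_threshold(d[d$state == "ET", ],
                                          d[d$state == "ET", ]), 0)
  # spreadsheet oracle on an arbitrary table
  da <- data.frame(days_below8 = c(1, 2, 6))
  db <- data.frame(days_below8 = c(4, 8))
  expect_equal(delta_days_below_threshold(da, db), mean(c(4, 8)) - 3)
  expect_error(delta_days_below_threshold(data.frame(x = 1), db),
               "days_below8")
})

test_that("annotation revision substitutes, merges, trims and drops", {
  # substitution + trim: gene [1000,5000) + segment [1200,8000) -> [1500,8000)
  g <- gene_row(1000, 5000)
  seg <- seg_row(1200, 8000, state = "merged")
  rv <- revise_annotation(g, seg)
  expect_equal(c(rv$start, rv$end), c(1500, 8000))
  expect_true(rv$de_eligible)
  # no extension: original minus the 5' trim
  rv2 <- revise_annotation(g, seg_row(1200, 4500, state = "merged"))
  expect_equal(c(rv2$start, rv2$end), c(1500, 5000))
  # minus strand trim comes off the interval end
  gm <- gene_row(4000, 9000, "-")
  rv3 <- revise_annotation(gm, seg_row(1800, 6000, "-", "merged"))
  expect_equal(c(rv3$start, rv3$end), c(1800, 8500))
  # tandem genes whose extended bodies overlap merge with ':' names
  gg <- rbind(gene_row(1000, 5000, id = "geneA"),
              gene_row(6000, 9000, id = "geneB"))
  rv4 <- revise_annotation(gg, seg_row(1200, 7000, state = "merged"))
  expect_equal(rv4$name, "geneA:geneB")
  expect_equal(rv4$n_members, 2L)
  expect_false(rv4$de_eligible)
  # trim longer than the body: dropped and logged
  tiny <- gene_row(100, 620, id = "tiny")
  rv5 <- revise_annotation(tiny, seg_row(5000, 6000, state = "merged"))
  expect_equal(nrow(rv5), 0L)
  expect_equal(attr(rv5, "dropped"), "tiny")
})

test_that("every gene appears in exactly one body name or the drop log", {
  g <- tiny_genome()
  d <- state_design("nascent", 1L)
  nas <- simulate_nascent(g$genes, g$truth, d, seed = 3, noise = FALSE,
                          background = 0)
  per_state <- lapply(levels(d$state), function(st)
    call_transcribed_segments(pool_state_coverage(nas$tracks, d, st),
                              "threshold", smooth_bp = 1, threshold = 0.5,
                              state = st))
  merged <- merge_segments_across_states(per_state)
  rv <- revise_annotation(g$genes, merged)
  names_all <- c(unlist(strsplit(rv$name, ":")),
                 unlist(strsplit(attr(rv, "dropped"), ":")))
  expect_setequal(names_all, g$genes$gene_id)
  expect_equal(anyDuplicated(names_all), 0L)
  # revised bodies never overlap on the same strand
  for (s in c("+", "-")) {
    sub <- rv[rv$strand == s, ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
})

test_that("gene-body quantification equals the base-wise oracle", {
  set.seed(77)
  v <- rpois(4000, 1.5)
  tr <- cov_set(coverage_track(c(c1 = 4000L)), "c1", "+", v)
  bodies <- data.frame(name = c("b1", "b2"), chrom = "c1",
                       start = c(100L, 2000L), end = c(1100L, 3500L),
                       strand = "+")
  m <- quantify_gene_bodies(bodies, list(s1 = tr))
  expect_equal(unname(m[, 1]), c(sum(v[101:1100]), sum(v[2001:3500])))
  # constant coverage 2 over a 1000-nt body
  tr2 <- cov_set(coverage_track(c(c1 = 4000L)), "c1", "+", rep(2, 4000))
  expect_equal(unname(quantify_gene_bodies(bodies[1, ],
                                           list(s = tr2))[1, 1]), 2000)
  # zero coverage: zero row
  tr0 <- coverage_track(c(c1 = 4000L))
  expect_true(all(quantify_gene_bodies(bodies, list(s = tr0)) == 0))
})

test_that("TPM normalization identities", {
  one <- matrix(50, 1, 1, dimnames = list("g", "s"))
  expect_equal(unname(compute_tpm(one, 1000)[1, 1]), 1e6)
  two <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s"))
  tpm <- compute_tpm(two, c(1000, 2000))
  expect_equal(unname(tpm["a", 1] / tpm["b", 1]), 2)
  set.seed(8)
  m <- matrix(rpois(60, 40), 10, 6)
  tpm <- compute_tpm(m, sample(500:5000, 10))
  expect_true(all(abs(colSums(tpm) - 1e6) < 1e-6))
  expect_warning(compute_tpm(cbind(m, 0), c(sample(500:5000, 10))),
                 "all-zero")
})
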