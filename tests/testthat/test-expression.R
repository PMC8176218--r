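# normalization/filtering, NB LRT DE, pattern assignment, GC comparison

test_that("pass filter implements the declared rule exactly", {
  d <- state_design("rna", 5L)
  set.seed(4)
  counts <- matrix(rnbinom(200 * nrow(d), mu = 150, size = 5), 200,
                   dimnames = list(sprintf("g%03d", 1:200), d$sample))
  nf <- normalize_and_filter(counts, d)
  # brute-force re-evaluation of the rule
  norm <- sweep(counts, 2, nf$size_factors, "/")
  lg <- log2(norm + 8)
  want <- rep(FALSE, 200)
  for (st in levels(d$state)) {
    cols <- d$sample[d$state == st]
    want <- want | rowSums(lg[, cols] >= 7) >= 4
  }
  expect_equal(nf$keep, want)
  expect_equal(rownames(nf$log), rownames(counts)[want])

  # constant high counts: everything retained, size factors 1
  hi <- matrix(1000L, 20, nrow(d),
               dimnames = list(sprintf("h%d", 1:20), d$sample))
  nf2 <- normalize_and_filter(hi, d)
  expect_true(all(nf2$keep))
  expect_true(all(abs(nf2$size_factors - 1) < 1e-12))

  # boundary: level just over 7 in exactly 4/5 IBA samples only
  b <- matrix(1, 1, nrow(d), dimnames = list("edge", d$sample))
  b[1, d$sample[d$state == "IBA"][1:4]] <- 2^7.1
  nf3 <- normalize_and_filter(rbind(hi, edge = b[1, ]), d)
  expect_true(nf3$keep[["edge"]])

  z <- hi; z[, 1] <- 0L
  expect_error(normalize_and_filter(z, d), "all-zero")
})

test_that("NB LRT separates dynamic from flat genes and agrees with DESeq2", {
  g <- build_genome(sim_config(n_genes = 40L, chrom_length = 1200000L,
                               seed = 19L))
  d <- state_design("rna", 5L)
  counts <- simulate_expression(g$genes, g$truth, d, seed = 23)
  nf <- normalize_and_filter(counts, d, min_level = 0)
  de <- nb_lrt_de(counts[nf$keep, ], d, size_factors = nf$size_factors)
  expect_true(all(de$q >= de$p, na.rm = TRUE))
  expect_true(all(de$q <= 1 & de$q >= 0, na.rm = TRUE))
  # BH monotonicity: q is non-decreasing along the p ordering
  ok <- !is.na(de$p)
  expect_false(is.unsorted(de$q[ok][order(de$p[ok])]))
  truth_de <- g$truth$genes$pattern[match(de$gene_id,
                                          g$truth$genes$gene_id)] != "flat"
  # dynamic genes (8-fold range, dispersion 0.05, n = 5) are called
  expect_gt(mean(de$de[truth_de]), 0.9)
  expect_lt(mean(de$de[!truth_de]), 0.05)

  # independent oracle: DESeq2 LRT on the same matrix ranks genes alike
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts[nf$keep, ],
    colData = S4Vectors::DataFrame(state = d$state, sex = factor(d$sex)),
    design = ~ sex + state)
  dds <- DESeq2::DESeq(dds, test = "LRT", reduced = ~ sex, quiet = TRUE)
  pd <- DESeq2::results(dds)$pvalue
  both <- !is.na(pd) & !is.na(de$p)
  expect_gt(cor(rank(pd[both]), rank(de$p[both])), 0.9)
})

test_that("pattern assignment: identity, invariance, ties, degeneracy", {
  lib <- pattern_library_rna()
  m <- rbind(Winter = lib["Winter_high", ],
             scaled = 5 * lib["Winter_high", ] + 3,
             flatg = rep(2, 5))
  asn <- assign_pattern(m, lib)
  expect_equal(asn$pattern[1], "Winter_high")
  expect_equal(asn$r[1], 1)
  expect_equal(asn$pattern[2], "Winter_high")   # scale/shift invariance
  expect_equal(asn$pattern[3], "Unassigned")
  expect_equal(asn$reason[3], "zero variance")
  # exact tie breaks to library order and is logged
  dup <- rbind(A = c(0, 1, 1, 1, 0), B = c(0, 1, 1, 1, 0))
  colnames(dup) <- colnames(lib)
  asn2 <- assign_pattern(matrix(c(0, 1, 1, 1, 0), 1,
                                dimnames = list("t", colnames(lib))), dup)
  expect_equal(asn2$pattern, "A")
  expect_equal(attr(asn2, "ties"), "t")
})

test_that("pattern recovery on noisy simulated genes exceeds 95%", {
  set.seed(71)
  lib <- pattern_library_rna()
  n <- 300
  truthp <- sample(rownames(lib), n, replace = TRUE)
  # log-expression scale: templates span log2(8) = 3 with noise sd 0.2
  means <- t(vapply(seq_len(n), function(i)
    3 * lib[truthp[i], ] + 5 + rnorm(5, 0, 0.2), numeric(5)))
  colnames(means) <- colnames(lib)
  rownames(means) <- sprintf("g%d", seq_len(n))
  asn <- assign_pattern(means, lib)
  expect_gt(mean(asn$pattern == truthp), 0.95)
})

test_that("pairwise log2 fold changes recover injected effects", {
  d <- state_design("rna", 5L)
  norm <- matrix(100, 3, nrow(d), dimnames = list(c("a", "b", "c"),
                                                  d$sample))
  fc <- pairwise_log2fc(norm, d, "SA", "IBA", pseudo = 0)
  expect_true(all(fc == 0))
  norm["b", d$state == "IBA"] <- 800
  fc <- pairwise_log2fc(norm, d, "SA", "IBA", pseudo = 0)
  expect_equal(unname(fc["b"]), 3)
  # injected 2-fold effects across many genes
  set.seed(15)
  n <- 400
  base <- exp(rnorm(n, log(200), 0.5))
  m <- sapply(seq_len(nrow(d)), function(j) {
    mu <- base * ifelse(d$state[j] == "Ar", 2, 1)
    rpois(n, mu)
  })
  rownames(m) <- sprintf("g%d", 1:n)
  colnames(m) <- d$sample
  fc <- pairwise_log2fc(m, d, "SA", "Ar", pseudo = 1)
  expect_lt(abs(median(abs(fc)) - 1), 0.1)
})

test_that("GC comparison finds the injected cold bias", {
  set.seed(6)
  gc <- c(setNames(rnorm(60, 0.60, 0.02), sprintf("up%d", 1:60)),
          setNames(rnorm(60, 0.45, 0.02), sprintf("dn%d", 1:60)))
  cmp <- gc_content_compare(
    list(`IBA:Ar` = list(up = sprintf("up%d", 1:60),
                         down = sprintf("dn%d", 1:60)),
         self = list(up = sprintf("up%d", 1:30),
                     down = sprintf("up%d", 31:60)),
         tiny = list(up = "up1", down = "dn1"),
         empty = list(up = character(0), down = "dn1")),
    gc)
  expect_lt(cmp$p[1], 0.01)
  expect_gt(cmp$median_gc_up[1], cmp$median_gc_down[1])
  expect_gt(cmp$p[2], 0.05)       # same population: no difference
  expect_true(cmp$low_n[3])       # single-gene sets flagged
  expect_true(is.na(cmp$p[4]))    # empty set: NA row
})
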