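# A-to-I editing statistics

mk_site_rows <- function(site_id, states, ref_count, alt_count) {
  data.frame(site_id = site_id, chrom = "c1", pos0 = 100L, strand = "+",
             ref = "A", alt = "G",
             sample = paste0(states, "_", seq_along(states)),
             state = states, ref_count = ref_count, alt_count = alt_count,
             stringsAsFactors = FALSE)
}

test_that("coverage filter applies the depth/sample rule", {
  tab <- rbind(mk_site_rows("deep", rep("SA", 8), rep(40, 8), rep(10, 8)),
               mk_site_rows("six", rep("SA", 6), rep(40, 6), rep(10, 6)),
               mk_site_rows("shallow", rep("SA", 8), rep(4, 8), rep(1, 8)))
  kept <- filter_sites_by_coverage(tab)
  expect_setequal(unique(kept$site_id), "deep")
  # brute-force oracle on a random table
  set.seed(9)
  rt <- do.call(rbind, lapply(1:30, function(i)
    mk_site_rows(paste0("s", i), rep("SA", 10),
                 rpois(10, 12), rpois(10, 2))))
  kept <- unique(filter_sites_by_coverage(rt, 10, 7)$site_id)
  oracle <- vapply(split(rt, rt$site_id), function(s)
    sum(s$ref_count + s$alt_count >= 10) >= 7, logical(1))
  expect_setequal(kept, names(oracle)[oracle])
})

test_that("state-variability G-test: null, degenerate and injected", {
  flat <- mk_site_rows("f", c("SA", "IBA", "Ent", "Ar", "SpD"),
                       rep(80, 5), rep(20, 5))
  r <- test_state_variability(flat)
  expect_gt(r$p, 0.99)
  allref <- mk_site_rows("z", c("SA", "IBA", "Ar"), rep(50, 3), rep(0, 3))
  r <- test_state_variability(allref)
  expect_equal(r$p, 1)
  hot <- mk_site_rows("h", c("SA", "IBA", "Ent", "Ar", "SpD"),
                      c(95, 95, 95, 60, 95), c(5, 5, 5, 40, 5))
  r <- test_state_variability(rbind(flat, hot))
  expect_lt(r$q[r$site_id == "h"], 0.05)
  expect_equal(unname(r[r$site_id == "h", "ef_Ar"]), 0.4)
})

test_that("substitution spectrum flips minus-strand sites (involution)", {
  sites <- data.frame(ref = c("A", "T", "C", "G"),
                      alt = c("G", "C", "T", "A"),
                      strand = c("+", "-", "+", "-"))
  sp <- substitution_spectrum(sites)
  expect_equal(unname(sp[["A>G"]]), 2L)  # plus A>G and minus T>C
  expect_equal(unname(sp[["C>T"]]), 2L)  # plus C>T and minus G>A
  expect_equal(sum(sp), 4L)
  # involution: flipping strand twice returns the original class
  flip2 <- sites; flip2$strand <- "+"
  sp0 <- substitution_spectrum(flip2)
  once <- sites; once$strand <- "-"
  twice_ref <- chartr("ACGT", "TGCA", chartr("ACGT", "TGCA", once$ref))
  expect_equal(twice_ref, once$ref)
  # ambiguous bases are excluded and counted
  amb <- data.frame(ref = c("A", "N"), alt = c("G", "G"),
                    strand = c("+", "+"))
  spa <- substitution_spectrum(amb)
  expect_equal(attr(spa, "excluded"), 1L)
  expect_equal(sum(spa), 1L)
})

test_that("cross-assay filter removes exactly the shared sites", {
  rna <- data.frame(chrom = "c1", pos0 = 1:719)
  nas <- data.frame(chrom = "c1", pos0 = c(1:14, 5000:5010))
  r <- cross_assay_filter(rna, nas)
  expect_equal(r$n_input, 719L)
  expect_equal(r$n_excluded, 14L)
  expect_equal(r$n_retained, 705L)
  expect_equal(r$n_retained + r$n_excluded, r$n_input)
  # empty nascent list: identity
  r0 <- cross_assay_filter(rna, data.frame(chrom = character(0),
                                           pos0 = integer(0)))
  expect_equal(r0$n_retained, 719L)
})

test_that("simulated polymorphisms are all and only the sites removed", {
  g <- tiny_genome()
  d_rna <- state_design("rna", 5L)
  d_nas <- state_design("nascent", 3L)
  sim <- simulate_editing(g$genes, g$truth, d_rna, d_nas, seed = 31,
                          n_sites = 80L, n_polymorphic = 12L, depth = 60)
  nas_var <- detect_variant_sites(sim$nascent)
  cand <- unique(sim$rna[, c("site_id", "chrom", "pos0")])
  r <- cross_assay_filter(cand, nas_var)
  poly <- sim$truth_sites$site_id[sim$truth_sites$polymorphic]
  expect_setequal(setdiff(cand$site_id, r$retained$site_id), poly)
})

test_that("pairwise differential editing matches the closed-form G-test", {
  eq <- mk_site_rows("e", c("Ent", "Ar"), c(70, 70), c(30, 30))
  r <- pairwise_differential_editing(eq, "Ent", "Ar")
  expect_equal(r$def, 0)
  expect_gt(r$p, 0.99)
  hot <- mk_site_rows("h", c("Ent", "Ar"), c(95, 70), c(5, 30))
  r <- pairwise_differential_editing(hot, "Ent", "Ar")
  expect_equal(r$def, 0.25)
  expect_lt(r$p, 0.001)
  # closed-form check: G = 2 sum O log(O/E)
  m <- rbind(c(95, 5), c(70, 30))
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(r$g, 2 * sum(m * log(m / e)), tolerance = 1e-12)
  # zero depth in one state: NA
  z <- mk_site_rows("z", c("Ent", "Ar"), c(0, 50), c(0, 10))
  r <- pairwise_differential_editing(z, "Ent", "Ar")
  expect_true(is.na(r$p))
})

test_that("cold-enriched detection requires Ar above every state", {
  states <- c("SA", "IBA", "Ent", "Ar", "SpD")
  hot <- mk_site_rows("hot", states, c(95, 95, 95, 60, 95),
                      c(5, 5, 5, 40, 5))
  warm <- mk_site_rows("warm", states, c(60, 95, 95, 95, 95),
                       c(40, 5, 5, 5, 5))
  hits <- cold_enriched_sites(rbind(hot, warm), "Ar")
  expect_equal(hits, "hot")
})

test_that("region annotation respects precedence and missing chromosomes", {
  g <- tiny_genome()
  ft <- gene_features(g$genes)
  cds <- ft[ft$type == "cds", ][1, ]
  u3 <- ft[ft$type == "utr3" & ft$gene_id == cds$gene_id, ]
  intr <- ft[ft$type == "intron", ]
  sites <- data.frame(
    chrom = c(cds$chrom, u3$chrom, "chrZZ"),
    pos0 = c(cds$start, u3$start, 5L))
  ann <- annotate_region(sites, ft)
  expect_equal(ann, c("CDS", "3'UTR", "intergenic"))
  if (nrow(intr)) {
    expect_equal(annotate_region(data.frame(chrom = intr$chrom[1],
                                            pos0 = intr$start[1] + 1L),
                                 ft), "intron")
  }
  # intergenic gap between genes
  mid <- g$genes$end[1] + 50L
  expect_equal(annotate_region(data.frame(chrom = "chr1", pos0 = mid), ft),
               "intergenic")
})

test_that("overlap test equals the enumeration oracle on a small universe", {
  universe <- 12L
  ref <- c("u1", "u2", "u3", "u4")
  sites <- c("u1", "u2", "u9")
  r <- overlap_reference(sites, ref, universe)
  expect_equal(r$n_overlap, 2L)
  # enumerate all C(12, 3) site draws and count overlaps >= 2
  all_sets <- combn(12, 3)
  ov <- colSums(matrix(all_sets %in% 1:4, nrow = 3))
  expect_equal(r$p, mean(ov >= 2), tolerance = 1e-12)
  # disjoint sets
  r0 <- overlap_reference(c("a", "b"), c("c", "d"), 20L)
  expect_equal(r0$n_overlap, 0L)
  expect_equal(r0$p, 1)
})
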