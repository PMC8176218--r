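# Concordance of steady-state and nascent differential expression, and
# AU-rich-element k-mer enrichment.

#' Intersect DE gene sets from the two assays
#'
#' @param de_rna,de_nascent character vectors of DE gene ids.
#' @return list: `both`, `rna_only`, `nascent_only`, and `counts` (named
#'   integer vector).  `|both| + |rna_only| = |de_rna|` always.
#' @export
intersect_de_sets <- function(de_rna, de_nascent) {
  de_rna <- unique(de_rna); de_nascent <- unique(de_nascent)
  both <- intersect(de_rna, de_nascent)
  if (!length(both)) warning("empty DE intersection")
  list(both = both,
       rna_only = setdiff(de_rna, de_nascent),
       nascent_only = setdiff(de_nascent, de_rna),
       counts = c(both = length(both),
                  rna_only = length(de_rna) - length(both),
                  nascent_only = length(de_nascent) - length(both)))
}

#' Build per-gene concordance records for one transition
#'
#' @param fc_rna,fc_nascent named log2 fold-change vectors (shared gene id
#'   namespace); nascent LT is conventionally matched to steady-state Ar.
#' @param de_rna,de_nascent DE gene id vectors.
#' @param transition label, e.g. `"IBA:Ar"`.
#' @return data.frame: `gene_id`, `fc_rna`, `fc_nascent`, `de_rna`,
#'   `de_nascent`, `transition`.
#' @export
concordance_records <- function(fc_rna, fc_nascent, de_rna = character(0),
                                de_nascent = character(0),
                                transition = NA_character_) {
  ids <- intersect(names(fc_rna), names(fc_nascent))
  data.frame(gene_id = ids, fc_rna = unname(fc_rna[ids]),
             fc_nascent = unname(fc_nascent[ids]),
             de_rna = ids %in% de_rna, de_nascent = ids %in% de_nascent,
             transition = transition, stringsAsFactors = FALSE)
}

#' Fold-change correlation between assays
#'
#' @param records data.frame from [concordance_records()].
#' @return list: `r` (Pearson), `p` (two-sided), `n`; `r = NA` with a
#'   reason when a column has zero variance.
#' @export
fc_correlation <- function(records) {
  stopifnot(nrow(records) >= 3)
  if (sd(records$fc_rna) == 0 || sd(records$fc_nascent) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(records),
                reason = "zero variance"))
  ct <- cor.test(records$fc_rna, records$fc_nascent, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(records))
}

#' Classify concordance quadrants
#'
#' Sign-based quadrants of (steady-state, nascent) fold change:
#' `pos_up` (both up), `pos_down` (both down), `stable_RNA` (RNA up,
#' transcription down -- cold-stabilised transcripts), `deferred`
#' (transcription up, RNA down).  Genes with a zero fold change are
#' assigned `concordant_null` and logged.
#'
#' @param records data.frame from [concordance_records()].
#' @return `records` with added `quadrant` column; attribute `n_null`
#'   counts zero-FC genes; attribute `summary` tabulates quadrants.
#' @export
classify_concordance <- function(records) {
  q <- ifelse(records$fc_rna > 0 & records$fc_nascent > 0, "pos_up",
       ifelse(records$fc_rna < 0 & records$fc_nascent < 0, "pos_down",
       ifelse(records$fc_rna > 0 & records$fc_nascent < 0, "stable_RNA",
       ifelse(records$fc_rna < 0 & records$fc_nascent > 0, "deferred",
              "concordant_null"))))
  records$quadrant <- q
  attr(records, "n_null") <- sum(q == "concordant_null")
  attr(records, "summary") <- table(factor(
    q, levels = c("pos_up", "pos_down", "stable_RNA", "deferred",
                  "concordant_null")))
  records
}

#' k-mer enrichment of a foreground vs a background sequence set
#'
#' Counts all overlapping k-mers (alphabet ACGT; U is mapped to T) in both
#' sets and tests each k-mer's foreground count against the background
#' frequency with a two-sided binomial test, BH-adjusted.  Sequences
#' shorter than `k` are skipped and counted.  The summary reports the AU
#' (AT) fraction of the 20 most enriched k-mers.
#'
#' @param fg,bg character vectors or `DNAStringSet`s of 3' non-coding
#'   sequences.
#' @param k k-mer length (default 6).
#' @return data.frame (one row per k-mer present in either set): `kmer`,
#'   `fg_count`, `bg_count`, `fg_freq`, `bg_freq`, `log2_enrichment`, `p`,
#'   `q`; attributes `skipped` (fg/bg too-short counts) and
#'   `top20_au_fraction`.
#' @export
kmer_enrichment <- function(fg, bg, k = 6L) {
  count_set <- function(x) {
    if (is.character(x)) x <- toupper(gsub("U", "T", toupper(x)))
    xs <- Biostrings::DNAStringSet(x)
    short <- sum(Biostrings::width(xs) < k)
    xs <- xs[Biostrings::width(xs) >= k]
    if (length(xs) == 0) return(list(counts = NULL, skipped = short))
    m <- Biostrings::oligonucleotideFrequency(xs, width = k)
    list(counts = colSums(m), skipped = short)
  }
  cf <- count_set(fg); cb <- count_set(bg)
  if (is.null(cf$counts))
    stop("all ", cf$skipped, " foreground sequences are shorter than k")
  if (is.null(cb$counts))
    stop("all ", cb$skipped, " background sequences are shorter than k")
  fg_tot <- sum(cf$counts); bg_tot <- sum(cb$counts)
  present <- cf$counts > 0 | cb$counts > 0
  kmers <- names(cf$counts)[present]
  fgc <- cf$counts[present]; bgc <- cb$counts[present]
  # background frequency with a half-count floor so p0 is never 0 or 1
  p0 <- pmin(pmax((bgc + 0.5) / (bg_tot + 1), 1e-12), 1 - 1e-12)
  pv <- vapply(seq_along(kmers), function(i)
    binom.test(fgc[i], fg_tot, p0[i])$p.value, numeric(1))
  out <- data.frame(kmer = kmers, fg_count = as.integer(fgc),
                    bg_count = as.integer(bgc),
                    fg_freq = fgc / fg_tot, bg_freq = bgc / bg_tot,
                    log2_enrichment = log2(((fgc + 0.5) / fg_tot) /
                                             ((bgc + 0.5) / bg_tot)),
                    p = pv, q = p.adjust(pv, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, -out$log2_enrichment), ]
  rownames(out) <- NULL
  top <- head(out[out$log2_enrichment > 0, ], 20)
  au <- vapply(strsplit(top$kmer, ""), function(ch)
    mean(ch %in% c("A", "T", "U")), numeric(1))
  attr(out, "skipped") <- c(fg = cf$skipped, bg = cb$skipped)
  attr(out, "top20_au_fraction") <- if (nrow(top)) mean(au) else NA_real_
  out
}

#' Extract 3' non-coding sequences of genes
#'
#' The annotated 3'UTR when present, otherwise the final `fallback_nt`
#' bases of the gene, in gene sense (5'->3').
#'
#' @param genes gene annotation.
#' @param seqs `DNAStringSet` of chromosomes.
#' @param fallback_nt length used when `utr3_len` is missing or zero.
#' @return named character vector of sequences.
#' @export
three_prime_sequences <- function(genes, seqs, fallback_nt = 500L) {
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    u3 <- if (!is.null(g$utr3_len) && !is.na(g$utr3_len) && g$utr3_len > 0)
      g$utr3_len else fallback_nt
    u3 <- min(u3, g$end - g$start)
    sq <- if (g$strand == "+")
      Biostrings::subseq(seqs[[g$chrom]], g$end - u3 + 1, g$end)
    else Biostrings::reverseComplement(
      Biostrings::subseq(seqs[[g$chrom]], g$start + 1, g$start + u3))
    out[i] <- as.character(sq)
  }
  setNames(out, genes$gene_id)
}
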