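# Genome and gene-model simulation.
# All coordinates 0-based half-open; TTS of a minus-strand gene = interval
# start.

rand_dna <- function(n, gc) {
  if (n == 0) return(character(0))
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

revcomp_chars <- function(x) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}

#' Build a synthetic genome, gene models and truth table
#'
#' Places non-overlapping genes (optionally one same-strand tandem pair) on
#' random-sequence chromosomes, assigns each gene a co-expression pattern, a
#' GC class, an AU-rich-motif count in its 3' non-coding sequence and a true
#' per-state 3' readthrough extension.  Genes carry a simple sub-structure
#' (5'UTR / CDS with optional single intron / 3'UTR) used by the
#' editing-site region classifier.
#'
#' Genes whose pattern peaks in the cold (`Cold_high_*`) draw the `high` GC
#' target and `high` AU-motif density; all others draw `low`.  The 3'
#' non-coding (3'UTR) sequence carries exactly the configured number of
#' motif copies; non-motif bases are emitted at a compensated GC so the
#' whole gene hits its GC target.
#'
#' @param config a [sim_config()].
#' @return list with elements `seqs` (`Biostrings::DNAStringSet`), `genes`
#'   (annotation data.frame), `truth` (list with `genes` data.frame and the
#'   config), `chrom_lengths`.
#' @export
build_genome <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- setNames(rep(as.integer(config$chrom_length),
                                config$n_chromosomes), chroms)

  min_body <- config$utr5_length + config$utr3_length +
    config$intron_length + 100L
  if (n > 0 && config$gene_length_range[1] < min_body)
    stop("gene_length_range too short for UTR/intron structure (need >= ",
         min_body, " nt)")

  ext_mean <- config$extension_truth$mean
  ext_sd <- config$extension_truth$sd
  margin <- max(ext_mean) + 6 * ext_sd + 10

  genes <- NULL
  if (n > 0) {
    chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n))
    len <- round(runif(n, config$gene_length_range[1],
                       config$gene_length_range[2]))
    gap <- round(runif(n, config$intergenic_gap_range[1],
                       config$intergenic_gap_range[2]))
    strand <- ifelse(runif(n) < config$strand_balance, "+", "-")
    if (config$tandem_pair && n >= 2) {
      strand[1:2] <- "+"
      gap[2] <- config$tandem_gap
      chrom_of[1:2] <- 1L
    }
    start <- integer(n); end <- integer(n)
    pos <- setNames(rep(0L, config$n_chromosomes), chroms)
    for (i in seq_len(n)) {
      ch <- chrom_of[i]
      s <- pos[ch] + gap[i]
      e <- s + len[i]
      if (e > config$chrom_length - margin)
        stop("genes cannot fit in chromosome: increase chrom_length or ",
             "reduce n_genes")
      start[i] <- s; end[i] <- e; pos[ch] <- e
    }
    pattern <- sample(names(config$pattern_mix), n, replace = TRUE,
                      prob = config$pattern_mix)
    expr_level <- exp(rnorm(n, config$expression_level[["meanlog"]],
                            config$expression_level[["sdlog"]]))
    gc_class <- ifelse(startsWith(pattern, "Cold_high"), "high", "low")
    gc_target <- unname(config$gc[gc_class])
    n_motif <- unname(config$motif$density[gc_class])
    has_intron <- runif(n) < config$intron_fraction

    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = chroms[chrom_of], start = start, end = end, strand = strand,
      length = len, utr5_len = config$utr5_length,
      utr3_len = config$utr3_length,
      has_intron = has_intron, stringsAsFactors = FALSE)

    # per-gene, per-state true extensions (0-mean states are exactly 0)
    for (st in names(ext_mean)) {
      m <- ext_mean[[st]]
      ext <- if (m == 0) rep(0, n)
             else pmax(0, round(rnorm(n, m, ext_sd)))
      tts <- ifelse(strand == "+", end, start)
      room <- ifelse(strand == "+", config$chrom_length - tts, tts)
      clipped <- ext > room
      genes[[paste0("ext_", st)]] <- pmin(ext, room)
      genes[[paste0("clip_", st)]] <- clipped
    }
  }

  # sequences: intergenic background GC 0.42, genes at their target
  seq_chars <- lapply(chrom_lengths, function(L) rand_dna(L, 0.42))
  n_au_real <- integer(n)
  gc_real <- numeric(n)
  motif <- strsplit(config$motif$motif, "")[[1]]
  if (n > 0) for (i in seq_len(n)) {
    L <- genes$length[i]
    nm <- n_motif[i]
    mot_bases <- nm * length(motif)
    gc_mot <- sum(motif %in% c("G", "C")) * nm
    gc_adj <- min(1, max(0, (gc_target[i] * L - gc_mot) / (L - mot_bases)))
    body <- rand_dna(L, gc_adj)
    # motifs evenly spaced in the 3' non-coding (3'UTR) sequence, gene sense
    u3 <- config$utr3_length
    if (nm > 0 && u3 >= length(motif)) {
      nm_fit <- min(nm, floor(u3 / (length(motif) + 3)))
      offs <- round(seq(0, u3 - length(motif), length.out = max(nm_fit, 1)))
      offs <- offs[seq_len(nm_fit)]
      if (genes$strand[i] == "+") {
        for (o in offs)
          body[(L - u3 + o + 1):(L - u3 + o + length(motif))] <- motif
      } else {
        rc <- revcomp_chars(motif)
        for (o in offs)
          body[(u3 - o - length(motif) + 1):(u3 - o)] <- rc
      }
      n_au_real[i] <- nm_fit
    }
    gc_real[i] <- mean(body %in% c("G", "C"))
    ch <- genes$chrom[i]
    seq_chars[[ch]][(genes$start[i] + 1):genes$end[i]] <- body
  }

  if (!is.null(config$n_gap_loci)) {
    gl <- config$n_gap_loci
    for (i in seq_len(nrow(gl))) {
      ch <- gl$chrom[i]
      seq_chars[[ch]][(gl$start[i] + 1):(gl$start[i] + gl$length[i])] <- "N"
    }
  }
  seqs <- Biostrings::DNAStringSet(
    vapply(seq_chars, paste, character(1), collapse = ""))
  names(seqs) <- chroms

  truth_genes <- genes
  if (n > 0) {
    truth_genes$pattern <- pattern
    truth_genes$gc_class <- gc_class
    truth_genes$gc_target <- gc_target
    truth_genes$gc_realized <- gc_real
    truth_genes$n_au_motifs <- n_au_real
    truth_genes$expr_level <- expr_level
    lib <- pattern_library_rna()
    for (st in config$states)
      truth_genes[[paste0("mean_", st)]] <- vapply(
        seq_len(n), function(i) expr_level[i] *
          pattern_level(pattern[i], st, lib, config$dynamic_range),
        numeric(1))
  }
  list(seqs = seqs,
       genes = genes,
       truth = list(genes = truth_genes, config = config),
       chrom_lengths = chrom_lengths)
}

#' Expand gene models into sub-features
#'
#' Returns one row per feature (5'UTR, CDS, intron, 3'UTR) per gene in
#' genome coordinates (0-based half-open), for region classification of
#' editing sites.
#'
#' @param genes gene annotation data.frame from [build_genome()].
#' @return data.frame with `gene_id`, `type`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
gene_features <- function(genes) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    u5 <- g$utr5_len; u3 <- g$utr3_len
    if (g$strand == "+") {
      utr5 <- c(g$start, g$start + u5)
      utr3 <- c(g$end - u3, g$end)
      cds <- c(g$start + u5, g$end - u3)
    } else {
      utr5 <- c(g$end - u5, g$end)
      utr3 <- c(g$start, g$start + u3)
      cds <- c(g$start + u3, g$end - u5)
    }
    feats <- data.frame(type = c("utr5", "utr3"),
                        start = c(utr5[1], utr3[1]),
                        end = c(utr5[2], utr3[2]))
    if (isTRUE(g$has_intron)) {
      mid <- floor((cds[1] + cds[2]) / 2)
      half <- 150L
      intr <- c(mid - half, mid + half)
      feats <- rbind(feats,
                     data.frame(type = c("cds", "intron", "cds"),
                                start = c(cds[1], intr[1], intr[2]),
                                end = c(intr[1], intr[2], cds[2])))
    } else {
      feats <- rbind(feats, data.frame(type = "cds", start = cds[1],
                                       end = cds[2]))
    }
    feats$gene_id <- g$gene_id
    feats$chrom <- g$chrom
    feats$strand <- g$strand
    feats
  })
  out <- do.call(rbind, rows)
  out[, c("gene_id", "type", "chrom", "start", "end", "strand")]
}
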