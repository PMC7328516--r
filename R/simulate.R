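#' Simulation configuration
#'
#' Parameters of the synthetic APA study generator. Defaults reflect the
#' emulated design: genes with 2-4 poly(A) sites, two replicates per
#' condition, mild negative-binomial overdispersion, an injected usage shift
#' of two log2 units in a fraction of genes (85% of them towards the
#' proximal PAS), and an optional U-rich motif embedded downstream of the
#' proximal PAS of affected genes.
#'
#' @param n_genes Number of genes.
#' @param pas_per_gene Length-2 integer range of PAS per gene (default 2-4).
#' @param baseline_distal Baseline distal usage fraction within the
#'   proximal/distal pair (default 0.5).
#' @param frac_shifted Fraction of genes with an injected APA shift
#'   (default 0.1).
#' @param effect_size Magnitude of the injected true score in log2
#'   usage-odds units (default 2; proximal shifts get score `-effect_size`).
#' @param prop_proximal Fraction of injected shifts that are proximal
#'   (default 0.85).
#' @param reads_per_gene Negative-binomial mean of a gene's total read count
#'   per replicate before library scaling (default 300).
#' @param dispersion NB dispersion of the gene total (default 0.05;
#'   0 = Poisson). Within a replicate, segment counts are a multinomial
#'   split of the gene total by usage, so each segment count is marginally
#'   negative-binomial with this dispersion while within-replicate usage
#'   proportions stay binomial.
#' @param n_wt,n_mut Replicates per condition (default 2 + 2).
#' @param library_multipliers Per-sample library-size multipliers
#'   (wt samples first); drawn uniformly from [0.75, 1.3] when `NULL`.
#' @param read_length Read length for coverage idealization (default 100).
#' @param pas3_total 3'-end-sequencing reads per gene for the PAS peak track
#'   (default 500).
#' @param frac_ncrna Fraction of ncRNA genes (default 0.1).
#' @param decoy_frac Fraction of genes given a decoy peak < 50 nt from the
#'   distal PAS, exercising peak merging (default 0.05).
#' @param motif Motif embedded downstream of proximal PAS (RNA alphabet,
#'   default `"UUGUUG"`).
#' @param motif_rate_affected,motif_rate_control Embedding rates in
#'   shifted-proximal vs other genes (defaults 0.5 and 0.05).
#' @param seed Integer seed fixing the whole bundle.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 200L, pas_per_gene = c(2L, 4L),
                              baseline_distal = 0.5, frac_shifted = 0.1,
                              effect_size = 2, prop_proximal = 0.85,
                              reads_per_gene = 300, dispersion = 0.05,
                              n_wt = 2L, n_mut = 2L,
                              library_multipliers = NULL, read_length = 100L,
                              pas3_total = 500L, frac_ncrna = 0.1,
                              decoy_frac = 0.05, motif = "UUGUUG",
                              motif_rate_affected = 0.5,
                              motif_rate_control = 0.05, seed = 1L) {
  stopifnot(n_genes >= 1, length(pas_per_gene) == 2,
            pas_per_gene[1] >= 2, pas_per_gene[2] >= pas_per_gene[1],
            baseline_distal > 0, baseline_distal < 1,
            frac_shifted >= 0, frac_shifted <= 1, is.finite(effect_size),
            prop_proximal >= 0, prop_proximal <= 1,
            dispersion >= 0, n_wt >= 1, n_mut >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

# usage fractions over k segments for both conditions of one gene;
# middle PAS share 20% of the mass when present, the proximal/distal pair
# the rest, so the injected log2 odds change acts on the pair only
gene_usage <- function(k, baseline_distal, true_score) {
  core <- if (k > 2L) 0.8 else 1.0
  mid <- if (k > 2L) rep(0.2 / (k - 2L), k - 2L) else numeric(0)
  odds_wt <- baseline_distal / (1 - baseline_distal)
  odds_mut <- odds_wt * 2^true_score
  wt <- c(core / (1 + odds_wt), mid, core * odds_wt / (1 + odds_wt))
  mut <- c(core / (1 + odds_mut), mid, core * odds_mut / (1 + odds_mut))
  list(wt = wt, mut = mut)
}

#' Simulate the ground-truth table
#'
#' Draws each gene's PAS count, injected class and true APA score
#' (log2 of the mutant/wild-type distal:proximal usage odds ratio).
#'
#' @param config A [simulation_config()].
#' @return Data.frame of class `truth_table`: gene_id, n_pas, true_class,
#'   true_score and the four proximal/distal usage fractions.
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("g%04d", seq_len(n))
  k_choices <- seq(config$pas_per_gene[1], config$pas_per_gene[2])
  n_pas <- k_choices[sample.int(length(k_choices), n, replace = TRUE)]
  n_shift <- round(config$frac_shifted * n)
  shifted <- sample(n, n_shift)
  prox_shift <- shifted[seq_len(round(config$prop_proximal * n_shift))]
  true_class <- rep("null", n)
  true_class[shifted] <- "distal"
  true_class[prox_shift] <- "proximal"
  true_score <- ifelse(true_class == "proximal", -config$effect_size,
                       ifelse(true_class == "distal", config$effect_size, 0))
  usage <- t(vapply(seq_len(n), function(i) {
    u <- gene_usage(n_pas[i], config$baseline_distal, true_score[i])
    c(u$wt[1], u$wt[n_pas[i]], u$mut[1], u$mut[n_pas[i]])
  }, numeric(4)))
  structure(data.frame(gene_id = gene_id, n_pas = n_pas,
                       true_class = true_class, true_score = true_score,
                       usage_wt_prox = usage[, 1], usage_wt_dist = usage[, 2],
                       usage_mut_prox = usage[, 3], usage_mut_dist = usage[, 4],
                       stringsAsFactors = FALSE),
            class = c("truth_table", "data.frame"))
}

sim_samples <- function(config) {
  ids <- c(sprintf("wt%d", seq_len(config$n_wt)),
           sprintf("mut%d", seq_len(config$n_mut)))
  cond <- rep(c("wt", "mut"), c(config$n_wt, config$n_mut))
  lib <- config$library_multipliers
  if (is.null(lib)) lib <- stats::runif(length(ids), 0.75, 1.3)
  if (length(lib) != length(ids))
    stop("library_multipliers must have one entry per sample")
  data.frame(sample_id = ids, condition = cond, lib = lib,
             stringsAsFactors = FALSE)
}

# one replicate's segment counts for one gene: NB gene total, multinomial split
sim_gene_counts <- function(usage, mean_total, dispersion) {
  total <- if (dispersion > 0)
    stats::rnbinom(1, mu = mean_total, size = 1 / dispersion)
  else stats::rpois(1, mean_total)
  if (total == 0) return(rep(0L, length(usage)))
  as.integer(stats::rmultinom(1, total, usage))
}

#' Simulate segment counts with ground truth (in memory)
#'
#' The count-level core of the generator: draws the truth table and the
#' per-replicate segment counts without touching the file system. Used for
#' calibration and power studies at scale.
#'
#' @param config A [simulation_config()].
#' @return List with `truth` ([simulate_truth()] table), `counts`
#'   ([segment_counts()]), and `samples` (sample table with library
#'   multipliers).
#' @export
simulate_apa_counts <- function(config) {
  truth <- simulate_truth(config)  # seeds the RNG
  samples <- sim_samples(config)
  n <- nrow(truth)
  rows_gene <- rep(truth$gene_id, truth$n_pas)
  rows_seg <- unlist(lapply(truth$n_pas, seq_len))
  m <- matrix(0, length(rows_gene), nrow(samples),
              dimnames = list(NULL, samples$sample_id))
  offs <- c(0L, cumsum(truth$n_pas))
  for (i in seq_len(n)) {
    u <- gene_usage(truth$n_pas[i], config$baseline_distal,
                    truth$true_score[i])
    rows <- (offs[i] + 1L):offs[i + 1L]
    for (j in seq_len(nrow(samples))) {
      usage <- if (samples$condition[j] == "wt") u$wt else u$mut
      m[rows, j] <- sim_gene_counts(usage,
                                    samples$lib[j] * config$reads_per_gene,
                                    config$dispersion)
    }
  }
  sc <- segment_counts(m, factor(samples$condition, levels = c("wt", "mut")),
                       gene_id = rows_gene, segment_index = rows_seg)
  list(truth = truth, counts = sc, samples = samples)
}

#' Expected per-segment, per-sample count means
#'
#' Closed-form negative-binomial means used by the sampler for one gene:
#' `library_multiplier x reads_per_gene x usage`, per segment and sample.
#'
#' @param config A [simulation_config()].
#' @param truth A `truth_table` (from [simulate_truth()]).
#' @param gene_id Gene to evaluate.
#' @param lib Library multipliers per sample (with condition as names or a
#'   `samples` table from [simulate_apa_counts()]).
#' @return Matrix (segments x samples) of means.
#' @export
expected_counts <- function(config, truth, gene_id, lib) {
  if (is.data.frame(lib)) lib <- stats::setNames(lib$lib, lib$condition)
  i <- match(gene_id, truth$gene_id)
  if (is.na(i)) stop("gene not in truth table: ", gene_id)
  u <- gene_usage(truth$n_pas[i], config$baseline_distal, truth$true_score[i])
  out <- vapply(seq_along(lib), function(j) {
    usage <- if (names(lib)[j] == "wt") u$wt else u$mut
    lib[j] * config$reads_per_gene * usage
  }, numeric(truth$n_pas[i]))
  colnames(out) <- names(lib)
  out
}

#' Simulate a complete input bundle on disk
#'
#' Writes everything the pipeline consumes — genome FASTA, gene annotation
#' GFF3, PAS peak BED (wild-type 3'-end read counts), one coverage bedGraph
#' per sample, a segment-count TSV, a sample sheet and the ground-truth
#' table — into one directory. Coverage is written as piecewise-constant
#' depth per segment (`count x read_length / length`), an idealization
#' documented in the methods vignette. A fixed seed makes the bundle
#' byte-for-byte reproducible.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list of file paths plus the truth table.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_apa_counts(config)  # seeds the RNG; RNG state continues below
  truth <- sim$truth
  samples <- sim$samples
  n <- nrow(truth)

  # --- geometry: genes laid head-to-tail on one contig with 300-nt gaps
  utr5_len <- 100L
  glen <- 500L + 120L * truth$n_pas
  gap <- 300L
  gstart <- cumsum(c(gap, glen[-n] + gap))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  contig <- "sim_1"
  contig_len <- gstart[n] + glen[n] + gap

  # transcription-coordinate PAS offsets (0-based offset of cleavage base)
  pas_off <- lapply(seq_len(n), function(i) {
    k <- truth$n_pas[i]
    glen[i] - 40L - 80L * (k - seq_len(k))
  })
  tx2genomic <- function(i, off) {
    if (strand[i] == "+") gstart[i] + off else gstart[i] + glen[i] - 1L - off
  }

  is_nc <- seq_len(n) %in% sample(n, round(config$frac_ncrna * n))
  gene_models <- vector("list", n)
  for (i in seq_len(n)) {
    u3s <- pas_off[[i]][1] - 41L
    tx_iv <- function(a, b) {
      if (strand[i] == "+") c(gstart[i] + a, gstart[i] + b)
      else c(gstart[i] + glen[i] - b, gstart[i] + glen[i] - a)
    }
    gene_models[[i]] <- if (is_nc[i]) {
      gene_model(truth$gene_id[i], contig, strand[i], gstart[i],
                 gstart[i] + glen[i], biotype = "ncRNA")
    } else {
      u5 <- tx_iv(0L, utr5_len); cd <- tx_iv(utr5_len, u3s)
      u3 <- tx_iv(u3s, glen[i])
      gene_model(truth$gene_id[i], contig, strand[i], gstart[i],
                 gstart[i] + glen[i], biotype = "coding",
                 utr5 = u5, cds = cd, utr3 = u3)
    }
  }
  names(gene_models) <- truth$gene_id

  # --- PAS peaks from wild-type usage; decoy peaks exercise merging
  decoy <- seq_len(n) %in% sample(n, round(config$decoy_frac * n))
  peak_rows <- list()
  for (i in seq_len(n)) {
    u <- gene_usage(truth$n_pas[i], config$baseline_distal,
                    truth$true_score[i])
    cnt <- as.integer(stats::rmultinom(1, config$pas3_total, u$wt))
    site <- tx2genomic(i, pas_off[[i]]) + 1L  # 1-based
    df <- data.frame(chrom = contig, strand = strand[i], site = site,
                     count = cnt, gene_id = truth$gene_id[i],
                     stringsAsFactors = FALSE)
    if (decoy[i]) {
      k <- truth$n_pas[i]
      dsite <- tx2genomic(i, pas_off[[i]][k] - 30L) + 1L
      df <- rbind(df, data.frame(chrom = contig, strand = strand[i],
                                 site = dsite,
                                 count = round(0.2 * config$pas3_total),
                                 gene_id = truth$gene_id[i]))
    }
    peak_rows[[i]] <- df
  }
  peaks <- as_pas_peaks(do.call(rbind, peak_rows))

  # --- genome with embedded motif downstream of proximal PAS
  base <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  motif_dna <- chartr("U", "T", toupper(config$motif))
  mlen <- nchar(motif_dna)
  affected <- truth$true_class == "proximal"
  embed <- stats::runif(n) < ifelse(affected, config$motif_rate_affected,
                                    config$motif_rate_control)
  truth$motif_embedded <- embed
  for (i in which(embed)) {
    off0 <- pas_off[[i]][1] + 8L  # inside the 40-nt downstream window
    pos <- vapply(off0 + seq_len(mlen), function(o) tx2genomic(i, o),
                  integer(1)) + 1L
    letters_ <- strsplit(if (strand[i] == "+") motif_dna
                         else revcomp(motif_dna), "")[[1]]
    if (strand[i] == "-") pos <- rev(pos)
    base[pos] <- letters_
  }
  genome <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(genome) <- contig

  # --- segment intervals mirror the pipeline's own windowing
  segs <- segmentation_table(lapply(seq_len(n), function(i) {
    segment_gene(gene_models[[i]],
                 as_pas_peaks(data.frame(chrom = contig, strand = strand[i],
                                         site = tx2genomic(i, pas_off[[i]]) + 1L,
                                         count = 1,
                                         gene_id = truth$gene_id[i])))
  }))

  # --- write everything
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    peaks = file.path(dir, "pas_peaks.bed"),
    samplesheet = file.path(dir, "samples.tsv"),
    counts = file.path(dir, "segment_counts.tsv"),
    truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(genome, paths$genome, width = 80L)
  write_gene_models(gene_models, paths$annotation)
  write_pas_peaks(peaks, paths$peaks)

  counts <- sim$counts$counts
  seg_key <- paste(segs$gene_id, segs$segment_index, sep = ":")
  ord <- match(rownames(counts), seg_key)
  bg_paths <- character(nrow(samples))
  for (j in seq_len(nrow(samples))) {
    dep <- counts[, j] * config$read_length /
      (segs$end[ord] - segs$start[ord])
    keep <- dep > 0
    bg <- data.frame(chrom = segs$chrom[ord][keep],
                     start = segs$start[ord][keep], end = segs$end[ord][keep],
                     depth = sprintf("%.10g", dep[keep]))
    bg <- bg[order(bg$start), ]
    bg_paths[j] <- file.path(dir, paste0(samples$sample_id[j], ".bedGraph"))
    utils::write.table(bg, bg_paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  # paths are written relative to the bundle directory so that the bundle is
  # byte-identical wherever it is generated
  sheet_df <- data.frame(sample_id = samples$sample_id,
                         condition = samples$condition,
                         path = basename(bg_paths))
  utils::write.table(sheet_df, paths$samplesheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc_out <- sim$counts
  sc_out$pas_site <- segs$pas_site[ord]
  write_segment_counts(sc_out, paths$counts)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$coverage <- bg_paths
  invisible(c(paths, list(truth_table = truth, genes = gene_models)))
}
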