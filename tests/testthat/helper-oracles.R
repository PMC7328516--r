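# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive results by a different route than the package.

# peaks fixture: a pas_peaks-shaped data.frame for one gene
peaks_df <- function(sites, counts, strand = "+", gene = "g1",
                     chrom = "chrI") {
  n <- length(sites)
  data.frame(chrom = rep(chrom, n), strand = rep(strand, n),
             site = as.integer(sites), count = as.numeric(counts),
             gene_id = rep(gene, n), stringsAsFactors = FALSE)
}

# brute-force filter: literal application of the two retention rules
oracle_filter <- function(p, min_reads = 6, min_frac = 0.05) {
  total <- sum(p$count)
  p[p$count >= min_reads & p$count / total >= min_frac, , drop = FALSE]
}

# brute-force merge: distance matrix + explicit closest-pair loop
oracle_merge <- function(p, min_dist = 50, strand = "+") {
  sites <- p$site[order(p$site)]
  counts <- p$count[order(p$site)]
  repeat {
    k <- length(sites)
    if (k <= 1) break
    d <- abs(outer(sites, sites, "-"))
    d[upper.tri(d, diag = TRUE)] <- Inf
    if (min(d) >= min_dist) break
    hit <- which(d == min(d), arr.ind = TRUE)
    # lowest-coordinate pair among equally close pairs
    lo <- apply(hit, 1, function(ij) min(sites[ij]))
    ij <- hit[which.min(lo), ]
    i <- min(ij); j <- max(ij)
    if (counts[i] > counts[j]) s <- sites[i]
    else if (counts[j] > counts[i]) s <- sites[j]
    else s <- if (strand == "+") max(sites[c(i, j)]) else min(sites[c(i, j)])
    counts[i] <- counts[i] + counts[j]
    sites[i] <- s
    sites <- sites[-j]; counts <- counts[-j]
    o <- order(sites); sites <- sites[o]; counts <- counts[o]
  }
  data.frame(site = sites, count = counts)
}

oracle_filter_merge <- function(p, min_reads = 6, min_frac = 0.05,
                                min_dist = 50, strand = "+") {
  oracle_merge(oracle_filter(p, min_reads, min_frac), min_dist, strand)
}

random_peaklist <- function(max_peaks = 10, max_count = 500, max_pos = 5000) {
  n <- sample(1:max_peaks, 1)
  peaks_df(sites = sort(sample(max_pos, n)),
           counts = sample(0:max_count, n, replace = TRUE))
}

# step-up FDR oracle: literal textbook loop
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    q[o[i]] <- min(running, 1)
  }
  q
}

# hypergeometric upper-tail oracle via choose() arithmetic
oracle_hyper_tail <- function(overlap, nA, nB, nU) {
  ks <- overlap:min(nA, nB)
  sum(choose(nB, ks) * choose(nU - nB, nA - ks)) / choose(nU, nA)
}

# toy coding gene: + strand [0, 1000) with utr5 [0,100), cds [100,700),
# utr3 [700,1000)
toy_gene <- function(gene_id = "g1", strand = "+", chrom = "chrI") {
  if (strand == "+")
    gene_model(gene_id, chrom, "+", 0, 1000, "coding",
               utr5 = c(0, 100), cds = c(100, 700), utr3 = c(700, 1000))
  else
    gene_model(gene_id, chrom, "-", 0, 1000, "coding",
               utr5 = c(900, 1000), cds = c(300, 900), utr3 = c(0, 300))
}

# segment_counts fixture for a single two-segment gene from four mean depths
two_seg_counts <- function(wt_prox, wt_dist, mut_prox, mut_dist,
                           n_wt = 1, n_mut = 1) {
  m <- cbind(matrix(rep(c(wt_prox, wt_dist), n_wt), nrow = 2),
             matrix(rep(c(mut_prox, mut_dist), n_mut), nrow = 2))
  colnames(m) <- c(paste0("wt", seq_len(n_wt)), paste0("mut", seq_len(n_mut)))
  segment_counts(m, rep(c("wt", "mut"), c(n_wt, n_mut)),
                 gene_id = c("g1", "g1"), segment_index = 1:2)
}

# random 40-nt RNA windows, optionally with a motif embedded downstream
sim_windows <- function(n, embed_rate = 0, motif = "UUGUUG", flank = 40) {
  rand <- function() paste(sample(c("A", "C", "G", "U"), flank,
                                  replace = TRUE), collapse = "")
  up <- replicate(n, rand())
  down <- replicate(n, rand())
  hit <- stats::runif(n) < embed_rate
  for (i in which(hit)) {
    pos <- sample(flank - nchar(motif) + 1, 1)
    substr(down[i], pos, pos + nchar(motif) - 1) <- motif
  }
  structure(data.frame(gene_id = sprintf("w%03d", seq_len(n)),
                       chrom = "c", strand = "+", site = 100L,
                       upstream = up, downstream = down, truncated = FALSE,
                       stringsAsFactors = FALSE),
            class = c("pas_windows", "data.frame"))
}
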