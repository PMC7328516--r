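#' Extract flanking sequence windows around cleavage sites
#'
#' For each PAS, the `flank`-nt sequences immediately upstream and
#' downstream of the cleavage position, read 5'->3' in transcription
#' direction (minus-strand windows are reverse-complemented). The cleavage
#' position itself belongs to neither window — cleavage occurs between
#' nucleotides. Sequences are reported in the RNA alphabet (T as U).
#' Windows truncated by a contig edge are flagged.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param pas A `pas_peaks` data.frame (chrom, strand, site, gene_id).
#' @param flank Window width in nt (default 40).
#' @return Data.frame of class `pas_windows`: gene_id, chrom, strand, site,
#'   upstream, downstream, truncated.
#' @export
extract_windows <- function(genome, pas, flank = 40L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  n <- nrow(pas)
  up <- down <- character(n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    chr <- pas$chrom[i]
    if (!chr %in% names(genome)) stop("contig not in genome: ", chr)
    len <- Biostrings::nchar(genome[[chr]])
    s <- pas$site[i]
    if (s < 1L || s > len) stop("site ", s, " off contig ", chr)
    left <- c(max(1L, s - flank), s - 1L)     # genomic left flank
    right <- c(s + 1L, min(len, s + flank))   # genomic right flank
    getseq <- function(iv) {
      if (iv[2] < iv[1]) return("")
      as.character(Biostrings::subseq(genome[[chr]], iv[1], iv[2]))
    }
    if (pas$strand[i] == "+") {
      u <- getseq(left); d <- getseq(right)
    } else {
      u <- revcomp(getseq(right)); d <- revcomp(getseq(left))
    }
    up[i] <- chartr("Tt", "Uu", u)
    down[i] <- chartr("Tt", "Uu", d)
    trunc[i] <- nchar(u) < flank || nchar(d) < flank
  }
  structure(data.frame(gene_id = pas$gene_id, chrom = pas$chrom,
                       strand = pas$strand, site = pas$site,
                       upstream = up, downstream = down, truncated = trunc,
                       stringsAsFactors = FALSE),
            class = c("pas_windows", "data.frame"))
}

revcomp <- function(s) {
  if (nchar(s) == 0L) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

window_region <- function(windows, region = c("both", "upstream", "downstream")) {
  region <- match.arg(region)
  switch(region,
         upstream = windows$upstream,
         downstream = windows$downstream,
         both = paste0(windows$upstream, windows$downstream))
}

#' Compare base composition between affected and control windows
#'
#' Computes the per-window fraction of one base (default uridine) over the
#' selected region and compares the affected and control groups with a
#' two-sided Wilcoxon rank-sum test. A pooled-count chi-square comparison is
#' available as an alternative.
#'
#' @param affected,control `pas_windows` objects (or data.frames with
#'   upstream/downstream columns).
#' @param base Base to count (default `"U"`; `"T"` is treated as `"U"`).
#' @param region `"both"` (default), `"upstream"` or `"downstream"`.
#' @param method `"ranksum"` (default) or `"chisq"` (pooled counts).
#' @return List with per-group mean fractions, the p-value, the method, and
#'   an `underpowered` flag for very small groups.
#' @export
composition_test <- function(affected, control, base = "U",
                             region = c("both", "upstream", "downstream"),
                             method = c("ranksum", "chisq")) {
  region <- match.arg(region)
  method <- match.arg(method)
  if (nrow(affected) == 0L || nrow(control) == 0L)
    stop("both window groups must be non-empty")
  if (toupper(base) == "T") base <- "U"
  frac <- function(w) {
    s <- toupper(chartr("Tt", "Uu", window_region(w, region)))
    vapply(s, function(x) {
      n <- nchar(x)
      if (n == 0L) return(NA_real_)
      sum(strsplit(x, "")[[1]] == toupper(base)) / n
    }, numeric(1), USE.NAMES = FALSE)
  }
  fa <- frac(affected); fc <- frac(control)
  p <- if (method == "ranksum") {
    suppressWarnings(stats::wilcox.test(fa, fc)$p.value)
  } else {
    hits <- function(w) {
      s <- toupper(chartr("Tt", "Uu", window_region(w, region)))
      c(sum(vapply(strsplit(s, ""), function(ch) sum(ch == toupper(base)),
                   numeric(1))), sum(nchar(s)))
    }
    ha <- hits(affected); hc <- hits(control)
    suppressWarnings(stats::prop.test(c(ha[1], hc[1]),
                                      c(ha[2], hc[2]))$p.value)
  }
  if (!is.finite(p)) p <- 1  # degenerate comparison carries no evidence
  list(mean_affected = mean(fa, na.rm = TRUE),
       mean_control = mean(fc, na.rm = TRUE),
       p_value = p, base = toupper(base), region = region, method = method,
       underpowered = min(nrow(affected), nrow(control)) < 5L)
}

#' Discriminative k-mer enrichment between window groups
#'
#' A simplified discriminative motif analysis: every exact k-mer (no
#' degenerate IUPAC letters) occurring in the selected region of either
#' group is scored by the number of windows containing it in each group,
#' tested one-sidedly for over-representation in the affected group with an
#' exact hypergeometric test, and Benjamini-Hochberg-corrected across all
#' k-mers tested. A degenerate motif would surface here as its constituent
#' exact k-mers.
#'
#' @param affected,control `pas_windows` objects.
#' @param k Integer vector of k-mer sizes (default 4:7).
#' @param region `"downstream"` (default), `"upstream"` or `"both"`.
#' @return Data.frame (kmer in the RNA alphabet, k, count_affected,
#'   count_control, p, q), ranked by p-value.
#' @export
discriminative_kmers <- function(affected, control, k = 4:7,
                                 region = c("downstream", "upstream", "both")) {
  region <- match.arg(region)
  to_dna <- function(w) {
    s <- chartr("Uu", "Tt", window_region(w, region))
    Biostrings::DNAStringSet(s[nchar(s) > 0])
  }
  sa <- to_dna(affected); sc <- to_dna(control)
  n1 <- length(sa); n2 <- length(sc)
  tabs <- lapply(k, function(kk) {
    ca <- colSums(Biostrings::oligonucleotideFrequency(sa, width = kk) > 0)
    cc <- colSums(Biostrings::oligonucleotideFrequency(sc, width = kk) > 0)
    keep <- (ca + cc) > 0
    if (!any(keep)) return(NULL)
    data.frame(kmer = names(ca)[keep], k = kk,
               count_affected = unname(ca[keep]),
               count_control = unname(cc[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(kmer = character(0), k = integer(0),
                      count_affected = integer(0), count_control = integer(0),
                      p = numeric(0), q = numeric(0)))
  m <- out$count_affected + out$count_control
  # one-sided exact test: P(overlap >= observed) given the margins
  out$p <- stats::phyper(out$count_affected - 1, m, n1 + n2 - m, n1,
                         lower.tail = FALSE)
  out$q <- bh_fdr(out$p)
  out$kmer <- chartr("T", "U", out$kmer)
  out <- out[order(out$p, -out$count_affected, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write windows to FASTA
#'
#' Writes the concatenated upstream|downstream sequences (RNA alphabet) with
#' headers `gene_id|site|strand`.
#'
#' @param windows A `pas_windows` data.frame.
#' @param path Output path.
#' @param region Which region to write (default `"both"`).
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path, region = "both") {
  seqs <- window_region(windows, region)
  hdr <- sprintf(">%s|%d|%s", windows$gene_id, windows$site, windows$strand)
  writeLines(as.vector(rbind(hdr, seqs)), path)
  invisible(path)
}
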