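#' Construct a PAS peak
#'
#' One candidate cleavage/polyadenylation site with its 3'-end-sequencing
#' read count. The site is a 1-based single-nucleotide position.
#'
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param site 1-based cleavage position.
#' @param count Non-negative integer read count.
#' @param gene_id Owning gene.
#' @return A one-row data.frame of class `pas_peaks`.
#' @export
pas_peak <- function(chrom, strand, site, count, gene_id) {
  if (count < 0) stop("PAS peak count must be non-negative")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(data.frame(chrom = chrom, strand = strand,
                       site = as.integer(site), count = as.numeric(count),
                       gene_id = gene_id, stringsAsFactors = FALSE),
            class = c("pas_peaks", "data.frame"))
}

as_pas_peaks <- function(df) {
  stopifnot(all(c("chrom", "strand", "site", "count", "gene_id") %in% names(df)))
  structure(as.data.frame(df), class = c("pas_peaks", "data.frame"))
}

#' Read PAS peaks from a BED6 file
#'
#' The BED name column carries the gene id and the score column the 3'-end
#' read count. BED 0-based starts are converted to 1-based sites
#' (`site = start + 1`). Peaks naming a gene absent from `genes` are skipped
#' with a warning; a positional fallback can instead assign such peaks to the
#' nearest same-strand gene ending within `fallback_window` nt upstream of
#' the peak.
#'
#' @param path Path to a BED6 file.
#' @param genes Named list of [gene_model()] objects.
#' @param positional_fallback Assign unnamed/unknown peaks by position
#'   (default `FALSE`).
#' @param fallback_window Downstream window (nt) for the positional fallback.
#' @return A `pas_peaks` data.frame (chrom, strand, site, count, gene_id).
#' @export
read_pas_peaks <- function(path, genes, positional_fallback = FALSE,
                           fallback_window = 200L) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 6L) stop("expected BED6 (6 columns) in ", path)
  score <- suppressWarnings(as.numeric(raw[[5]]))
  if (anyNA(score))
    stop("non-numeric score (read count) at BED line ",
         which(is.na(score))[1], " in ", path)
  df <- data.frame(chrom = raw[[1]],
                   site = as.integer(raw[[2]]) + 1L,
                   gene_id = raw[[4]], count = score, strand = raw[[6]],
                   stringsAsFactors = FALSE)
  if (any(df$count < 0)) stop("negative read count in ", path)

  known <- df$gene_id %in% names(genes)
  if (positional_fallback && any(!known)) {
    for (i in which(!known)) {
      df$gene_id[i] <- nearest_gene_downstream(df$chrom[i], df$strand[i],
                                               df$site[i], genes,
                                               fallback_window)
    }
    known <- !is.na(df$gene_id)
  }
  if (any(!known)) {
    warning(sum(!known), " peak(s) skipped: gene not in annotation")
    df <- df[known, , drop = FALSE]
  }
  gstrand <- vapply(genes[df$gene_id], `[[`, character(1), "strand")
  if (any(df$strand != gstrand)) {
    bad <- df$gene_id[df$strand != gstrand][1]
    stop("strand mismatch between peak and gene ", bad)
  }
  as_pas_peaks(df[, c("chrom", "strand", "site", "count", "gene_id")])
}

# nearest same-strand gene whose 3' end lies within `window` nt upstream of
# the peak (peak may fall slightly downstream of the annotated end)
nearest_gene_downstream <- function(chrom, strand, site, genes, window) {
  pos0 <- site - 1L
  best <- NA_character_; best_d <- Inf
  for (g in genes) {
    if (g$chrom != chrom || g$strand != strand) next
    if (pos0 >= g$start && pos0 < g$end) d <- 0
    else if (strand == "+" && pos0 >= g$end && pos0 < g$end + window)
      d <- pos0 - g$end + 1L
    else if (strand == "-" && pos0 < g$start && pos0 >= g$start - window)
      d <- g$start - pos0
    else next
    if (d < best_d) { best <- g$gene_id; best_d <- d }
  }
  best
}

#' Write PAS peaks to a BED6 file
#'
#' Inverse of [read_pas_peaks()]: 1-based sites become BED 0-based starts.
#'
#' @param peaks A `pas_peaks` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pas_peaks <- function(peaks, path) {
  bed <- data.frame(peaks$chrom, peaks$site - 1L, peaks$site,
                    peaks$gene_id, peaks$count, peaks$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
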