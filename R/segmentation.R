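#' Filter PAS peaks by read support and relative abundance
#'
#' Keeps the peaks of one gene that carry more than `min_reads - 1` reads
#' (strictly more than five at the default) AND account for at least
#' `min_frac` of the gene's total 3'-end read count. The total is computed
#' over all of the gene's peaks before any filtering.
#'
#' @param peaks `pas_peaks` data.frame for a single gene.
#' @param min_reads Minimum retained count (default 6: "more than five").
#' @param min_frac Minimum fraction of the gene total (inclusive, default 0.05).
#' @return The retained rows, order preserved.
#' @export
filter_peaks <- function(peaks, min_reads = 6, min_frac = 0.05) {
  if (nrow(peaks) == 0L) return(peaks)
  if (length(unique(peaks$gene_id)) != 1L)
    stop("filter_peaks() expects the peaks of a single gene")
  total <- sum(peaks$count)
  keep <- peaks$count >= min_reads & peaks$count >= min_frac * total
  peaks[keep, , drop = FALSE]
}

#' Merge closely spaced PAS peaks
#'
#' Peaks closer than `min_dist` nt are merged at the position of the stronger
#' peak, summing their counts. Merging is iterative, always collapsing the
#' current closest pair first (ties broken towards the lower-coordinate
#' pair); when the two members have equal counts the merged peak sits at the
#' more distal (3') position. Iteration continues until no two peaks are
#' closer than `min_dist`.
#'
#' @param peaks `pas_peaks` data.frame for a single gene (any order).
#' @param min_dist Peaks strictly closer than this many nt merge (default 50).
#' @param strand Strand used for the equal-count distal tie-break; taken from
#'   the peaks when missing.
#' @return Merged peaks sorted by genomic coordinate.
#' @export
merge_peaks <- function(peaks, min_dist = 50, strand = NULL) {
  if (nrow(peaks) <= 1L) return(peaks)
  if (is.null(strand)) strand <- peaks$strand[1]
  p <- peaks[order(peaks$site), , drop = FALSE]
  repeat {
    if (nrow(p) <= 1L) break
    gaps <- diff(p$site)
    close <- which(gaps < min_dist)
    if (length(close) == 0L) break
    i <- close[which.min(gaps[close])]  # which.min takes the first = lowest coordinate on ties
    a <- p[i, ]; b <- p[i + 1L, ]
    if (a$count > b$count) site <- a$site
    else if (b$count > a$count) site <- b$site
    else site <- if (strand == "+") b$site else a$site  # equal: more distal 3' position
    p$site[i] <- site
    p$count[i] <- a$count + b$count
    p <- p[-(i + 1L), , drop = FALSE]
    p <- p[order(p$site), , drop = FALSE]
  }
  rownames(p) <- NULL
  p
}

#' Segment a gene at its retained PAS peaks
#'
#' Divides the transcription unit into ordered windows, each ending at (and
#' including) one retained PAS, starting from the annotated TSS. Segment 1 is
#' the most proximal window, the last segment the most distal. The region
#' downstream of the distal PAS is not a segment. Genes with fewer than two
#' retained peaks are flagged ineligible for APA analysis.
#'
#' @param gene A [gene_model()].
#' @param peaks Filtered+merged `pas_peaks` of the gene.
#' @return An object of class `gene_segmentation` with elements `gene_id`,
#'   `chrom`, `strand`, `peaks` (5'->3' in transcription direction),
#'   `segments` (data.frame start/end, 0-based half-open, 5'->3' order),
#'   and `eligible`.
#' @export
segment_gene <- function(gene, peaks) {
  if (nrow(peaks) == 0L) {
    return(structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                          strand = gene$strand, peaks = peaks,
                          segments = data.frame(start = integer(0),
                                                end = integer(0)),
                          eligible = FALSE),
                     class = "gene_segmentation"))
  }
  plus <- gene$strand == "+"
  p <- peaks[order(peaks$site, decreasing = !plus), , drop = FALSE]  # 5'->3'
  sites <- p$site
  n <- length(sites)
  if (plus) {
    # 1-based site s occupies 0-based [s-1, s); segment ends include the site
    starts <- c(gene$start, sites[-n])
    ends <- sites
  } else {
    starts <- sites - 1L
    ends <- c(gene$end, sites[-n] - 1L)
  }
  rownames(p) <- NULL
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, peaks = p,
                 segments = data.frame(start = as.integer(starts),
                                       end = as.integer(ends)),
                 eligible = n >= 2L),
            class = "gene_segmentation")
}

#' @export
print.gene_segmentation <- function(x, ...) {
  cat(sprintf("<gene_segmentation> %s (%s): %d segment(s)%s\n",
              x$gene_id, x$strand, nrow(x$segments),
              if (x$eligible) "" else " [ineligible for APA]"))
  invisible(x)
}

#' Segment many genes
#'
#' Applies [filter_peaks()], [merge_peaks()] and [segment_gene()] per gene.
#' The filter-then-merge order follows the method's definition; the
#' alternative merge-then-filter order is available via `order`.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param peaks `pas_peaks` data.frame over all genes.
#' @param min_reads,min_frac,min_dist See [filter_peaks()] and [merge_peaks()].
#' @param order `"filter_first"` (default) or `"merge_first"`.
#' @return Named list of `gene_segmentation` objects (genes with peaks only).
#' @export
segment_genes <- function(genes, peaks, min_reads = 6, min_frac = 0.05,
                          min_dist = 50,
                          order = c("filter_first", "merge_first")) {
  order <- match.arg(order)
  out <- list()
  for (gid in unique(peaks$gene_id)) {
    g <- genes[[gid]]
    if (is.null(g)) stop("peaks name unknown gene ", gid)
    p <- peaks[peaks$gene_id == gid, , drop = FALSE]
    if (order == "filter_first") {
      p <- merge_peaks(filter_peaks(p, min_reads, min_frac), min_dist,
                       strand = g$strand)
    } else {
      p <- filter_peaks(merge_peaks(p, min_dist, strand = g$strand),
                        min_reads, min_frac)
    }
    out[[gid]] <- segment_gene(g, p)
  }
  out
}

#' Write a segmentation to BED
#'
#' One row per segment; the name column is `gene_id:segment_index`.
#'
#' @param segmentations List of `gene_segmentation` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_bed <- function(segmentations, path) {
  rows <- lapply(segmentations, function(s) {
    if (nrow(s$segments) == 0L) return(NULL)
    data.frame(chrom = s$chrom, start = s$segments$start, end = s$segments$end,
               name = paste(s$gene_id, seq_len(nrow(s$segments)), sep = ":"),
               score = 0L, strand = s$strand, stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Quantify segment coverage from per-sample bedGraph tracks
#'
#' Sums per-base depth (coverage mass) over each segment in each sample and
#' derives the mean depth (mass / length) and an integer pseudo-read count
#' (`round(mass / read_length)`) for count-based testing. Genomic intervals
#' absent from a track have depth zero.
#'
#' @param segmentations List of `gene_segmentation` objects.
#' @param sheet A [sample_sheet()] whose `path` column points to bedGraph
#'   files, or a named list of paths plus `condition`.
#' @param read_length Read length used to convert coverage mass to
#'   pseudo-counts (default 100).
#' @param condition Condition per sample when `sheet` is a plain list of paths.
#' @return A [segment_counts()] object carrying counts, mean depths and the
#'   PAS site delimiting each segment.
#' @export
quantify_segments <- function(segmentations, sheet, read_length = 100,
                              condition = NULL) {
  if (inherits(sheet, "sample_sheet")) {
    if (is.null(sheet$path)) stop("sample sheet lacks a 'path' column")
    paths <- stats::setNames(sheet$path, sheet$sample_id)
    condition <- sheet$condition
  } else {
    paths <- unlist(sheet)
    if (is.null(condition)) stop("supply 'condition' with a plain path list")
  }
  segs <- segmentation_table(segmentations)
  n <- nrow(segs)
  counts <- depth <- matrix(0, n, length(paths),
                            dimnames = list(NULL, names(paths)))
  for (s in names(paths)) {
    gr <- rtracklayer::import(paths[[s]], format = "bedGraph")
    if (any(gr$score < 0)) stop("negative coverage value in ", paths[[s]])
    cov <- GenomicRanges::coverage(gr, weight = gr$score)
    for (chr in unique(segs$chrom)) {
      idx <- which(segs$chrom == chr)
      rle <- if (chr %in% names(cov)) cov[[chr]]
             else S4Vectors::Rle(0, max(segs$end[idx]))
      if (length(rle) < max(segs$end[idx]))
        rle <- c(rle, S4Vectors::Rle(0, max(segs$end[idx]) - length(rle)))
      v <- IRanges::Views(rle, start = segs$start[idx] + 1L, end = segs$end[idx])
      mass <- IRanges::viewSums(v)
      depth[idx, s] <- mass / (segs$end[idx] - segs$start[idx])
      counts[idx, s] <- round(mass / read_length)
    }
  }
  segment_counts(counts, condition, depth = depth, gene_id = segs$gene_id,
                 segment_index = segs$segment_index, pas_site = segs$pas_site)
}

# flatten segmentations into one table, 5'->3' segment order per gene
segmentation_table <- function(segmentations) {
  rows <- lapply(segmentations, function(s) {
    k <- nrow(s$segments)
    if (k == 0L) return(NULL)
    data.frame(gene_id = s$gene_id, segment_index = seq_len(k),
               chrom = s$chrom, strand = s$strand,
               start = s$segments$start, end = s$segments$end,
               pas_site = s$peaks$site, eligible = s$eligible,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
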