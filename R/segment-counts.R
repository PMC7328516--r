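#' Construct a sample sheet
#'
#' Maps sample ids to a two-level condition factor and, optionally, to a
#' per-sample coverage file (bedGraph). The first condition level (or the
#' level named `"wt"` when present) is treated as the reference downstream.
#'
#' @param sample_id Character vector of sample ids.
#' @param condition Condition label per sample (exactly two distinct levels).
#' @param path Optional per-sample file path (coverage tracks).
#' @return A data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, condition, path = NULL) {
  condition <- as.character(condition)
  lev <- unique(condition)
  if (length(lev) != 2L)
    stop("sample sheet must have exactly two condition levels, found ",
         length(lev))
  if (any(table(condition) < 1L)) stop("each condition needs >= 1 sample")
  if (anyDuplicated(sample_id)) stop("duplicated sample ids")
  ref <- if ("wt" %in% lev) "wt" else lev[1]
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = factor(condition, levels = c(ref, setdiff(lev, ref))),
                   stringsAsFactors = FALSE)
  if (!is.null(path)) df$path <- as.character(path)
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Read a sample sheet from TSV
#'
#' Expects columns `sample_id`, `condition` and optionally `path`.
#'
#' @param path TSV path.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition") %in% names(df)))
    stop("sample sheet needs 'sample_id' and 'condition' columns")
  p <- NULL
  if ("path" %in% names(df)) {
    # relative paths resolve against the sheet's own directory
    p <- ifelse(file.exists(df$path), df$path,
                file.path(dirname(path), df$path))
  }
  sample_sheet(df$sample_id, df$condition, path = p)
}

#' Construct a segment count matrix
#'
#' Segments-by-samples table of read counts (and mean per-base depths) with
#' the sample-to-condition mapping. Rows are keyed by gene id and segment
#' index, segment 1 being the most proximal (5'-most in transcription
#' direction) and the last the most distal.
#'
#' @param counts Numeric matrix (segments x samples) of non-negative read
#'   counts; rownames `gene:segment` or supplied via `gene_id`/`segment_index`.
#' @param condition Condition per column (two levels), or a [sample_sheet()].
#' @param depth Optional matrix of mean per-base depths (defaults to
#'   `counts`, appropriate when segment lengths are unknown: lengths cancel
#'   in the distal/proximal ratio-of-ratios).
#' @param gene_id,segment_index Row keys; derived from rownames when absent.
#' @param pas_site Optional 1-based PAS position delimiting each segment.
#' @return An object of class `segment_counts`.
#' @export
segment_counts <- function(counts, condition, depth = NULL,
                           gene_id = NULL, segment_index = NULL,
                           pas_site = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.null(gene_id)) {
    if (is.null(rownames(counts)))
      stop("supply gene_id/segment_index or rownames 'gene:segment'")
    key <- strsplit(rownames(counts), ":", fixed = TRUE)
    gene_id <- vapply(key, `[`, character(1), 1)
    segment_index <- as.integer(vapply(key, `[`, character(1), 2))
  }
  if (inherits(condition, "sample_sheet")) {
    sheet <- condition
    if (is.null(colnames(counts))) colnames(counts) <- sheet$sample_id
    miss <- setdiff(colnames(counts), sheet$sample_id)
    if (length(miss) > 0)
      stop("sample(s) absent from sample sheet: ", paste(miss, collapse = ", "))
    condition <- sheet$condition[match(colnames(counts), sheet$sample_id)]
  } else {
    condition <- as.factor(condition)
    if ("wt" %in% levels(condition))
      condition <- stats::relevel(condition, "wt")
  }
  if (nlevels(condition) != 2L)
    stop("exactly two condition levels are required")
  if (length(condition) != ncol(counts))
    stop("condition length must match the number of samples")
  if (is.null(depth)) depth <- counts
  depth <- as.matrix(depth)
  rn <- paste(gene_id, segment_index, sep = ":")
  rownames(counts) <- rownames(depth) <- rn
  structure(list(counts = counts, depth = depth,
                 gene_id = as.character(gene_id),
                 segment_index = as.integer(segment_index),
                 pas_site = if (is.null(pas_site)) rep(NA_integer_, nrow(counts))
                            else as.integer(pas_site),
                 condition = condition, size_factors = NULL),
            class = "segment_counts")
}

#' @export
print.segment_counts <- function(x, ...) {
  cat(sprintf("<segment_counts> %d segments, %d genes, %d samples (%s)\n",
              nrow(x$counts), length(unique(x$gene_id)), ncol(x$counts),
              paste(sprintf("%s: %d", levels(x$condition),
                            tabulate(x$condition)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.segment_counts <- function(x) dim(x$counts)

#' Read a segment count table from TSV
#'
#' The TSV must have `gene_id` and `segment_index` columns followed by one
#' numeric column per sample; samples are matched to conditions via the
#' sample sheet.
#'
#' @param path TSV path.
#' @param sheet A [sample_sheet()].
#' @return A [segment_counts()] object.
#' @export
read_segment_counts <- function(path, sheet) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "segment_index") %in% names(df)))
    stop("segment count table needs 'gene_id' and 'segment_index' columns")
  has_site <- "pas_site" %in% names(df)
  scols <- setdiff(names(df), c("gene_id", "segment_index", "pas_site"))
  miss <- setdiff(scols, sheet$sample_id)
  if (length(miss) > 0)
    stop("sample(s) in table absent from sample sheet: ",
         paste(miss, collapse = ", "))
  absent <- setdiff(sheet$sample_id, scols)
  if (length(absent) > 0)
    stop("sample column missing from table: ", paste(absent, collapse = ", "))
  m <- as.matrix(df[, sheet$sample_id, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric count in ", path)
  if (any(m < 0)) stop("negative count in ", path)
  segment_counts(m, sheet, gene_id = df$gene_id,
                 segment_index = df$segment_index,
                 pas_site = if (has_site) df$pas_site else NULL)
}

#' Write a segment count table to TSV
#'
#' @param x A [segment_counts()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_counts <- function(x, path) {
  df <- data.frame(gene_id = x$gene_id, segment_index = x$segment_index,
                   stringsAsFactors = FALSE)
  if (!all(is.na(x$pas_site))) df$pas_site <- x$pas_site
  df <- cbind(df, as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
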