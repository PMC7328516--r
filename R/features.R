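#' Locate a PAS within a gene's features
#'
#' Assigns a cleavage site to the gene feature that contains it: `ncRNA` for
#' noncoding genes, otherwise `5UTR`, `CDS` or `3UTR`. A site past the
#' annotated 3'UTR end (up to `fallback_window` nt downstream of the gene in
#' transcription direction) is still called `3UTR`, reflecting cleavage
#' slightly beyond the annotated end.
#'
#' @param gene A [gene_model()].
#' @param site 1-based cleavage position.
#' @param fallback_window Downstream tolerance in nt (default 200).
#' @return One of `"3UTR"`, `"5UTR"`, `"CDS"`, `"ncRNA"`.
#' @export
locate_pas <- function(gene, site, fallback_window = 200L) {
  if (gene$biotype == "ncRNA") return("ncRNA")
  pos <- site - 1L  # 0-based
  contains <- function(iv) !is.null(iv) && pos >= iv[1] && pos < iv[2]
  if (contains(gene$utr5)) return("5UTR")
  if (contains(gene$cds)) return("CDS")
  if (contains(gene$utr3)) return("3UTR")
  downstream3 <- if (gene$strand == "+")
    pos >= gene$utr3[2] && pos < gene$end + fallback_window
  else
    pos < gene$utr3[1] && pos >= gene$start - fallback_window
  if (downstream3) return("3UTR")
  stop("gene ", gene$gene_id, ": site ", site,
       " falls in no annotated feature")
}

#' Annotate APA results with the proximal-PAS feature
#'
#' Fills the `feature` column of an [apa_fit()] result: the feature of the
#' proximal PAS — the site whose usage increases in a proximal shift.
#'
#' @param fit An [apa_fit()] object.
#' @param genes Named list of [gene_model()] objects.
#' @param fallback_window See [locate_pas()].
#' @return The fit with `results$feature` filled.
#' @export
annotate_features <- function(fit, genes, fallback_window = 200L) {
  stopifnot(inherits(fit, "apa_fit"))
  res <- fit$results
  for (i in seq_len(nrow(res))) {
    g <- genes[[res$gene_id[i]]]
    if (is.null(g) || is.na(res$proximal_pas_site[i])) next
    res$feature[i] <- locate_pas(g, res$proximal_pas_site[i], fallback_window)
  }
  fit$results <- res
  fit
}

#' Summarize significant events by feature and direction
#'
#' Contingency counts of events over gene features, split by shift
#' direction, with per-direction fractions.
#'
#' @param fit An [apa_fit()] object (annotated) or a data.frame with
#'   `class` and `feature` columns.
#' @return List with `counts` (feature x direction matrix) and `fractions`
#'   (columns sum to 1 where events exist).
#' @export
summarize_features <- function(fit) {
  res <- if (inherits(fit, "apa_fit")) fit$results else fit
  sig <- res[res$class %in% c("proximal", "distal"), , drop = FALSE]
  feats <- c("3UTR", "5UTR", "CDS", "ncRNA")
  counts <- table(factor(sig$feature, levels = feats),
                  factor(sig$class, levels = c("proximal", "distal")))
  counts <- unclass(counts)
  names(dimnames(counts)) <- c("feature", "direction")
  tot <- colSums(counts)
  fractions <- sweep(counts, 2, ifelse(tot == 0, 1, tot), "/")
  list(counts = counts, fractions = fractions)
}
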