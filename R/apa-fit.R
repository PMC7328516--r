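#' Fit the differential PAS-usage model
#'
#' The central estimator: for every gene with at least two segments it
#' computes the APA score — the log2 ratio of distal/proximal normalized
#' segment depth between the test and reference conditions,
#' `log2[(test/ref)_distal / (test/ref)_proximal]` — and tests the change in
#' distal PAS usage with a binomial generalized linear model on the
#' per-replicate (distal, proximal) read counts. A negative score means the
#' test condition shifts usage towards the proximal PAS. P-values are
#' adjusted with the Benjamini-Hochberg procedure and genes are classified
#' as `proximal` (score < -score_threshold, FDR below threshold), `distal`
#' (score > score_threshold, FDR below threshold) or `unchanged`.
#'
#' Ratios use replicate-averaged, size-factor-normalized mean depths of the
#' most distal and most proximal segments. When any of the four averaged
#' depths is zero, `pseudocount` is added to all four so the score stays
#' finite. The GLM models, per replicate, the distal count as binomial
#' successes out of distal + proximal trials with condition as the only
#' covariate; by default a two-sided Wald test on the condition coefficient
#' is reported. Non-converged or separated fits fall back to a Wald test on
#' the pooled 2x2 condition totals with a 0.5 continuity correction and are
#' flagged.
#'
#' @param object A [segment_counts()] object.
#' @param score_threshold Absolute APA score needed to call an event
#'   (default 1).
#' @param fdr_threshold FDR needed to call an event (default 0.01).
#' @param pseudocount Added to the four averaged depths when one is zero
#'   (default 0.5).
#' @param test `"wald"` (default) or `"lrt"` (likelihood-ratio).
#' @param family `"binomial"` (default) or `"quasibinomial"`.
#' @param size_factors Optional precomputed size factors.
#' @return An object of class `apa_fit`: a list with `results` (one row per
#'   eligible gene: gene_id, ratio_ref, ratio_test, apa_score, p_value, fdr,
#'   class, proximal_pas_site, feature, glm_flag), `size_factors`,
#'   `conditions`, `skipped` (ineligible genes with reasons), `params` and
#'   `call`.
#' @seealso [classify_events()], [select_unaffected_controls()],
#'   [annotate_features()], [summary.apa_fit()]
#' @export
apa_fit <- function(object, score_threshold = 1, fdr_threshold = 0.01,
                    pseudocount = 0.5, test = c("wald", "lrt"),
                    family = c("binomial", "quasibinomial"),
                    size_factors = NULL) {
  stopifnot(inherits(object, "segment_counts"))
  test <- match.arg(test)
  family <- match.arg(family)
  if (is.null(size_factors)) size_factors <- median_ratio_size_factors(object)

  cond <- object$condition
  ref <- cond == levels(cond)[1]
  norm_depth <- sweep(object$depth, 2, size_factors, "/")

  genes <- unique(object$gene_id)
  nseg <- table(object$gene_id)[genes]
  eligible <- genes[nseg >= 2L]
  skipped <- data.frame(gene_id = genes[nseg < 2L],
                        reason = rep("fewer than two segments",
                                     sum(nseg < 2L)),
                        stringsAsFactors = FALSE)

  n <- length(eligible)
  res <- data.frame(gene_id = eligible,
                    ratio_ref = NA_real_, ratio_test = NA_real_,
                    apa_score = NA_real_, p_value = NA_real_,
                    fdr = NA_real_, class = "unchanged",
                    proximal_pas_site = NA_integer_,
                    feature = NA_character_, glm_flag = FALSE,
                    stringsAsFactors = FALSE)

  idx_by_gene <- split(seq_along(object$gene_id), object$gene_id)
  for (i in seq_len(n)) {
    gid <- eligible[i]
    idx <- idx_by_gene[[gid]]
    idx <- idx[order(object$segment_index[idx])]
    prox <- idx[1]; dist <- idx[length(idx)]
    res$proximal_pas_site[i] <- object$pas_site[prox]

    # --- APA score from replicate-averaged normalized mean depths
    v <- c(ref_prox = mean(norm_depth[prox, ref]),
           ref_dist = mean(norm_depth[dist, ref]),
           test_prox = mean(norm_depth[prox, !ref]),
           test_dist = mean(norm_depth[dist, !ref]))
    if (any(v == 0)) v <- v + pseudocount
    res$ratio_ref[i] <- v["ref_dist"] / v["ref_prox"]
    res$ratio_test[i] <- v["test_dist"] / v["test_prox"]
    res$apa_score[i] <- log2(res$ratio_test[i] / res$ratio_ref[i])

    # --- binomial GLM on raw per-replicate (distal, proximal) counts
    glm_res <- binomial_usage_test(object$counts[dist, ],
                                   object$counts[prox, ], cond,
                                   test = test, family = family)
    res$p_value[i] <- glm_res$p
    res$glm_flag[i] <- glm_res$flag
  }
  res$fdr <- bh_fdr(res$p_value)
  res$class <- classify_events(res$apa_score, res$fdr,
                               score_threshold = score_threshold,
                               fdr_threshold = fdr_threshold)

  structure(list(results = res, size_factors = size_factors,
                 conditions = cond, skipped = skipped,
                 params = list(score_threshold = score_threshold,
                               fdr_threshold = fdr_threshold,
                               pseudocount = pseudocount,
                               test = test, family = family),
                 call = match.call()),
            class = "apa_fit")
}

#' Binomial GLM test of differential distal usage for one gene
#'
#' Logit-link binomial regression of per-replicate distal counts (successes
#' out of distal + proximal trials) on condition, fitted by iteratively
#' reweighted least squares (convergence |delta coef| < 1e-8, at most 50
#' iterations). Returns a two-sided Wald p-value on the condition
#' coefficient, or a likelihood-ratio p-value when `test = "lrt"`. Fits that
#' do not converge or are separated fall back to a continuity-corrected
#' (+0.5) Wald test on the pooled condition totals and are flagged. Genes
#' with zero total counts return `NA`.
#'
#' @param distal,proximal Per-sample counts of the distal and proximal
#'   segments.
#' @param condition Two-level factor, reference level first.
#' @param test `"wald"` or `"lrt"`.
#' @param family `"binomial"` or `"quasibinomial"`.
#' @return List with `p` (p-value), `coef` (condition log-odds-ratio) and
#'   `flag` (TRUE when the continuity-corrected fallback was used).
#' @export
binomial_usage_test <- function(distal, proximal, condition,
                                test = c("wald", "lrt"),
                                family = c("binomial", "quasibinomial")) {
  test <- match.arg(test)
  family <- match.arg(family)
  distal <- round(as.numeric(distal)); proximal <- round(as.numeric(proximal))
  tot <- distal + proximal
  if (all(tot == 0)) return(list(p = NA_real_, coef = NA_real_, flag = FALSE))

  fam <- if (family == "binomial") stats::binomial() else stats::quasibinomial()
  use <- tot > 0
  fit <- tryCatch(
    suppressWarnings(stats::glm(cbind(distal, proximal) ~ condition,
                                family = fam, subset = use,
                                control = stats::glm.control(epsilon = 1e-8,
                                                             maxit = 50))),
    error = function(e) NULL)
  degenerate <- is.null(fit) || !fit$converged ||
    length(stats::coef(fit)) < 2L || anyNA(stats::coef(fit))
  if (!degenerate) {
    sm <- summary(fit)$coefficients
    se <- sm[2, 2]
    degenerate <- !is.finite(se) || se > 50  # separation: unbounded estimate
  }
  if (degenerate) {
    # pooled 2x2 condition totals with Haldane-Anscombe correction
    ref <- condition == levels(condition)[1]
    a <- sum(distal[!ref]) + 0.5; b <- sum(proximal[!ref]) + 0.5
    c_ <- sum(distal[ref]) + 0.5; d <- sum(proximal[ref]) + 0.5
    lor <- log(a / b) - log(c_ / d)
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    return(list(p = 2 * stats::pnorm(-abs(lor / se)), coef = lor, flag = TRUE))
  }
  cf <- stats::coef(fit)[2]
  p <- if (test == "lrt") {
    dev <- fit$null.deviance - fit$deviance
    if (family == "quasibinomial") {
      disp <- summary(fit)$dispersion
      stats::pchisq(dev / disp, df = 1, lower.tail = FALSE)
    } else stats::pchisq(dev, df = 1, lower.tail = FALSE)
  } else summary(fit)$coefficients[2, 4]
  list(p = unname(p), coef = unname(cf), flag = FALSE)
}

#' Classify APA events
#'
#' Applies the event thresholds: `proximal` when the score is below
#' `-score_threshold` with FDR below `fdr_threshold`, `distal` when above
#' `score_threshold` with FDR below threshold, otherwise `unchanged`.
#' Missing scores or FDRs are `unchanged`.
#'
#' @param apa_score Numeric scores.
#' @param fdr Adjusted p-values.
#' @param score_threshold,fdr_threshold Event thresholds (defaults 1, 0.01).
#' @return Character vector in `{proximal, distal, unchanged}`.
#' @export
classify_events <- function(apa_score, fdr, score_threshold = 1,
                            fdr_threshold = 0.01) {
  cls <- rep("unchanged", length(apa_score))
  sig <- !is.na(apa_score) & !is.na(fdr) & fdr < fdr_threshold
  cls[sig & apa_score < -score_threshold] <- "proximal"
  cls[sig & apa_score > score_threshold] <- "distal"
  cls
}

#' Select the unaffected control gene set
#'
#' Picks, among eligible genes not called significant, the `n` genes whose
#' APA scores are closest to zero (rank by |score|, ties by gene id) — an
#' equal-size control group for sequence comparisons against affected genes.
#'
#' @param fit An [apa_fit()] object (or its results data.frame).
#' @param n Number of controls; defaults to the number of significant
#'   proximal events.
#' @return Character vector of control gene ids.
#' @export
select_unaffected_controls <- function(fit, n = NULL) {
  res <- if (inherits(fit, "apa_fit")) fit$results else fit
  if (is.null(n)) n <- sum(res$class == "proximal")
  cand <- res[res$class == "unchanged" & !is.na(res$apa_score), , drop = FALSE]
  if (n > nrow(cand))
    stop("requested ", n, " controls but only ", nrow(cand),
         " non-significant genes are available")
  if (n == 0L) return(character(0))
  cand <- cand[order(abs(cand$apa_score), cand$gene_id), , drop = FALSE]
  cand$gene_id[seq_len(n)]
}

#' Exact overlap enrichment between two gene sets
#'
#' Builds the 2x2 membership table of two sets within a universe and returns
#' the sample odds ratio together with a one-sided hypergeometric p-value
#' for over-representation of the overlap.
#'
#' @param setA,setB Character vectors (subsets of `universe`).
#' @param universe Character vector of all genes considered.
#' @return List with `table` (2x2), `odds_ratio` and `p_value`.
#' @export
overlap_enrichment <- function(setA, setB, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(intersect(setA, universe))
  setB <- unique(intersect(setB, universe))
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c_ <- length(setB) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, 2,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  or <- (a * d) / (b * c_)
  p <- stats::phyper(a - 1, length(setB), length(universe) - length(setB),
                     length(setA), lower.tail = FALSE)
  list(table = tab, odds_ratio = or, p_value = p)
}

#' Write an APA results table to TSV
#'
#' @param fit An [apa_fit()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_apa_results <- function(fit, path) {
  utils::write.table(fit$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.apa_fit <- function(x, ...) {
  res <- x$results
  cat(sprintf("Differential PAS usage fit: %d eligible genes (%d skipped)\n",
              nrow(res), nrow(x$skipped)))
  cat(sprintf("  thresholds: |APA score| > %g, FDR < %g (%s %s GLM)\n",
              x$params$score_threshold, x$params$fdr_threshold,
              x$params$family, x$params$test))
  cat(sprintf("  events: %d proximal, %d distal, %d unchanged\n",
              sum(res$class == "proximal"), sum(res$class == "distal"),
              sum(res$class == "unchanged")))
  invisible(x)
}

#' Summarize an APA fit
#'
#' @param object An [apa_fit()] object.
#' @param n Number of top events to display.
#' @param ... Unused.
#' @return `object`'s results, invisibly.
#' @export
summary.apa_fit <- function(object, n = 10, ...) {
  print(object)
  res <- object$results
  sig <- res[res$class != "unchanged", , drop = FALSE]
  if (nrow(sig) > 0) {
    sig <- sig[order(sig$fdr, -abs(sig$apa_score)), , drop = FALSE]
    cat("\nTop events:\n")
    print(utils::head(sig[, c("gene_id", "apa_score", "fdr", "class",
                              "feature")], n), row.names = FALSE)
  }
  cat(sprintf("\nSize factors: %s\n",
              paste(sprintf("%s=%.3f", names(object$size_factors),
                            object$size_factors), collapse = ", ")))
  invisible(res)
}

#' @export
coef.apa_fit <- function(object, ...) {
  stats::setNames(object$results$apa_score, object$results$gene_id)
}

#' Volcano plot of an APA fit
#'
#' APA score against -log10 FDR with the event thresholds drawn as dashed
#' lines; significant proximal and distal events are colored.
#'
#' @param x An [apa_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.apa_fit <- function(x, ...) {
  res <- x$results
  col <- c(proximal = "firebrick", distal = "steelblue",
           unchanged = "grey60")[res$class]
  graphics::plot(res$apa_score, -log10(res$fdr), pch = 16, cex = 0.6,
                 col = col, xlab = "APA score (log2 ratio of ratios)",
                 ylab = expression(-log[10] ~ FDR), ...)
  graphics::abline(v = c(-1, 1) * x$params$score_threshold, lty = 2)
  graphics::abline(h = -log10(x$params$fdr_threshold), lty = 2)
  invisible(x)
}
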