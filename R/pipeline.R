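#' Run configuration
#'
#' Assembles the paths and thresholds driving [apa_run()]. Defaults equal
#' the method's stated parameters: peaks need more than five reads
#' (`min_reads = 6`) and at least 5% of the gene total, peaks closer than
#' 50 nt merge, events need |APA score| > 1 at FDR < 0.01, sequence windows
#' are 40 nt, and coverage is converted to pseudo-counts with a 100-nt read
#' length.
#'
#' @param output_dir Directory for all stage outputs.
#' @param annotation,peaks,genome,samplesheet,counts Input paths (a stage
#'   only needs the inputs it consumes; `counts` defaults to the segment
#'   stage's output).
#' @param min_reads,min_frac,merge_dist,score_threshold,fdr_threshold,flank,read_length
#'   Method parameters (see above).
#' @param test,family Options of the usage GLM (see [apa_fit()]).
#' @param simulate Optional named list of [simulation_config()] overrides
#'   for the `simulate` stage.
#' @param seed Integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(output_dir = ".", annotation = NULL, peaks = NULL,
                       genome = NULL, samplesheet = NULL, counts = NULL,
                       min_reads = 6, min_frac = 0.05, merge_dist = 50,
                       score_threshold = 1.0, fdr_threshold = 0.01,
                       flank = 40L, read_length = 100L,
                       test = "wald", family = "binomial",
                       simulate = list(), seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly.
#'
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("invalid config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run one pipeline stage (or all of them)
#'
#' Orchestrates the analysis as subcommands sharing one configuration:
#' `simulate` writes a synthetic input bundle; `segment` filters, merges and
#' windows PAS peaks and quantifies per-sample coverage; `score` fits the
#' differential-usage model; `annotate` adds gene-feature labels and the
#' feature summary; `motifs` runs the flank-sequence comparisons; `all`
#' chains every stage. Each stage writes its outputs plus a JSON log
#' (parameters, seed, package version, input checksums) under the
#' configured output directory. Missing inputs raise an error of class
#' `apashift_input_error` (the command-line wrapper maps it to exit
#' status 2).
#'
#' @param stage One of `"simulate"`, `"segment"`, `"score"`, `"annotate"`,
#'   `"motifs"`, `"all"`.
#' @param config A [run_config()] (or path to a YAML file).
#' @param seed Optional seed overriding the config's.
#' @return Invisible named list of artifact paths.
#' @export
apa_run <- function(stage = c("simulate", "segment", "score", "annotate",
                              "motifs", "all"),
                    config, seed = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    out <- apa_run("simulate", config)
    cfg <- config
    cfg$annotation <- out$annotation; cfg$peaks <- out$peaks
    cfg$genome <- out$genome; cfg$samplesheet <- out$samplesheet
    for (s in c("segment", "score", "annotate", "motifs"))
      out <- utils::modifyList(out, apa_run(s, cfg))
    return(invisible(out))
  }
  out <- switch(stage,
                simulate = stage_simulate(config),
                segment = stage_segment(config),
                score = stage_score(config),
                annotate = stage_annotate(config),
                motifs = stage_motifs(config))
  write_stage_log(stage, config, out)
  invisible(out)
}

input_error <- function(...) {
  stop(structure(class = c("apashift_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    input_error("missing ", what, " input",
                if (!is.null(path)) paste0(": ", path) else
                  " (not set in config)")
  path
}

write_stage_log <- function(stage, config, out) {
  inputs <- Filter(function(p) is.character(p) && length(p) == 1 &&
                     file.exists(p),
                   config[c("annotation", "peaks", "genome", "samplesheet",
                            "counts")])
  log <- list(stage = stage, seed = config$seed,
              package = as.character(utils::packageVersion("apashift")),
              parameters = config[c("min_reads", "min_frac", "merge_dist",
                                    "score_threshold", "fdr_threshold",
                                    "flank", "read_length", "test",
                                    "family")],
              input_md5 = as.list(vapply(inputs, function(p)
                unname(tools::md5sum(p)), character(1))),
              artifacts = Filter(is.character, out))
  jsonlite::write_json(log, file.path(config$output_dir,
                                      paste0("log_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

stage_simulate <- function(config) {
  sim_cfg <- do.call(simulation_config,
                     utils::modifyList(list(seed = config$seed,
                                            read_length = config$read_length),
                                       config$simulate))
  res <- simulate_bundle(sim_cfg, config$output_dir)
  res[c("genome", "annotation", "peaks", "samplesheet", "counts", "truth")]
}

stage_segment <- function(config) {
  genes <- read_gene_models(require_input(config$annotation, "annotation"))
  peaks <- read_pas_peaks(require_input(config$peaks, "PAS peak"), genes)
  sheet <- read_sample_sheet(require_input(config$samplesheet,
                                           "sample sheet"))
  segm <- segment_genes(genes, peaks, min_reads = config$min_reads,
                        min_frac = config$min_frac,
                        min_dist = config$merge_dist)
  sc <- quantify_segments(segm, sheet, read_length = config$read_length)
  seg_bed <- file.path(config$output_dir, "segments.bed")
  counts_tsv <- file.path(config$output_dir, "segment_counts.quantified.tsv")
  write_segmentation_bed(segm, seg_bed)
  write_segment_counts(sc, counts_tsv)
  list(segments_bed = seg_bed, counts = counts_tsv)
}

stage_score <- function(config) {
  counts_path <- config$counts
  if (is.null(counts_path))
    counts_path <- file.path(config$output_dir,
                             "segment_counts.quantified.tsv")
  counts_path <- require_input(counts_path, "segment count table")
  sheet <- read_sample_sheet(require_input(config$samplesheet,
                                           "sample sheet"))
  sc <- read_segment_counts(counts_path, sheet)
  fit <- apa_fit(sc, score_threshold = config$score_threshold,
                 fdr_threshold = config$fdr_threshold,
                 test = config$test, family = config$family)
  res_tsv <- file.path(config$output_dir, "apa_results.tsv")
  write_apa_results(fit, res_tsv)
  list(results = res_tsv, counts = counts_path)
}

read_results_fit <- function(config) {
  res_tsv <- require_input(file.path(config$output_dir, "apa_results.tsv"),
                           "APA results (run the score stage first)")
  res <- utils::read.delim(res_tsv, stringsAsFactors = FALSE)
  res$feature <- as.character(res$feature)
  structure(list(results = res,
                 params = list(score_threshold = config$score_threshold,
                               fdr_threshold = config$fdr_threshold)),
            class = "apa_fit")
}

stage_annotate <- function(config) {
  genes <- read_gene_models(require_input(config$annotation, "annotation"))
  fit <- annotate_features(read_results_fit(config), genes)
  res_tsv <- file.path(config$output_dir, "apa_results.tsv")
  write_apa_results(fit, res_tsv)
  summ <- summarize_features(fit)
  summ_tsv <- file.path(config$output_dir, "feature_summary.tsv")
  utils::write.table(cbind(feature = rownames(summ$counts),
                           as.data.frame(summ$counts)),
                     summ_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(results = res_tsv, feature_summary = summ_tsv)
}

stage_motifs <- function(config) {
  genome <- require_input(config$genome, "genome FASTA")
  fit <- read_results_fit(config)
  res <- fit$results
  affected <- res[res$class == "proximal", , drop = FALSE]
  if (nrow(affected) == 0L)
    input_error("no significant proximal events; nothing to compare")
  ctrl_ids <- select_unaffected_controls(fit, n = nrow(affected))
  ctrl <- res[res$gene_id %in% ctrl_ids, , drop = FALSE]
  genes <- read_gene_models(require_input(config$annotation, "annotation"))
  mk_pas <- function(df) {
    g <- genes[df$gene_id]
    as_pas_peaks(data.frame(
      chrom = vapply(g, `[[`, character(1), "chrom"),
      strand = vapply(g, `[[`, character(1), "strand"),
      site = df$proximal_pas_site, count = 0, gene_id = df$gene_id,
      stringsAsFactors = FALSE))
  }
  wa <- extract_windows(genome, mk_pas(affected), flank = config$flank)
  wc <- extract_windows(genome, mk_pas(ctrl), flank = config$flank)
  comp <- composition_test(wa, wc, base = "U", region = "both")
  km <- discriminative_kmers(wa, wc, region = "downstream")
  km_tsv <- file.path(config$output_dir, "kmer_enrichment.tsv")
  utils::write.table(km, km_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  comp_tsv <- file.path(config$output_dir, "composition.tsv")
  utils::write.table(data.frame(base = comp$base, region = comp$region,
                                mean_affected = comp$mean_affected,
                                mean_control = comp$mean_control,
                                p_value = comp$p_value),
                     comp_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  wins_fa <- file.path(config$output_dir, "affected_windows.fa")
  write_windows_fasta(wa, wins_fa)
  list(kmers = km_tsv, composition = comp_tsv, windows = wins_fa)
}
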