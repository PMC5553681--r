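## Figures, summaries, and the end-to-end pipeline driver.

#' Principal component views of an expression matrix
#'
#' Centered (not scaled) PCA of arrays over a chosen sequence subset.
#' "Supervised" means restricting the subset to a significant set (e.g. the
#' 12 passage-significant sequences); unsupervised uses all sequences.
#'
#' @param mat log2 ExpressionMatrix (sequences x arrays).
#' @param labels Optional character/factor vector per array (donor, passage
#'   or cohort) carried into the result for plotting.
#' @param subset Optional character vector of sequence ids (>= 2).
#' @return A list of class `pca_views`: `scores` (arrays x first <= 3 PCs),
#'   `sdev`, `var_explained`, `labels`.
#' @export
pca_views <- function(mat, labels = NULL, subset = NULL) {
  if (!is.null(subset)) {
    subset <- intersect(subset, rownames(mat))
    if (length(subset) < 2L)
      stop("pca_views: subset must contain at least 2 sequences", call. = FALSE)
    mat <- mat[subset, , drop = FALSE]
  }
  if (nrow(mat) < 2L)
    stop("pca_views: need at least 2 sequences", call. = FALSE)
  pr <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pr$x))
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 sdev = pr$sdev,
                 var_explained = pr$sdev^2 / sum(pr$sdev^2),
                 labels = labels),
            class = "pca_views")
}

#' Pipeline configuration
#'
#' @param sim_config A [simulation_config()]; used when `probes`/`sheet` are
#'   not supplied.
#' @param probes,sheet Optional pre-loaded ProbeTable and SampleSheet.
#' @param duplicate_pairs Optional duplicate-pair table (defaults to the
#'   simulator's when simulating).
#' @param normalization `"quantile"` (default downstream input) or
#'   `"afe_tgs_p75"`.
#' @param outlier_k Robust multiplier for outlier-array flagging.
#' @param background_mode `"mean_plus_sd"` or `"mean"` background cutoffs.
#' @param alpha_bio Stage-3 biological-variability alpha.
#' @param alpha_de Adjusted-p significance level for passage contrasts.
#' @param adjust_scope BH scope for passage contrasts (see [rm_anova_cs()]).
#' @param seed Integer seed for any randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim_config = simulation_config(),
                            probes = NULL, sheet = NULL,
                            duplicate_pairs = NULL,
                            normalization = c("quantile", "afe_tgs_p75"),
                            outlier_k = 5,
                            background_mode = c("mean_plus_sd", "mean"),
                            alpha_bio = 0.05,
                            alpha_de = 0.05,
                            adjust_scope = c("per_contrast", "pooled"),
                            seed = 1L) {
  for (a in c(alpha_bio, alpha_de))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("invalid configuration: alpha levels must lie in (0, 1)", call. = FALSE)
  structure(list(sim_config = sim_config, probes = probes, sheet = sheet,
                 duplicate_pairs = duplicate_pairs,
                 normalization = match.arg(normalization),
                 outlier_k = outlier_k,
                 background_mode = match.arg(background_mode),
                 alpha_bio = alpha_bio, alpha_de = alpha_de,
                 adjust_scope = match.arg(adjust_scope),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full passage-analysis pipeline
#'
#' Executes normalization -> outlier-array removal -> background cutoffs and
#' detection calls -> duplicate long/short comparison -> four-stage filter
#' cascade -> repeated-measures ANOVA with BH-adjusted passage contrasts,
#' and assembles a machine-readable summary of all stage counts.
#' Deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes the detection table,
#'   filter trace, DE table and `summary.json` there (TSV/JSON).
#' @return A list of class `pipeline_result`: `matrix` (normalized log2,
#'   experimental sequences), `sheet`, `outliers`, `cutoffs`, `detection`,
#'   `duplicate`, `trace`, `de`, `pca` (unsupervised and supervised views),
#'   `summary` (named list of counts), and `truth` when simulated.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config object", call. = FALSE)
  truth <- NULL
  if (is.null(config$probes)) {
    sim <- simulate_experiment(config$sim_config)
    probes <- sim$probes; sheet <- sim$sheet; truth <- sim$truth
    pairs <- config$duplicate_pairs %||% config$sim_config$duplicate_pairs
  } else {
    probes <- validate_probe_table(config$probes)
    sheet <- config$sheet
    pairs <- config$duplicate_pairs
  }

  ## outlier arrays flagged on raw negative-control background, then dropped
  outliers <- flag_outlier_arrays(probes, k = config$outlier_k)
  keep_arrays <- setdiff(unique(probes$array_id), outliers)
  probes <- probes[probes$array_id %in% keep_arrays, , drop = FALSE]
  sheet <- sheet[sheet$array_id %in% keep_arrays, , drop = FALSE]

  ## collapse probe replicates, then normalize the collapsed matrix
  raw <- collapse_probe_replicates(probes)
  ann <- attr(raw, "annotation")
  mat <- switch(config$normalization,
                quantile = quantile_normalize(raw),
                afe_tgs_p75 = afe_tgs_p75(raw))

  negctl_ids <- ann$sequence_id[ann$control_type == "negative"]
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  cutoffs <- background_cutoffs(mat, sheet, negctl_ids,
                                mode = config$background_mode)
  emat <- mat[exp_ids, , drop = FALSE]

  detection <- detection_calls(emat, sheet, cutoffs, ann)
  common_seqs <- detection$sequence$sequence_id[detection$sequence$commonly_expressed]

  duplicate <- NULL
  if (!is.null(pairs) && nrow(pairs) >= 2L)
    duplicate <- tryCatch(
      duplicate_length_comparison(emat, pairs, restrict = common_seqs),
      error = function(e) NULL)

  within <- within_chip_cutoffs(probes)
  between <- between_chip_cutoffs(emat, sheet)
  trace <- apply_cascade(emat, sheet, within, between,
                         magnitude_cutoff = cutoffs$global$cutoff,
                         alpha = config$alpha_bio)
  eligible <- trace$sequence_id[trace$final_eligible]

  de <- NULL
  if (length(eligible))
    de <- rm_anova_cs(emat, sheet, eligible, alpha = config$alpha_de,
                      adjust_scope = config$adjust_scope)

  sig_seqs <- if (!is.null(de)) unique(de$sequence_id[de$significant]) else character(0)
  pca <- list(unsupervised = pca_views(emat, labels = sheet$passage))
  if (length(sig_seqs) >= 2L)
    pca$supervised <- pca_views(emat, labels = sheet$passage, subset = sig_seqs)

  counts <- attr(trace, "counts")
  n_sig_by_contrast <- if (!is.null(de))
    tapply(de$significant, de$contrast, sum) else integer(0)
  summary <- list(
    n_arrays_input = length(keep_arrays) + length(outliers),
    n_outlier_arrays = length(outliers),
    outlier_arrays = as.character(outliers),
    n_arrays_analyzed = length(keep_arrays),
    n_groups = length(detection$groups),
    n_sequences = length(exp_ids),
    n_commonly_expressed_sequences = length(common_seqs),
    n_commonly_expressed_mirnas =
      sum(detection$mirna$commonly_expressed),
    duplicate_fold = if (!is.null(duplicate)) duplicate$fold else NA_real_,
    duplicate_p = if (!is.null(duplicate)) duplicate$p_value else NA_real_,
    cascade = as.list(counts),
    n_eligible = length(eligible),
    n_significant_sequences = length(sig_seqs),
    n_significant_by_contrast = as.list(n_sig_by_contrast)
  )

  result <- structure(list(matrix = emat, sheet = sheet, outliers = outliers,
                           cutoffs = cutoffs, detection = detection,
                           duplicate = duplicate, trace = trace, de = de,
                           pca = pca, summary = summary, truth = truth),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

#' Write the pipeline's report bundle to a directory
#'
#' Emits the detection table (sequence, miRNA, per-group flags), the filter
#' trace, the passage-DE table, and `summary.json`.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  det <- data.frame(sequence_id = result$detection$sequence$sequence_id,
                    commonly_expressed = result$detection$sequence$commonly_expressed,
                    result$detection$expressed, check.names = FALSE)
  write.table(det, file.path(out_dir, "detection_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$detection$mirna, file.path(out_dir, "detection_mirna.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_filter_trace(result$trace, file.path(out_dir, "filter_trace.tsv"))
  if (!is.null(result$de))
    write.table(as.data.frame(result$de), file.path(out_dir, "passage_de.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Volcano plot of a contrast (requires ggplot2)
#'
#' @param de A `passage_de` or `group_de` data.frame.
#' @param contrast Contrast label to plot (ignored for `group_de`).
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, contrast = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_volcano requires ggplot2", call. = FALSE)
  df <- as.data.frame(de)
  if (!is.null(contrast) && "contrast" %in% names(df))
    df <- df[df$contrast == contrast, , drop = FALSE]
  df$neglog10p <- -log10(df$raw_p)
  ggplot2::ggplot(df, ggplot2::aes(x = estimate, y = neglog10p,
                                   color = significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "log2 difference", y = "-log10(p)") +
    ggplot2::theme_minimal()
}

#' Hierarchical-clustering heatmap of selected sequences (requires pheatmap)
#'
#' Uses 1 - Pearson correlation distance with average linkage.
#'
#' @param mat log2 ExpressionMatrix.
#' @param subset Sequence ids to display.
#' @param filename Optional file to write the plot to.
#' @return The pheatmap object, invisibly.
#' @export
plot_heatmap <- function(mat, subset, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_heatmap requires pheatmap", call. = FALSE)
  m <- mat[intersect(subset, rownames(mat)), , drop = FALSE]
  invisible(pheatmap::pheatmap(
    m, clustering_distance_rows = "correlation",
    clustering_distance_cols = "correlation",
    clustering_method = "average", filename = filename, silent = TRUE))
}
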