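## Negative-control-based background cutoffs, outlier-array flagging,
## expressed / commonly-expressed calls and the duplicate long/short
## sequence comparison.

.group_id <- function(sheet) paste(sheet$donor_id, sheet$passage, sep = "/")

#' Background cutoffs from negative-control signals
#'
#' For every donor/passage group the cutoff is the mean plus one standard
#' deviation of the pooled negative-control values of that group's
#' technical-replicate arrays (e.g. 3 x 434 values). A global cutoff is
#' computed the same way from the pooled negative controls of all arrays.
#'
#' @param mat log2 ExpressionMatrix whose rows include the collapsed
#'   negative-control sequences.
#' @param sheet Sample sheet covering the columns of `mat`.
#' @param negctl_ids Row names of `mat` that are negative controls.
#' @param mode `"mean_plus_sd"` (default) or `"mean"`.
#' @return A list with `groups` (data.frame: `group`, `donor_id`, `passage`,
#'   `mean`, `sd`, `cutoff`) and `global` (`mean`, `sd`, `cutoff`).
#' @export
background_cutoffs <- function(mat, sheet, negctl_ids,
                               mode = c("mean_plus_sd", "mean")) {
  mode <- match.arg(mode)
  negctl_ids <- intersect(negctl_ids, rownames(mat))
  if (!length(negctl_ids))
    stop("background_cutoffs: no negative-control rows in matrix", call. = FALSE)
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  neg <- mat[negctl_ids, sheet$array_id, drop = FALSE]
  grp <- .group_id(sheet)
  ug <- unique(grp)
  stats <- t(vapply(ug, function(g) {
    v <- as.vector(neg[, grp == g, drop = FALSE])
    c(mean(v), sd(v))
  }, numeric(2)))
  add_sd <- if (mode == "mean_plus_sd") 1 else 0
  groups <- data.frame(
    group = ug,
    donor_id = sheet$donor_id[match(ug, grp)],
    passage = sheet$passage[match(ug, grp)],
    mean = stats[, 1], sd = stats[, 2],
    cutoff = stats[, 1] + add_sd * stats[, 2],
    stringsAsFactors = FALSE, row.names = NULL)
  v <- as.vector(neg)
  global <- list(mean = mean(v), sd = sd(v),
                 cutoff = mean(v) + add_sd * sd(v))
  list(groups = groups, global = global, mode = mode)
}

#' Flag arrays with extremely elevated negative-control background
#'
#' An array is flagged when its mean log2 negative-control signal exceeds the
#' median plus `k` times the MAD of the per-array negative-control means.
#' Flagged arrays are excluded from all downstream analysis.
#'
#' @param probes A `probe_table` with negative-control rows per array.
#' @param k Robust multiplier (default 5); `Inf` disables flagging.
#' @return Character vector of flagged array ids (possibly empty), with the
#'   per-array negative-control means attached as attribute `"negctl_means"`.
#' @export
flag_outlier_arrays <- function(probes, k = 5) {
  neg <- probes[probes$control_type == "negative", , drop = FALSE]
  if (!nrow(neg))
    stop("flag_outlier_arrays: no negative-control rows", call. = FALSE)
  means <- tapply(log2(neg$raw_signal), neg$array_id, mean)
  if (length(means) < 3L) {
    warning("fewer than 3 arrays: outlier flagging disabled")
    out <- character(0)
    attr(out, "negctl_means") <- means
    return(out)
  }
  if (!is.finite(k)) {
    out <- character(0)
    attr(out, "negctl_means") <- means
    return(out)
  }
  thr <- median(means) + k * mad(means)
  flagged <- names(means)[means > thr]
  if (length(flagged))
    message(sprintf("flagged %d outlier array(s): %s",
                    length(flagged), paste(flagged, collapse = ", ")))
  attr(flagged, "negctl_means") <- means
  flagged
}

#' Expressed and commonly-expressed detection calls
#'
#' A sequence is called expressed in a donor/passage group when its median
#' log2 expression across the group's technical-replicate arrays exceeds the
#' group's background cutoff; it is commonly expressed when this holds in
#' every group. A miRNA is commonly expressed when at least one of its
#' sequences is, after excluding sequences reclassified as tRNA or rRNA;
#' its median expression is the median over all arrays of its
#' commonly-expressed sequences' values.
#'
#' @param mat log2 ExpressionMatrix restricted to experimental sequences.
#' @param sheet Sample sheet for the columns of `mat`.
#' @param cutoffs Output of [background_cutoffs()] on the same arrays.
#' @param annotation Per-sequence annotation ([sequence_annotation()]).
#' @return A list of class `detection_calls`: `expressed` (sequence x group
#'   logical matrix), `sequence` (data.frame with `commonly_expressed` per
#'   sequence), `mirna` (data.frame with `commonly_expressed` and
#'   `median_expression` per miRNA), `group_medians`.
#' @export
detection_calls <- function(mat, sheet, cutoffs, annotation) {
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  grp <- .group_id(sheet)
  ug <- cutoffs$groups$group
  empty <- setdiff(ug, unique(grp))
  if (length(empty)) {
    warning(sprintf("group(s) with zero arrays excluded from detection: %s",
                    paste(empty, collapse = ", ")))
    ug <- setdiff(ug, empty)
  }
  med <- vapply(ug, function(g) {
    cols <- sheet$array_id[grp == g]
    apply(mat[, cols, drop = FALSE], 1L, median)
  }, numeric(nrow(mat)))
  cut <- cutoffs$groups$cutoff[match(ug, cutoffs$groups$group)]
  expressed <- sweep(med, 2L, cut, `>`)
  commonly <- rowSums(expressed) == length(ug)

  seq_df <- data.frame(sequence_id = rownames(mat),
                       commonly_expressed = unname(commonly),
                       stringsAsFactors = FALSE)
  ann <- annotation[match(rownames(mat), annotation$sequence_id), ]
  keep <- !(ann$rna_class %in% c("tRNA", "rRNA")) & !is.na(ann$mirna_name)
  mir_ids <- unique(ann$mirna_name[keep])
  mir_common <- vapply(mir_ids, function(m) {
    any(commonly[keep & ann$mirna_name == m])
  }, logical(1))
  mir_median <- vapply(mir_ids, function(m) {
    rows <- which(keep & ann$mirna_name == m & commonly)
    if (!length(rows)) return(NA_real_)
    median(mat[rows, , drop = FALSE])
  }, numeric(1))
  mirna <- data.frame(mirna_name = mir_ids,
                      commonly_expressed = unname(mir_common),
                      median_expression = unname(mir_median),
                      stringsAsFactors = FALSE)
  structure(list(expressed = expressed, sequence = seq_df, mirna = mirna,
                 group_medians = med, groups = ug),
            class = "detection_calls")
}

#' Long versus short duplicate-sequence expression comparison
#'
#' For duplicate probe sequences differing by one terminal base, compares the
#' mean log2 expression of the longer against the shorter sequence across all
#' arrays with a paired t-test over pairs; the fold change is
#' `2^(mean log2 difference)` under the signed convention of
#' [fold_from_log2diff()].
#'
#' @param mat log2 ExpressionMatrix.
#' @param pairs Data.frame with columns `long_seq`, `short_seq`.
#' @param restrict Optional character vector (e.g. commonly expressed
#'   sequence ids); pairs are kept only when both members are in it.
#' @return A list: `n_pairs`, `mean_log2_diff`, `fold`, `t`, `p_value`, and
#'   the per-pair differences `log2_diffs`.
#' @export
duplicate_length_comparison <- function(mat, pairs, restrict = NULL) {
  if (!is.null(restrict))
    pairs <- pairs[pairs$long_seq %in% restrict & pairs$short_seq %in% restrict, ,
                   drop = FALSE]
  pairs <- pairs[pairs$long_seq %in% rownames(mat) &
                 pairs$short_seq %in% rownames(mat), , drop = FALSE]
  if (nrow(pairs) < 2L)
    stop("duplicate_length_comparison: fewer than 2 usable duplicate pairs",
         call. = FALSE)
  d <- rowMeans(mat[pairs$long_seq, , drop = FALSE]) -
       rowMeans(mat[pairs$short_seq, , drop = FALSE])
  tt <- .paired_t(d)
  list(n_pairs = nrow(pairs), mean_log2_diff = mean(d),
       fold = fold_from_log2diff(mean(d)), t = tt$t, p_value = tt$p,
       log2_diffs = unname(d))
}

## one-sample (paired-difference) t-test; zero-variance degenerate inputs
## return p = 0 (nonzero mean) or p = 1 (all-zero differences) with a note
.paired_t <- function(d) {
  n <- length(d)
  s <- sd(d)
  if (n < 2L || is.na(s)) return(list(t = NA_real_, p = NA_real_, df = n - 1L))
  if (s == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1L))
    message("degenerate paired t-test: zero variance with nonzero mean; p = 0")
    return(list(t = Inf * sign(mean(d)), p = 0, df = n - 1L))
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), n - 1L), df = n - 1L)
}
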