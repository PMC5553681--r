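## The four-stage filter cascade that reduces the full sequence set to the
## ANOVA-eligible set: (1) within-chip technical variability, (2) between-chip
## technical variability, (3) biological variability, (4) magnitude of
## expression.

#' Within-chip technical-variability cutoffs
#'
#' Per sequence and array, the sample standard deviation (n-1) across that
#' array's 4-8 probe replicates is computed on log2 signals; the cutoff is
#' the median of these SDs over arrays. Within-array SDs are invariant to
#' array-level additive offsets on the log2 scale.
#'
#' @param probes A `probe_table`; only experimental rows are used.
#' @param values Optional numeric vector of normalized log2 values aligned
#'   with the rows of `probes`; defaults to `log2(raw_signal)`.
#' @return Named numeric vector: sequence id -> cutoff (log2 units).
#'   Sequences spotted once on every array get cutoff 0 with a warning.
#' @export
within_chip_cutoffs <- function(probes, values = NULL) {
  df <- as.data.frame(probes)
  v <- values %||% log2(df$raw_signal)
  keep <- df$control_type == "experimental"
  dt <- data.table(sequence_id = df$sequence_id[keep],
                   array_id = df$array_id[keep], value = v[keep])
  per_array <- dt[, list(s = sd(value)), by = c("sequence_id", "array_id")]
  cuts <- per_array[, list(cutoff = median(s, na.rm = TRUE)), by = "sequence_id"]
  out <- setNames(cuts$cutoff, cuts$sequence_id)
  if (anyNA(out)) {
    warning(sprintf("%d sequence(s) with a single probe replicate on every array: cutoff set to 0",
                    sum(is.na(out))))
    out[is.na(out)] <- 0
  }
  out[sort(names(out))]
}

#' Between-chip technical-variability cutoffs
#'
#' Per sequence, the SD of the collapsed value across the technical-replicate
#' arrays of each donor/passage group is computed; the cutoff is the median
#' of these SDs over groups with at least two replicate arrays.
#'
#' @param mat Sequence x array matrix (log2 scale).
#' @param sheet Sample sheet covering the columns of `mat`.
#' @return Named numeric vector: sequence id -> cutoff (log2 units).
#' @export
between_chip_cutoffs <- function(mat, sheet) {
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  grp <- .group_id(sheet)
  ok <- names(which(table(grp) >= 2L))
  if (!length(ok))
    stop("between_chip_cutoffs: no donor/passage group with >= 2 replicate arrays",
         call. = FALSE)
  sds <- vapply(ok, function(g) {
    cols <- sheet$array_id[grp == g]
    apply(mat[, cols, drop = FALSE], 1L, sd)
  }, numeric(nrow(mat)))
  out <- apply(sds, 1L, median)
  setNames(out, rownames(mat))
}

#' Apply the four-stage filter cascade
#'
#' Only donors present at both endpoint passages enter the contrast; donor-
#' level values are means over technical replicates. Stages, in order:
#' \enumerate{
#'   \item keep sequences with |mean over donors of (late - early)| strictly
#'     greater than the within-chip cutoff;
#'   \item the same against the between-chip cutoff;
#'   \item keep sequences whose paired t-test (per-donor early vs late) has
#'     p <= `alpha`;
#'   \item keep sequences whose mean expression at every passage exceeds the
#'     global negative-control cutoff.
#' }
#' A sequence failing stage i has stages > i recorded as `NA`
#' (not evaluated). `final_eligible` is true iff all four flags are true.
#'
#' @param mat log2 ExpressionMatrix of experimental sequences.
#' @param sheet Sample sheet for the columns of `mat` (MSC arrays).
#' @param within,between Named cutoff vectors ([within_chip_cutoffs()],
#'   [between_chip_cutoffs()]).
#' @param magnitude_cutoff Global background cutoff (log2), normally
#'   `background_cutoffs(...)$global$cutoff`.
#' @param alpha Stage-3 alpha (p <= alpha keeps; default 0.05).
#' @param endpoints Length-2 character vector of the early and late passage;
#'   defaults to the first and last passage present.
#' @return A `filter_trace` data.frame with one row per sequence: cutoffs,
#'   `contrast_abs_diff`, `bio_p`, per-passage means, the four pass flags and
#'   `final_eligible`; per-stage elimination counts in attribute `"counts"`.
#' @export
apply_cascade <- function(mat, sheet, within, between, magnitude_cutoff,
                          alpha = 0.05, endpoints = NULL) {
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  passages <- unique(sheet$passage)
  if (is.null(endpoints)) endpoints <- c(passages[1], passages[length(passages)])
  early <- endpoints[1]; late <- endpoints[2]

  donors_early <- unique(sheet$donor_id[sheet$passage == early])
  donors_late <- unique(sheet$donor_id[sheet$passage == late])
  complete <- intersect(donors_early, donors_late)
  if (length(complete) < 2L)
    stop("apply_cascade: fewer than 2 donors present at both endpoint passages",
         call. = FALSE)

  donor_mean <- function(d, p) {
    cols <- sheet$array_id[sheet$donor_id == d & sheet$passage == p]
    rowMeans(mat[, cols, drop = FALSE])
  }
  diffs <- vapply(complete, function(d) donor_mean(d, late) - donor_mean(d, early),
                  numeric(nrow(mat)))
  mean_diff <- rowMeans(diffs)
  abs_diff <- abs(mean_diff)

  pass_means <- vapply(passages, function(p) {
    cols <- sheet$array_id[sheet$passage == p]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))

  ids <- rownames(mat)
  w <- within[ids]; b <- between[ids]
  pass_within <- abs_diff > w
  pass_between <- ifelse(pass_within, abs_diff > b, NA)

  bio_p <- rep(NA_real_, length(ids))
  idx <- which(!is.na(pass_between) & pass_between)
  if (length(idx))
    bio_p[idx] <- vapply(idx, function(i) .paired_t(diffs[i, ])$p, numeric(1))
  pass_bio <- ifelse(!is.na(pass_between) & pass_between, bio_p <= alpha, NA)

  mag_ok <- rowSums(pass_means > magnitude_cutoff) == ncol(pass_means)
  pass_mag <- ifelse(!is.na(pass_bio) & pass_bio, mag_ok, NA)

  final <- !is.na(pass_mag) & pass_mag
  trace <- data.frame(
    sequence_id = ids,
    within_cutoff = unname(w), between_cutoff = unname(b),
    contrast_abs_diff = unname(abs_diff), bio_p = bio_p,
    stringsAsFactors = FALSE)
  for (p in passages) trace[[paste0("mean_", p)]] <- unname(pass_means[, p])
  trace$pass_within <- unname(pass_within)
  trace$pass_between <- unname(pass_between)
  trace$pass_bio <- unname(pass_bio)
  trace$pass_magnitude <- unname(pass_mag)
  trace$final_eligible <- unname(final)
  class(trace) <- c("filter_trace", "data.frame")
  attr(trace, "counts") <- c(
    total = length(ids),
    fail_within = sum(!pass_within),
    fail_between = sum(!pass_between, na.rm = TRUE),
    fail_bio = sum(!pass_bio, na.rm = TRUE),
    fail_magnitude = sum(!pass_mag, na.rm = TRUE),
    eligible = sum(final))
  attr(trace, "endpoints") <- endpoints
  attr(trace, "complete_donors") <- complete
  attr(trace, "magnitude_cutoff") <- magnitude_cutoff
  trace
}
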