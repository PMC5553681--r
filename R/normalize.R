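## Probe-replicate collapsing and the two normalization schemes considered
## for the raw signals: cross-array quantile normalization (the default
## downstream input) and AFE-style 75th-percentile scaling.

#' Collapse on-array probe replicates to one value per (sequence, array)
#'
#' Each sequence is spotted 4-8 times per array; the collapsed value is the
#' median of its probe replicates on the raw scale (robust to single spot
#' artifacts). Negative-control and other control probes are collapsed the
#' same way (each negative-control probe is its own sequence, so they pass
#' through unchanged).
#'
#' @param probes A `probe_table` (see [validate_probe_table()]).
#' @return A numeric sequence x array matrix of raw-scale medians, with the
#'   per-sequence annotation attached as attribute `"annotation"`
#'   (see [sequence_annotation()]).
#' @export
collapse_probe_replicates <- function(probes) {
  dt <- as.data.table(as.data.frame(probes))
  coll <- dt[, list(value = median(raw_signal)), by = c("sequence_id", "array_id")]
  wide <- dcast(coll, sequence_id ~ array_id, value.var = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sequence_id
  attr(m, "annotation") <- sequence_annotation(probes)
  m
}

#' Per-sequence annotation extracted from a probe table
#'
#' @param probes A `probe_table`.
#' @return A data.frame with one row per sequence: `sequence_id`,
#'   `mirna_name`, `control_type`, `rna_class`.
#' @export
sequence_annotation <- function(probes) {
  dt <- as.data.table(as.data.frame(probes))
  ann <- unique(dt[, c("sequence_id", "mirna_name", "control_type", "rna_class")])
  as.data.frame(ann[order(ann$sequence_id), ])
}

#' Quantile normalization (no background correction) followed by log2
#'
#' Maps each array's signal distribution to the common reference
#' distribution: the reference quantile at rank r is the mean across arrays
#' of each array's r-th order statistic; tied values within an array receive
#' the mean of their tied ranks' reference values. log2 is applied after the
#' mapping, so the output is an ExpressionMatrix on the log2 scale with every
#' column sharing an identical sorted value multiset.
#'
#' @param raw Positive numeric matrix (rows: sequences, columns: arrays).
#' @return log2-scale matrix with attribute `provenance = "quantile_raw"`.
#' @export
quantile_normalize <- function(raw) {
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("quantile_normalize: all values must be positive and finite", call. = FALSE)
  if (ncol(raw) == 1L) {
    warning("single-array input: returning log2 of the input unchanged")
    out <- log2(raw)
    attr(out, "provenance") <- "quantile_raw"
    return(out)
  }
  ref <- rowMeans(apply(raw, 2L, sort))
  out <- raw
  n <- nrow(raw)
  for (j in seq_len(ncol(raw))) {
    col <- raw[, j]
    assigned <- numeric(n)
    assigned[order(col)] <- ref
    ## ties: mean of the tied ranks' reference values
    if (anyDuplicated(col)) assigned <- ave(assigned, col, FUN = mean)
    out[, j] <- assigned
  }
  out <- log2(out)
  attr(out, "provenance") <- "quantile_raw"
  out
}

#' AFE total-gene-signal 75th-percentile scaling followed by log2
#'
#' Each array is rescaled so its 75th percentile equals the geometric mean of
#' all arrays' 75th percentiles (a fixed target that cancels in downstream
#' differences), then log2-transformed.
#'
#' @param raw Positive numeric matrix (rows: sequences, columns: arrays).
#' @return log2-scale matrix with attribute `provenance = "afe_tgs_p75"`.
#' @export
afe_tgs_p75 <- function(raw) {
  if (any(!is.finite(raw)) || any(raw <= 0))
    stop("afe_tgs_p75: all values must be positive and finite", call. = FALSE)
  p75 <- apply(raw, 2L, quantile, probs = 0.75, names = FALSE)
  if (ncol(raw) == 1L)
    warning("single-array input: scaling to its own 75th percentile")
  target <- exp(mean(log(p75)))
  out <- log2(sweep(raw, 2L, target / p75, `*`))
  attr(out, "provenance") <- "afe_tgs_p75"
  out
}
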