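## Tabular IO: probe tables (internal long / AFE-like / GEO series-matrix),
## sample sheets, qPCR plates, expression matrices and filter traces.

.PROBE_COLS <- c("array_id", "probe_id", "sequence_id", "mirna_name",
                 "control_type", "rna_class", "raw_signal")
.CONTROL_TYPES <- c("experimental", "negative", "other_control")

## AFE-like dialect: minimal column map for Agilent Feature Extraction-style
## per-array files (ControlType: 0 experimental, -1 negative, else control)
.AFE_MAP <- c(probe_id = "ProbeName", mirna_name = "SystematicName",
              sequence_id = "Sequence", control_type = "ControlType",
              raw_signal = "gTotalProbeSignal")

#' Validate a probe table
#'
#' Checks column presence, positive signals, per-array negative controls and
#' (array, probe) uniqueness. Unknown control-type codes are mapped to
#' `other_control` with a warning.
#'
#' @param probes A data.frame of probe-level rows.
#' @param require_negctl Require at least one negative-control row per array
#'   (disabled for processed series-matrix tables, which carry no control
#'   probes).
#' @return The validated `probe_table`.
#' @export
validate_probe_table <- function(probes, require_negctl = TRUE) {
  miss <- setdiff(.PROBE_COLS, names(probes))
  if (length(miss))
    stop(sprintf("probe table format error: missing column '%s'", miss[1]),
         call. = FALSE)
  bad <- which(!is.finite(probes$raw_signal) | probes$raw_signal <= 0)
  if (length(bad))
    stop(sprintf("probe table validation error: non-positive raw_signal at row %d",
                 bad[1]), call. = FALSE)
  unknown <- !(probes$control_type %in% .CONTROL_TYPES)
  if (any(unknown)) {
    warning(sprintf("%d rows with unknown control_type mapped to 'other_control'",
                    sum(unknown)))
    probes$control_type[unknown] <- "other_control"
  }
  if (anyDuplicated(probes[, c("array_id", "probe_id")]))
    stop("probe table validation error: duplicated (array_id, probe_id)",
         call. = FALSE)
  neg_by_array <- tapply(probes$control_type == "negative", probes$array_id, any)
  if (require_negctl && !all(neg_by_array))
    stop(sprintf("probe table validation error: array '%s' has no negative-control rows",
                 names(neg_by_array)[!neg_by_array][1]), call. = FALSE)
  class(probes) <- c("probe_table", "data.frame")
  probes
}

#' Read a probe-level table
#'
#' @param path Path to a tab-separated file.
#' @param dialect `"internal_long"` (this package's writer format, all
#'   columns present), `"afe_like"` (a minimal Agilent Feature
#'   Extraction-style per-array file; supply `array_id`), or
#'   `"geo_series_matrix"` (a `!`-prefixed-preamble, `ID_REF`-keyed processed
#'   matrix, returned as one experimental pseudo-probe per sequence/array).
#' @param array_id Array identifier for single-array `afe_like` files.
#' @param dialect_map Named character vector overriding the AFE-like column
#'   map (names are internal columns, values are file columns).
#' @return A validated `probe_table` data.frame.
#' @export
read_probe_table <- function(path, dialect = c("internal_long", "afe_like",
                                               "geo_series_matrix"),
                             array_id = NULL, dialect_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (dialect == "internal_long") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    return(validate_probe_table(df))
  }
  if (dialect == "afe_like") {
    map <- .AFE_MAP
    if (!is.null(dialect_map)) map[names(dialect_map)] <- dialect_map
    raw <- read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(unname(map), names(raw))
    if (length(miss))
      stop(sprintf("probe table format error: missing column '%s'", miss[1]),
           call. = FALSE)
    ct <- raw[[map[["control_type"]]]]
    df <- data.frame(
      array_id = array_id %||% sub("\\.[^.]*$", "", basename(path)),
      probe_id = raw[[map[["probe_id"]]]],
      sequence_id = raw[[map[["sequence_id"]]]],
      mirna_name = raw[[map[["mirna_name"]]]],
      control_type = ifelse(ct == 0, "experimental",
                            ifelse(ct == -1, "negative", "other_control")),
      rna_class = if ("rna_class" %in% names(raw)) raw$rna_class else "unknown",
      raw_signal = raw[[map[["raw_signal"]]]],
      stringsAsFactors = FALSE)
    return(validate_probe_table(df))
  }
  ## geo_series_matrix: processed sequence x sample table
  m <- read_series_matrix(path)
  long <- data.frame(
    array_id = rep(colnames(m), each = nrow(m)),
    probe_id = rep(rownames(m), ncol(m)),
    sequence_id = rep(rownames(m), ncol(m)),
    mirna_name = NA_character_,
    control_type = ifelse(rep(grepl("^NC", rownames(m)), ncol(m)),
                          "negative", "experimental"),
    rna_class = "unknown",
    raw_signal = as.vector(m),
    stringsAsFactors = FALSE)
  validate_probe_table(long, require_negctl = any(grepl("^NC", rownames(m))))
}

#' Write a probe table as internal-long TSV
#' @param probes A `probe_table`.
#' @param path Output path.
#' @export
write_probe_table <- function(probes, path) {
  probes <- validate_probe_table(as.data.frame(probes))
  write.table(probes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix-style expression table
#'
#' Tolerates the `!`-prefixed metadata preamble and expects a tab-separated
#' table whose first column is `ID_REF` and whose remaining columns are
#' samples.
#'
#' @param path Path to the file.
#' @return A numeric matrix (rows: `ID_REF`, columns: samples).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^!", lines) & nzchar(lines)
  con <- textConnection(lines[keep])
  on.exit(close(con))
  df <- read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "ID_REF")
    stop("probe table format error: missing column 'ID_REF'", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$ID_REF
  storage.mode(m) <- "double"
  m
}

#' Read/write a sample sheet (array to donor/passage/replicate map)
#' @param path CSV path.
#' @param probes Optional `probe_table`; if given, array ids are checked to
#'   match exactly.
#' @return A data.frame with `array_id`, `donor_id`, `passage`, `tech_rep`,
#'   `cohort`.
#' @export
read_sample_sheet <- function(path, probes = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("array_id", "donor_id", "passage", "tech_rep", "cohort"),
                  names(df))
  if (length(miss))
    stop(sprintf("sample sheet format error: missing column '%s'", miss[1]),
         call. = FALSE)
  if (anyDuplicated(df[, c("donor_id", "passage", "tech_rep")]))
    stop("sample sheet validation error: duplicated (donor_id, passage, tech_rep)",
         call. = FALSE)
  if (!is.null(probes) && !setequal(df$array_id, unique(probes$array_id)))
    stop("sample sheet validation error: array ids do not match probe table",
         call. = FALSE)
  df
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RT-qPCR plate CSV
#'
#' Undetected wells may be encoded as empty fields, `NA` or `Undetermined`;
#' they are represented as `NA` Cq (never numeric 0). Validates that every
#' sample carries all reference targets and that Cq values lie in (0, 45].
#'
#' @param path CSV path with columns `sample_id`, `cohort`, `passage`,
#'   `target_id`, `is_reference`, `control_role`, `well_rep`, `cq`.
#' @return A `qpcr_plate` data.frame.
#' @export
read_qpcr_plate <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("NA", "", "Undetermined"))
  validate_qpcr_plate(df)
}

#' @rdname read_qpcr_plate
#' @param plate A qPCR plate data.frame.
#' @export
validate_qpcr_plate <- function(plate) {
  miss <- setdiff(c("sample_id", "cohort", "passage", "target_id",
                    "is_reference", "control_role", "well_rep", "cq"),
                  names(plate))
  if (length(miss))
    stop(sprintf("qPCR plate format error: missing column '%s'", miss[1]),
         call. = FALSE)
  plate$is_reference <- as.logical(plate$is_reference)
  bad <- which(!is.na(plate$cq) & (plate$cq <= 0 | plate$cq > 45))
  if (length(bad))
    stop(sprintf("qPCR plate validation error: cq out of (0, 45] at row %d",
                 bad[1]), call. = FALSE)
  refs <- unique(plate$target_id[plate$is_reference])
  for (s in unique(plate$sample_id)) {
    have <- unique(plate$target_id[plate$sample_id == s])
    missing_ref <- setdiff(refs, have)
    if (length(missing_ref))
      stop(sprintf("qPCR plate validation error: sample '%s' missing reference target '%s'",
                   s, missing_ref[1]), call. = FALSE)
  }
  class(plate) <- c("qpcr_plate", "data.frame")
  plate
}

#' @rdname read_qpcr_plate
#' @export
write_qpcr_plate <- function(plate, path) {
  out <- as.data.frame(plate)
  out$cq <- ifelse(is.na(out$cq), "Undetermined", format(out$cq, digits = 15))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a filter-cascade trace as TSV
#'
#' One row per sequence; columns record each stage's cutoff, statistic and
#' pass flag plus the final eligibility flag (see [apply_cascade()]).
#'
#' @param trace A `filter_trace` data.frame.
#' @param path TSV path.
#' @export
write_filter_trace <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_filter_trace
#' @export
read_filter_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("filter_trace", "data.frame")
  df
}

#' Write / read an expression matrix as TSV (sequences x arrays)
#'
#' The written format is readable by [read_series_matrix()] (first column
#' `ID_REF`).
#'
#' @param mat Numeric matrix with sequence rownames and array colnames.
#' @param path TSV path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(ID_REF = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  read_series_matrix(path)
}
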