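## RT-qPCR confirmation arm: geometric-mean reference normalization,
## detection calls, passage fold changes and cross-set / cross-cohort tests.

#' Reference-normalize an RT-qPCR plate
#'
#' Per (sample, target) the median Cq across well replicates is taken; a
#' target is detected when at least half of its wells amplified and the
#' median Cq is below `detection_cq`. The per-sample reference value is the
#' arithmetic mean of the 5 reference targets' median Cq (the geometric mean
#' of their `2^-Cq` abundances equals the arithmetic mean on the Cq scale),
#' and normalized expression is `delta_cq = reference - target` (log2
#' abundance units, increasing with expression). Samples with an undetected
#' reference are excluded with a warning. PPC/miRTC control rows are checked
#' (warning outside `ppc_band`) but never used in normalization.
#'
#' @param plate A `qpcr_plate` ([read_qpcr_plate()] / [simulate_qpcr()]).
#' @param detection_cq Detection threshold on the median Cq (default 35).
#' @param ppc_band Acceptable Cq band for PPC positive controls.
#' @return A `qpcr_result` data.frame, one row per (sample, non-control
#'   target): `sample_id`, `cohort`, `passage`, `target_id`, `median_cq`,
#'   `detected`, `reference_cq`, `delta_cq`; excluded samples in attribute
#'   `"excluded_samples"`.
#' @export
normalize_qpcr <- function(plate, detection_cq = 35, ppc_band = c(15, 25)) {
  plate <- validate_qpcr_plate(as.data.frame(plate))
  dt <- as.data.table(plate)
  med <- dt[, list(
    median_cq = {
      ok <- !is.na(cq)
      if (sum(ok) * 2L < .N) NA_real_ else median(cq[ok])
    },
    cohort = cohort[1], passage = passage[1],
    is_reference = is_reference[1], control_role = control_role[1]
  ), by = c("sample_id", "target_id")]
  med[, "detected" := !is.na(med$median_cq) & med$median_cq < detection_cq]

  ppc <- med[med$control_role == "PPC" & !is.na(med$median_cq), ]
  if (nrow(ppc) && any(ppc$median_cq < ppc_band[1] | ppc$median_cq > ppc_band[2]))
    warning("PPC positive-control Cq outside the expected band for some samples")

  refs <- med[med$is_reference == TRUE, ]
  ref_ok <- tapply(refs$detected, refs$sample_id, all)
  excluded <- names(ref_ok)[!ref_ok]
  if (length(excluded))
    warning(sprintf("sample(s) with undetected reference excluded: %s",
                    paste(excluded, collapse = ", ")))
  ref_mean <- tapply(refs$median_cq, refs$sample_id, mean)

  out <- med[med$is_reference == FALSE & med$control_role == "none" &
             !(med$sample_id %in% excluded), ]
  out <- as.data.frame(out)
  out$reference_cq <- as.numeric(ref_mean[out$sample_id])
  out$delta_cq <- out$reference_cq - out$median_cq
  out <- out[, c("sample_id", "cohort", "passage", "target_id",
                 "median_cq", "detected", "reference_cq", "delta_cq")]
  out <- out[order(out$sample_id, out$target_id), ]
  rownames(out) <- NULL
  class(out) <- c("qpcr_result", "data.frame")
  attr(out, "excluded_samples") <- excluded
  out
}

## per-line passage difference (late - early) of delta_cq within one cohort;
## returns a named vector over lines, NA where either passage is undetected
.line_diffs <- function(res, cohort, target) {
  r <- res[res$cohort == cohort & res$target_id == target, , drop = FALSE]
  if (!nrow(r)) return(numeric(0))
  pass <- unique(res$passage[res$cohort == cohort])
  early <- pass[1]; late <- pass[length(pass)]
  line <- sub("_[^_]*$", "", r$sample_id)
  ul <- unique(line)
  e <- r[match(paste(ul, early), paste(line, r$passage)), ]
  l <- r[match(paste(ul, late), paste(line, r$passage)), ]
  ok <- !is.na(e$detected) & !is.na(l$detected) & e$detected & l$detected
  d <- ifelse(ok, l$delta_cq - e$delta_cq, NA_real_)
  setNames(d, ul)
}

#' Passage fold changes and statistical tests per target
#'
#' For each target and MSC set, the per-line change in normalized expression
#' between the late and early passage (ddCq in log2 units) is tested with a
#' paired t-test across matched lines (or a one-group-per-passage two-sample
#' t-test when `paired = FALSE`); the fold change is `2^(mean ddCq)` under
#' the signed convention of [fold_from_log2diff()]. Targets undetected in a
#' line at either passage are excluded line-wise; targets with fewer than 3
#' usable lines in a set are reported as `NA`. Additionally reports, per
#' target, whether the early-to-late change differs between the two MSC sets
#' (two-sample t on the per-line differences), and whether early-passage MSC
#' expression differs from each non-MSC cohort.
#'
#' @param result A `qpcr_result` from [normalize_qpcr()].
#' @param set_cohorts Character vector of the MSC set cohort labels.
#' @param nonmsc_cohorts Cohorts compared against early-passage MSCs.
#' @param paired Use paired tests across matched lines (default).
#' @return A list of class `qpcr_tests`: `per_set` (target x set folds and
#'   p-values), `cross_set` (per target, p for set1-vs-set2 difference in
#'   passage change), `vs_nonmsc` (per target and cohort, p and log2
#'   difference of early-passage expression).
#' @export
passage_fold_tests <- function(result,
                               set_cohorts = c("MSC_set1", "MSC_set2"),
                               nonmsc_cohorts = c("mesoderm", "cancer"),
                               paired = TRUE) {
  res <- as.data.frame(result)
  targets <- sort(unique(res$target_id))
  set_cohorts <- intersect(set_cohorts, unique(res$cohort))

  per_set <- do.call(rbind, lapply(set_cohorts, function(co) {
    rows <- lapply(targets, function(tg) {
      d <- .line_diffs(res, co, tg)
      d <- d[!is.na(d)]
      if (length(d) < 3L)
        return(data.frame(cohort = co, target_id = tg, n_lines = length(d),
                          fold = NA_real_, p = NA_real_,
                          stringsAsFactors = FALSE))
      if (paired) {
        tt <- .paired_t(d)
        data.frame(cohort = co, target_id = tg, n_lines = length(d),
                   fold = fold_from_log2diff(mean(d)), p = tt$p,
                   stringsAsFactors = FALSE)
      } else {
        r <- res[res$cohort == co & res$target_id == tg & res$detected, ]
        pass <- unique(res$passage[res$cohort == co])
        a <- r$delta_cq[r$passage == pass[1]]
        b <- r$delta_cq[r$passage == pass[length(pass)]]
        tt <- .pooled_t(matrix(a, 1), matrix(b, 1))
        data.frame(cohort = co, target_id = tg, n_lines = length(d),
                   fold = fold_from_log2diff(mean(b) - mean(a)), p = tt$p,
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  }))

  cross_set <- NULL
  if (length(set_cohorts) == 2L) {
    cross_set <- do.call(rbind, lapply(targets, function(tg) {
      d1 <- .line_diffs(res, set_cohorts[1], tg)
      d2 <- .line_diffs(res, set_cohorts[2], tg)
      d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
      if (length(d1) < 2L || length(d2) < 2L)
        return(data.frame(target_id = tg, diff_of_diffs = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      tt <- .pooled_t(matrix(d1, 1), matrix(d2, 1))
      data.frame(target_id = tg, diff_of_diffs = mean(d2) - mean(d1),
                 p = unname(tt$p), stringsAsFactors = FALSE)
    }))
  }

  early_msc <- res[res$cohort %in% set_cohorts, , drop = FALSE]
  early_of <- function(co) {
    pass <- unique(res$passage[res$cohort == co])
    res[res$cohort == co & res$passage == pass[1], , drop = FALSE]
  }
  msc_early <- do.call(rbind, lapply(set_cohorts, early_of))
  vs_nonmsc <- NULL
  nonmsc_cohorts <- intersect(nonmsc_cohorts, unique(res$cohort))
  if (length(nonmsc_cohorts) && nrow(msc_early)) {
    vs_nonmsc <- do.call(rbind, lapply(nonmsc_cohorts, function(co) {
      other <- res[res$cohort == co, , drop = FALSE]
      rows <- lapply(targets, function(tg) {
        a <- msc_early$delta_cq[msc_early$target_id == tg & msc_early$detected]
        b <- other$delta_cq[other$target_id == tg & other$detected]
        if (length(a) < 2L || length(b) < 2L)
          return(data.frame(cohort = co, target_id = tg,
                            log2_diff = NA_real_, p = NA_real_,
                            stringsAsFactors = FALSE))
        tt <- .pooled_t(matrix(a, 1), matrix(b, 1))
        data.frame(cohort = co, target_id = tg,
                   log2_diff = mean(b) - mean(a), p = unname(tt$p),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }
  structure(list(per_set = per_set, cross_set = cross_set,
                 vs_nonmsc = vs_nonmsc),
            class = "qpcr_tests")
}
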