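## Repeated-measures ANOVA across passages with compound-symmetry
## correlation, BH-adjusted pairwise passage contrasts and fold changes, and
## the pooled-variance group contrast (MSC vs cancer).

#' Signed fold change from a log2 difference
#'
#' Positive differences give `2^d`; negative differences give `-2^(-d)`, so
#' a fold of +1.45 means 1.45-fold up at the later (or second) level and
#' -1.45 means 1.45-fold down. `d = 0` gives 1.
#'
#' @param d Numeric vector of log2 differences.
#' @return Signed fold changes.
#' @export
fold_from_log2diff <- function(d) {
  ifelse(d >= 0, 2^d, -2^(-d))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH false-discovery-rate adjustment (monotone step-up, capped at
#' 1), delegated to [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1)))
    stop("benjamini_hochberg: p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}

## donor x passage mean table for one set of arrays; technical replicates are
## averaged to donor/passage units before any modeling
.donor_passage_means <- function(mat, sheet) {
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  combos <- unique(sheet[, c("donor_id", "passage")])
  vals <- vapply(seq_len(nrow(combos)), function(i) {
    cols <- sheet$array_id[sheet$donor_id == combos$donor_id[i] &
                           sheet$passage == combos$passage[i]]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  if (!is.matrix(vals))
    vals <- matrix(vals, nrow = nrow(mat), dimnames = list(rownames(mat), NULL))
  list(values = vals, combos = combos)
}

## closed-form paired contrasts, the documented fallback when the GLS fit
## fails (e.g. zero residual variance in degenerate fixtures)
.paired_contrast_fallback <- function(y, donor, passage, contrasts) {
  key <- paste(donor, passage)
  ud <- unique(donor)
  out <- lapply(contrasts, function(ct) {
    d <- y[match(paste(ud, ct[2]), key)] - y[match(paste(ud, ct[1]), key)]
    tt <- .paired_t(d)
    list(estimate = mean(d), p = tt$p)
  })
  list(contrasts = out, overall_p = NA_real_, method = "paired_fallback")
}

## fit value ~ passage with compound-symmetry within-donor correlation for
## one sequence; contrasts tested with containment df (n_donors-1)(n_pass-1)
.fit_cs_one <- function(y, donor, passage, levels_, contrasts) {
  df <- data.frame(y = y, donor = factor(donor),
                   passage = factor(passage, levels = levels_))
  n_d <- nlevels(df$donor); n_p <- nlevels(df$passage)
  den_df <- (n_d - 1L) * (n_p - 1L)
  fit <- tryCatch(
    nlme::gls(y ~ passage, data = df,
              correlation = nlme::corCompSymm(form = ~ 1 | donor),
              method = "REML",
              control = nlme::glsControl(maxIter = 200, msMaxIter = 200,
                                         tolerance = 1e-8, msTol = 1e-9)),
    error = function(e) NULL)
  if (is.null(fit))
    return(.paired_contrast_fallback(y, donor, passage, contrasts))
  beta <- coef(fit); V <- vcov(fit)
  res <- lapply(contrasts, function(ct) {
    L <- setNames(numeric(length(beta)), names(beta))
    for (lev in ct[2]) if (lev != levels_[1]) L[paste0("passage", lev)] <- 1
    for (lev in ct[1]) if (lev != levels_[1]) L[paste0("passage", lev)] <- -1
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tstat <- est / se
    list(estimate = est, p = 2 * pt(-abs(tstat), den_df))
  })
  ## overall Wald F on the passage coefficients
  pk <- grep("^passage", names(beta))
  Fp <- NA_real_
  if (length(pk)) {
    Fstat <- drop(t(beta[pk]) %*% solve(V[pk, pk, drop = FALSE]) %*% beta[pk]) /
      length(pk)
    Fp <- pf(Fstat, length(pk), den_df, lower.tail = FALSE)
  }
  list(contrasts = res, overall_p = Fp, method = "gls_cs")
}

#' Repeated-measures ANOVA with compound-symmetry correlation
#'
#' For each eligible sequence, fits log2 expression against passage with a
#' compound-symmetry correlation structure within donors (equal correlation
#' between any two passages of a donor; fitted by REML via [nlme::gls()],
#' which also admits the negative within-donor correlations a random-
#' intercept parameterization forbids). Technical replicates are averaged to
#' donor/passage means first, and only donors observed at every passage are
#' used. All pairwise passage contrasts are tested with containment degrees
#' of freedom `(n_donors - 1)(n_passages - 1)`, so the balanced two-passage
#' special case reproduces the paired t-test exactly. Benjamini-Hochberg
#' adjustment is applied per contrast family across sequences (or pooled
#' across all contrasts with `adjust_scope = "pooled"`).
#'
#' @param mat log2 ExpressionMatrix.
#' @param sheet Sample sheet for the columns of `mat`.
#' @param eligible Character vector of sequence ids to model.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param adjust_scope `"per_contrast"` (default) or `"pooled"`.
#' @return A `passage_de` data.frame, one row per sequence x contrast:
#'   `sequence_id`, `contrast` (e.g. `"P7/P3"`), `estimate` (log2), `raw_p`,
#'   `adj_p`, `fold`, `significant`, `overall_p`, `method`.
#' @export
rm_anova_cs <- function(mat, sheet, eligible, alpha = 0.05,
                        adjust_scope = c("per_contrast", "pooled")) {
  adjust_scope <- match.arg(adjust_scope)
  eligible <- intersect(eligible, rownames(mat))
  if (!length(eligible))
    stop("rm_anova_cs: no eligible sequences", call. = FALSE)
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  passages <- unique(sheet$passage)

  dp <- .donor_passage_means(mat, sheet)
  tab <- table(dp$combos$donor_id)
  complete <- names(tab)[tab == length(passages)]
  dropped <- setdiff(unique(dp$combos$donor_id), complete)
  if (length(dropped))
    warning(sprintf("donor(s) without all passages dropped: %s",
                    paste(dropped, collapse = ", ")))
  if (length(complete) < 3L)
    stop("rm_anova_cs: fewer than 3 donors with all passages", call. = FALSE)
  keep <- dp$combos$donor_id %in% complete
  combos <- dp$combos[keep, ]
  vals <- dp$values[, keep, drop = FALSE]

  contrasts <- list()
  for (i in seq_along(passages)) for (j in seq_along(passages))
    if (j > i) contrasts[[paste0(passages[j], "/", passages[i])]] <-
      c(passages[i], passages[j])

  rows <- lapply(eligible, function(s) {
    fit <- .fit_cs_one(vals[match(s, rownames(mat)), ], combos$donor_id,
                       combos$passage, passages, contrasts)
    data.frame(sequence_id = s,
               contrast = names(contrasts),
               estimate = vapply(fit$contrasts, `[[`, numeric(1), "estimate"),
               raw_p = vapply(fit$contrasts, `[[`, numeric(1), "p"),
               overall_p = fit$overall_p, method = fit$method,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- if (adjust_scope == "per_contrast")
    ave(res$raw_p, res$contrast, FUN = benjamini_hochberg)
  else benjamini_hochberg(res$raw_p)
  res$fold <- fold_from_log2diff(res$estimate)
  res$significant <- !is.na(res$adj_p) & res$adj_p < alpha
  res <- res[, c("sequence_id", "contrast", "estimate", "raw_p", "adj_p",
                 "fold", "significant", "overall_p", "method")]
  class(res) <- c("passage_de", "data.frame")
  res
}

## classic pooled-variance two-sample t-test, vectorized over rows
.pooled_t <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, var); vb <- apply(xb, 1L, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (mb - ma) / se
  df <- na + nb - 2
  p <- 2 * pt(-abs(tstat), df)
  p[se == 0 & (mb - ma) == 0] <- 1
  p[se == 0 & (mb - ma) != 0] <- 0
  list(t = tstat, p = p, df = df, diff = mb - ma)
}

#' Pooled-variance group contrast (e.g. MSC versus cancer)
#'
#' Unequal-sample-size, equal-variance two-sample t-test per sequence between
#' two cohorts, on biological-sample units (technical replicates averaged per
#' donor / cancer sample). Before testing, the technical filter stages are
#' re-run for this comparison with the group difference in place of the
#' passage difference: sequences are kept when the absolute group-mean
#' difference exceeds both the within-chip and between-chip cutoffs
#' (computed on these arrays), then when the mean expression of every group
#' exceeds the background cutoff. BH adjustment is applied across the tested
#' sequences.
#'
#' @param mat log2 ExpressionMatrix (experimental sequences).
#' @param sheet Sample sheet for the columns of `mat`; must contain the two
#'   cohorts.
#' @param probes The `probe_table` for these arrays (for within-chip
#'   cutoffs).
#' @param cohort_a,cohort_b Cohort labels in `sheet$cohort` (difference and
#'   fold are b minus a, e.g. a = MSC, b = cancer).
#' @param magnitude_cutoff Global negative-control background cutoff (log2).
#' @param alpha_adj Significance level on adjusted p (default 0.01).
#' @return A `group_de` data.frame per tested sequence: `sequence_id`, `t`,
#'   `raw_p`, `adj_p`, `estimate` (log2 b - a), `fold`, `significant`;
#'   filter counts in attribute `"counts"`.
#' @export
pooled_t_group_contrast <- function(mat, sheet, probes,
                                    cohort_a = "MSC_set1", cohort_b = "cancer",
                                    magnitude_cutoff, alpha_adj = 0.01) {
  sheet <- sheet[sheet$array_id %in% colnames(mat), , drop = FALSE]
  sa <- sheet[sheet$cohort == cohort_a, , drop = FALSE]
  sb <- sheet[sheet$cohort == cohort_b, , drop = FALSE]
  units_of <- function(s) {
    u <- unique(s$donor_id)
    vapply(u, function(d) rowMeans(mat[, s$array_id[s$donor_id == d],
                                       drop = FALSE]),
           numeric(nrow(mat)))
  }
  xa <- units_of(sa); xb <- units_of(sb)
  if (ncol(xa) < 2L || ncol(xb) < 2L)
    stop("pooled_t_group_contrast: both groups need >= 2 biological units",
         call. = FALSE)

  within <- within_chip_cutoffs(probes[probes$array_id %in% sheet$array_id, ,
                                       drop = FALSE])
  between <- between_chip_cutoffs(mat, sheet)
  ids <- rownames(mat)
  gdiff <- abs(rowMeans(xb) - rowMeans(xa))
  pass_tech <- gdiff > within[ids] & gdiff > between[ids]
  pass_mag <- rowMeans(xa) > magnitude_cutoff & rowMeans(xb) > magnitude_cutoff
  tested <- pass_tech & pass_mag

  tt <- .pooled_t(xa[tested, , drop = FALSE], xb[tested, , drop = FALSE])
  res <- data.frame(
    sequence_id = ids[tested],
    t = unname(tt$t), raw_p = unname(tt$p),
    adj_p = benjamini_hochberg(unname(tt$p)),
    estimate = unname(tt$diff),
    fold = fold_from_log2diff(unname(tt$diff)),
    stringsAsFactors = FALSE)
  res$significant <- res$adj_p < alpha_adj
  class(res) <- c("group_de", "data.frame")
  attr(res, "counts") <- c(total = length(ids),
                           pass_technical = sum(pass_tech),
                           tested = sum(tested),
                           significant = sum(res$significant))
  res
}
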