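test_that("signed fold change has the documented closed forms", {
  expect_equal(fold_from_log2diff(0), 1.0)
  expect_equal(fold_from_log2diff(1), 2.0)
  expect_equal(fold_from_log2diff(-1), -2.0)
  expect_equal(fold_from_log2diff(log2(1.45)), 1.45, tolerance = 1e-12)
  expect_equal(fold_from_log2diff(c(0.5, -0.5)), c(2^0.5, -2^0.5))
})

test_that("BH adjustment matches the step-up oracle and dominates raw p", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- numeric(m)
    prev <- 1
    for (k in seq_along(o)) {
      i <- o[k]
      r <- m - k + 1          # rank of p[i] among sorted ascending
      prev <- min(prev, p[i] * m / r)
      adj[i] <- prev
    }
    pmin(adj, 1)
  }
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  set.seed(99)
  for (i in 1:50) {
    p <- runif(sample(1:60, 1))
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

make_rm_fixture <- function(values, donors, passages) {
  arrays <- as.vector(outer(donors, passages, paste, sep = "_"))
  sheet <- data.frame(array_id = arrays,
                      donor_id = rep(donors, length(passages)),
                      passage = rep(passages, each = length(donors)),
                      tech_rep = 1, cohort = "MSC_set1")
  mat <- matrix(values, nrow = 1, dimnames = list("s1", arrays))
  list(mat = mat, sheet = sheet)
}

test_that("a sequence constant within donors gives null contrasts", {
  donors <- paste0("D", 1:4)
  vals <- rep(c(5, 6, 7, 8), 3)     # donor level only, no passage effect
  fx <- make_rm_fixture(vals, donors, c("P3", "P5", "P7"))
  res <- rm_anova_cs(fx$mat, fx$sheet, "s1")
  expect_equal(res$estimate, rep(0, 3))
  expect_equal(res$raw_p, rep(1, 3))
  expect_equal(res$fold, rep(1, 3))
})

test_that("balanced two-passage CS model reproduces the paired t-test", {
  set.seed(17)
  for (i in 1:5) {
    donors <- paste0("D", 1:6)
    d_eff <- rnorm(6, 0, 1)
    y3 <- 6 + d_eff + rnorm(6, 0, 0.3)
    y7 <- 6.4 + d_eff + rnorm(6, 0, 0.3)
    fx <- make_rm_fixture(c(y3, y7), donors, c("P3", "P7"))
    res <- rm_anova_cs(fx$mat, fx$sheet, "s1")
    tt <- t.test(y7, y3, paired = TRUE)
    ## REML optimizer precision bounds the agreement at ~1e-6 relative
    expect_equal(res$raw_p, tt$p.value, tolerance = 1e-5)
    expect_equal(res$estimate, unname(tt$estimate), tolerance = 1e-8)
    expect_equal(res$method, "gls_cs")
  }
})

test_that("CS contrast estimates equal passage-mean differences when balanced", {
  set.seed(23)
  donors <- paste0("D", 1:5)
  passages <- c("P3", "P5", "P7")
  y <- 6 + rep(rnorm(5, 0, 0.5), 3) + rep(c(0, 0.2, 0.5), each = 5) +
    rnorm(15, 0, 0.1)
  fx <- make_rm_fixture(y, donors, passages)
  res <- rm_anova_cs(fx$mat, fx$sheet, "s1")
  means <- tapply(y, rep(passages, each = 5), mean)
  expect_equal(res$estimate[res$contrast == "P7/P3"],
               unname(means["P7"] - means["P3"]), tolerance = 1e-8)
  expect_equal(res$estimate[res$contrast == "P5/P3"],
               unname(means["P5"] - means["P3"]), tolerance = 1e-8)
})

test_that("incomplete donors are dropped with a warning; too few is an error", {
  donors <- paste0("D", 1:4)
  fx <- make_rm_fixture(rnorm(12, 6), donors, c("P3", "P5", "P7"))
  fx$sheet <- fx$sheet[-1, ]                      # D1 misses P3
  fx$mat <- fx$mat[, fx$sheet$array_id, drop = FALSE]
  expect_warning(res <- rm_anova_cs(fx$mat, fx$sheet, "s1"), "D1")
  fx2 <- make_rm_fixture(rnorm(6, 6), paste0("D", 1:2), c("P3", "P5", "P7"))
  expect_error(rm_anova_cs(fx2$mat, fx2$sheet, "s1"), "fewer than 3 donors")
})

test_that("a consistent late-passage shift is detected in nearly all seeds", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    donors <- paste0("D", 1:6)
    d_eff <- rnorm(6, 0, 0.3)
    y <- c(6 + d_eff + rnorm(6, 0, 0.05),
           6 + d_eff + rnorm(6, 0, 0.05),
           6.5 + d_eff + rnorm(6, 0, 0.05))
    fx <- make_rm_fixture(y, donors, c("P3", "P5", "P7"))
    res <- rm_anova_cs(fx$mat, fx$sheet, "s1")
    res$significant[res$contrast == "P7/P3"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permuting passage labels within donors destroys significance", {
  cf <- small_config(seed = 41, sigma_donor = 0.05)
  sim <- simulate_experiment(cf)
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  emat <- mat[exp_ids, ]
  eligible <- names(sim$truth$true_de)
  res <- rm_anova_cs(emat, sim$sheet, eligible)
  expect_gt(sum(res$significant[res$contrast == "P7/P3"]), 8)
  set.seed(1)
  n_sig <- vapply(1:20, function(i) {
    sh <- sim$sheet
    for (d in unique(sh$donor_id)) {
      rows <- sh$donor_id == d
      pmap <- sample(unique(sh$passage[rows]))
      sh$passage[rows] <- pmap[match(sh$passage[rows], unique(sh$passage[rows]))]
    }
    r <- rm_anova_cs(emat, sh, eligible)
    sum(r$significant[r$contrast == "P7/P3"])
  }, numeric(1))
  expect_lte(median(n_sig), max(1, 0.05 * length(eligible)))
})

test_that("pooled-variance t-test matches hand evaluation", {
  tt <- mirpassage:::.pooled_t(matrix(c(1, 2, 3), 1), matrix(c(3, 4, 5), 1))
  expect_equal(unname(tt$t), 2.449, tolerance = 1e-3)
  expect_equal(unname(tt$p), 0.0705, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  same <- mirpassage:::.pooled_t(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1))
  expect_equal(unname(same$t), 0)
  expect_equal(unname(same$p), 1)
})

test_that("a spiked sequence ranks first in the MSC-vs-cancer contrast", {
  eff <- setNames(log2(7), "seq_0011")
  cf <- small_config(seed = 44, passages = "P3", n_donors = 8, n_tech_reps = 3,
                     n_sequences = 400, n_mirnas = 150, n_variable = 150L,
                     n_trna_rrna = 0,
                     n_cancer_samples = 2L, cancer_tech_reps = 2L,
                     cancer_effects = eff, passage_effects = list(),
                     dropout_donors = setNames(integer(0), character(0)))
  sim <- simulate_experiment(cf)
  expect_equal(nrow(sim$sheet), 28L)      # 8 x 3 MSC + 2 x 2 cancer arrays
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  neg_ids <- ann$sequence_id[ann$control_type == "negative"]
  cuts <- background_cutoffs(mat, sim$sheet, neg_ids)
  res <- pooled_t_group_contrast(mat[exp_ids, ], sim$sheet, sim$probes,
                                 magnitude_cutoff = cuts$global$cutoff)
  expect_equal(res$sequence_id[which.max(abs(res$t))], "seq_0011")
  ## quantile normalization compresses the extreme top, so the recovered
  ## fold is attenuated relative to the configured 7
  expect_gt(res$fold[res$sequence_id == "seq_0011"], 3)
  expect_true(res$significant[res$sequence_id == "seq_0011"])
  cnt <- attr(res, "counts")
  expect_lte(cnt["tested"], cnt["pass_technical"])
})
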