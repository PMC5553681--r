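test_that("group background cutoffs pool the replicate arrays' negatives", {
  ## 1 donor/passage group, 2 arrays x 3 negative controls
  mat <- rbind(NC_1 = c(5.0, 5.2), NC_2 = c(5.4, 5.0), NC_3 = c(5.2, 5.6),
               seq_a = c(7, 7))
  colnames(mat) <- c("A1", "A2")
  sheet <- data.frame(array_id = c("A1", "A2"), donor_id = "D1",
                      passage = "P3", tech_rep = 1:2, cohort = "MSC_set1")
  cuts <- background_cutoffs(mat, sheet, c("NC_1", "NC_2", "NC_3"))
  pooled <- c(5.0, 5.4, 5.2, 5.2, 5.0, 5.6)
  expect_equal(cuts$groups$cutoff, mean(pooled) + sd(pooled), tolerance = 1e-12)
  expect_equal(cuts$global$cutoff, mean(pooled) + sd(pooled), tolerance = 1e-12)
  cuts_m <- background_cutoffs(mat, sheet, c("NC_1", "NC_2", "NC_3"),
                               mode = "mean")
  expect_equal(cuts_m$groups$cutoff, mean(pooled), tolerance = 1e-12)
  expect_true(all(cuts$groups$cutoff >= cuts$groups$mean))
})

test_that("outlier flagging finds the constructed elevated array and only it", {
  cf <- small_config(seed = 8, n_outlier_arrays = 1L, outlier_elevation = 3)
  sim <- simulate_experiment(cf)
  flagged <- suppressMessages(flag_outlier_arrays(sim$probes, k = 5))
  expect_equal(as.character(flagged), sim$truth$outlier_arrays)
  ## null case: no elevation, identical generative distributions
  cf0 <- small_config(seed = 8, n_outlier_arrays = 0L)
  sim0 <- simulate_experiment(cf0)
  expect_length(flag_outlier_arrays(sim0$probes, k = 5), 0L)
  ## limit case
  expect_length(flag_outlier_arrays(sim$probes, k = Inf), 0L)
})

test_that("detection calls apply the median-over-replicates rule per group", {
  mat <- rbind(s1 = rep(6, 4), s2 = c(6, 6, 4.4, 4.5), NC = rep(5, 4))
  colnames(mat) <- paste0("A", 1:4)
  sheet <- data.frame(array_id = paste0("A", 1:4),
                      donor_id = rep(c("D1", "D2"), each = 2),
                      passage = "P3", tech_rep = c(1, 2, 1, 2),
                      cohort = "MSC_set1")
  cuts <- list(groups = data.frame(group = c("D1/P3", "D2/P3"),
                                   donor_id = c("D1", "D2"), passage = "P3",
                                   mean = 5, sd = 0, cutoff = c(5, 5)),
               global = list(mean = 5, sd = 0, cutoff = 5))
  ann <- data.frame(sequence_id = c("s1", "s2"), mirna_name = c("m1", "m2"),
                    control_type = "experimental", rna_class = "miRNA")
  calls <- detection_calls(mat[1:2, ], sheet, cuts, ann)
  expect_true(calls$sequence$commonly_expressed[calls$sequence$sequence_id == "s1"])
  ## s2 fails in exactly one group (D2 median 4.45 < 5) -> not commonly expressed
  expect_false(calls$sequence$commonly_expressed[calls$sequence$sequence_id == "s2"])
  expect_equal(unname(calls$expressed["s2", ]), c(TRUE, FALSE))
})

test_that("low-noise detection calls recover the generative ground truth", {
  cf <- small_config(seed = 14, sigma_probe = 0.01, sigma_array = 0.01,
                     sigma_donor = 0.02, n_variable = 0L)
  sim <- simulate_experiment(cf)
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  neg_ids <- ann$sequence_id[ann$control_type == "negative"]
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  cuts <- background_cutoffs(mat, sim$sheet, neg_ids)
  calls <- detection_calls(mat[exp_ids, ], sim$sheet, cuts, ann)
  found <- calls$sequence$sequence_id[calls$sequence$commonly_expressed]
  expect_setequal(found, sim$truth$true_detected)
  ## miRNA roll-up excludes tRNA/rRNA sequences
  ann_found <- ann[match(found, ann$sequence_id), ]
  expected_mirnas <- unique(ann_found$mirna_name[
    !(ann_found$rna_class %in% c("tRNA", "rRNA"))])
  expect_setequal(calls$mirna$mirna_name[calls$mirna$commonly_expressed],
                  expected_mirnas)
})

test_that("raising cutoffs never grows the commonly-expressed set", {
  cf <- small_config(seed = 15)
  sim <- simulate_experiment(cf)
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  neg_ids <- ann$sequence_id[ann$control_type == "negative"]
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  cuts <- background_cutoffs(mat, sim$sheet, neg_ids)
  for (delta in c(0, 0.25, 0.5, 1)) {
    up <- cuts
    up$groups$cutoff <- cuts$groups$cutoff + delta
    calls <- detection_calls(mat[exp_ids, ], sim$sheet, up, ann)
    set_now <- calls$sequence$sequence_id[calls$sequence$commonly_expressed]
    if (delta == 0) set_prev <- set_now
    expect_true(all(set_now %in% set_prev))
    set_prev <- set_now
  }
})

test_that("duplicate comparison has the stated closed forms and error", {
  mat <- rbind(l1 = c(6, 6), s1 = c(6, 6), l2 = c(7, 7), s2 = c(7, 7))
  colnames(mat) <- c("A1", "A2")
  pairs <- data.frame(long_seq = c("l1", "l2"), short_seq = c("s1", "s2"))
  res <- duplicate_length_comparison(mat, pairs)
  expect_equal(res$fold, 1.0)
  expect_equal(res$t, 0)
  ## exact +1 log2 in every pair: fold 2, degenerate zero-variance p = 0
  mat2 <- mat
  mat2[c("l1", "l2"), ] <- mat2[c("s1", "s2"), ] + 1
  res2 <- suppressMessages(duplicate_length_comparison(mat2, pairs))
  expect_equal(res2$fold, 2.0)
  expect_equal(res2$p_value, 0)
  expect_error(duplicate_length_comparison(mat, pairs[1, , drop = FALSE]),
               "fewer than 2")
})

test_that("the configured long/short offset is recovered across 41 pairs", {
  cf <- small_config(seed = 21, n_sequences = 400, n_mirnas = 150,
                     n_duplicate_pairs = 41, n_expressed_singletons = 10,
                     n_trna_rrna = 0, n_variable = 60L,
                     n_donors = 4, n_tech_reps = 2)
  sim <- simulate_experiment(cf)
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  res <- duplicate_length_comparison(mat[exp_ids, ], cf$duplicate_pairs)
  ## estimate within its own 99.7% CI of the configured fold 2^0.74 = 1.67
  se <- sd(res$log2_diffs) / sqrt(res$n_pairs)
  expect_lt(abs(res$mean_log2_diff - 0.74), 3 * se)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$fold, 1.4)
})
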