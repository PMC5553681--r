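test_that("within-chip cutoff is the median over arrays of probe-replicate SDs", {
  pt <- data.frame(array_id = rep(c("A1", "A2"), each = 2),
                   probe_id = paste0("p", 1:4),
                   sequence_id = "s1", mirna_name = "m",
                   control_type = "experimental", rna_class = "miRNA",
                   raw_signal = 2^c(1, 3, 2, 2), stringsAsFactors = FALSE)
  ## per-array SDs on log2: sd(1,3) = sqrt(2), sd(2,2) = 0; median = mean here
  cut <- within_chip_cutoffs(pt)
  expect_equal(unname(cut["s1"]), (sqrt(2) + 0) / 2, tolerance = 1e-12)
})

test_that("zero-noise within-chip cutoffs are exactly zero", {
  cf <- quiet_config(seed = 5)
  sim <- simulate_experiment(cf)
  cuts <- within_chip_cutoffs(sim$probes)
  expect_true(all(cuts == 0))
})

test_that("single-probe sequences get cutoff zero with a warning", {
  pt <- data.frame(array_id = c("A1", "A2"), probe_id = c("p1", "p1"),
                   sequence_id = "solo", mirna_name = "m",
                   control_type = "experimental", rna_class = "miRNA",
                   raw_signal = c(4, 4), stringsAsFactors = FALSE)
  expect_warning(cut <- within_chip_cutoffs(pt), "single probe")
  expect_equal(unname(cut["solo"]), 0)
})

test_that("within-chip cutoffs concentrate near the c4-corrected probe SD", {
  cf <- small_config(seed = 31, sigma_probe = 0.1, n_sequences = 60,
                     n_mirnas = 30, n_duplicate_pairs = 0,
                     n_expressed_singletons = 5, n_trna_rrna = 0,
                     n_variable = 0L)
  sim <- simulate_experiment(cf)
  cuts <- within_chip_cutoffs(sim$probes)
  ## E[SD] for n = 4 normal draws is c4(4) * sigma ~ 0.921 * 0.1
  expect_lt(abs(mean(cuts) - 0.0921), 0.01)
  expect_true(all(cuts > 0.04 & cuts < 0.16))
})

test_that("between-chip cutoffs reproduce hand-computed group SDs", {
  ## all groups have replicate values {5, 6, 7}: SD 1 everywhere
  mat <- matrix(rep(c(5, 6, 7), 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), paste0("A", 1:6)))
  sheet <- data.frame(array_id = paste0("A", 1:6),
                      donor_id = rep(c("D1", "D2"), each = 3),
                      passage = "P3", tech_rep = rep(1:3, 2),
                      cohort = "MSC_set1")
  expect_equal(unname(between_chip_cutoffs(mat, sheet)), c(1, 1),
               tolerance = 1e-12)
  ## identical technical replicates give zero cutoffs
  mat0 <- matrix(5, 2, 6, dimnames = dimnames(mat))
  expect_equal(unname(between_chip_cutoffs(mat0, sheet)), c(0, 0))
  ## no replicated group is an error
  sheet1 <- sheet; sheet1$donor_id <- paste0("D", 1:6)
  expect_error(between_chip_cutoffs(mat, sheet1), ">= 2")
})

test_that("between-chip cutoffs track the array-offset SD", {
  cf <- small_config(seed = 32, sigma_array = 0.2, n_tech_reps = 5,
                     n_sequences = 60, n_mirnas = 30, n_duplicate_pairs = 0,
                     n_expressed_singletons = 5, n_trna_rrna = 0,
                     n_variable = 0L)
  sim <- simulate_experiment(cf)
  ## un-normalized log2 matrix keeps the array offsets
  mat <- log2(collapse_probe_replicates(sim$probes))
  exp_ids <- grep("^seq_", rownames(mat), value = TRUE)
  cuts <- between_chip_cutoffs(mat[exp_ids, ], sim$sheet)
  expect_lt(abs(mean(cuts) - 0.19), 0.05)
})

test_that("cascade stages apply in order with NA for unevaluated stages", {
  ## 4 donors x 2 passages, 1 rep; three hand-built sequences:
  ## s_flat fails stage 1; s_good passes all; s_dim passes 1-3, fails 4
  arrays <- paste0("A", 1:8)
  sheet <- data.frame(array_id = arrays,
                      donor_id = rep(paste0("D", 1:4), 2),
                      passage = rep(c("P3", "P7"), each = 4),
                      tech_rep = 1, cohort = "MSC_set1")
  mat <- rbind(
    s_flat = rep(7, 8),
    s_good = c(7, 7.1, 6.9, 7, 7.52, 7.63, 7.40, 7.55),
    s_dim  = c(4.0, 4.1, 3.9, 4.0, 4.52, 4.63, 4.40, 4.55))
  colnames(mat) <- arrays
  w <- setNames(rep(0.2, 3), rownames(mat))
  b <- setNames(rep(0.2, 3), rownames(mat))
  tr <- apply_cascade(mat, sheet, w, b, magnitude_cutoff = 5.4)
  get <- function(s, col) tr[[col]][tr$sequence_id == s]
  expect_false(get("s_flat", "pass_within"))
  expect_true(is.na(get("s_flat", "pass_bio")))
  expect_true(get("s_good", "final_eligible"))
  expect_true(get("s_dim", "pass_bio"))
  expect_false(get("s_dim", "pass_magnitude"))
  expect_false(get("s_dim", "final_eligible"))
  cnt <- attr(tr, "counts")
  expect_equal(unname(cnt["total"]),
               unname(cnt["fail_within"] + cnt["fail_between"] +
                      cnt["fail_bio"] + cnt["fail_magnitude"] + cnt["eligible"]))
})

test_that("spiked sequences survive the cascade and nulls fail early", {
  ## calibrated so cutoffs (~0.22 within-chip) sit well below the 0.5 effect
  ## but well above the null sequences' residual variation
  eff <- setNames(rep(list(c(P3 = 0, P5 = 0.25, P7 = 0.5)), 8),
                  sprintf("seq_%04d", 11:18))
  cf <- small_config(seed = 33, sigma_donor = 0.05, sigma_probe = 0.25,
                     n_sequences = 400, n_mirnas = 150, n_variable = 150L,
                     n_duplicate_pairs = 5, n_expressed_singletons = 8,
                     n_trna_rrna = 0, passage_effects = eff)
  sim <- simulate_experiment(cf)
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  neg_ids <- ann$sequence_id[ann$control_type == "negative"]
  cuts <- background_cutoffs(mat, sim$sheet, neg_ids)
  w <- within_chip_cutoffs(sim$probes)
  b <- between_chip_cutoffs(mat[exp_ids, ], sim$sheet)
  tr <- apply_cascade(mat[exp_ids, ], sim$sheet, w, b,
                      magnitude_cutoff = cuts$global$cutoff)
  spiked <- names(sim$truth$true_de)
  eligible <- tr$sequence_id[tr$final_eligible]
  expect_true(all(spiked %in% eligible))
  expect_lt(length(setdiff(eligible, spiked)), 4)
})

test_that("cascade output is invariant to sequence order and monotone in cutoffs", {
  cf <- small_config(seed = 34)
  sim <- simulate_experiment(cf)
  raw <- collapse_probe_replicates(sim$probes)
  ann <- attr(raw, "annotation")
  mat <- quantile_normalize(raw)
  exp_ids <- ann$sequence_id[ann$control_type == "experimental"]
  emat <- mat[exp_ids, ]
  w <- within_chip_cutoffs(sim$probes)
  b <- between_chip_cutoffs(emat, sim$sheet)
  tr <- apply_cascade(emat, sim$sheet, w, b, magnitude_cutoff = 5.4)
  perm <- sample(nrow(emat))
  tr_p <- apply_cascade(emat[perm, ], sim$sheet, w, b, magnitude_cutoff = 5.4)
  expect_setequal(tr$sequence_id[tr$final_eligible],
                  tr_p$sequence_id[tr_p$final_eligible])
  ## tightening any cutoff shrinks the eligible set
  base_set <- tr$sequence_id[tr$final_eligible]
  tr_w <- apply_cascade(emat, sim$sheet, w * 2, b, magnitude_cutoff = 5.4)
  tr_b <- apply_cascade(emat, sim$sheet, w, b * 2, magnitude_cutoff = 5.4)
  tr_m <- apply_cascade(emat, sim$sheet, w, b, magnitude_cutoff = 6.4)
  tr_a <- apply_cascade(emat, sim$sheet, w, b, magnitude_cutoff = 5.4,
                        alpha = 0.01)
  for (t2 in list(tr_w, tr_b, tr_m, tr_a))
    expect_true(all(t2$sequence_id[t2$final_eligible] %in% base_set))
})

test_that("fewer than two complete donors is an error", {
  sheet <- data.frame(array_id = c("A1", "A2", "A3"),
                      donor_id = c("D1", "D1", "D2"),
                      passage = c("P3", "P7", "P3"),
                      tech_rep = 1, cohort = "MSC_set1")
  mat <- matrix(5, 1, 3, dimnames = list("s1", c("A1", "A2", "A3")))
  expect_error(apply_cascade(mat, sheet, c(s1 = 0), c(s1 = 0), 5),
               "fewer than 2 donors")
})
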