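#' Configuration for a synthetic miRNA microarray experiment
#'
#' Builds the configuration object consumed by [simulate_experiment()]. The
#' defaults emulate the repeated-measures MSC study design: 8 donors cultured
#' to passages P3/P5/P7 and hybridized in technical triplicate (one donor
#' stops at P3 and one at P5, giving 63 arrays and 21 donor/passage groups),
#' 2686 probe sequences representing 939 miRNAs with 4-8 on-array probe
#' replicates each, 434 negative-control probes per array, 41 duplicate
#' long/short sequence pairs offset by 0.74 log2 (fold 1.67), 11 expressed
#' sequences flagged as tRNA/rRNA, and 12 sequences carrying passage effects
#' with fold magnitudes between 1.05 and 1.49. Two arrays receive an elevated
#' negative-control background so the outlier-flagging rule has true
#' positives to find.
#'
#' All signals are built additively on the log2 scale:
#' `baseline + donor effect + passage effect + array offset + probe noise`,
#' then exponentiated (`2^x`) to the raw-intensity scale, so that taking log2
#' of the raw signal recovers the additive model exactly.
#'
#' @param n_donors Number of MSC donors.
#' @param passages Ordered character vector of passage labels.
#' @param n_tech_reps Technical-replicate arrays per donor/passage.
#' @param n_sequences Number of experimental probe sequences.
#' @param n_mirnas Number of distinct miRNA names (`<= n_sequences`).
#' @param probe_reps_range Inclusive integer range for on-array probe
#'   replicates per sequence (default 4-8).
#' @param n_negative_controls Negative-control probes per array.
#' @param baseline_log2_range Interval for baselines of background
#'   (non-expressed) sequences, log2 units.
#' @param expressed_log2_range Interval for baselines of expressed sequences.
#' @param n_duplicate_pairs,n_expressed_singletons,n_trna_rrna Composition of
#'   the expressed set; `NULL` uses the study-like composition (41/30/11),
#'   shrunk if `n_sequences`/`n_mirnas` cannot accommodate it.
#' @param n_variable Number of heterogeneously expressed sequences: expressed
#'   at high level in most donors but silenced (near background) in
#'   `n_silent_donors` donors, so they are never commonly expressed. They
#'   fill the upper intensity range with a dense continuum of values, as on
#'   real arrays. `NULL` scales the study-like proportion (~19% of
#'   sequences); 0 disables the class.
#' @param variable_log2_range Baseline interval for the variable class.
#' @param n_silent_donors Donors in which each variable sequence is silenced.
#' @param silent_level Expression level (log2) of a silenced sequence.
#' @param duplicate_offset Log2 excess of the long over the short sequence of
#'   each duplicate pair.
#' @param sigma_probe SD of within-array probe-replicate noise (log2).
#' @param sigma_array SD of the per-array additive offset (log2).
#' @param sigma_donor SD of the per-(sequence, donor) random effect (log2).
#' @param passage_effects Named list mapping sequence ids to a numeric vector
#'   of per-passage log2 shifts (named by passage, first passage is the
#'   reference). `NULL` installs the default 12-sequence effect set.
#' @param negctl_mean,negctl_sd Negative-control distribution (log2).
#' @param dropout_donors Named integer vector: donor id -> number of leading
#'   passages that donor reaches. `NULL` gives the study-like dropout (one
#'   donor stops after the first passage, one after the second) when the
#'   design is the full default, otherwise no dropout.
#' @param n_outlier_arrays,outlier_elevation Number of arrays given an
#'   elevated negative-control background, and the elevation (log2).
#' @param n_cancer_samples,cancer_tech_reps Optional comparison cohort of
#'   non-MSC samples hybridized at a single passage.
#' @param cancer_effects Named numeric vector of log2 shifts (sequence id ->
#'   shift) applied in the cancer cohort; `NULL` installs a default set with
#'   shifts up to log2(7.16) when `n_cancer_samples > 0`.
#' @param seed Integer seed; every random draw in the simulation flows from it.
#'
#' @return A list of class `simulation_config` with resolved sequence/miRNA
#'   maps, duplicate pairs, effect maps and all parameters above.
#' @export
simulation_config <- function(n_donors = 8L,
                              passages = c("P3", "P5", "P7"),
                              n_tech_reps = 3L,
                              n_sequences = 2686L,
                              n_mirnas = 939L,
                              probe_reps_range = c(4L, 8L),
                              n_negative_controls = 434L,
                              baseline_log2_range = c(3.5, 5.2),
                              expressed_log2_range = c(5.8, 9.8),
                              n_duplicate_pairs = NULL,
                              n_expressed_singletons = NULL,
                              n_trna_rrna = NULL,
                              n_variable = NULL,
                              variable_log2_range = c(5.2, 9.8),
                              n_silent_donors = 1L,
                              silent_level = 4.2,
                              duplicate_offset = 0.74,
                              sigma_probe = 0.05,
                              sigma_array = 0.05,
                              sigma_donor = 0.15,
                              passage_effects = NULL,
                              negctl_mean = 5.29,
                              negctl_sd = 0.11,
                              dropout_donors = NULL,
                              n_outlier_arrays = 2L,
                              outlier_elevation = 3,
                              n_cancer_samples = 0L,
                              cancer_tech_reps = 2L,
                              cancer_effects = NULL,
                              seed = 1L) {
  n_donors      <- .check_count(n_donors, "n_donors")
  n_tech_reps   <- .check_count(n_tech_reps, "n_tech_reps")
  n_sequences   <- .check_count(n_sequences, "n_sequences")
  n_mirnas      <- .check_count(n_mirnas, "n_mirnas")
  n_negative_controls <- .check_count(n_negative_controls, "n_negative_controls")
  if (n_mirnas > n_sequences)
    stop("invalid configuration: 'n_mirnas' must not exceed 'n_sequences'", call. = FALSE)
  if (!is.character(passages) || length(passages) < 1L || anyDuplicated(passages))
    stop("invalid configuration: 'passages' must be distinct labels", call. = FALSE)
  probe_reps_range <- .check_interval(probe_reps_range, "probe_reps_range")
  if (probe_reps_range[1] < 1 || any(probe_reps_range != floor(probe_reps_range)))
    stop("invalid configuration: 'probe_reps_range' must be positive integers", call. = FALSE)
  baseline_log2_range  <- .check_interval(baseline_log2_range, "baseline_log2_range")
  expressed_log2_range <- .check_interval(expressed_log2_range, "expressed_log2_range")
  for (nm in c("sigma_probe", "sigma_array", "sigma_donor", "negctl_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("invalid configuration: '%s' must be a single non-negative number", nm),
           call. = FALSE)
  }

  sequence_ids <- sprintf("seq_%04d", seq_len(n_sequences))
  mirna_ids    <- sprintf("mir-%04d", seq_len(n_mirnas))

  ## expressed-set composition, shrunk to fit small test configs
  n_dup  <- n_duplicate_pairs %||% 41L
  n_sing <- n_expressed_singletons %||% 30L
  n_odd  <- n_trna_rrna %||% 11L
  shrink <- function() {
    while (2L * n_dup + n_sing + n_odd > n_sequences ||
           n_dup + n_sing + n_odd > n_mirnas) {
      if (n_odd > 0L) n_odd <<- n_odd - 1L
      else if (n_dup >= n_sing && n_dup > 0L) n_dup <<- n_dup - 1L
      else if (n_sing > 0L) n_sing <<- n_sing - 1L
      else stop("invalid configuration: 'n_sequences' too small", call. = FALSE)
    }
  }
  n_dup <- as.integer(n_dup); n_sing <- as.integer(n_sing); n_odd <- as.integer(n_odd)
  shrink()
  n_var <- as.integer(n_variable %||% round(0.186 * n_sequences))
  n_var <- max(0L, min(n_var, n_sequences - (2L * n_dup + n_sing + n_odd)))
  variable_log2_range <- .check_interval(variable_log2_range, "variable_log2_range")

  ## sequence -> miRNA map: duplicate pairs first (two sequences per miRNA),
  ## then singletons, then tRNA/rRNA-flagged, remainder spread round-robin
  mirna_of <- character(n_sequences)
  rna_class <- rep("miRNA", n_sequences)
  role <- rep("background", n_sequences)
  i <- 0L
  dup_long <- dup_short <- character(n_dup)
  if (n_dup > 0L) for (k in seq_len(n_dup)) {
    dup_long[k]  <- sequence_ids[i + 1L]
    dup_short[k] <- sequence_ids[i + 2L]
    mirna_of[i + 1:2] <- mirna_ids[k]
    role[i + 1:2] <- "expressed"
    i <- i + 2L
  }
  if (n_sing > 0L) for (k in seq_len(n_sing)) {
    mirna_of[i + 1L] <- mirna_ids[n_dup + k]
    role[i + 1L] <- "expressed"
    i <- i + 1L
  }
  if (n_odd > 0L) for (k in seq_len(n_odd)) {
    mirna_of[i + 1L] <- mirna_ids[n_dup + n_sing + k]
    rna_class[i + 1L] <- if (k %% 2L) "tRNA" else "rRNA"
    role[i + 1L] <- "expressed"
    i <- i + 1L
  }
  if (n_var > 0L) role[i + seq_len(n_var)] <- "variable"
  rest_mirnas <- mirna_ids[seq.int(n_dup + n_sing + n_odd + 1L, length.out = n_mirnas - n_dup - n_sing - n_odd)]
  if (i < n_sequences) {
    if (length(rest_mirnas) == 0L) rest_mirnas <- mirna_ids
    mirna_of[(i + 1L):n_sequences] <-
      rep_len(rest_mirnas, n_sequences - i)
  }

  duplicate_pairs <- data.frame(long_seq = dup_long, short_seq = dup_short,
                                log2_offset = rep(duplicate_offset, n_dup),
                                stringsAsFactors = FALSE)

  ## default passage effects: 12 spiked sequences with study-scale folds,
  ## one duplicate pair sharing a miRNA (the strongest, fold 1.45/1.49)
  if (is.null(passage_effects)) {
    passage_effects <- list()
    if (length(passages) >= 2L) {
      late7 <- c(-1.05, -1.39, 1.32, -1.15, 1.26, -1.19, 1.45, 1.49,
                 1.32, -1.22, -1.13, -1.42)
      late5 <- c(-1.05, -1.33, 1.39, -1.19, 1.24, -1.21, 1.28, 1.38,
                 NA, NA, NA, NA)      # NA: not significant mid-passage; use 40%
      expressed_ids <- sequence_ids[role == "expressed" & rna_class == "miRNA"]
      spike_ids <- character(0)
      if (n_dup >= 1L) spike_ids <- c(dup_long[1], dup_short[1])
      others <- setdiff(expressed_ids, spike_ids)
      spike_ids <- c(spike_ids, others[seq_len(min(10L, length(others)))])
      n_spike <- length(spike_ids)
      if (n_spike > 0L) {
        ## put the paired sequences on the 1.45/1.49 entries
        ord <- c(7L, 8L, 1:6, 9:12)[seq_len(n_spike)]
        for (j in seq_len(n_spike)) {
          f7 <- late7[ord[j]]; f5 <- late5[ord[j]]
          s7 <- sign(f7) * log2(abs(f7))
          s5 <- if (is.na(f5)) 0.4 * s7 else sign(f5) * log2(abs(f5))
          eff <- setNames(numeric(length(passages)), passages)
          eff[length(passages)] <- s7
          if (length(passages) >= 3L) eff[2:(length(passages) - 1L)] <- s5
          passage_effects[[spike_ids[j]]] <- eff
        }
      }
    }
  }
  if (length(passage_effects)) {
    if (is.null(names(passage_effects)) ||
        !all(names(passage_effects) %in% sequence_ids))
      stop("invalid configuration: 'passage_effects' keys must be sequence ids",
           call. = FALSE)
  }

  ## default dropout mirrors the study only under the full default design
  if (is.null(dropout_donors)) {
    dropout_donors <-
      if (n_donors == 8L && length(passages) == 3L)
        setNames(c(2L, 1L), sprintf("D%02d", c(7L, 8L)))
      else setNames(integer(0), character(0))
  }

  n_cancer_samples <- .check_count(n_cancer_samples, "n_cancer_samples", min = 0L)
  if (is.null(cancer_effects) && n_cancer_samples > 0L) {
    expressed_ids <- sequence_ids[role == "expressed" & rna_class == "miRNA"]
    k <- min(45L, length(expressed_ids))
    if (k > 0L) {
      folds <- seq(1.3, 7.16, length.out = k) * rep_len(c(1, -1), k)
      cancer_effects <- setNames(sign(folds) * log2(abs(folds)),
                                 expressed_ids[seq_len(k)])
    }
  }
  if (length(cancer_effects) &&
      !all(names(cancer_effects) %in% sequence_ids))
    stop("invalid configuration: 'cancer_effects' keys must be sequence ids",
         call. = FALSE)

  structure(list(
    n_donors = n_donors, passages = passages, n_tech_reps = n_tech_reps,
    n_sequences = n_sequences, n_mirnas = n_mirnas,
    probe_reps_range = as.integer(probe_reps_range),
    n_negative_controls = n_negative_controls,
    baseline_log2_range = baseline_log2_range,
    expressed_log2_range = expressed_log2_range,
    n_variable = n_var, variable_log2_range = variable_log2_range,
    n_silent_donors = .check_count(n_silent_donors, "n_silent_donors", 0L),
    silent_level = silent_level,
    sequence_ids = sequence_ids, mirna_of = mirna_of, rna_class = rna_class,
    role = role, duplicate_pairs = duplicate_pairs,
    sigma_probe = sigma_probe, sigma_array = sigma_array,
    sigma_donor = sigma_donor,
    passage_effects = passage_effects,
    negctl_mean = negctl_mean, negctl_sd = negctl_sd,
    dropout_donors = dropout_donors,
    n_outlier_arrays = as.integer(n_outlier_arrays),
    outlier_elevation = outlier_elevation,
    n_cancer_samples = n_cancer_samples,
    cancer_tech_reps = as.integer(cancer_tech_reps),
    cancer_effects = cancer_effects,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a probe-level miRNA microarray experiment
#'
#' Generates one probe row per (array, sequence, probe replicate) plus the
#' negative-control rows of every array, under the additive log2 model
#' described in [simulation_config()]. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()] object.
#' @return A list with components `probes` (ProbeTable data.frame), `sheet`
#'   (SampleSheet data.frame: `array_id`, `donor_id`, `passage`, `tech_rep`,
#'   `cohort`) and `truth` (ground truth: `true_detected` sequence ids,
#'   `true_de` nonzero passage-effect map, `array_offsets`, `donor_effects`,
#'   `outlier_arrays`, `baselines`).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a simulation_config object", call. = FALSE)
  cf <- config
  set.seed(cf$seed)

  ## --- design ------------------------------------------------------------
  donors <- sprintf("D%02d", seq_len(cf$n_donors))
  n_pass <- length(cf$passages)
  reach <- setNames(rep(n_pass, cf$n_donors), donors)
  if (length(cf$dropout_donors)) {
    keep <- intersect(names(cf$dropout_donors), donors)
    reach[keep] <- pmin(reach[keep], cf$dropout_donors[keep])
  }
  sheet <- do.call(rbind, lapply(donors, function(d) {
    expand.grid(donor_id = d, passage = cf$passages[seq_len(reach[d])],
                tech_rep = seq_len(cf$n_tech_reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  sheet$cohort <- "MSC_set1"
  if (cf$n_cancer_samples > 0L) {
    cs <- expand.grid(donor_id = sprintf("C%02d", seq_len(cf$n_cancer_samples)),
                      passage = "none", tech_rep = seq_len(cf$cancer_tech_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cs$cohort <- "cancer"
    sheet <- rbind(sheet, cs)
  }
  sheet$array_id <- sprintf("%s_%s_r%d", sheet$donor_id, sheet$passage, sheet$tech_rep)
  sheet <- sheet[, c("array_id", "donor_id", "passage", "tech_rep", "cohort")]
  rownames(sheet) <- NULL
  n_arrays <- nrow(sheet)

  ## outlier arrays: elevated negative-control background, rep-1 MSC arrays
  ## (later passages preferred, mirroring the removed P5/P7 arrays)
  cand <- sheet$array_id[sheet$tech_rep == 1L & sheet$cohort == "MSC_set1" &
                         sheet$passage != cf$passages[1]]
  if (!length(cand))
    cand <- sheet$array_id[sheet$tech_rep == 1L & sheet$cohort == "MSC_set1"]
  n_out <- min(cf$n_outlier_arrays, length(cand))
  outlier_arrays <- if (n_out > 0L)
    cand[unique(pmax(1L, round(seq(0.35, 0.75, length.out = n_out) * length(cand))))]
  else character(0)

  ## --- per-sequence structure -------------------------------------------
  nseq <- cf$n_sequences
  expressed <- cf$role == "expressed"
  variable <- cf$role == "variable"
  baselines <- numeric(nseq)
  baselines[!expressed & !variable] <-
    runif(sum(!expressed & !variable), cf$baseline_log2_range[1],
          cf$baseline_log2_range[2])
  baselines[expressed] <- runif(sum(expressed), cf$expressed_log2_range[1],
                                cf$expressed_log2_range[2])
  baselines[variable] <- runif(sum(variable), cf$variable_log2_range[1],
                               cf$variable_log2_range[2])
  names(baselines) <- cf$sequence_ids
  if (nrow(cf$duplicate_pairs)) {
    dp <- cf$duplicate_pairs
    baselines[dp$long_seq] <- baselines[dp$short_seq] + dp$log2_offset
  }

  pr <- cf$probe_reps_range
  probe_reps <- if (pr[1] == pr[2]) rep(pr[1], nseq) else
    sample(seq.int(pr[1], pr[2]), nseq, replace = TRUE)

  ## passage-shift matrix: sequence x passage
  shift <- matrix(0, nseq, n_pass, dimnames = list(cf$sequence_ids, cf$passages))
  for (s in names(cf$passage_effects)) {
    eff <- cf$passage_effects[[s]]
    shift[s, names(eff)] <- eff
  }

  units <- unique(sheet$donor_id)                      # donors + cancer samples
  donor_eff <- matrix(rnorm(nseq * length(units), 0, cf$sigma_donor),
                      nseq, length(units),
                      dimnames = list(cf$sequence_ids, units))
  ## variable class: silenced (near background) in a few donors per sequence
  if (any(variable) && cf$n_silent_donors > 0L && length(donors)) {
    for (s in which(variable)) {
      silent <- donors[sample.int(length(donors),
                                  min(cf$n_silent_donors, length(donors)))]
      donor_eff[s, silent] <- cf$silent_level - baselines[s]
    }
  }
  array_off <- setNames(rnorm(n_arrays, 0, cf$sigma_array), sheet$array_id)

  cancer_shift <- setNames(numeric(nseq), cf$sequence_ids)
  if (length(cf$cancer_effects))
    cancer_shift[names(cf$cancer_effects)] <- cf$cancer_effects

  ## --- experimental probe rows ------------------------------------------
  seq_idx <- rep.int(seq_len(nseq), probe_reps)
  probe_id <- sprintf("%s_p%d", cf$sequence_ids[seq_idx],
                      sequence(probe_reps))
  n_spots <- length(seq_idx)

  arr_idx <- rep(seq_len(n_arrays), each = n_spots)
  sidx <- rep.int(seq_idx, n_arrays)                   # sequence index per row
  is_cancer <- sheet$cohort == "cancer"
  pass_col <- match(sheet$passage, cf$passages)        # NA for cancer arrays
  shift_row <- ifelse(is_cancer[arr_idx],
                      cancer_shift[sidx],
                      shift[cbind(sidx, pass_col[arr_idx])])
  log2sig <- baselines[sidx] +
    donor_eff[cbind(sidx, match(sheet$donor_id, units)[arr_idx])] +
    shift_row + array_off[arr_idx] +
    rnorm(n_spots * n_arrays, 0, cf$sigma_probe)

  exp_rows <- data.frame(
    array_id = sheet$array_id[arr_idx],
    probe_id = rep.int(probe_id, n_arrays),
    sequence_id = cf$sequence_ids[sidx],
    mirna_name = cf$mirna_of[sidx],
    control_type = "experimental",
    rna_class = cf$rna_class[sidx],
    raw_signal = 2^log2sig,
    stringsAsFactors = FALSE
  )

  ## --- negative-control rows --------------------------------------------
  nc <- cf$n_negative_controls
  nc_ids <- sprintf("NC_%04d", seq_len(nc))
  elev <- setNames(rep(0, n_arrays), sheet$array_id)
  elev[outlier_arrays] <- cf$outlier_elevation
  nc_arr <- rep(seq_len(n_arrays), each = nc)
  nc_log2 <- rnorm(nc * n_arrays, cf$negctl_mean, cf$negctl_sd) +
    array_off[nc_arr] + elev[nc_arr]
  nc_rows <- data.frame(
    array_id = sheet$array_id[nc_arr],
    probe_id = rep.int(nc_ids, n_arrays),
    sequence_id = rep.int(nc_ids, n_arrays),
    mirna_name = NA_character_,
    control_type = "negative",
    rna_class = "unknown",
    raw_signal = 2^nc_log2,
    stringsAsFactors = FALSE
  )

  probes <- rbind(exp_rows, nc_rows)
  probes <- probes[order(probes$array_id, probes$probe_id), ]
  rownames(probes) <- NULL
  class(probes) <- c("probe_table", "data.frame")

  bg <- cf$negctl_mean + cf$negctl_sd
  true_de <- cf$passage_effects[
    vapply(cf$passage_effects, function(e) any(e != e[1]), logical(1))]
  ## detected = expected donor-level value above background in every donor
  msc_units <- intersect(units, donors)
  donor_level_min <- baselines +
    apply(donor_eff[, msc_units, drop = FALSE], 1L, min)
  truth <- list(
    true_detected = cf$sequence_ids[baselines > bg & donor_level_min > bg],
    true_de = true_de,
    array_offsets = array_off,
    donor_effects = donor_eff,
    outlier_arrays = outlier_arrays,
    baselines = baselines
  )
  list(probes = probes, sheet = sheet, truth = truth)
}

#' Configuration for a synthetic RT-qPCR confirmation experiment
#'
#' Defaults emulate the confirmation arm of the MSC study: two MSC sets (6
#' lines at P3/P7 and 7 lines at P4/P8), 4 mesoderm and 4 cancer lines at a
#' single passage, 30 assayed miRNAs plus 5 SNORD reference targets and
#' PPC/miRTC controls, wells in triplicate. Passage shifts are expressed as
#' the change in target Cq at the late passage (negative shift =
#' upregulation); the defaults give miR-572 folds 1.54 (set 1) / 1.59 (set 2)
#' and miR-638 folds 1.71 / 1.35.
#'
#' @param targets Character vector of assayed miRNA names.
#' @param references The 5 reference targets used for normalization.
#' @param set1_lines,set2_lines,mesoderm_lines,cancer_lines Cohort sizes.
#' @param passages_set1,passages_set2 Early/late passage labels per MSC set.
#' @param well_reps Wells per (sample, target).
#' @param sigma_well SD of well-replicate noise (Cq units).
#' @param sigma_sample SD of the per-sample global Cq offset (cancelled by
#'   reference normalization).
#' @param baseline_cq Named numeric: target -> baseline Cq. `NULL` installs
#'   deterministic defaults in 24-31, with a small undetected subset near 36.5.
#' @param reference_cq Baseline Cq of the reference targets.
#' @param passage_shifts Named list: target -> c(set1 = shift, set2 = shift),
#'   Cq change at the late passage.
#' @param cohort_shifts Named list: target -> c(mesoderm = shift, cancer =
#'   shift), Cq change in non-MSC cohorts.
#' @param undetected_as `"sentinel"` emits undetected wells as missing (`NA`),
#'   `"high_cq"` emits them as their (>= 35) simulated value.
#' @param seed Integer seed.
#' @return A list of class `qpcr_sim_config`.
#' @export
qpcr_sim_config <- function(targets = NULL,
                            references = c("SNORD61", "SNORD68", "SNORD72",
                                           "SNORD95", "SNORD96A"),
                            set1_lines = 6L, set2_lines = 7L,
                            mesoderm_lines = 4L, cancer_lines = 4L,
                            passages_set1 = c("P3", "P7"),
                            passages_set2 = c("P4", "P8"),
                            well_reps = 3L,
                            sigma_well = 0.15,
                            sigma_sample = 0.3,
                            baseline_cq = NULL,
                            reference_cq = 20,
                            passage_shifts = NULL,
                            cohort_shifts = NULL,
                            undetected_as = c("sentinel", "high_cq"),
                            seed = 1L) {
  if (is.null(targets))
    targets <- c("miR-196b-5p", "miR-16-5p", "miR-1202", "let-7g-5p",
                 "miR-572", "miR-92a-3p", "miR-638", "miR-1915-3p",
                 "miR-17-5p", "miR-29b-1-5p", "miR-15b-5p",
                 "let-7f", "let-7i", "miR-199a-5p", "miR-25-3p",
                 "miR-106b-5p", "miR-130b-3p", "miR-22-3p", "miR-27a-3p",
                 "miR-34a-5p", "miR-193b-3p", "miR-320b", "miR-320c",
                 "miR-320d", "miR-324-3p", "miR-365a-3p", "miR-365a-5p",
                 "miR-494-3p", "miR-1260a", "miR-1305")
  if (!is.character(references) || length(references) < 1L)
    stop("invalid configuration: 'references' must be a character vector", call. = FALSE)
  if (any(references %in% targets))
    stop("invalid configuration: 'references' must be distinct from 'targets'", call. = FALSE)
  if (is.null(baseline_cq)) {
    baseline_cq <- setNames(24 + (seq_along(targets) - 1L) %% 8, targets)
    off <- intersect(c("miR-106b-5p", "miR-320c", "miR-320d",
                       "miR-365a-3p", "miR-1305"), targets)
    baseline_cq[off] <- 36.5
  }
  missing_t <- setdiff(targets, names(baseline_cq))
  if (length(missing_t))
    stop(sprintf("invalid configuration: 'baseline_cq' missing target '%s'",
                 missing_t[1]), call. = FALSE)
  if (is.null(passage_shifts))
    passage_shifts <- list(
      "miR-572" = c(set1 = -log2(1.54), set2 = -log2(1.59)),
      "miR-638" = c(set1 = -log2(1.71), set2 = -log2(1.35)))
  passage_shifts <- passage_shifts[names(passage_shifts) %in% targets]
  if (length(passage_shifts) && is.null(names(passage_shifts)))
    stop("invalid configuration: 'passage_shifts' must be a named list", call. = FALSE)
  if (is.null(cohort_shifts))
    cohort_shifts <- list()
  structure(list(
    targets = targets, references = references,
    set1_lines = .check_count(set1_lines, "set1_lines", 0L),
    set2_lines = .check_count(set2_lines, "set2_lines", 0L),
    mesoderm_lines = .check_count(mesoderm_lines, "mesoderm_lines", 0L),
    cancer_lines = .check_count(cancer_lines, "cancer_lines", 0L),
    passages_set1 = passages_set1, passages_set2 = passages_set2,
    well_reps = .check_count(well_reps, "well_reps"),
    sigma_well = sigma_well, sigma_sample = sigma_sample,
    baseline_cq = baseline_cq, reference_cq = reference_cq,
    passage_shifts = passage_shifts, cohort_shifts = cohort_shifts,
    undetected_as = match.arg(undetected_as),
    seed = as.integer(seed)
  ), class = "qpcr_sim_config")
}

#' Simulate an RT-qPCR plate
#'
#' @param config A [qpcr_sim_config()] object.
#' @return A list with `plate` (QpcrPlate data.frame: `sample_id`, `cohort`,
#'   `passage`, `target_id`, `is_reference`, `control_role`, `well_rep`,
#'   `cq`; undetected wells per `config$undetected_as`) and `truth`
#'   (configured per-set fold changes and the undetected target set).
#' @export
simulate_qpcr <- function(config) {
  if (!inherits(config, "qpcr_sim_config"))
    stop("'config' must be a qpcr_sim_config object", call. = FALSE)
  cf <- config
  set.seed(cf$seed)

  samp <- list()
  add <- function(prefix, n, cohort, passages) {
    if (n == 0L) return()
    for (p in passages)
      samp[[length(samp) + 1L]] <<- data.frame(
        sample_id = sprintf("%s%02d_%s", prefix, seq_len(n), p),
        line_id = sprintf("%s%02d", prefix, seq_len(n)),
        cohort = cohort, passage = p, stringsAsFactors = FALSE)
  }
  add("L", cf$set1_lines, "MSC_set1", cf$passages_set1)
  add("M", cf$set2_lines, "MSC_set2", cf$passages_set2)
  add("F", cf$mesoderm_lines, "mesoderm", "early")
  add("K", cf$cancer_lines, "cancer", "early")
  samples <- do.call(rbind, samp)

  late1 <- cf$passages_set1[length(cf$passages_set1)]
  late2 <- cf$passages_set2[length(cf$passages_set2)]

  all_targets <- c(cf$targets, cf$references, "PPC", "miRTC")
  base <- c(cf$baseline_cq,
            setNames(rep(cf$reference_cq, length(cf$references)), cf$references),
            PPC = 20, miRTC = 22)
  sample_off <- setNames(rnorm(nrow(samples), 0, cf$sigma_sample),
                         samples$sample_id)

  grid <- expand.grid(well_rep = seq_len(cf$well_reps),
                      target_id = all_targets,
                      row = seq_len(nrow(samples)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- samples[grid$row, ]
  shift <- numeric(nrow(grid))
  for (tg in names(cf$passage_shifts)) {
    sh <- cf$passage_shifts[[tg]]
    shift[grid$target_id == tg & s$passage == late1 & s$cohort == "MSC_set1"] <-
      sh[["set1"]]
    shift[grid$target_id == tg & s$passage == late2 & s$cohort == "MSC_set2"] <-
      sh[["set2"]]
  }
  for (tg in names(cf$cohort_shifts)) {
    sh <- cf$cohort_shifts[[tg]]
    for (co in names(sh))
      shift[grid$target_id == tg & s$cohort == co] <- sh[[co]]
  }
  cq <- base[grid$target_id] + sample_off[s$sample_id] + shift +
    rnorm(nrow(grid), 0, cf$sigma_well)
  if (cf$undetected_as == "sentinel") cq[cq >= 35] <- NA_real_

  plate <- data.frame(
    sample_id = s$sample_id, cohort = s$cohort, passage = s$passage,
    target_id = grid$target_id,
    is_reference = grid$target_id %in% cf$references,
    control_role = ifelse(grid$target_id == "PPC", "PPC",
                          ifelse(grid$target_id == "miRTC", "miRTC", "none")),
    well_rep = grid$well_rep,
    cq = unname(cq),
    stringsAsFactors = FALSE
  )
  plate <- plate[order(plate$sample_id, plate$target_id, plate$well_rep), ]
  rownames(plate) <- NULL
  class(plate) <- c("qpcr_plate", "data.frame")

  truth <- list(
    fold_set1 = vapply(cf$passage_shifts, function(x) 2^(-x[["set1"]]), numeric(1)),
    fold_set2 = vapply(cf$passage_shifts, function(x) 2^(-x[["set2"]]), numeric(1)),
    undetected_targets = names(cf$baseline_cq)[cf$baseline_cq >= 35]
  )
  list(plate = plate, truth = truth)
}
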