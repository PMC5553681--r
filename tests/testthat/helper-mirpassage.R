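## Shared fixture builders for the test suite. All fixtures are generated in
## code; sizes are scaled down from the full study design but keep its
## structure (donors x passages x technical replicates, probe replicates,
## negative controls per array).

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_donors = 6L, passages = c("P3", "P5", "P7"), n_tech_reps = 2L,
    n_sequences = 150L, n_mirnas = 80L, probe_reps_range = c(4L, 4L),
    n_negative_controls = 60L,
    n_duplicate_pairs = 5L, n_expressed_singletons = 8L, n_trna_rrna = 2L,
    dropout_donors = setNames(integer(0), character(0)),
    n_outlier_arrays = 0L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

## noise-free variant: every probe equals its generative mean exactly
quiet_config <- function(seed = 1L, ...) {
  small_config(seed = seed, sigma_probe = 0, sigma_array = 0,
               sigma_donor = 0, negctl_sd = 0, n_variable = 0L, ...)
}

## minimal hand-built probe table (2 arrays is the smallest valid design)
tiny_probe_table <- function() {
  rows <- expand.grid(array_id = c("A1", "A2", "A3"),
                      probe_id = sprintf("s%d_p%d", rep(1:5, each = 2), 1:2),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$sequence_id <- sub("_p[12]$", "", rows$probe_id)
  rows$mirna_name <- paste0("m", rows$sequence_id)
  rows$control_type <- "experimental"
  rows$rna_class <- "miRNA"
  rows$raw_signal <- 2^(5 + seq_len(nrow(rows)) / 10)
  neg <- expand.grid(array_id = c("A1", "A2", "A3"),
                     probe_id = sprintf("NC_%02d", 1:4),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  neg$sequence_id <- neg$probe_id
  neg$mirna_name <- NA_character_
  neg$control_type <- "negative"
  neg$rna_class <- "unknown"
  neg$raw_signal <- 2^(3 + seq_len(nrow(neg)) / 20)
  validate_probe_table(rbind(rows, neg))
}

## hand-built qPCR plate: one sample, 5 references at ref_cq, one target
tiny_plate <- function(target_cq = 18, ref_cq = 20, sample_id = "S1",
                       well_reps = 1L) {
  refs <- c("SNORD61", "SNORD68", "SNORD72", "SNORD95", "SNORD96A")
  df <- expand.grid(target_id = c(refs, "miR-x"), well_rep = seq_len(well_reps),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(sample_id = sample_id, cohort = "MSC_set1", passage = "P3",
             target_id = df$target_id,
             is_reference = df$target_id %in% refs,
             control_role = "none", well_rep = df$well_rep,
             cq = ifelse(df$target_id == "miR-x", target_cq, ref_cq),
             stringsAsFactors = FALSE)
}
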