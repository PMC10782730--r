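# Build a small AbundanceMatrix from a peptide x sample value matrix.
# Columns follow the study_design order: subj1_control, subj1_treated, ...
toy_matrix <- function(values, n_subjects = ncol(values) / 2,
                       sequences = NULL, accessions = NULL,
                       starts = NULL, mods = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  design <- study_design(sprintf("s%02d", seq_len(n_subjects)))
  colnames(values) <- design$sample
  if (is.null(sequences)) sequences <- strrep("A", 7 + (seq_len(n) %% 5))
  if (is.null(starts)) starts <- 10L + seq_len(n)   # keeps identity tuples unique
  records <- data.frame(
    peptide_id = sprintf("p%03d", seq_len(n)),
    sequence = sequences,
    accession = if (is.null(accessions)) rep("ACC1", n) else accessions,
    gene_symbol = NA_character_,
    start = starts,
    end = starts + nchar(sequences) - 1L,
    modifications = if (is.null(mods)) "" else mods,
    stringsAsFactors = FALSE)
  abundance_matrix(records, design, values, length_bounds = NULL)
}

# A paired matrix with per-subject columns laid out phase-by-phase:
# control values in `ctrl`, treated in `trt` (peptides x subjects each).
paired_matrix <- function(ctrl, trt, ...) {
  ctrl <- as.matrix(ctrl); trt <- as.matrix(trt)
  n_subj <- ncol(ctrl)
  vals <- matrix(NA_real_, nrow(ctrl), 2 * n_subj)
  vals[, seq(1, 2 * n_subj, by = 2)] <- ctrl
  vals[, seq(2, 2 * n_subj, by = 2)] <- trt
  toy_matrix(vals, n_subjects = n_subj, ...)
}
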