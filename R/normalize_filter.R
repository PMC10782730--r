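#' Stage-1 normalization: total peak intensity
#'
#' Scales every sample so its total present intensity equals the grand mean of
#' the per-sample totals; this keeps downstream values on the instrument's
#' intensity scale rather than forcing unit totals. Missing cells are
#' untouched and the grand total intensity of the matrix is conserved.
#'
#' @param mat An `AbundanceMatrix`.
#' @return A list with elements `matrix` (normalized `AbundanceMatrix`) and
#'   `model` (per-sample scale factors applied).
#' @export
normalize_total_intensity <- function(mat) {
  totals <- colSums(mat$values, na.rm = TRUE)
  empty <- colSums(!is.na(mat$values)) == 0
  if (any(empty)) stop("sample(s) with no present values: ",
                       paste(names(totals)[empty], collapse = ", "))
  target <- mean(totals)
  factors <- target / totals
  out <- mat
  out$values <- sweep(mat$values, 2L, factors, `*`)
  list(matrix = out,
       model = list(stage1_factors = factors, stage1_target = target))
}

#' Select stable reference peptides
#'
#' Reference peptides are complete-case peptides that are both stably
#' expressed and unchanged by treatment: their coefficient of variation across
#' all samples AND their absolute log2 treated/control mean ratio must each
#' fall at or below the given quantile of the respective distribution over
#' complete-case peptides.
#'
#' @param mat A stage-1-normalized `AbundanceMatrix`.
#' @param quantile Fraction in (0, 1]; default 0.1.
#' @return Character vector of reference peptide ids.
#' @export
select_reference_peptides <- function(mat, quantile = 0.1) {
  if (!(quantile > 0 && quantile <= 1)) stop("quantile must be in (0, 1]")
  v <- mat$values
  complete <- rowSums(is.na(v)) == 0
  if (!any(complete)) stop("no complete-case peptides available")
  v <- v[complete, , drop = FALSE]
  cv <- apply(v, 1L, stats::sd) / rowMeans(v)
  ctrl <- design_samples(mat$design, "control")
  trt <- design_samples(mat$design, "treated")
  ratio <- abs(log2(rowMeans(v[, trt, drop = FALSE]) /
                    rowMeans(v[, ctrl, drop = FALSE])))
  keep <- cv <= stats::quantile(cv, quantile) &
    ratio <= stats::quantile(ratio, quantile)
  ids <- rownames(v)[keep]
  if (!length(ids))
    stop("no peptide satisfies both criteria at quantile ", quantile,
         "; retry with a larger quantile")
  ids
}

#' Stage-2 normalization: stable-reference peptides
#'
#' Divides every sample by the mean of its reference-peptide values, then
#' rescales by the grand mean of those reference means so the matrix keeps its
#' original magnitude. Afterwards the per-sample reference means are equal.
#' The operation is idempotent.
#'
#' @param mat An `AbundanceMatrix`.
#' @param reference Character vector of reference peptide ids.
#' @return Normalized `AbundanceMatrix`; the factors applied are attached as
#'   attribute `"stage2_factors"`.
#' @export
normalize_to_reference <- function(mat, reference) {
  if (!length(reference)) stop("reference peptide set is empty")
  missing_ref <- setdiff(reference, mat$records$peptide_id)
  if (length(missing_ref)) stop("reference peptide(s) absent from matrix: ",
                                paste(utils::head(missing_ref), collapse = ", "))
  ref_vals <- mat$values[reference, , drop = FALSE]
  ref_means <- colMeans(ref_vals, na.rm = TRUE)
  if (anyNA(ref_means)) stop("sample(s) with no present reference value: ",
                             paste(names(ref_means)[is.na(ref_means)],
                                   collapse = ", "))
  factors <- mean(ref_means) / ref_means
  out <- mat
  out$values <- sweep(mat$values, 2L, factors, `*`)
  attr(out, "stage2_factors") <- factors
  out
}

#' Filter peptides by per-group missingness
#'
#' Retains peptides with at most `max_missing_per_group` missing values in
#' EACH phase; with 11 subjects and the default of 4 this keeps peptides
#' present in more than 6 control and more than 6 treated samples.
#'
#' @param mat An `AbundanceMatrix`.
#' @param max_missing_per_group Maximum missing values tolerated per phase.
#' @return Filtered `AbundanceMatrix`.
#' @export
filter_by_missingness <- function(mat, max_missing_per_group = 4L) {
  ctrl <- design_samples(mat$design, "control")
  trt <- design_samples(mat$design, "treated")
  n_miss_c <- rowSums(is.na(mat$values[, ctrl, drop = FALSE]))
  n_miss_t <- rowSums(is.na(mat$values[, trt, drop = FALSE]))
  keep <- n_miss_c <= max_missing_per_group & n_miss_t <= max_missing_per_group
  subset_peptides(mat, mat$records$peptide_id[keep])
}

#' Detect treatment-specific presence/absence markers
#'
#' A peptide is a marker of the treated state when it is detected (any present
#' value) in at least `min_treated` treated samples and at most `max_control`
#' control samples. Depends only on the presence pattern, never on magnitudes.
#'
#' @param mat An `AbundanceMatrix`.
#' @param min_treated Minimum treated samples with a detection (default 9).
#' @param max_control Maximum control samples with a detection (default 2).
#' @return data.frame `peptide_id`, `n_detected_treated`, `n_detected_control`,
#'   `marker`.
#' @export
detect_treatment_specific <- function(mat, min_treated = 9L, max_control = 2L) {
  n_subj <- length(unique(mat$design$subject))
  if (min_treated < 0 || min_treated > n_subj ||
      max_control < 0 || max_control > n_subj)
    stop("marker thresholds must lie in [0, ", n_subj, "]")
  ctrl <- design_samples(mat$design, "control")
  trt <- design_samples(mat$design, "treated")
  n_t <- rowSums(!is.na(mat$values[, trt, drop = FALSE]))
  n_c <- rowSums(!is.na(mat$values[, ctrl, drop = FALSE]))
  data.frame(peptide_id = mat$records$peptide_id,
             n_detected_treated = n_t, n_detected_control = n_c,
             marker = n_t >= min_treated & n_c <= max_control,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize per-probe peptide yield
#'
#' One probe monitors one subject's control and treated phases, so per peptide
#' and probe the larger of the two phase abundances represents what the probe
#' recovered. Reports per-subject detection counts and max-abundance
#' summaries, per-phase detection counts and mean present abundances, and
#' paired two-tailed t-tests comparing phases on counts and on means.
#'
#' @param mat An `AbundanceMatrix`.
#' @return A list: `per_subject` (subject, n_detected, mean/median of the
#'   max-of-phases abundances), `yield_mean`, `yield_sd`, `per_phase`
#'   (phase, n_detected, mean_abundance), `count_test` and `abundance_test`
#'   (paired t-test results).
#' @export
summarize_probe_yield <- function(mat) {
  subjects <- unique(mat$design$subject)
  ctrl <- design_samples(mat$design, "control")
  trt <- design_samples(mat$design, "treated")
  vc <- mat$values[, ctrl, drop = FALSE]
  vt <- mat$values[, trt, drop = FALSE]
  # pmax with NA as "absent": max of (x, NA) is x; both NA stays NA
  vmax <- pmax(ifelse(is.na(vc), -Inf, vc), ifelse(is.na(vt), -Inf, vt))
  vmax[!is.finite(vmax)] <- NA_real_
  per_subject <- data.frame(
    subject = subjects,
    n_detected = colSums(!is.na(vmax)),
    mean_abundance = colMeans(vmax, na.rm = TRUE),
    median_abundance = apply(vmax, 2L, stats::median, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  counts_c <- colSums(!is.na(vc))
  counts_t <- colSums(!is.na(vt))
  means_c <- colMeans(vc, na.rm = TRUE)
  means_t <- colMeans(vt, na.rm = TRUE)
  per_phase <- data.frame(
    phase = design_phases(mat$design),
    n_detected_mean = c(mean(counts_c), mean(counts_t)),
    mean_abundance = c(mean(means_c), mean(means_t)),
    stringsAsFactors = FALSE)
  list(per_subject = per_subject,
       yield_mean = mean(per_subject$n_detected),
       yield_sd = stats::sd(per_subject$n_detected),
       per_phase = per_phase,
       count_test = tryCatch(paired_t_test(counts_c, counts_t),
                             error = function(e) NULL),
       abundance_test = tryCatch(paired_t_test(means_c, means_t),
                                 error = function(e) NULL))
}

#' Run the two-stage normalization
#'
#' Convenience wrapper: total-intensity normalization, reference-peptide
#' selection at `ref_quantile`, then reference normalization. A reference
#' mean over very few peptides is itself noisy, so when fewer than
#' `min_reference` peptides qualify the quantile is doubled (with a warning)
#' until enough do or the quantile reaches 1.
#'
#' @param mat An `AbundanceMatrix`.
#' @param ref_quantile Starting quantile for [select_reference_peptides()].
#' @param min_reference Minimum acceptable reference-set size (default 5).
#' @return list `matrix`, `model` (stage-1 factors, reference ids, the
#'   quantile actually used, stage-2 factors).
#' @export
normalize_two_stage <- function(mat, ref_quantile = 0.1, min_reference = 5L) {
  s1 <- normalize_total_intensity(mat)
  q <- ref_quantile
  repeat {
    ref <- tryCatch(select_reference_peptides(s1$matrix, quantile = q),
                    error = function(e) character(0))
    if (length(ref) >= min_reference || q >= 1) break
    q <- min(1, 2 * q)
  }
  if (!length(ref))
    stop("no reference peptides even at quantile 1; ",
         "matrix has no complete-case peptides")
  if (q > ref_quantile)
    warning("reference quantile escalated from ", ref_quantile, " to ", q,
            " to reach ", length(ref), " reference peptide(s)")
  s2 <- normalize_to_reference(s1$matrix, ref)
  list(matrix = s2,
       model = c(s1$model,
                 list(reference_peptides = ref, reference_quantile = q,
                      stage2_factors = attr(s2, "stage2_factors"))))
}
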