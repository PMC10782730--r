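# Approximate natural amino-acid frequencies (vertebrate proteome averages);
# used for random precursor sequences so K/R occur at realistic rates.
AA_FREQ <- c(A = 0.074, C = 0.025, D = 0.054, E = 0.068, F = 0.047,
             G = 0.074, H = 0.026, I = 0.068, K = 0.058, L = 0.099,
             M = 0.025, N = 0.045, P = 0.039, Q = 0.034, R = 0.052,
             S = 0.057, T = 0.051, V = 0.073, W = 0.013, Y = 0.032)

# Deterministic sub-seed: mixes the master seed with a string key; result is
# a valid 32-bit seed so independent module substreams never collide.
mix_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(seed) * 1009 + h) %% 2147483647)
}

#' Synthetic-study configuration
#'
#' Default parameters emulate the study conditions of a paired 4-AP
#' microdialysate peptidome: 11 subjects sampled in control and treated
#' phases, ~2,500 peptides of length 7-50 (right-skewed, mean ~16.8 residues)
#' from a few hundred precursors, trypsin-like K/R bias at P1 (70%), ~16.6%
#' N-terminal fragments of which 93% are N-terminally acetylated, log-normal
#' abundances spanning the instrument's intensity range, paired treatment
#' effects in both directions with fold >= 2 (upregulated effects drawn
#' shorter), abundance-dependent (left-censoring-like) missingness, and EEG
#' traces with urethane slow waves plus a 60 Hz gamma component whose
#' amplitude doubles under treatment.
#'
#' @param seed Master seed; all module substreams derive from it.
#' @param n_subjects Paired subjects (default 11).
#' @param n_precursors Random precursor proteins (default 300).
#' @param n_peptides Peptides to draw (default 2500).
#' @param length_range Permitted peptide lengths (default 7-50).
#' @param length_mean,length_sd Mean/sd of the clipped-gamma length draw.
#' @param p1_basic_prob Probability that an internal peptide's P1 residue is
#'   K or R (default 0.7).
#' @param nterm_fraction Fraction of peptides starting at precursor position
#'   <= 2 (default 0.166).
#' @param acetyl_given_nterm Acetylation probability for N-terminal fragments
#'   (default 0.93).
#' @param abundance_mu,abundance_sigma Log-normal baseline abundance
#'   parameters (log scale).
#' @param subject_cv Biological coefficient of variation per sample
#'   (default 0.3).
#' @param scale_sigma Log-sd of per-sample multiplicative scale corruption,
#'   undone by normalization (default 0.25).
#' @param effect_fraction Fraction of peptides with a planted treatment
#'   effect (default 0.45: among consistently detected peptides the study saw
#'   widespread change).
#' @param fold_range True fold-change range for effects (default 2-6).
#' @param frac_up Probability an effect is upregulated (default 0.30;
#'   downregulated effects are additionally lost to left-censoring, so the
#'   realized significant sets come out near balance).
#' @param up_length_shift Mean-length offset (residues) of upregulated effect
#'   peptides relative to the population (default -1.7).
#' @param missing_rate Expected overall fraction of missing cells
#'   (default 0.5).
#' @param missing_slope Logistic slope on standardized -log(abundance);
#'   positive makes low-abundance cells more likely missing (default 2,
#'   strongly left-censored: abundant peptides are almost always detected).
#' @param eeg List of EEG parameters: `fs`, `duration` (s), `slow_freq`,
#'   `slow_amp`, `gamma_freq`, `gamma_amp`, `gamma_treated_ratio`, `bg_amp`
#'   (1/f background), `noise_amp` (phase-level sensor noise), `amp_cv`
#'   (subject-level amplitude jitter).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_subjects = 11L, n_precursors = 300L,
                         n_peptides = 2500L, length_range = c(7L, 50L),
                         length_mean = 16.8, length_sd = 7,
                         p1_basic_prob = 0.7, nterm_fraction = 0.166,
                         acetyl_given_nterm = 0.93,
                         abundance_mu = 1.0, abundance_sigma = 1.5,
                         subject_cv = 0.3, scale_sigma = 0.25,
                         effect_fraction = 0.45, fold_range = c(2, 6),
                         frac_up = 0.30, up_length_shift = -1.7,
                         missing_rate = 0.5, missing_slope = 2,
                         eeg = list()) {
  stopifnot(n_peptides > 0, fold_range[1] >= 1,
            all(c(p1_basic_prob, nterm_fraction, acetyl_given_nterm, frac_up,
                  missing_rate, effect_fraction) >= 0),
            all(c(p1_basic_prob, nterm_fraction, acetyl_given_nterm, frac_up,
                  missing_rate, effect_fraction) <= 1))
  eeg_defaults <- list(fs = 2000, duration = 120, slow_freq = 1,
                       slow_amp = 1, gamma_freq = 60, gamma_amp = 0.25,
                       gamma_treated_ratio = 2, bg_amp = 0.3,
                       noise_amp = 0.05, amp_cv = 0.2)
  eeg <- utils::modifyList(eeg_defaults, eeg)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate random precursor proteins
#'
#' Random sequences over the 20-letter alphabet at natural residue
#' frequencies, lengths uniform in 80-800, always starting with the initiator
#' methionine. Deterministic per seed.
#'
#' @param config A `synth_config`.
#' @return Named character vector (accessions `SYNP0001`, ...).
#' @export
generate_precursors <- function(config) {
  set.seed(mix_seed(config$seed, "precursors"))
  n <- config$n_precursors
  if (n == 0) return(stats::setNames(character(0), character(0)))
  lens <- sample(80:800, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste0("M", paste(sample(names(AA_FREQ), L - 1L, replace = TRUE,
                             prob = AA_FREQ), collapse = ""))
  }, character(1))
  stats::setNames(seqs, sprintf("SYNP%04d", seq_len(n)))
}

# draw one peptide length from the clipped-gamma model
draw_lengths <- function(n, config) {
  lo <- config$length_range[1]; hi <- config$length_range[2]
  m <- config$length_mean - lo; s <- config$length_sd
  shape <- (m / s)^2; rate <- m / s^2
  pmin(hi, lo + round(stats::rgamma(n, shape = shape, rate = rate)))
}

#' Simulate a peptidome from precursor proteins
#'
#' Cuts peptides out of the precursors: a configured fraction are N-terminal
#' fragments (start <= 2, mostly acetylated); the rest are internal cuts
#' whose upstream P1 residue is K or R with probability `p1_basic_prob`
#' (cut points preferentially placed after K/R). Lengths follow the clipped
#' right-skewed model within the configured range. Identity tuples
#' (sequence, modifications, accession, start) are unique.
#'
#' @param config A `synth_config`.
#' @param precursors Named precursor sequences from [generate_precursors()].
#' @return Peptide records data.frame.
#' @export
simulate_peptidome <- function(config, precursors) {
  if (!length(precursors)) stop("precursors must be non-empty")
  min_len <- config$length_range[1]
  usable <- precursors[nchar(precursors) >= min_len + 2L]
  if (length(usable) < length(precursors))
    warning(length(precursors) - length(usable),
            " precursor(s) shorter than the minimum peptide length skipped")
  set.seed(mix_seed(config$seed, "peptidome"))
  plens <- nchar(usable)
  # precompute K/R positions per precursor (position of the residue itself)
  kr_pos <- lapply(usable, function(s)
    which(strsplit(s, "")[[1]] %in% c("K", "R")))
  n <- config$n_peptides
  acc <- character(n); start <- integer(n); len <- integer(n)
  is_nterm <- stats::runif(n) < config$nterm_fraction
  lens_draw <- draw_lengths(n, config)
  for (i in seq_len(n)) {
    for (attempt in 1:20) {
      j <- sample.int(length(usable), 1L)
      L <- plens[j]
      if (is_nterm[i]) {
        s0 <- sample(1:2, 1L)
      } else {
        basic <- stats::runif(1) < config$p1_basic_prob
        # eligible starts leave room for a minimum-length peptide and are
        # internal (start >= 3 so the peptide is not N-terminal)
        cand_kr <- kr_pos[[j]][kr_pos[[j]] >= 2L] + 1L
        cand_kr <- cand_kr[cand_kr >= 3L & cand_kr <= L - min_len + 1L]
        if (basic && length(cand_kr)) {
          s0 <- cand_kr[sample.int(length(cand_kr), 1L)]
        } else {
          all_cand <- 3:(L - min_len + 1L)
          pool <- if (basic) cand_kr else setdiff(all_cand, cand_kr)
          if (!length(pool)) pool <- all_cand
          s0 <- pool[sample.int(length(pool), 1L)]
        }
      }
      li <- min(lens_draw[i], L - s0 + 1L)
      if (li >= min_len) { acc[i] <- names(usable)[j]; start[i] <- s0
                           len[i] <- li; break }
    }
    if (start[i] == 0L) stop("could not place peptide ", i,
                             "; precursors too short")
  }
  end <- start + len - 1L
  mods <- ifelse(is_nterm & stats::runif(n) < config$acetyl_given_nterm,
                 "1:acetyl", "")
  rec <- data.frame(peptide_id = sprintf("pep%05d", seq_len(n)),
                    sequence = substr(usable[acc], start, end),
                    accession = acc,
                    gene_symbol = sub("SYNP", "Gene", acc),
                    start = start, end = end, modifications = mods,
                    stringsAsFactors = FALSE, row.names = NULL)
  # enforce unique identity tuples by dropping duplicates
  key <- paste(rec$sequence, rec$modifications, rec$accession, rec$start,
               sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  rec$peptide_id <- sprintf("pep%05d", seq_len(nrow(rec)))
  rownames(rec) <- NULL
  rec
}

# exponential tilting weight solver: lambda such that the weighted mean
# length hits target
tilt_lambda <- function(lengths, target) {
  f <- function(l) sum(lengths * exp(l * lengths)) /
    sum(exp(l * lengths)) - target
  if (abs(f(0)) < 1e-9) return(0)
  stats::uniroot(f, c(-1, 1), tol = 1e-9)$root
}

#' Simulate paired abundances with planted effects
#'
#' Per-peptide log-normal baselines, per-cell biological noise at the
#' configured CV, per-sample multiplicative scale corruption (for the
#' normalization stage to undo), and planted treatment effects: a configured
#' fraction of peptides is multiplied by its true fold in the treated phase
#' only, upward with probability `frac_up`. Upregulated effects are drawn
#' preferentially from shorter peptides (exponential tilting) so their mean
#' length sits `up_length_shift` residues below the population mean.
#'
#' @param config A `synth_config`.
#' @param records Peptide records from [simulate_peptidome()].
#' @return list `matrix` (complete `AbundanceMatrix`), `truth` (per-peptide
#'   effect flags/folds/directions, per-sample true scale factors, stable
#'   reference ids).
#' @export
simulate_paired_abundances <- function(config, records) {
  set.seed(mix_seed(config$seed, "abundances"))
  n <- nrow(records)
  subjects <- sprintf("rat%02d", seq_len(config$n_subjects))
  design <- study_design(subjects)
  n_samp <- nrow(design)
  baseline <- stats::rlnorm(n, config$abundance_mu, config$abundance_sigma)
  n_eff <- round(config$effect_fraction * n)
  n_up <- round(n_eff * config$frac_up)
  lengths <- nchar(records$sequence)
  up_idx <- integer(0)
  if (n_up > 0) {
    lam <- tilt_lambda(lengths, mean(lengths) + config$up_length_shift)
    w <- exp(lam * (lengths - mean(lengths)))
    up_idx <- sample.int(n, n_up, prob = w)
  }
  down_idx <- if (n_eff - n_up > 0)
    sample(setdiff(seq_len(n), up_idx), n_eff - n_up) else integer(0)
  fold <- rep(1, n)
  eff_idx <- c(up_idx, down_idx)
  fold[eff_idx] <- stats::runif(length(eff_idx), config$fold_range[1],
                                config$fold_range[2])
  direction <- rep(NA_character_, n)
  direction[up_idx] <- "up"; direction[down_idx] <- "down"
  sigma_bio <- sqrt(log(1 + config$subject_cv^2))
  noise <- matrix(stats::rlnorm(n * n_samp, -sigma_bio^2 / 2, sigma_bio),
                  n, n_samp)
  scale_factors <- stats::setNames(
    stats::rlnorm(n_samp, 0, config$scale_sigma), design$sample)
  vals <- baseline * noise
  colnames(vals) <- design$sample
  treated_cols <- design_samples(design, "treated")
  mult <- rep(1, n)
  mult[up_idx] <- fold[up_idx]
  mult[down_idx] <- 1 / fold[down_idx]
  vals[, treated_cols] <- vals[, treated_cols] * mult
  vals <- sweep(vals, 2L, scale_factors, `*`)
  truth <- list(
    effects = data.frame(peptide_id = records$peptide_id,
                         effect = seq_len(n) %in% eff_idx,
                         fold = fold, direction = direction,
                         stringsAsFactors = FALSE),
    scale_factors = scale_factors,
    stable_peptides = records$peptide_id[setdiff(seq_len(n), eff_idx)])
  list(matrix = abundance_matrix(records, design, vals, length_bounds = NULL),
       truth = truth)
}

#' Apply abundance-dependent missingness
#'
#' Each cell is dropped independently with a probability that is logistic in
#' standardized -log(abundance): low-abundance cells are more likely missing
#' (left-censoring-like). The intercept is solved so the expected overall
#' missing rate equals `missing_rate` exactly.
#'
#' @param mat A complete `AbundanceMatrix`.
#' @param config A `synth_config`.
#' @return `AbundanceMatrix` with `NA` cells.
#' @export
apply_missingness <- function(mat, config) {
  if (config$missing_rate == 0) return(mat)
  set.seed(mix_seed(config$seed, "missingness"))
  v <- mat$values
  z <- -log(v)
  z <- (z - mean(z)) / stats::sd(z)
  slope <- config$missing_slope
  a0 <- stats::uniroot(function(a) mean(stats::plogis(a + slope * z)) -
                         config$missing_rate, c(-30, 30), tol = 1e-10)$root
  p <- stats::plogis(a0 + slope * z)
  drop <- matrix(stats::runif(length(v)) < p, nrow(v), ncol(v))
  # never empty out a whole sample
  for (j in seq_len(ncol(v))) if (all(drop[, j])) drop[which.max(v[, j]), j] <- FALSE
  out <- mat
  out$values[drop] <- NA_real_
  out
}

#' Simulate a synthetic EEG trace
#'
#' One subject-phase trace: a 1/f background and a ~1 Hz high-amplitude slow
#' wave shared by both phases of a subject (same animal, same anaesthesia and
#' electrodes), plus a gamma-band (default 60 Hz) oscillation whose amplitude
#' in the treated phase is `gamma_treated_ratio` times the control amplitude,
#' plus phase-level sensor noise. Deterministic per (seed, subject, phase).
#'
#' @param config A `synth_config`.
#' @param subject Subject identifier (any string).
#' @param phase `"control"` or `"treated"`.
#' @return An `eeg_trace`.
#' @export
simulate_eeg <- function(config, subject, phase = c("control", "treated")) {
  phase <- match.arg(phase)
  e <- config$eeg
  n <- round(e$fs * e$duration)
  t <- (seq_len(n) - 1L) / e$fs
  # subject-level components (identical across the two phases)
  set.seed(mix_seed(config$seed, "eeg", subject))
  slow_amp <- e$slow_amp * exp(stats::rnorm(1, 0, e$amp_cv))
  gamma_base <- e$gamma_amp * exp(stats::rnorm(1, 0, e$amp_cv))
  slow_phi <- stats::runif(1, 0, 2 * pi)
  bg <- if (e$bg_amp > 0) {
    w <- stats::fft(stats::rnorm(n))
    f <- (seq_len(n) - 1L) / n * e$fs
    f <- pmin(f, e$fs - f)
    w <- w / sqrt(pmax(f, f[2]))          # 1/f power shaping
    w[1] <- 0
    x <- Re(stats::fft(w, inverse = TRUE)) / n
    e$bg_amp * x / stats::sd(x)
  } else 0
  # phase-level components
  set.seed(mix_seed(config$seed, "eeg", subject, phase))
  gamma_phi <- stats::runif(1, 0, 2 * pi)
  gamma_amp <- gamma_base *
    if (phase == "treated") e$gamma_treated_ratio else 1
  noise <- if (e$noise_amp > 0) stats::rnorm(n, 0, e$noise_amp) else 0
  x <- bg + slow_amp * sin(2 * pi * e$slow_freq * t + slow_phi) +
    gamma_amp * sin(2 * pi * e$gamma_freq * t + gamma_phi) + noise
  eeg_trace(x, e$fs, subject = subject, phase = phase)
}

#' Generate the complete synthetic study
#'
#' Precursors, peptidome, paired abundances with planted effects, missingness,
#' and a ground-truth ledger, all from one seed.
#'
#' @param config A `synth_config`.
#' @return list `matrix` (with missingness), `complete_matrix`, `precursors`,
#'   `records`, `design`, `truth`, `config`.
#' @export
generate_synthetic_study <- function(config = synth_config()) {
  precursors <- generate_precursors(config)
  records <- simulate_peptidome(config, precursors)
  ab <- simulate_paired_abundances(config, records)
  mat <- apply_missingness(ab$matrix, config)
  list(matrix = mat, complete_matrix = ab$matrix, precursors = precursors,
       records = records, design = mat$design, truth = ab$truth,
       config = config)
}

#' Write a synthetic study to disk
#'
#' Emits the peptide table, design table, precursor FASTA and truth ledger in
#' the same plain-text dialects the readers accept.
#'
#' @param study Result of [generate_synthetic_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peptides = file.path(dir, "peptides.tsv"),
    design = file.path(dir, "design.tsv"),
    fasta = file.path(dir, "precursors.fasta"),
    truth = file.path(dir, "truth.tsv"))
  write_peptide_table(study$matrix, paths["peptides"])
  write_design(study$design, paths["design"])
  write_precursor_fasta(study$precursors, paths["fasta"])
  utils::write.table(study$truth$effects, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
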