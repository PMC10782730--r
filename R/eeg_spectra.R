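#' Construct an EEG trace
#'
#' @param samples Numeric voltage sequence.
#' @param fs Sampling rate in Hz (the study digitized at 2000 Hz).
#' @param subject,phase Optional labels.
#' @return list of class `eeg_trace`.
#' @export
eeg_trace <- function(samples, fs, subject = NA_character_,
                      phase = NA_character_) {
  if (fs <= 0) stop("sampling rate must be positive")
  structure(list(samples = as.numeric(samples), fs = fs,
                 subject = subject, phase = phase),
            class = "eeg_trace")
}

#' @export
print.eeg_trace <- function(x, ...) {
  cat(sprintf("eeg_trace: %.1f s at %g Hz (subject %s, phase %s)\n",
              length(x$samples) / x$fs, x$fs, x$subject, x$phase))
  invisible(x)
}

#' FFT low-pass filter
#'
#' Zeroes all frequency components above the cutoff in the discrete Fourier
#' domain and transforms back; length is preserved and the operation is
#' idempotent.
#'
#' @param trace An `eeg_trace` (or numeric vector with `fs` given).
#' @param cutoff Cutoff frequency in Hz (default 200); must be below Nyquist.
#' @param fs Sampling rate when `trace` is a bare vector.
#' @return Filtered `eeg_trace`.
#' @export
lowpass_filter <- function(trace, cutoff = 200, fs = NULL) {
  if (!inherits(trace, "eeg_trace")) trace <- eeg_trace(trace, fs)
  if (cutoff >= trace$fs / 2) stop("cutoff must be below the Nyquist frequency")
  x <- trace$samples
  n <- length(x)
  freqs <- (seq_len(n) - 1L) / n * trace$fs
  freqs <- pmin(freqs, trace$fs - freqs)   # two-sided spectrum
  X <- stats::fft(x)
  X[freqs > cutoff] <- 0
  out <- trace
  out$samples <- Re(stats::fft(X, inverse = TRUE)) / n
  out
}

#' Welch power spectral density (Hanning window)
#'
#' Averaged modified periodogram over Hanning-windowed segments of `n_points`
#' samples with 50% overlap - the stable estimator for multi-minute epochs at
#' this window length. One-sided density, scaled so that the integral of the
#' PSD over frequency approximates the signal variance (Parseval); frequency
#' resolution fs/n_points.
#'
#' @param trace An `eeg_trace`.
#' @param n_points Window length (default 1024).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return list of class `power_spectrum`: `freq` (Hz), `psd` (power/Hz),
#'   `fs`, `n_points`, `n_segments`.
#' @export
power_spectrum <- function(trace, n_points = 1024L, overlap = 0.5) {
  x <- trace$samples
  n <- length(x)
  if (n < n_points) stop("trace shorter than the analysis window")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n_points) / (n_points + 1)))  # Hann
  step <- max(1L, floor(n_points * (1 - overlap)))
  starts <- seq(1L, n - n_points + 1L, by = step)
  scale <- trace$fs * sum(w^2)
  acc <- numeric(n_points %/% 2L + 1L)
  for (s0 in starts) {
    seg <- x[s0:(s0 + n_points - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / scale
    half <- P[seq_len(n_points %/% 2L + 1L)]
    # one-sided: double everything except DC and Nyquist
    half[2:(n_points %/% 2L)] <- 2 * half[2:(n_points %/% 2L)]
    acc <- acc + half
  }
  structure(list(freq = (seq_len(n_points %/% 2L + 1L) - 1L) *
                   trace$fs / n_points,
                 psd = acc / length(starts),
                 fs = trace$fs, n_points = n_points,
                 n_segments = length(starts)),
            class = "power_spectrum")
}

#' Integrated spectral power over a frequency band
#'
#' Trapezoidal integral of the PSD between the band edges; exact edges are
#' obtained by linear interpolation on the discrete frequency grid, so areas
#' are additive over adjacent bands.
#'
#' @param spectrum A `power_spectrum`.
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi`, within the spectrum
#'   range.
#' @return Band area (power units).
#' @export
band_area <- function(spectrum, f_lo, f_hi) {
  if (f_lo >= f_hi) stop("band edges inverted: need f_lo < f_hi")
  if (f_lo < min(spectrum$freq) || f_hi > max(spectrum$freq))
    stop("band outside the spectrum's frequency range")
  inside <- spectrum$freq > f_lo & spectrum$freq < f_hi
  grid <- c(f_lo, spectrum$freq[inside], f_hi)
  vals <- stats::approx(spectrum$freq, spectrum$psd, xout = grid)$y
  pracma::trapz(grid, vals)
}

#' Paired comparison of band power between phases
#'
#' Per-subject band areas of the two phases are compared by a two-tailed
#' paired t-test; a Shapiro-Wilk normality p-value on the paired differences
#' is reported as an advisory, never as an exclusion rule.
#'
#' @param control,treated Numeric vectors of band areas paired by subject
#'   (same order); n >= 3.
#' @return list: `mean_control`, `sd_control`, `mean_treated`, `sd_treated`,
#'   `t_stat`, `df`, `p`, `n`, `shapiro_p`, `degenerate`.
#' @export
compare_band_power <- function(control, treated) {
  if (length(control) != length(treated))
    stop("band areas must be paired by subject (equal length)")
  tt <- paired_t_test(control, treated)
  d <- treated - control
  shapiro_p <- if (tt$degenerate || length(unique(d)) < 3) NA_real_ else
    stats::shapiro.test(d)$p.value
  list(mean_control = mean(control), sd_control = stats::sd(control),
       mean_treated = mean(treated), sd_treated = stats::sd(treated),
       t_stat = tt$t_stat, df = tt$df, p = tt$p_raw, n = tt$n_pairs,
       shapiro_p = shapiro_p, degenerate = tt$degenerate)
}

#' Read / write EEG traces as delimited text
#'
#' Single-column text with a header line `fs=<Hz>`, one sample per line.
#'
#' @param path File path.
#' @return An `eeg_trace`.
#' @export
read_eeg_trace <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^fs=", header)) stop("EEG text trace must start with 'fs=<Hz>'")
  fs <- as.numeric(sub("^fs=", "", header))
  x <- utils::read.table(path, skip = 1L)[[1]]
  eeg_trace(x, fs)
}

#' @rdname read_eeg_trace
#' @param trace An `eeg_trace` to write.
#' @export
write_eeg_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("fs=", trace$fs), con)
  writeLines(format(trace$samples, trim = TRUE, scientific = FALSE,
                    digits = 10), con)
  invisible(path)
}
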