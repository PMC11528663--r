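#' Spectral noise gate via the 1.5 x IQR rule
#'
#' Denoises a uniformly sampled width trace in the frequency domain: forward
#' FFT, power spectral density, zeroing of every non-DC bin whose power does
#' not exceed the Q3 + 1.5 IQR noise border of the PSD (applied symmetrically
#' to conjugate bins so the inverse transform stays real), inverse FFT.
#'
#' @param trace numeric vector, >= 16 uniformly sampled values.
#' @param times_s optional timestamps used to verify uniform sampling.
#' @return real-valued denoised trace of the same length.
#' @export
iqrNoiseFilter <- function(trace, times_s = NULL) {
  n <- length(trace)
  if (n < 16L) stop("at least 16 samples are required")
  if (!is.null(times_s)) {
    dt <- diff(times_s)
    if (any(abs(dt - dt[1]) > 1e-6 * abs(dt[1])))
      stop("trace is not uniformly sampled")
  }
  X <- stats::fft(trace)
  half <- seq(2L, floor(n / 2) + 1L)           # positive-frequency bins
  psd <- Mod(X[half])^2 / n
  q <- stats::quantile(psd, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  kill <- half[psd <= thr]
  X[kill] <- 0
  conj_idx <- n + 2L - kill                    # mirror bins
  conj_idx <- conj_idx[conj_idx <= n & conj_idx >= 2L]
  X[conj_idx] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

hanningWindow <- function(n) 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))

#' Welch power spectral density over overlapping slices
#'
#' Segments the trace into overlapping slices (stride
#' `floor(segment_length * (1 - overlap))`, at least 1 sample), removes each
#' slice's mean, applies a Hanning window, and returns the per-slice
#' periodograms. Heavy overlap (90% by default) keeps the frequency content
#' within each slice near-stationary, which a single full-length FFT cannot
#' offer when the contraction frequency drifts.
#'
#' @param trace numeric vector.
#' @param segment_length points per slice (default 256).
#' @param overlap fractional overlap between consecutive slices (default
#'   0.9).
#' @return list with `power` (matrix, one column per slice, bins
#'   `0..segment_length-1`), `stride`, `n_slices`, `starts`.
#' @export
welchPsd <- function(trace, segment_length = 256, overlap = 0.9) {
  L <- length(trace)
  if (segment_length > L)
    stop("segment_length exceeds trace length")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  stride <- max(1L, floor(segment_length * (1 - overlap)))
  starts <- seq.int(1L, L - segment_length + 1L, by = stride)
  win <- hanningWindow(segment_length)
  wnorm <- sum(win^2)
  power <- vapply(starts, function(s) {
    x <- trace[s:(s + segment_length - 1L)]
    x <- (x - mean(x)) * win
    Mod(stats::fft(x))^2 / wnorm
  }, numeric(segment_length))
  list(power = matrix(power, nrow = segment_length), stride = stride,
       n_slices = length(starts), starts = starts)
}

#' Power-weighted frequency estimate for one PSD slice
#'
#' Locates the spectral peak j (maximum power, DC excluded) and returns the
#' power-weighted mean frequency over the seven-bin neighbourhood j-3..j+3
#' (clipped to the one-sided band): `sum(power_i * i * Fs/N) / sum(power_i)`.
#' The weighting interpolates between bins, resolving frequencies finer than
#' the Fs/N bin width.
#'
#' @param power numeric vector, PSD of one slice over bins `0..N-1` (or the
#'   one-sided half; indexing is handled).
#' @param fs sampling frequency (Hz).
#' @param n points per transform.
#' @return estimated frequency in Hz.
#' @examples
#' p <- numeric(256); p[11] <- 1  # all power in bin i = 10
#' estimateSliceFrequency(p, fs = 0.25, n = 256)  # 10 * 0.25/256
#' @export
estimateSliceFrequency <- function(power, fs, n) {
  half <- floor(n / 2)
  p <- power[seq_len(half + 1L)]            # bins 0..n/2
  if (all(p[-1L] <= 0)) stop("all-zero power: frequency undefined")
  j <- which.max(p[-1L])                    # bin index, DC excluded
  idx <- max(1L, j - 3L):min(half, j + 3L)
  pw <- p[idx + 1L]
  sum(pw * idx * fs / n) / sum(pw)
}

#' Contraction frequency of one width trace
#'
#' Full spectral pipeline for one vein section: IQR noise gate (optional),
#' Welch segmentation with Hanning windows, per-slice power-weighted
#' frequency estimates, and their mean as the section's contraction
#' frequency. The estimate is flagged low-confidence when the full-trace
#' spectral peak does not rise above the IQR noise border.
#'
#' @param trace width-versus-time signal (one value per frame).
#' @param fs sampling frequency in Hz (default 0.25: one frame per 4 s).
#' @param segment_length Welch slice length (default 256 samples, ~17 min).
#' @param overlap slice overlap fraction (default 0.9).
#' @param denoise apply [iqrNoiseFilter()] before Welch (default TRUE).
#' @param peak_margin factor by which the spectral peak must exceed the IQR
#'   noise border to count as a confident oscillation; for featureless
#'   (white-noise) traces the extreme periodogram bin sits just above the
#'   border, so a margin of 3 separates real peaks from noise extremes.
#' @param section_id label carried into the result.
#' @return a \linkS4class{SpectralEstimate}.
#' @export
contractionFrequency <- function(trace, fs = 0.25, segment_length = 256,
                                 overlap = 0.9, denoise = TRUE,
                                 peak_margin = 3,
                                 section_id = NA_character_) {
  n0 <- length(trace)
  # full-trace PSD for the noise-confidence report
  X <- stats::fft(trace - mean(trace))
  half <- seq(2L, floor(n0 / 2) + 1L)
  full_psd <- Mod(X[half])^2 / n0
  q <- stats::quantile(full_psd, c(0.25, 0.75), names = FALSE)
  thr <- q[2] + 1.5 * (q[2] - q[1])
  lowconf <- max(full_psd) <= peak_margin * thr
  work <- if (denoise) iqrNoiseFilter(trace) else trace
  w <- welchPsd(work, segment_length, overlap)
  sl <- apply(w$power, 2L, estimateSliceFrequency, fs = fs,
              n = segment_length)
  new("SpectralEstimate",
      sectionId = as.character(section_id), fs = fs, n = segment_length,
      freqs = (half - 1L) * fs / n0, power = full_psd,
      noiseThreshold = thr, sliceFreqs = as.numeric(sl),
      estFrequencyHz = mean(sl), lowConfidence = lowconf)
}

#' Organism-level contraction frequency
#'
#' Averages per-section frequency estimates over the whole organism after a
#' concluding 1.5 x IQR outlier check: sections outside the Tukey fences of
#' the per-section frequencies are excluded and reported.
#'
#' @param estimates list of \linkS4class{SpectralEstimate} objects (or a
#'   numeric vector of per-section frequencies in Hz).
#' @return list with `mean_hz`, `sd_hz`, `n_used`, `excluded` (section ids
#'   or indices), `frequencies_hz`.
#' @export
organismAverage <- function(estimates) {
  if (is.list(estimates)) {
    f <- vapply(estimates, estFrequency, numeric(1))
    ids <- vapply(estimates, function(e) e@sectionId, character(1))
    ids[is.na(ids)] <- as.character(seq_along(f))[is.na(ids)]
  } else {
    f <- as.numeric(estimates)
    ids <- as.character(seq_along(f))
  }
  if (length(f) < 3L) {
    warning("fewer than 3 sections: averaging without outlier test")
    return(list(mean_hz = mean(f), sd_hz = stats::sd(f), n_used = length(f),
                excluded = character(), frequencies_hz = f))
  }
  q <- stats::quantile(f, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  ok <- f >= q[1] - 1.5 * iqr & f <= q[2] + 1.5 * iqr
  list(mean_hz = mean(f[ok]), sd_hz = stats::sd(f[ok]), n_used = sum(ok),
       excluded = ids[!ok], frequencies_hz = f)
}
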