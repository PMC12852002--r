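# Signal conditioning for raw heart-sound recordings:
# bandpass -> mains notch -> (optional) SVD + wavelet denoise -> resample
# -> z-score.  Filtering runs at the native rate; resampling comes last so
# the filters see the full recorded band.

#' Preprocessing configuration
#'
#' @param band_low_hz,band_high_hz Butterworth passband edges (Hz). Heart
#'   sounds carry most energy from a few Hz up to several hundred Hz;
#'   10-1000 Hz removes baseline wander and out-of-band artifact.
#' @param butter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation doubles and the phase is zero).
#' @param notch_hz Mains interference frequency (Hz).
#' @param notch_bw_hz Width of the FIR notch stopband (Hz).
#' @param target_fs Output sampling rate (Hz).
#' @param denoise_enabled Run the SVD + wavelet denoiser. Off by default in
#'   the pipeline profile; the subspace step is the one expensive stage.
#' @param svd_energy Fraction of squared singular-value energy retained by
#'   the Hankel subspace step.
#' @param wavelet_levels Decomposition depth of the wavelet thresholding.
#' @return List of class `pcg_preprocess_config`.
#' @export
preprocess_config <- function(band_low_hz = 10, band_high_hz = 1000,
                              butter_order = 4,
                              notch_hz = 50, notch_bw_hz = 12,
                              target_fs = 2205,
                              denoise_enabled = FALSE,
                              svd_energy = 0.995,
                              wavelet_levels = 5) {
  check_positive(band_low_hz, "band_low_hz")
  check_positive(band_high_hz, "band_high_hz")
  check_positive(notch_hz, "notch_hz")
  check_positive(target_fs, "target_fs")
  check_flag(denoise_enabled, "denoise_enabled")
  if (band_low_hz >= band_high_hz) {
    rlang::abort("band_low_hz must be below band_high_hz.",
                 class = "pcgstack_invalid_config")
  }
  structure(list(
    band_low_hz = band_low_hz, band_high_hz = band_high_hz,
    butter_order = as.integer(butter_order),
    notch_hz = notch_hz, notch_bw_hz = notch_bw_hz,
    target_fs = as.integer(target_fs),
    denoise_enabled = denoise_enabled,
    svd_energy = svd_energy,
    wavelet_levels = as.integer(wavelet_levels)
  ), class = "pcg_preprocess_config")
}

#' Zero-phase Butterworth bandpass
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate (Hz).
#' @param cfg A [preprocess_config()].
#' @return Filtered waveform, same length.
#' @export
bandpass_butterworth <- function(x, fs, cfg = preprocess_config()) {
  if (cfg$band_high_hz >= fs / 2) {
    rlang::abort("band_high_hz must be below the Nyquist frequency.",
                 class = "pcgstack_invalid_config")
  }
  bf <- signal::butter(cfg$butter_order,
                       c(cfg$band_low_hz, cfg$band_high_hz) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Linear-phase FIR band-stop centred on the mains frequency, applied with
# group-delay compensation so the output stays aligned with the input.
design_notch_fir <- function(fs, notch_hz, bw_hz) {
  # transition width ~ bw/3 on each side; Hamming window design
  trans <- bw_hz / 3
  n_taps <- 2L * ceiling(3.3 * fs / trans / 2) # even order -> odd length
  edges <- c(notch_hz - bw_hz / 2, notch_hz + bw_hz / 2) / (fs / 2)
  signal::fir1(n_taps, edges, type = "stop")
}

#' FIR notch filter for mains interference
#'
#' Fixed linear-phase band-stop at `cfg$notch_hz` (default 50 Hz), applied
#' with its group delay removed.
#'
#' @inheritParams bandpass_butterworth
#' @return Filtered waveform, same length.
#' @export
notch_filter <- function(x, fs, cfg = preprocess_config()) {
  if (cfg$notch_hz >= fs / 2) {
    rlang::abort("notch_hz must be below the Nyquist frequency.",
                 class = "pcgstack_invalid_config")
  }
  h <- design_notch_fir(fs, cfg$notch_hz, cfg$notch_bw_hz)
  delay <- (length(h) - 1L) / 2L
  n <- length(x)
  # pad so the delayed output covers the full input
  y <- fft_convolve(c(x, numeric(delay)), h)
  y[(delay + 1L):(delay + n)]
}

# Linear convolution via FFT, full length.
fft_convolve <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
              fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

## ---- wavelet machinery (Daubechies-4, periodized) ----

daub4_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
daub4_hi <- rev(daub4_lo) * c(1, -1, 1, -1)

dwt_step <- function(x) {
  n <- length(x)
  idx0 <- 2L * (seq_len(n / 2L) - 1L) # 0-based even positions
  a <- numeric(n / 2L)
  d <- numeric(n / 2L)
  for (m in 0:3) {
    xi <- x[((idx0 + m) %% n) + 1L]
    a <- a + daub4_lo[m + 1L] * xi
    d <- d + daub4_hi[m + 1L] * xi
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  n <- 2L * length(a)
  x <- numeric(n)
  idx0 <- 2L * (seq_along(a) - 1L)
  for (m in 0:3) {
    pos <- ((idx0 + m) %% n) + 1L
    contrib <- daub4_lo[m + 1L] * a + daub4_hi[m + 1L] * d
    x[pos] <- x[pos] + contrib
  }
  x
}

# Multilevel soft-threshold wavelet denoising. The noise scale is estimated
# once from the finest detail level (median absolute deviation / 0.6745)
# and each level is soft-thresholded at the universal threshold
# sigma * sqrt(2 log n).
wavelet_denoise <- function(x, levels = 5L) {
  n0 <- length(x)
  block <- 2L^levels
  n_pad <- ceiling(n0 / block) * block
  xp <- c(x, rev(x)[seq_len(n_pad - n0)]) # reflect pad to a multiple of 2^levels
  details <- vector("list", levels)
  a <- xp
  for (l in seq_len(levels)) {
    st <- dwt_step(a)
    a <- st$a
    details[[l]] <- st$d
  }
  sigma <- stats::median(abs(details[[1L]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n_pad))
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  for (l in seq_len(levels)) details[[l]] <- soft(details[[l]])
  for (l in rev(seq_len(levels))) a <- idwt_step(a, details[[l]])
  a[seq_len(n0)]
}

# Rank-reduction denoising on the Hankel (trajectory) embedding: keep the
# leading singular subspace holding `energy` of the squared singular-value
# mass, reconstruct by anti-diagonal averaging.
svd_denoise <- function(x, window = NULL, energy = 0.995) {
  n <- length(x)
  if (is.null(window)) window <- min(256L, floor(n / 2L))
  L <- as.integer(window)
  if (n < 2L * L) {
    rlang::abort("signal too short for the SVD embedding.",
                 class = "pcgstack_invalid_input")
  }
  K <- n - L + 1L
  H <- matrix(0, L, K)
  for (i in seq_len(L)) H[i, ] <- x[i:(i + K - 1L)]
  # eigen-decomposition of the small Gram matrix instead of a full SVD
  G <- tcrossprod(H)
  eg <- eigen(G, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (sum(ev) <= 0) return(x)
  r <- which(cumsum(ev) / sum(ev) >= energy)[1L]
  U <- eg$vectors[, seq_len(r), drop = FALSE]
  Hr <- U %*% (t(U) %*% H)
  # anti-diagonal (Hankel) averaging back to a 1-D signal
  num <- numeric(n)
  den <- numeric(n)
  for (i in seq_len(L)) {
    idx <- i:(i + K - 1L)
    num[idx] <- num[idx] + Hr[i, ]
    den[idx] <- den[idx] + 1
  }
  num / den
}

#' SVD + wavelet denoising
#'
#' Two-stage denoiser: a Hankel-embedding singular-subspace projection
#' (retaining `svd_energy` of squared singular-value energy) followed by
#' multilevel Daubechies-4 soft thresholding at the universal threshold.
#'
#' @param x Numeric waveform.
#' @param window Hankel embedding length; default `min(256, n/2)`.
#' @param energy Retained squared singular-value energy fraction.
#' @param levels Wavelet decomposition depth.
#' @return Denoised waveform, same length as the input.
#' @export
denoise_svd_wavelet <- function(x, window = NULL, energy = 0.995, levels = 5L) {
  if (all(x == 0)) return(x)
  y <- svd_denoise(x, window = window, energy = energy)
  wavelet_denoise(y, levels = levels)
}

# Rational-factor resampling (FFT method); output length round(n*p/q).
resample_to <- function(x, fs, target_fs) {
  if (target_fs == fs) return(x)
  if (target_fs > fs) {
    rlang::abort("target_fs must not exceed the input sampling rate.",
                 class = "pcgstack_invalid_config")
  }
  n_out <- round(length(x) * target_fs / fs)
  # anti-alias, then interpolate on the continuous-time grid
  bf <- signal::butter(8, 0.9 * target_fs / fs)
  y <- as.numeric(signal::filtfilt(bf, x))
  t_in <- (seq_along(x) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  approx(t_in, y, xout = t_out, rule = 2)$y
}

#' Resample to the working rate and z-score
#'
#' @inheritParams bandpass_butterworth
#' @return List with `samples` (mean 0, sd 1) and `fs = cfg$target_fs`.
#' @export
standardize_pcg <- function(x, fs, cfg = preprocess_config()) {
  if (stats::sd(x) < 1e-12 * max(abs(x), 1)) {
    rlang::abort("signal is constant; cannot z-score.",
                 class = "pcgstack_degenerate_input")
  }
  y <- resample_to(x, fs, cfg$target_fs)
  s <- stats::sd(y)
  if (!is.finite(s) || s < 1e-12) {
    rlang::abort("signal is constant after resampling; cannot z-score.",
                 class = "pcgstack_degenerate_input")
  }
  list(samples = (y - mean(y)) / s, fs = cfg$target_fs)
}

#' Full preprocessing chain for one waveform
#'
#' Bandpass, notch, optional SVD+wavelet denoise, resample, z-score.
#'
#' @inheritParams bandpass_butterworth
#' @return List with `samples` and `fs`.
#' @export
preprocess_signal <- function(x, fs, cfg = preprocess_config()) {
  y <- bandpass_butterworth(x, fs, cfg)
  y <- notch_filter(y, fs, cfg)
  if (cfg$denoise_enabled) y <- denoise_svd_wavelet(y)
  standardize_pcg(y, fs, cfg)
}

#' Preprocess every recording of a dataset
#'
#' @param dataset Dataset tibble (`samples` list-column plus `fs`).
#' @param cfg A [preprocess_config()].
#' @return The dataset with `samples` replaced by the conditioned waveforms
#'   and `fs` set to `cfg$target_fs`.
#' @export
preprocess_pcg <- function(dataset, cfg = preprocess_config()) {
  out <- purrr::map(seq_len(nrow(dataset)), function(i) {
    preprocess_signal(dataset$samples[[i]], dataset$fs[i], cfg)$samples
  })
  dplyr::mutate(dataset, samples = out, fs = cfg$target_fs)
}
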