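# Gammatone filterbank spectrograms ("gammatonegrams").
#
# The gammatone impulse response is the product of a gamma envelope and a
# sinusoidal carrier:
#
#   g(t; fc) = a * t^(n-1) * exp(-2 pi b t) * cos(2 pi fc t + phi),  t >= 0
#
# with order n (4 here), bandwidth parameter b tied to the equivalent
# rectangular bandwidth (ERB) of the channel, and causal response (zero for
# t < 0).  Channels are spaced uniformly on the ERB-rate scale, so low
# frequencies get narrow filters and high frequencies broad ones — the
# auditory-motivated contrast with a constant-bandwidth STFT.

#' Equivalent rectangular bandwidth (Glasberg-Moore)
#'
#' @param f Frequency in Hz.
#' @return ERB in Hz.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' ERB-spaced center frequencies
#'
#' `n_channels` frequencies from `fmin` to `fmax` inclusive, equally spaced
#' on the ERB-rate scale.
#'
#' @param fmin,fmax Frequency range in Hz.
#' @param n_channels Number of channels (>= 2).
#' @return Strictly increasing numeric vector of length `n_channels`.
#' @export
erb_center_freqs <- function(fmin, fmax, n_channels) {
  if (!(fmin > 0 && fmax > fmin)) {
    rlang::abort("need 0 < fmin < fmax.", class = "pcgstack_invalid_config")
  }
  if (n_channels < 2) {
    rlang::abort("n_channels must be >= 2.", class = "pcgstack_invalid_config")
  }
  erb_rate_inv(seq(erb_rate(fmin), erb_rate(fmax), length.out = n_channels))
}

#' Gammatone impulse response
#'
#' @param t Time in seconds (vectorized); the response is causal (0 for
#'   `t < 0`).
#' @param fc Center frequency (Hz).
#' @param n Filter order.
#' @param b Bandwidth parameter (Hz); default `1.019 * erb_bandwidth(fc)`.
#' @param a Amplitude.
#' @param phase Carrier phase (radians).
#' @return Response values, same length as `t`.
#' @export
gammatone_ir <- function(t, fc, n = 4, b = NULL, a = 1, phase = 0) {
  if (is.null(b)) b <- 1.019 * erb_bandwidth(fc)
  out <- a * t^(n - 1) * exp(-2 * pi * b * t) * cos(2 * pi * fc * t + phase)
  out[t < 0] <- 0
  out
}

#' Build a gammatone filterbank
#'
#' Impulse responses are sampled at `fs`, truncated where the gamma
#' envelope falls below `1e-5` of its peak, and gain-normalized so every
#' channel has unit magnitude response at its own center frequency.
#'
#' @param fs Sampling rate (Hz).
#' @param n_channels Number of channels.
#' @param fmin,fmax Frequency range (Hz); `fmax` must be below Nyquist.
#' @param order Gammatone order n.
#' @param phase Carrier phase (radians).
#' @return List of class `pcg_gammatone_bank` with `center_freqs`, `irs`
#'   (list of numeric impulse responses), `fs`, `order`, `bandwidths`.
#' @export
gammatone_filterbank <- function(fs, n_channels = 64, fmin = 20, fmax = 1000,
                                 order = 4, phase = 0) {
  if (fmax >= fs / 2) {
    rlang::abort("fmax must be below the Nyquist frequency.",
                 class = "pcgstack_invalid_config")
  }
  cfs <- erb_center_freqs(fmin, fmax, n_channels)
  bws <- 1.019 * erb_bandwidth(cfs)
  irs <- vector("list", n_channels)
  for (k in seq_len(n_channels)) {
    b <- bws[k]
    # envelope t^(n-1) exp(-2 pi b t) peaks at t* = (n-1)/(2 pi b);
    # extend until it decays to 1e-5 of the peak
    tpk <- (order - 1) / (2 * pi * b)
    tmax <- tpk
    env <- function(t) t^(order - 1) * exp(-2 * pi * b * t)
    peak <- env(tpk)
    while (env(tmax) > 1e-5 * peak) tmax <- tmax * 1.5
    t <- seq(0, tmax, by = 1 / fs)
    h <- gammatone_ir(t, cfs[k], n = order, phase = phase)
    # unit gain at the channel center frequency
    gain <- abs(sum(h * exp(-2i * pi * cfs[k] * t)))
    irs[[k]] <- h / gain
  }
  structure(list(center_freqs = cfs, bandwidths = bws, irs = irs,
                 fs = fs, order = order),
            class = "pcg_gammatone_bank")
}

#' Compute a gammatonegram
#'
#' Filters the signal with every channel of the bank (FFT convolution,
#' causal alignment) and reduces each channel to framed root-mean-square
#' energy.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate (Hz); must match the bank.
#' @param bank A [gammatone_filterbank()].
#' @param frame_len Frame length in samples (default 25 ms).
#' @param hop Hop size in samples (default 10 ms).
#' @return Object of class `pcg_gammatonegram`: list with `values`
#'   (channels x frames, non-negative), `center_freqs`, `frame_times`.
#' @export
compute_gammatonegram <- function(x, fs, bank = NULL,
                                  frame_len = round(0.025 * fs),
                                  hop = round(0.010 * fs)) {
  if (length(x) == 0) {
    rlang::abort("empty signal.", class = "pcgstack_invalid_input")
  }
  if (is.null(bank)) bank <- gammatone_filterbank(fs)
  if (bank$fs != fs) {
    rlang::abort("bank was designed for a different sampling rate.",
                 class = "pcgstack_invalid_config")
  }
  if (frame_len > length(x)) {
    rlang::abort("frame_len exceeds the signal length.",
                 class = "pcgstack_invalid_input")
  }
  n <- length(x)
  max_ir <- max(lengths(bank$irs))
  nfft <- stats::nextn(n + max_ir - 1L, 2)
  X <- fft(c(x, numeric(nfft - n)))
  n_frames <- floor((n - frame_len) / hop) + 1L
  starts <- 1L + (seq_len(n_frames) - 1L) * hop
  G <- matrix(0, length(bank$irs), n_frames)
  for (k in seq_along(bank$irs)) {
    h <- bank$irs[[k]]
    y <- Re(fft(X * fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
    y <- y[seq_len(n)] # causal part aligned with x
    cs <- cumsum(c(0, y^2))
    G[k, ] <- sqrt((cs[starts + frame_len] - cs[starts]) / frame_len)
  }
  structure(list(values = G,
                 center_freqs = bank$center_freqs,
                 frame_times = (starts - 1L + frame_len / 2) / fs),
            class = "pcg_gammatonegram")
}

#' Convert a gammatonegram to a gray image
#'
#' Log-compresses to decibels, clips to `dynamic_range_db` below the
#' maximum, min-max scales to \[0, 1\] and resizes bilinearly. An all-zero
#' input maps to an all-zero image (documented degenerate case).
#'
#' @param G A `pcg_gammatonegram`.
#' @param dynamic_range_db Dynamic range kept below the peak (dB).
#' @param out_size Output `c(height, width)` in pixels.
#' @return Matrix in \[0, 1\] of dimension `out_size`.
#' @export
gammatonegram_image <- function(G, dynamic_range_db = 60,
                                out_size = c(224, 224)) {
  V <- G$values
  if (length(V) == 0) {
    rlang::abort("empty gammatonegram.", class = "pcgstack_invalid_input")
  }
  if (all(V == 0)) {
    return(matrix(0, out_size[1], out_size[2]))
  }
  mx <- max(V)
  floor_lin <- mx * 10^(-dynamic_range_db / 20)
  db <- 20 * log10(pmax(V, floor_lin))
  img <- (db - (20 * log10(mx) - dynamic_range_db)) / dynamic_range_db
  resize_bilinear(img, out_size[1], out_size[2])
}

#' @export
print.pcg_gammatonegram <- function(x, ...) {
  cat(sprintf("<pcg_gammatonegram: %d channels x %d frames, %.0f-%.0f Hz>\n",
              nrow(x$values), ncol(x$values),
              min(x$center_freqs), max(x$center_freqs)))
  invisible(x)
}

#' Plot a gammatonegram
#'
#' @param object A `pcg_gammatonegram`.
#' @param dynamic_range_db Display dynamic range in dB.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcg_gammatonegram <- function(object, dynamic_range_db = 60, ...) {
  V <- object$values
  mx <- max(V, 1e-300)
  db <- 20 * log10(pmax(V, mx * 10^(-dynamic_range_db / 20)))
  df <- tidyr::expand_grid(channel = seq_len(nrow(V)), frame = seq_len(ncol(V)))
  df$time_s <- object$frame_times[df$frame]
  df$freq_hz <- object$center_freqs[df$channel]
  df$db <- as.vector(db[cbind(df$channel, df$frame)])
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz, fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB") +
    ggplot2::labs(x = "time (s)", y = "center frequency (Hz)") +
    ggplot2::theme_minimal()
}
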