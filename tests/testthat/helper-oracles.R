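# Independent brute-force oracles, written directly from the defining
# equations of each quantity and kept loop-based on purpose: they share no
# code path with the package implementations they check.

# GLCM: count pairs I(x,y)=gi, I(x+dx,y+dy)=gj by explicit enumeration.
oracle_glcm <- function(q, dx, dy, ng, symmetric = TRUE) {
  nr <- nrow(q); nc <- ncol(q)
  P <- matrix(0, ng, ng)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      x2 <- x + dx; y2 <- y + dy
      if (x2 >= 1 && x2 <= nc && y2 >= 1 && y2 <= nr) {
        P[q[y, x], q[y2, x2]] <- P[q[y, x], q[y2, x2]] + 1
      }
    }
  }
  if (symmetric) P <- P + t(P)
  P / sum(P)
}

# GLRLM: walk every line of the direction, counting maximal runs.
oracle_glrlm <- function(q, direction, ng) {
  nr <- nrow(q); nc <- ncol(q)
  step <- switch(as.character(direction),
                 `0` = c(1, 0), `45` = c(1, -1), `90` = c(0, 1),
                 `135` = c(1, 1))
  dx <- step[1]; dy <- step[2]
  # line starts: pixels with no in-line predecessor
  starts <- list()
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      px <- x - dx; py <- y - dy
      if (px < 1 || px > nc || py < 1 || py > nr) {
        starts[[length(starts) + 1]] <- c(x, y)
      }
    }
  }
  counts <- matrix(0, ng, nr * nc)
  for (s in starts) {
    x <- s[1]; y <- s[2]
    run_val <- q[y, x]; run_len <- 0
    while (x >= 1 && x <= nc && y >= 1 && y <= nr) {
      if (q[y, x] == run_val) {
        run_len <- run_len + 1
      } else {
        counts[run_val, run_len] <- counts[run_val, run_len] + 1
        run_val <- q[y, x]; run_len <- 1
      }
      x <- x + dx; y <- y + dy
    }
    counts[run_val, run_len] <- counts[run_val, run_len] + 1
  }
  counts[, seq_len(max(1, max(which(colSums(counts) > 0)))), drop = FALSE]
}

# GLSZM: explicit stack-based flood fill over 8-connected equal-level sets.
oracle_glszm <- function(q, ng) {
  nr <- nrow(q); nc <- ncol(q)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (y0 in seq_len(nr)) {
    for (x0 in seq_len(nc)) {
      if (seen[y0, x0]) next
      lev <- q[y0, x0]
      stack <- list(c(x0, y0))
      seen[y0, x0] <- TRUE
      size <- 0
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1
        for (dy in -1:1) for (dx in -1:1) {
          if (dx == 0 && dy == 0) next
          x <- p[1] + dx; y <- p[2] + dy
          if (x >= 1 && x <= nc && y >= 1 && y <= nr &&
              !seen[y, x] && q[y, x] == lev) {
            seen[y, x] <- TRUE
            stack[[length(stack) + 1]] <- c(x, y)
          }
        }
      }
      zones[[length(zones) + 1]] <- c(lev, size)
    }
  }
  counts <- matrix(0, ng, nr * nc)
  for (z in zones) counts[z[1], z[2]] <- counts[z[1], z[2]] + 1
  counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
}

# GLDM: per-pixel neighbor enumeration within the Chebyshev window.
oracle_gldm <- function(q, ng, delta = 0, distance = 1) {
  nr <- nrow(q); nc <- ncol(q)
  dep <- matrix(0, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      d <- 0
      for (dy in -distance:distance) for (dx in -distance:distance) {
        if (dx == 0 && dy == 0) next
        x2 <- x + dx; y2 <- y + dy
        if (x2 >= 1 && x2 <= nc && y2 >= 1 && y2 <= nr &&
            abs(q[y, x] - q[y2, x2]) <= delta) {
          d <- d + 1
        }
      }
      dep[y, x] <- d
    }
  }
  dmax <- max(dep)
  counts <- matrix(0, ng, dmax + 1)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    counts[q[y, x], dep[y, x] + 1] <- counts[q[y, x], dep[y, x] + 1] + 1
  }
  counts
}

# AUC by all-pairs comparison, ties half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels > 0]; neg <- scores[labels <= 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# count S1 bursts: smoothed envelope, local maxima above half the peak
# with a refractory period of half a cardiac cycle
oracle_count_s1 <- function(x, fs, heart_rate_bpm) {
  env <- stats::filter(abs(x), rep(1 / round(0.05 * fs), round(0.05 * fs)),
                       sides = 2)
  env[is.na(env)] <- 0
  thr <- 0.5 * max(env)
  min_gap <- round(0.5 * 60 / heart_rate_bpm * fs)
  peaks <- integer(0)
  i <- 2
  while (i < length(env)) {
    if (env[i] > thr && env[i] >= env[i - 1] && env[i] >= env[i + 1]) {
      if (length(peaks) == 0 || i - peaks[length(peaks)] > min_gap) {
        peaks <- c(peaks, i)
      }
      i <- i + min_gap
    } else {
      i <- i + 1
    }
  }
  length(peaks)
}

# paired bootstrap p-value for a difference of correlated AUCs
oracle_bootstrap_delong_p <- function(sa, sb, y, reps = 10000, seed = 1) {
  set.seed(seed)
  pos <- which(y > 0); neg <- which(y <= 0)
  delta <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    delta[r] <- roc_auc(sa[idx], y[idx]) - roc_auc(sb[idx], y[idx])
  }
  2 * min(mean(delta <= 0), mean(delta >= 0))
}

# spectral RMS of a sinusoid component via the FFT magnitude at its bin
fft_band_rms <- function(x, fs, freq, half_width = 2) {
  n <- length(x)
  mag <- abs(fft(x))[seq_len(floor(n / 2))] / n
  bins <- round(freq * n / fs) + 1
  idx <- max(1, bins - half_width):min(length(mag), bins + half_width)
  sqrt(2 * sum(mag[idx]^2))
}
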