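# Synthetic phonocardiogram simulator.
#
# Each recording is a quasi-periodic train of two Gaussian-windowed tone
# bursts per cardiac cycle: S1 (mitral/tricuspid closure, ~45 Hz here) at
# the cycle onset and S2 (aortic/pulmonic closure, ~70 Hz) at end-systole.
# The positive (HFpEF-like) class additionally receives an early-diastolic
# low-frequency burst (an S3-like filling sound, ~28 Hz) and an upward shift
# of the S2 band, both scaled by `effect_size`, so the class difference
# manifests as a band-energy / texture difference in the gammatonegram.
# Per-subject random effects (overall amplitude, resting heart rate, cycle
# timing jitter) make subject-grouped data splitting meaningful.

#' Simulation configuration for synthetic heart-sound datasets
#'
#' Bundles every knob of the synthetic phonocardiogram generator. The
#' defaults describe a desk-scale cohort: two classes of subjects, five
#' roughly 10-second auscultation segments per subject, recorded at
#' 4410 Hz so the preprocessing resample step is exercised.
#'
#' @param n_subjects_per_class Subjects simulated per class.
#' @param segments_per_subject Recordings per subject (all share the
#'   subject's label and random effects).
#' @param duration_s Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param heart_rate_bpm Population mean heart rate (beats per minute).
#' @param effect_size Non-negative class-separation scale. `0` makes the two
#'   class-conditional generative distributions identical.
#' @param noise_sd Standard deviation of additive white measurement noise.
#' @param seed Integer seed; every recording's seed derives from it.
#'
#' @return A list of class `pcg_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects_per_class = 2, segments_per_subject = 2,
#'                   duration_s = 2, seed = 7)
#' simulate_pcg_dataset(cfg)
sim_config <- function(n_subjects_per_class = 40,
                       segments_per_subject = 5,
                       duration_s = 10,
                       fs = 4410,
                       heart_rate_bpm = 75,
                       effect_size = 1,
                       noise_sd = 0.1,
                       seed = 1) {
  check_positive(n_subjects_per_class, "n_subjects_per_class")
  check_positive(segments_per_subject, "segments_per_subject")
  check_positive(duration_s, "duration_s")
  check_positive(fs, "fs")
  check_positive(heart_rate_bpm, "heart_rate_bpm")
  if (!is.numeric(effect_size) || effect_size < 0) {
    rlang::abort("`effect_size` must be non-negative.", class = "pcgstack_invalid_config")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    rlang::abort("`noise_sd` must be non-negative.", class = "pcgstack_invalid_config")
  }
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-8 || n <= 0) {
    rlang::abort("`duration_s * fs` must be a positive integer sample count.",
                 class = "pcgstack_invalid_config")
  }
  structure(list(
    n_subjects_per_class = as.integer(n_subjects_per_class),
    segments_per_subject = as.integer(segments_per_subject),
    duration_s = duration_s,
    fs = as.integer(fs),
    heart_rate_bpm = heart_rate_bpm,
    effect_size = effect_size,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "pcg_sim_config")
}

# Gaussian-windowed tone burst centred at `center` seconds.
tone_burst <- function(t, center, sigma, freq, amp) {
  amp * exp(-(t - center)^2 / (2 * sigma^2)) * cos(2 * pi * freq * (t - center))
}

#' Draw per-subject random effects
#'
#' Amplitude scale (log-normal), resting heart-rate offset and a timing
#' jitter scale, all deterministic given `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this subject.
#' @return Named list of subject-level effects.
#' @export
subject_effects <- function(cfg, seed) {
  with_local_seed(seed, {
    list(
      amp = exp(rnorm(1, 0, 0.15)),
      hr_offset_bpm = rnorm(1, 0, 4),
      jitter_sd_s = 0.008 + abs(rnorm(1, 0, 0.004))
    )
  })
}

#' Simulate one synthetic PCG recording
#'
#' @param cls Class label, `-1` (non-HF) or `+1` (HFpEF-like).
#' @param effects Subject-level effects from [subject_effects()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this recording.
#'
#' @return A tibble with one row: `segment_id`, `subject_id`, `label`, `fs`
#'   and a `samples` list-column holding the waveform.
#' @export
simulate_recording <- function(cls, effects, cfg, seed) {
  if (!inherits(cfg, "pcg_sim_config")) {
    rlang::abort("`cfg` must come from sim_config().", class = "pcgstack_invalid_config")
  }
  if (!cls %in% c(-1, 1)) {
    rlang::abort("`cls` must be -1 or +1.", class = "pcgstack_invalid_input")
  }
  n <- as.integer(round(cfg$duration_s * cfg$fs))
  t <- (seq_len(n) - 1) / cfg$fs
  hr <- cfg$heart_rate_bpm + effects$hr_offset_bpm
  cycle <- 60 / hr
  n_beats <- ceiling(cfg$duration_s / cycle) + 1L

  x <- with_local_seed(seed, {
    jitter <- rnorm(n_beats, 0, effects$jitter_sd_s)
    onsets <- (seq_len(n_beats) - 1) * cycle + jitter
    sig <- numeric(n)
    es <- cfg$effect_size
    for (k in seq_len(n_beats)) {
      t0 <- onsets[k]
      if (t0 > cfg$duration_s + 0.2) next
      # S1 at cycle onset; S2 after systole (~1/3 cycle).  The positive
      # class gets its S2 band shifted up and an S3-like early-diastolic
      # low-frequency burst, both scaled by effect_size.
      s2_freq <- 70 + if (cls > 0) 5 * es else 0
      sig <- sig +
        tone_burst(t, t0, 0.022, 45, 1.0 * effects$amp) +
        tone_burst(t, t0 + 0.33 * cycle, 0.015, s2_freq, 0.6 * effects$amp)
      if (cls > 0 && es > 0) {
        sig <- sig +
          tone_burst(t, t0 + 0.50 * cycle, 0.030, 28, 0.25 * es * effects$amp)
      }
    }
    sig + rnorm(n, 0, cfg$noise_sd)
  })

  tibble::tibble(
    segment_id = NA_character_,
    subject_id = NA_character_,
    label = as.integer(cls),
    fs = cfg$fs,
    samples = list(x)
  )
}

#' Simulate a labelled, subject-grouped PCG dataset
#'
#' Generates `n_subjects_per_class` subjects per class, each contributing
#' `segments_per_subject` recordings that share the subject's label and
#' random effects. All randomness derives deterministically from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with columns `segment_id`, `subject_id`, `label`, `fs`
#'   and list-column `samples`, one row per recording.
#' @export
simulate_pcg_dataset <- function(cfg) {
  if (!inherits(cfg, "pcg_sim_config")) {
    rlang::abort("`cfg` must come from sim_config().", class = "pcgstack_invalid_config")
  }
  rows <- list()
  for (ci in 1:2) {
    cls <- c(-1L, 1L)[ci]
    cls_tag <- c("neg", "pos")[ci]
    for (s in seq_len(cfg$n_subjects_per_class)) {
      sid <- sprintf("%s%03d", cls_tag, s)
      eff <- subject_effects(cfg, derive_seed(cfg$seed, ci, s))
      for (g in seq_len(cfg$segments_per_subject)) {
        rec <- simulate_recording(cls, eff, cfg,
                                  derive_seed(cfg$seed, ci, s, g))
        rec$subject_id <- sid
        rec$segment_id <- sprintf("%s_seg%02d", sid, g)
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  dplyr::bind_rows(rows)
}
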