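# Synthetic cardiovascular signal simulator. Produces synchronized PPG / ECG /
# ABP traces with per-beat SBP/DBP ground truth so the whole estimation stack
# can be exercised and tested without access-controlled waveform databases.
#
# Model sketch: each subject gets a heart rate, baseline SBP/DBP and a slow
# latent blood-pressure drift. Every beat is a template on [0, 1) built from
# two Gaussians (systolic peak + dicrotic bump) on a diastolic baseline,
# min-max normalised per beat so the sampled ABP attains exactly the drawn
# SBP/DBP. `coupling_strength` morphs the template (peak position/width,
# dicrotic amplitude) and the ECG-to-pulse lag monotonically with the beat's
# blood pressure, so waveform shape carries BP information; at 0 the shape is
# BP-independent and the inputs are uninformative by construction.

#' Simulation configuration
#'
#' @param n_subjects Number of subjects to simulate.
#' @param duration_s Record length per subject, seconds.
#' @param fs Sampling rate, Hz (125 Hz by default, the common bedside-monitor
#'   waveform rate).
#' @param hr_range Heart-rate range (min, max) in beats per minute; each
#'   subject's rate is drawn uniformly from it.
#' @param sbp_range Systolic range (min, max) in mmHg for subject baselines.
#' @param dbp_range Diastolic range (min, max) in mmHg; its maximum must stay
#'   below the systolic minimum.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   (unit-scale) PPG and ECG signals.
#' @param coupling_strength Value in \[0, 1\]: how strongly waveform morphology
#'   and pulse-transit lag encode the underlying blood pressure. 0 means the
#'   input signals carry no BP information.
#' @param bp_drift_mmHg Amplitude of the slow within-record BP drift, mmHg.
#' @param seed Integer root RNG seed; per-subject streams are derived from it
#'   so records do not depend on generation order.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L, duration_s = 60, fs = 125,
                       hr_range = c(55, 95), sbp_range = c(95, 165),
                       dbp_range = c(55, 90), noise_sd = 0.05,
                       coupling_strength = 1, bp_drift_mmHg = 8,
                       seed = 1L) {
  check_scalar_number(n_subjects, "n_subjects", lower = 1, integer = TRUE)
  check_scalar_number(duration_s, "duration_s", lower = 1e-9)
  check_scalar_number(fs, "fs", lower = 1e-9)
  check_range_pair(hr_range, "hr_range")
  check_range_pair(sbp_range, "sbp_range")
  check_range_pair(dbp_range, "dbp_range")
  if (sbp_range[1] <= dbp_range[2]) {
    pg_stop("pg_config_error",
            "sbp_range minimum (%s) must exceed dbp_range maximum (%s)",
            sbp_range[1], dbp_range[2])
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(coupling_strength, "coupling_strength",
                      lower = 0, upper = 1)
  check_scalar_number(bp_drift_mmHg, "bp_drift_mmHg", lower = 0)
  check_scalar_number(seed, "seed", integer = TRUE)
  structure(
    list(n_subjects = as.integer(n_subjects), duration_s = duration_s,
         fs = fs, hr_range = hr_range, sbp_range = sbp_range,
         dbp_range = dbp_range, noise_sd = noise_sd,
         coupling_strength = coupling_strength,
         bp_drift_mmHg = bp_drift_mmHg, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Bundle synchronized waveforms into a signal record
#'
#' @param subject_id Character identifier.
#' @param fs Sampling rate, Hz.
#' @param ppg,ecg,abp Equal-length numeric traces; `abp` in mmHg.
#' @param beat_onsets Strictly increasing 1-based sample indices of beat
#'   starts.
#' @param sbp_per_beat,dbp_per_beat Per-beat systolic/diastolic values, mmHg.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(subject_id, fs, ppg, ecg, abp, beat_onsets,
                          sbp_per_beat, dbp_per_beat) {
  n <- length(abp)
  if (length(ppg) != n || length(ecg) != n) {
    pg_stop("pg_shape_error", "ppg, ecg and abp must have equal length")
  }
  if (length(beat_onsets) && (any(diff(beat_onsets) <= 0) ||
                              beat_onsets[1] < 1 ||
                              beat_onsets[length(beat_onsets)] > n)) {
    pg_stop("pg_shape_error",
            "beat_onsets must be strictly increasing and within the record")
  }
  if (length(sbp_per_beat) != length(dbp_per_beat)) {
    pg_stop("pg_shape_error", "per-beat SBP/DBP vectors must match in length")
  }
  if (any(sbp_per_beat <= dbp_per_beat)) {
    pg_stop("pg_config_error",
            "systolic must exceed diastolic for every beat")
  }
  structure(
    list(subject_id = as.character(subject_id), fs = fs,
         ppg = as.numeric(ppg), ecg = as.numeric(ecg), abp = as.numeric(abp),
         beat_onsets = as.integer(beat_onsets),
         sbp_per_beat = as.numeric(sbp_per_beat),
         dbp_per_beat = as.numeric(dbp_per_beat)),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf(
    "<signal_record %s: %.1f s @ %g Hz, %d beats, SBP %.0f-%.0f, DBP %.0f-%.0f mmHg>\n",
    x$subject_id, length(x$abp) / x$fs, x$fs, length(x$beat_onsets),
    min(x$sbp_per_beat), max(x$sbp_per_beat),
    min(x$dbp_per_beat), max(x$dbp_per_beat)))
  invisible(x)
}

# Beat template: two Gaussians on a zero baseline over phase u in [0, 1).
# The BP cues are expressed in absolute time (seconds), not beat phase, so
# they stay identifiable across heart rates: the systolic peak's width (in
# seconds) grows monotonically with the systolic level (broader ejection
# phase under higher systolic load) and the dicrotic bump's relative
# amplitude falls with the diastolic level (reflected-wave attenuation with
# vascular tone), both scaled by `coupling` (0 = shape independent of BP).
beat_pulse_shape <- function(u, u_sys, u_dia, coupling, beat_sec) {
  mu1 <- 0.30
  s1 <- 0.055 * (1 + 0.35 * coupling * u_sys) / beat_sec
  a2 <- 0.28 * (1 - 0.45 * coupling * u_dia)
  mu2 <- 0.62
  s2 <- 0.09
  exp(-0.5 * ((u - mu1) / s1)^2) + a2 * exp(-0.5 * ((u - mu2) / s2)^2)
}

#' Simulate one subject's record
#'
#' Deterministic given `(config$seed, subject_index)`: per-subject RNG streams
#' are derived from the root seed, so the same subject can be regenerated in
#' any order. The ABP oscillates between the drawn per-beat DBP trough and SBP
#' peak (the sampled extrema match the labels exactly); the PPG is a min-max
#' normalised, 50 ms moving-average smoothed copy of the ABP plus Gaussian
#' noise; the ECG is an R-peak impulse train, each peak preceding its beat's
#' pulse foot by a lag that decreases with the beat's mean arterial pressure
#' in proportion to `coupling_strength`.
#'
#' @param config A [sim_config()].
#' @param subject_index Integer in `1..config$n_subjects`.
#' @return A [signal_record()].
#' @export
simulate_record <- function(config, subject_index) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar_number(subject_index, "subject_index", lower = 1,
                      upper = config$n_subjects, integer = TRUE)
  sseed <- derive_seeds(config$seed, config$n_subjects)[subject_index]
  with_seed(sseed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    hr <- stats::runif(1, config$hr_range[1], config$hr_range[2])
    beat_len <- max(4L, round(fs * 60 / hr))
    onsets <- seq(1L, n - beat_len + 1L, by = beat_len)
    n_beats <- length(onsets)
    if (n_beats < 1L) {
      pg_stop("pg_config_error",
              "duration_s too short for a single beat at the drawn heart rate")
    }

    sbp_base <- stats::runif(1, config$sbp_range[1], config$sbp_range[2])
    dbp_base <- stats::runif(1, config$dbp_range[1], config$dbp_range[2])
    # slow latent drift shared by SBP and DBP (random phase sinusoid)
    phase <- stats::runif(1, 0, 2 * pi)
    period <- stats::runif(1, 20, 45)            # seconds
    t_beat <- (onsets - 1) / fs
    drift <- sin(2 * pi * t_beat / period + phase)
    sbp <- sbp_base + config$bp_drift_mmHg * drift
    dbp <- dbp_base + 0.6 * config$bp_drift_mmHg * drift
    sbp <- pmin(pmax(sbp, config$sbp_range[1]), config$sbp_range[2])
    dbp <- pmin(pmax(dbp, config$dbp_range[1]), config$dbp_range[2])

    # normalised levels in [-1, 1] used by the morphology coupling
    # (degenerate ranges give level 0)
    u_sys <- 2 * (sbp - mean(config$sbp_range)) /
      max(diff(config$sbp_range), 1e-9)
    u_dia <- 2 * (dbp - mean(config$dbp_range)) /
      max(diff(config$dbp_range), 1e-9)

    abp <- numeric(n)
    ecg <- numeric(n)
    map_mid <- mean(c(mean(config$sbp_range), mean(config$dbp_range)))
    map_half <- max((mean(config$sbp_range) - mean(config$dbp_range)) / 2 +
                      diff(config$sbp_range) / 2, 1e-9)
    for (k in seq_len(n_beats)) {
      idx <- onsets[k]:(onsets[k] + beat_len - 1L)
      u <- (seq_len(beat_len) - 1) / beat_len
      g <- beat_pulse_shape(u, u_sys[k], u_dia[k], config$coupling_strength,
                            beat_len / fs)
      g <- (g - min(g)) / (max(g) - min(g))      # sampled extrema hit 0 and 1
      abp[idx] <- dbp[k] + (sbp[k] - dbp[k]) * g

      # ECG R-peak: fixed base lag before the pulse foot, shortened as mean
      # arterial pressure rises (inverse pulse-transit-time relation)
      map_k <- dbp[k] + (sbp[k] - dbp[k]) / 3
      u_map <- (map_k - map_mid) / map_half
      lag <- round(fs * (0.22 - 0.10 * config$coupling_strength * u_map))
      r_at <- onsets[k] - lag
      if (r_at >= 1L && r_at <= n) {
        # Gaussian R-wave, ~20 ms wide
        half <- max(2L, round(0.04 * fs))
        span <- max(1L, r_at - half):min(n, r_at + half)
        ecg[span] <- pmax(ecg[span],
                          exp(-0.5 * ((span - r_at) / (0.02 * fs))^2))
      }
    }
    # trailing partial beat keeps the diastolic baseline of the last beat
    tail_idx <- if (onsets[n_beats] + beat_len <= n) {
      (onsets[n_beats] + beat_len):n
    } else integer()
    if (length(tail_idx)) abp[tail_idx] <- dbp[n_beats]

    # PPG: min-max normalised ABP, 50 ms moving-average smoothing, noise
    rng_abp <- range(abp)
    ppg <- (abp - rng_abp[1]) / max(rng_abp[2] - rng_abp[1], 1e-12)
    klen <- max(1L, round(0.05 * fs))
    if (klen > 1L) {
      padded <- c(rep(ppg[1], klen), ppg, rep(ppg[n], klen))
      sm <- stats::filter(padded, rep(1 / klen, klen), sides = 2)
      ppg <- as.numeric(sm[(klen + 1):(klen + n)])
    }
    if (config$noise_sd > 0) {
      ppg <- ppg + stats::rnorm(n, 0, config$noise_sd)
    }

    signal_record(sprintf("S%03d", subject_index), fs, ppg, ecg, abp,
                  onsets, sbp, dbp)
  })
}

#' Per-beat systolic/diastolic extraction from a pressure waveform
#'
#' Splits the waveform into half-open beat intervals
#' `[onset_k, onset_{k+1})` and returns the per-interval maximum (SBP) and
#' minimum (DBP). The trailing partial beat after the last onset is dropped.
#'
#' @param abp Numeric pressure waveform, mmHg.
#' @param beat_onsets Strictly increasing 1-based onset indices; at least 2
#'   are required so one complete interval exists.
#' @return A list with numeric vectors `sbp` and `dbp`, one value per
#'   complete beat interval.
#' @export
extract_sbp_dbp <- function(abp, beat_onsets) {
  if (length(beat_onsets) < 2L) {
    pg_stop("pg_insufficient_beats_error",
            "need at least 2 beat onsets to form a complete beat interval")
  }
  if (any(diff(beat_onsets) <= 0) || beat_onsets[1] < 1 ||
      beat_onsets[length(beat_onsets)] > length(abp)) {
    pg_stop("pg_shape_error",
            "beat_onsets must be strictly increasing and within the signal")
  }
  k <- length(beat_onsets) - 1L
  sbp <- numeric(k)
  dbp <- numeric(k)
  for (i in seq_len(k)) {
    seg <- abp[beat_onsets[i]:(beat_onsets[i + 1L] - 1L)]
    sbp[i] <- max(seg)
    dbp[i] <- min(seg)
  }
  list(sbp = sbp, dbp = dbp)
}

#' Build a windowed training dataset from simulated subjects
#'
#' Slides fixed-length windows over each subject's record and collects, per
#' window: the PPG (and ECG) input segment, the ABP waveform target, and the
#' SBP/DBP regression targets (mean over the beats whose onsets fall in the
#' window). Windowing is beat-synchronous: each nominal window start on the
#' stride grid is snapped back to the latest beat onset at or before it, so
#' every window begins at a pulse foot and windows are phase-aligned across
#' subjects. Subject ids are retained for leave-one-out grouping.
#'
#' @param config A [sim_config()].
#' @param window_s Window length in seconds (must not exceed `duration_s`).
#' @param stride_s Positive stride between window starts, seconds.
#' @return An object of class `bp_dataset`: list with matrices `ppg`, `ecg`,
#'   `abp` (rows = windows), numeric `sbp`, `dbp`, character `subject`,
#'   and the generating metadata.
#' @export
make_dataset <- function(config, window_s = 4, stride_s = 2) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar_number(window_s, "window_s", lower = 1e-9,
                      upper = config$duration_s)
  if (!is.numeric(stride_s) || length(stride_s) != 1L || stride_s <= 0) {
    pg_stop("pg_config_error", "`stride_s` must be a positive number")
  }
  wl <- round(window_s * config$fs)
  sl <- max(1L, round(stride_s * config$fs))
  rows_ppg <- list(); rows_ecg <- list(); rows_abp <- list()
  sbp <- numeric(); dbp <- numeric(); subject <- character()
  win_beats <- list()
  for (s in seq_len(config$n_subjects)) {
    rec <- simulate_record(config, s)
    n <- length(rec$abp)
    nominal <- seq(1L, n - wl + 1L, by = sl)
    starts <- unique(vapply(nominal, function(s0) {
      cand <- rec$beat_onsets[rec$beat_onsets <= s0]
      if (length(cand)) cand[length(cand)] else s0
    }, integer(1)))
    for (st in starts) {
      idx <- st:(st + wl - 1L)
      in_win <- which(rec$beat_onsets >= st & rec$beat_onsets <= st + wl - 1L)
      if (length(in_win) == 0L) next
      rows_ppg[[length(rows_ppg) + 1L]] <- rec$ppg[idx]
      rows_ecg[[length(rows_ecg) + 1L]] <- rec$ecg[idx]
      rows_abp[[length(rows_abp) + 1L]] <- rec$abp[idx]
      sbp <- c(sbp, mean(rec$sbp_per_beat[in_win]))
      dbp <- c(dbp, mean(rec$dbp_per_beat[in_win]))
      subject <- c(subject, rec$subject_id)
      win_beats[[length(win_beats) + 1L]] <-
        list(sbp = rec$sbp_per_beat[in_win], dbp = rec$dbp_per_beat[in_win],
             onsets = rec$beat_onsets[in_win] - st + 1L)
    }
  }
  structure(
    list(ppg = do.call(rbind, rows_ppg), ecg = do.call(rbind, rows_ecg),
         abp = do.call(rbind, rows_abp), sbp = sbp, dbp = dbp,
         subject = subject, beats = win_beats,
         fs = config$fs, window_s = window_s, stride_s = stride_s,
         config = config),
    class = "bp_dataset"
  )
}

#' @export
print.bp_dataset <- function(x, ...) {
  cat(sprintf(
    "<bp_dataset: %d windows (%g s @ %g Hz) from %d subjects>\n",
    nrow(x$ppg), x$window_s, x$fs, length(unique(x$subject))))
  invisible(x)
}

#' Extract the model input matrix for a channel configuration
#'
#' @param dataset A `bp_dataset`.
#' @param channels `"ppg"` or `"ppg_ecg"`; the latter concatenates channels
#'   column-wise (PPG first).
#' @return Numeric matrix, one window per row.
#' @export
dataset_inputs <- function(dataset, channels = c("ppg", "ppg_ecg")) {
  channels <- match.arg(channels)
  if (channels == "ppg") dataset$ppg else cbind(dataset$ppg, dataset$ecg)
}
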