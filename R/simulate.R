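#' Configuration for a synthetic CKC recording
#'
#' Defines the conditions of a simulated physiotherapist-assisted passive
#' wrist-movement block: periodic 2 Hz flexion-extension with half-cycle
#' timing jitter and metronome-following drift correction, a focal cortical
#' source over the sensorimotor electrodes contralateral to the moved hand,
#' phase-locked to the movement at the fundamental frequency (F0) and its
#' first harmonic (F1), on top of 1/f background EEG, with optional blink
#' artifacts, gel-bridged electrode pairs and accelerometer 8th-bit flip
#' artifacts.
#'
#' @param movement_rate_hz fundamental movement rate (Hz); protocol rate 2
#' @param period_jitter_ms target interquartile range of the peak-to-peak
#'   movement periods (ms); the study-like regime is 20-26 ms
#' @param correction_gain per-half-cycle gain with which the simulated agent
#'   corrects phase drift relative to the pacing metronome (0 = free-running
#'   random walk, 1 = full correction each half-cycle)
#' @param movement_amplitude_m displacement amplitude of the wrist (m);
#'   total excursion is twice this value
#' @param movement_harmonic relative amplitude of the second displacement
#'   harmonic; makes the trajectory non-sinusoidal so the acceleration
#'   carries power at F1 as real wrist kinematics do
#' @param harmonic_ratio relative amplitude of the cortical source component
#'   at F1 versus F0
#' @param source_channel electrode at the centre of the coupled cortical
#'   source (defaults to C3, contralateral to right-hand movement)
#' @param source_snr ratio of coupled source variance to background EEG
#'   variance at the source channel
#' @param source_width_m standard deviation of the Gaussian spatial falloff
#'   of the source topography, as chord distance on the unit sphere
#' @param n_channels 63 (full montage) or 61 (without O1/O2)
#' @param eeg_fs_hz,accel_fs_hz sampling rates (Hz)
#' @param duration_s block length (s)
#' @param background_sd_uv standard deviation of the 1/f background (uV)
#' @param one_over_f_alpha spectral exponent of the background (power ~
#'   1/f^alpha)
#' @param blink_rate_hz mean blink rate (Hz); 0 disables blinks
#' @param blink_amplitude_uv blink peak amplitude at the frontal pole (uV)
#' @param bridged_pairs list of 2-element character vectors of electrode
#'   labels to be gel-bridged (replaced by their pairwise average)
#' @param bitflip_prob per-sample, per-axis probability of an accelerometer
#'   8th-bit flip; must be < 0.01
#' @param accel_clock_offset_s constant offset of the accelerometer clock
#'   relative to the EEG clock (s)
#' @param accel_clock_drift relative rate error of the accelerometer clock
#' @param hand which hand is moved ("left" or "right"); metadata only
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output
#' @return a validated list of class \code{ckc_sim_config}
#' @export
sim_config <- function(movement_rate_hz = 2,
                       period_jitter_ms = 23,
                       correction_gain = 0.5,
                       movement_amplitude_m = 0.015,
                       movement_harmonic = 0.2,
                       harmonic_ratio = 0.5,
                       source_channel = "C3",
                       source_snr = 1.0,
                       source_width_m = 0.35,
                       n_channels = 63,
                       eeg_fs_hz = 2000,
                       accel_fs_hz = 1094,
                       duration_s = 140,
                       background_sd_uv = 10,
                       one_over_f_alpha = 1,
                       blink_rate_hz = 0.15,
                       blink_amplitude_uv = 80,
                       bridged_pairs = list(),
                       bitflip_prob = 0,
                       accel_clock_offset_s = 0.05,
                       accel_clock_drift = 2e-5,
                       hand = c("right", "left"),
                       seed = 1L) {
  hand <- match.arg(hand)
  stopifnot(movement_rate_hz > 0, duration_s > 0,
            bitflip_prob >= 0, bitflip_prob < 0.01,
            eeg_fs_hz > 0, accel_fs_hz > 0,
            correction_gain > 0, correction_gain <= 1,
            source_snr >= 0, period_jitter_ms >= 0,
            seed == as.integer(seed), abs(seed) < 2^30)
  if (!n_channels %in% c(61, 63))
    stop("n_channels must be 61 or 63")
  ## half-cycle jitter SD such that IQR(period) ~ period_jitter_ms
  ## (period variance is 2*sigma_j^2 under drift-corrected construction)
  sigma_j <- period_jitter_ms / 1000 / (1.349 * sqrt(2))
  half_nom <- 1 / (2 * movement_rate_hz)
  if (5 * sigma_j >= half_nom)
    stop("period_jitter_ms too large: half-cycles would become non-positive")
  cfg <- as.list(environment())
  structure(cfg, class = "ckc_sim_config")
}

## internal: half-cycle boundary times of the jittered, drift-corrected
## movement, extended a little beyond [0, duration] on both sides
sim_half_cycles <- function(config) {
  h <- config$half_nom
  pre <- ceiling((1 + abs(config$accel_clock_offset_s)) / h) + 2L
  n_half <- as.integer(ceiling(config$duration_s / h)) + 2L * pre
  j <- rnorm(n_half, 0, config$sigma_j)
  e <- numeric(n_half + 1L)
  hk <- numeric(n_half)
  for (k in seq_len(n_half)) {
    hk[k] <- max(0.2 * h, h - config$correction_gain * e[k] + j[k])
    e[k + 1L] <- e[k] + hk[k] - h
  }
  t0 <- -pre * h
  list(times = t0 + c(0, cumsum(hk)), first_index = -pre)
}

## internal: movement phase (rad) and half-cycle length at times t (s);
## phase is pi * (half-cycle index + within-cycle fraction), with maxima of
## the displacement at even multiples of pi
sim_phase <- function(half, t) {
  k <- findInterval(t, half$times, rightmost.closed = TRUE)
  k[k < 1L] <- 1L
  k[k >= length(half$times)] <- length(half$times) - 1L
  len <- half$times[k + 1L] - half$times[k]
  u <- (t - half$times[k]) / len
  list(phi = pi * ((k - 1L + half$first_index) + u), len = len)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulate the passive wrist movement and its accelerometer trace
#'
#' Builds a quasi-periodic displacement from half-cycles whose durations are
#' drawn around the nominal half-period with the configured jitter and
#' corrected toward the nominal phase (metronome following, so long-run
#' drift is bounded). The acceleration is the analytic second derivative of
#' the displacement, projected onto three sensor axes by a fixed random
#' orientation, with gravity as a constant offset on the third axis, and
#' quantized to accelerometer resolution steps (16 bit over +/- 4 g).
#'
#' @param config a \code{\link{sim_config}}
#' @return list with \code{displacement} (m, at the accelerometer sample
#'   times), \code{accel} (a \code{\link{accel_trace}} in resolution steps,
#'   timestamped in the accelerometer clock), \code{peak_times} (true
#'   displacement maxima, s, EEG clock), \code{orientation} (unit 3-vector
#'   of the projection axis) and \code{half} (half-cycle boundaries).
#' @export
simulate_movement <- function(config) {
  stopifnot(inherits(config, "ckc_sim_config"))
  with_seed(config$seed, {
    ## fixed random sensor orientation (first draws of the stream)
    o <- rnorm(3)
    o <- o / sqrt(sum(o^2))
    half <- sim_half_cycles(config)
  })

  fs <- config$accel_fs_hz
  m <- floor(config$duration_s * fs)
  ts_accel <- (0:(m - 1L)) / fs                        # accelerometer clock
  t_real <- ts_accel / (1 + config$accel_clock_drift) - config$accel_clock_offset_s

  ph <- sim_phase(half, t_real)
  A <- config$movement_amplitude_m
  kap <- config$movement_harmonic
  disp <- A * (cos(ph$phi) + kap * cos(2 * ph$phi))
  ## angular-rate-squared interpolated across half-cycle midpoints so the
  ## acceleration is continuous at the boundaries (a real limb does not
  ## jerk instantaneously when the cycle duration drifts)
  nh <- length(half$times) - 1L
  mid_t <- (half$times[-1] + half$times[-(nh + 1L)]) / 2
  om2 <- stats::approx(mid_t, (pi / diff(half$times))^2, xout = t_real,
                       rule = 2)$y
  acc <- -A * om2 * (cos(ph$phi) + 4 * kap * cos(2 * ph$phi))

  g <- 9.80665
  axes <- rbind(o[1] * acc, o[2] * acc, o[3] * acc)
  axes[3, ] <- axes[3, ] + g
  steps_per_g <- 2^16 / (2 * 4)                        # 8192 steps per g
  steps <- round(axes / g * steps_per_g)
  steps[steps > 32767] <- 32767
  steps[steps < -32768] <- -32768

  ev_real <- c(0.5, config$duration_s - 0.5)
  ev_accel <- (ev_real + config$accel_clock_offset_s) * (1 + config$accel_clock_drift)

  ## boundaries with even phase index are displacement maxima
  phase_index <- (seq_along(half$times) - 1L) + half$first_index
  maxima <- half$times[phase_index %% 2L == 0L]
  maxima <- maxima[maxima >= 0 & maxima <= config$duration_s]

  list(displacement = disp,
       accel = accel_trace(steps, ts_accel, fs_hz = fs, range_g = 4,
                           sync_events = ev_accel),
       peak_times = maxima,
       orientation = o,
       half = half)
}

## internal: 1/f^alpha noise, unit variance, via spectral shaping
one_over_f_noise <- function(n, fs, alpha) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                                 # two-sided frequencies
  sc <- c(0, f[-1]^(-alpha / 2))
  x <- Re(fft(W * sc, inverse = TRUE)) / n
  x / sd(x)
}

#' Simulate a coupled EEG + accelerometer recording
#'
#' Generates a full synthetic block: per-channel 1/f background EEG plus a
#' coupled cortical source (components at F0 and F1, phase-locked to the
#' simulated movement) with Gaussian spatial falloff centred on
#' \code{source_channel}, blink transients weighted toward frontal channels
#' and mirrored into the EOG channels, optional gel-bridged pairs (replaced
#' by their pairwise average) and accelerometer 8th-bit flips. TTL sync
#' events are embedded in both streams.
#'
#' @param config a \code{\link{sim_config}}
#' @return a \code{ckc_recording}: list with \code{eeg} (channels x samples,
#'   uV), \code{eog} (2 x samples), \code{fs_hz}, \code{montage},
#'   \code{labels}, \code{accel} (see \code{\link{accel_trace}}),
#'   \code{events} (TTL times, EEG clock), \code{hand}, and \code{truth}
#'   (ground-truth components for oracle tests).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "ckc_sim_config"))
  mont <- ckc_montage()
  if (config$n_channels == 61)
    mont <- montage_subset(mont, setdiff(mont$labels, c("O1", "O2")))
  if (!config$source_channel %in% mont$labels)
    stop("unknown source_channel: ", config$source_channel)
  for (bp in config$bridged_pairs) {
    if (length(bp) != 2 || !all(bp %in% mont$labels))
      stop("bridged_pairs must be pairs of montage labels")
  }

  mv <- simulate_movement(config)
  n_ch <- length(mont$labels)
  fs <- config$eeg_fs_hz
  n <- floor(config$duration_s * fs)
  t_eeg <- (0:(n - 1L)) / fs

  with_seed(config$seed + 7654321L, {
    eeg <- matrix(0, n_ch, n, dimnames = list(mont$labels, NULL))
    for (c_i in seq_len(n_ch))
      eeg[c_i, ] <- one_over_f_noise(n, fs, config$one_over_f_alpha)
    eeg <- eeg * config$background_sd_uv

    ## coupled source, phase-locked to the movement
    ph <- sim_phase(mv$half, t_eeg)
    src <- cos(ph$phi) + config$harmonic_ratio * cos(2 * ph$phi)
    src <- src / sd(src)
    d2 <- colSums((t(mont$positions) - mont$positions[config$source_channel, ])^2)
    w_src <- exp(-d2 / (2 * config$source_width_m^2))
    src_amp <- sqrt(config$source_snr) * config$background_sd_uv
    eeg <- eeg + outer(w_src * src_amp, src)

    ## blinks: smooth transients, frontal-weighted, mirrored into EOG
    blink <- numeric(n)
    if (config$blink_rate_hz > 0) {
      n_blink <- rpois(1, config$blink_rate_hz * config$duration_s)
      if (n_blink > 0) {
        times <- sort(runif(n_blink, 0.5, config$duration_s - 0.5))
        blen <- round(0.35 * fs)
        bump <- (sin(pi * seq_len(blen) / (blen + 1)))^2
        for (bt in times) {
          i0 <- round(bt * fs)
          blink[i0:(i0 + blen - 1L)] <- blink[i0:(i0 + blen - 1L)] + bump
        }
      }
    }
    d2f <- colSums((t(mont$positions) - mont$positions["Fpz", ])^2)
    w_blink <- exp(-d2f / (2 * 0.5^2)) * config$blink_amplitude_uv
    if (any(blink != 0)) eeg <- eeg + outer(w_blink, blink)

    eog <- rbind(
      VEOG = 1.8 * config$blink_amplitude_uv * blink +
        config$background_sd_uv * one_over_f_noise(n, fs, config$one_over_f_alpha),
      HEOG = 0.2 * config$blink_amplitude_uv * blink +
        config$background_sd_uv * one_over_f_noise(n, fs, config$one_over_f_alpha))

    ## gel bridges: both members carry the pairwise average
    for (bp in config$bridged_pairs) {
      avg <- (eeg[bp[1], ] + eeg[bp[2], ]) / 2
      eeg[bp[1], ] <- avg
      eeg[bp[2], ] <- avg
    }

    ## accelerometer 8th-bit flips
    accel <- mv$accel
    if (config$bitflip_prob > 0) {
      s <- accel$samples
      flip <- matrix(runif(length(s)) < config$bitflip_prob, nrow(s), ncol(s))
      bit <- floor((s + 32768) / 128) %% 2
      s[flip] <- s[flip] + ifelse(bit[flip] == 1, -128, 128)
      accel$samples <- s
    }
  })

  structure(list(
    eeg = eeg, eog = eog, fs_hz = fs,
    montage = mont, labels = mont$labels,
    accel = accel,
    events = c(0.5, config$duration_s - 0.5),
    hand = config$hand,
    reference = "nose",
    provenance = list(),
    truth = list(peak_times = mv$peak_times,
                 orientation = mv$orientation,
                 displacement = mv$displacement,
                 source_wave = src * src_amp,
                 source_weights = w_src,
                 blink_wave = blink,
                 blink_weights = w_blink,
                 config = config)),
    class = "ckc_recording")
}

#' @export
print.ckc_recording <- function(x, ...) {
  cat("<ckc_recording> ", nrow(x$eeg), " EEG + ", nrow(x$eog),
      " EOG channels, ", ncol(x$eeg), " samples @ ", x$fs_hz, " Hz; hand = ",
      x$hand, "\n", sep = "")
  invisible(x)
}

#' Write a recording to a self-describing directory container
#'
#' Plain-text container: per-stream CSV files (eeg, eog, accel, events) and
#' a JSON metadata file. Intended for interchange and inspection, not for
#' speed.
#'
#' @param rec a \code{ckc_recording}
#' @param path directory to create
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(t(rec$eeg)), file.path(path, "eeg.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(t(rec$eog)), file.path(path, "eog.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(t = rec$accel$timestamps,
                              ax = rec$accel$samples[1, ],
                              ay = rec$accel$samples[2, ],
                              az = rec$accel$samples[3, ]),
                   file.path(path, "accel.csv"), row.names = FALSE)
  meta <- list(fs_hz = rec$fs_hz, labels = rec$labels, hand = rec$hand,
               reference = rec$reference, events = rec$events,
               accel_fs_hz = rec$accel$fs_hz,
               accel_sync_events = rec$accel$sync_events)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  invisible(path)
}
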