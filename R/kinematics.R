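#' Timestamped 3-axis accelerometer trace
#'
#' @param samples 3 x N matrix, in accelerometer resolution steps (16-bit
#'   over +/- \code{range_g}) or m/s^2
#' @param timestamps per-sample times (s), strictly increasing
#' @param fs_hz nominal sampling rate
#' @param range_g full-scale range in g
#' @param sync_events TTL event times in the accelerometer clock
#' @return an object of class \code{ckc_accel_trace}
#' @export
accel_trace <- function(samples, timestamps, fs_hz = 1094, range_g = 4,
                        sync_events = numeric(0)) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == 3, length(timestamps) == ncol(samples),
            all(diff(timestamps) > 0))
  structure(list(samples = samples, timestamps = as.numeric(timestamps),
                 fs_hz = fs_hz, range_g = range_g,
                 sync_events = as.numeric(sync_events)),
            class = "ckc_accel_trace")
}

#' Read a timestamped accelerometer log (CSV/TSV)
#'
#' Expects columns \code{t, ax, ay, az} and optionally \code{event}
#' (non-zero rows mark TTL sync events).
#'
#' @param file path to the log
#' @param fs_hz nominal rate
#' @param range_g full-scale range in g
#' @return a \code{\link{accel_trace}}
#' @export
read_accel_csv <- function(file, fs_hz = 1094, range_g = 4) {
  df <- utils::read.csv(file, sep = if (grepl("\\.tsv$", file)) "\t" else ",")
  ev <- if ("event" %in% names(df)) df$t[df$event != 0] else numeric(0)
  accel_trace(t(as.matrix(df[, c("ax", "ay", "az")])), df$t,
              fs_hz = fs_hz, range_g = range_g, sync_events = ev)
}

#' Repair single-sample 8th-bit flip artifacts
#'
#' A flipped 8th bit shows as a single-sample excursion of +/- 128
#' resolution steps: consecutive first differences exceeding 127 steps in
#' opposite directions. Flagged samples are replaced by the mean of their
#' two neighbours; runs of adjacent flips are repaired iteratively.
#'
#' @param trace a \code{\link{accel_trace}} in raw resolution steps
#' @param threshold_steps detection threshold on consecutive opposite-sign
#'   first differences (resolution steps)
#' @param max_pass maximal number of repair passes
#' @return the repaired trace, with attribute \code{n_corrections}
#' @export
correct_bit_flips <- function(trace, threshold_steps = 127, max_pass = 8L) {
  stopifnot(inherits(trace, "ckc_accel_trace"))
  s <- trace$samples
  total <- 0L
  for (pass in seq_len(max_pass)) {
    n_fixed <- 0L
    for (ax in 1:3) {
      x <- s[ax, ]
      d <- diff(x)
      up_down <- which(d[-length(d)] > threshold_steps &
                         d[-1] < -threshold_steps) + 1L
      down_up <- which(d[-length(d)] < -threshold_steps &
                         d[-1] > threshold_steps) + 1L
      bad <- union(up_down, down_up)
      if (length(bad)) {
        ## rebuild flagged samples from the nearest unflagged neighbours,
        ## so adjacent flagged runs do not repair from each other
        good <- setdiff(seq_along(x), bad)
        x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
        s[ax, ] <- x
        n_fixed <- n_fixed + length(bad)
      }
    }
    total <- total + n_fixed
    if (n_fixed == 0L) break
  }
  out <- trace
  out$samples <- s
  attr(out, "n_corrections") <- total
  out
}

## internal: Kaiser-window FIR high-pass, designed from cutoff (Hz),
## transition width (Hz) and stopband attenuation (dB). Tap count follows
## the standard Kaiser estimate n = ceil((A - 7.95) / (2.285 * dw)) + 1
## (12209 taps at fs = 1094, 0.2 Hz cutoff / 0.2 Hz width / 40 dB),
## rounded up to odd length so the zero-phase delay is an integer.
kaiser_highpass <- function(fs, cutoff = 0.2, width = 0.2, atten_db = 40) {
  dw <- 2 * pi * width / fs
  n <- ceiling((atten_db - 7.95) / (2.285 * dw)) + 1
  if (n %% 2 == 0) n <- n + 1
  beta <- if (atten_db > 50) 0.1102 * (atten_db - 8.7)
          else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 +
            0.07886 * (atten_db - 21)
          else 0
  m <- (n - 1) / 2
  k <- seq_len(n) - 1 - m
  fc <- cutoff / (fs / 2)                       # normalized (Nyquist = 1)
  lp <- fc * sinc(fc * k) * as.numeric(signal::kaiser(n, beta))
  lp <- lp / sum(lp)                            # unit (exact) DC gain
  hp <- -lp
  hp[m + 1] <- hp[m + 1] + 1                    # spectral inversion
  hp
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

## internal: zero-phase application of a symmetric odd-length FIR via FFT
## convolution, with exact group-delay compensation and odd-reflection
## padding at both ends to suppress edge transients
fir_filt_zerophase <- function(b, x) {
  n <- length(x); l <- length(b)
  m <- (l - 1) / 2
  pad <- min(m, n - 1L)
  xe <- c(2 * x[1] - x[(pad + 1L):2],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  ne <- length(xe)
  nfft <- 2^ceiling(log2(ne + l - 1))
  y <- Re(fft(fft(c(xe, numeric(nfft - ne))) *
                fft(c(b, numeric(nfft - l))), inverse = TRUE)) / nfft
  y[(m + pad + 1):(m + pad + n)]
}

#' Estimate displacement from 3-axis acceleration by double integration
#'
#' The trace is resampled onto a uniform grid (linear interpolation over
#' the timestamps), then each axis goes twice through: Kaiser-FIR high-pass
#' (zero-phase), cumulative trapezoidal integration, and subtraction of the
#' median signal — a running-median baseline over a window of a few
#' movement cycles — which compensates the drift the integration
#' accumulates (a global median would only re-centre it).
#'
#' @param trace a \code{\link{accel_trace}} (resolution steps or m/s^2; the
#'   output is in the input unit times s^2)
#' @param cutoff_hz,width_hz,atten_db high-pass design parameters
#' @param median_window_s length of the running-median baseline window (s)
#' @return list with \code{displacement} (3 x N), \code{fs_hz} and
#'   \code{time} (s, uniform grid in the trace's clock)
#' @export
estimate_displacement <- function(trace, cutoff_hz = 0.2, width_hz = 0.2,
                                  atten_db = 40, median_window_s = 1) {
  stopifnot(inherits(trace, "ckc_accel_trace"))
  fs <- trace$fs_hz
  tt <- trace$timestamps
  tu <- seq(tt[1], tt[length(tt)], by = 1 / fs)
  b <- kaiser_highpass(fs, cutoff_hz, width_hz, atten_db)
  if (length(tu) <= length(b))
    stop("trace shorter than the high-pass filter (", length(b), " taps)")
  k <- round(median_window_s * fs)
  if (k %% 2 == 0) k <- k + 1
  disp <- matrix(0, 3, length(tu))
  for (ax in 1:3) {
    x <- stats::approx(tt, trace$samples[ax, ], xout = tu)$y
    for (pass in 1:2) {
      x <- fir_filt_zerophase(b, x)
      x <- cumsum((x + c(x[1], x[-length(x)])) / 2) / fs   # trapezoid
      x <- x - stats::runmed(x, k, endrule = "median")
    }
    disp[ax, ] <- x
  }
  list(displacement = disp, fs_hz = fs, time = tu)
}

#' Project a 3-axis signal onto its main axis (first principal component)
#'
#' The sign of the principal axis is pinned so that its loading on the
#' raw-variance-dominant input axis is positive.
#'
#' @param signal_3axis 3 x N matrix
#' @return list with \code{signal} (length N), \code{axis} (unit loading
#'   3-vector) and \code{explained} (share of variance explained)
#' @export
main_axis <- function(signal_3axis) {
  stopifnot(nrow(signal_3axis) == 3, ncol(signal_3axis) >= 2)
  v <- apply(signal_3axis, 1, stats::var)
  if (all(v == 0)) stop("degenerate zero-variance input")
  pc <- stats::prcomp(t(signal_3axis), center = TRUE, scale. = FALSE)
  ax <- pc$rotation[, 1]
  proj <- as.numeric(ax %*% sweep(signal_3axis, 1, rowMeans(signal_3axis)))
  ## pin the arbitrary PCA sign: positive correlation with the
  ## largest-raw-variance input axis
  if (stats::cov(proj, signal_3axis[which.max(v), ]) < 0) {
    ax <- -ax
    proj <- -proj
  }
  list(signal = proj,
       axis = ax,
       explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Detect movement extrema in a 1-d displacement signal
#'
#' The signal is smoothed with a 100-sample moving average; peaks of the
#' smoothed signal (and of its negation, for minima) are detected with a
#' minimal inter-peak distance of 300 samples and a minimal prominence of
#' 1% of the smoothed signal range. Indices refer to the input timeline.
#'
#' @param signal_1d displacement at the accelerometer rate
#' @param fs_hz sampling rate (carried through to \code{peak_times})
#' @param smooth_len moving-average length (samples)
#' @param min_distance minimal inter-peak distance (samples)
#' @param prominence_frac minimal prominence as a fraction of signal range
#' @return list with \code{max_peaks}, \code{min_peaks} (sample indices)
#'   and \code{max_times}, \code{min_times} (s)
#' @export
detect_movement_peaks <- function(signal_1d, fs_hz, smooth_len = 100L,
                                  min_distance = 300L,
                                  prominence_frac = 0.01) {
  if (length(signal_1d) < smooth_len + 2L || diff(range(signal_1d)) == 0)
    stop("signal empty, constant, or shorter than the smoothing window")
  sm <- as.numeric(stats::filter(signal_1d, rep(1 / smooth_len, smooth_len),
                                 sides = 2))
  ## fill the NA margins by extension so edge peaks are not fabricated
  ok <- which(!is.na(sm))
  sm[seq_len(ok[1] - 1L)] <- sm[ok[1]]
  sm[seq(ok[length(ok)] + 1L, length.out = length(sm) - ok[length(ok)])] <-
    sm[ok[length(ok)]]
  prom <- prominence_frac * diff(range(sm))
  mx <- find_peaks(sm, min_distance = min_distance, min_prominence = prom)
  mn <- find_peaks(-sm, min_distance = min_distance, min_prominence = prom)
  list(max_peaks = mx, min_peaks = mn,
       max_times = (mx - 1L) / fs_hz, min_times = (mn - 1L) / fs_hz)
}

#' Median and IQR of peak-to-peak movement periods
#'
#' @param peaks peak sample indices (or times if \code{fs_hz = 1000} and
#'   input already in ms)
#' @param fs_hz sampling rate used to convert indices to ms
#' @return list with \code{median_ms}, \code{iqr_ms} and \code{n_periods}
#' @export
period_stats <- function(peaks, fs_hz) {
  if (length(peaks) < 3) stop("need at least 3 peaks")
  p_ms <- diff(peaks) / fs_hz * 1000
  list(median_ms = stats::median(p_ms),
       iqr_ms = stats::IQR(p_ms),
       n_periods = length(p_ms))
}

#' Median run length of periods on one side of the block median
#'
#' Partitions the period sequence into maximal runs of consecutive values
#' strictly above or strictly below the block median and returns the median
#' run length — how many movement cycles pass before the agent compensates
#' a drift from the pacing stimulus. Periods exactly equal to the median
#' terminate the current run and belong to no run.
#'
#' @param periods_ms numeric vector of successive periods
#' @return median run length (NA if every period equals the median)
#' @export
cycles_before_compensation <- function(periods_ms) {
  if (length(periods_ms) < 3) stop("need at least 3 periods")
  med <- stats::median(periods_ms)
  side <- sign(periods_ms - med)          # -1 below, 0 at, +1 above
  r <- rle(side)
  runs <- r$lengths[r$values != 0]
  if (!length(runs)) return(NA_real_)
  stats::median(runs)
}

#' Movement-regularity summary for one block
#'
#' Runs the full kinematics chain: bit-flip repair, filtered double
#' integration, PCA main axis, smoothed prominence-based peak detection and
#' period statistics, separately for maximum- and minimum-based peaks.
#'
#' @param trace a \code{\link{accel_trace}} in raw resolution steps
#' @param block_id,hand labels carried into the summary
#' @return data frame with one row per peak polarity: median/IQR of the
#'   period (ms), median cycles before compensation, and peak count
#' @export
kinematics_summary <- function(trace, block_id = 1L, hand = "right") {
  tr <- correct_bit_flips(trace)
  disp <- estimate_displacement(tr)
  pc1 <- main_axis(disp$displacement)
  pk <- detect_movement_peaks(pc1$signal, disp$fs_hz)
  rows <- lapply(list(max = pk$max_peaks, min = pk$min_peaks), function(p) {
    st <- period_stats(p, disp$fs_hz)
    data.frame(median_period_ms = st$median_ms, iqr_period_ms = st$iqr_ms,
               median_cycles_before_compensation =
                 cycles_before_compensation(diff(p) / disp$fs_hz * 1000),
               n_peaks = length(p))
  })
  out <- do.call(rbind, rows)
  out$polarity <- names(rows)
  out$block_id <- block_id
  out$hand <- hand
  out$n_bitflip_corrections <- attr(tr, "n_corrections")
  rownames(out) <- NULL
  out
}
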