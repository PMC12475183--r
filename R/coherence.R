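#' Synchronize and summarize the accelerometer for coherence analysis
#'
#' Aligns the accelerometer clock to the EEG clock by a two-point linear
#' fit on the first and last TTL sync events, low-pass filters the three
#' axes at 50 Hz, resamples them onto the EEG sample grid, and reduces them
#' to one channel either as the Euclidean norm of the median-subtracted
#' axes (\code{"magnitude"}; the median subtraction discounts gravity) or
#' as the first principal component (\code{"pca"}).
#'
#' @param trace a \code{\link{accel_trace}} with sync events
#' @param events_eeg TTL event times in the EEG clock (s)
#' @param eeg_fs_hz EEG sampling rate
#' @param n_samples number of EEG samples to align to
#' @param method \code{"magnitude"} or \code{"pca"}
#' @param lowpass_hz accelerometer low-pass edge
#' @return list of class \code{ckc_accel_summary} with \code{signal}
#'   (length \code{n_samples}), \code{method} and \code{provenance}
#' @export
prepare_accel <- function(trace, events_eeg, eeg_fs_hz = 2000, n_samples,
                          method = c("magnitude", "pca"), lowpass_hz = 50) {
  method <- match.arg(method)
  if (length(trace$sync_events) < 2 || length(events_eeg) < 2)
    stop("need at least two sync events in both streams")
  ev_a <- range(trace$sync_events)
  ev_e <- range(events_eeg)
  slope <- diff(ev_e) / diff(ev_a)
  t_eeg_of_sample <- ev_e[1] + (trace$timestamps - ev_a[1]) * slope

  lp <- signal::butter(4, lowpass_hz / (trace$fs_hz / 2), type = "low")
  t_target <- (seq_len(n_samples) - 1L) / eeg_fs_hz
  axes <- matrix(0, 3, n_samples)
  for (ax in 1:3) {
    x <- trace$samples[ax, ]
    ## remove the gravity offset before filtering: a large DC level would
    ## otherwise excite filter startup transients at the block edges
    xf <- signal::filtfilt(lp, x - stats::median(x))
    axes[ax, ] <- stats::approx(t_eeg_of_sample, xf, xout = t_target,
                                rule = 2)$y
  }
  sig <- if (method == "magnitude") {
    ctr <- axes - apply(axes, 1, stats::median)
    sqrt(colSums(ctr^2))
  } else {
    main_axis(axes)$signal
  }
  structure(list(signal = sig, method = method, fs_hz = eeg_fs_hz,
                 provenance = list(lowpass_hz = lowpass_hz,
                                   sync_slope = slope,
                                   sync_offset = ev_e[1] - ev_a[1] * slope)),
            class = "ckc_accel_summary")
}

## internal: windowed, constant-detrended segment FFTs.
## Returns complex matrix (n_freq x n_segments), one-sided bins 0..fs/2.
seg_spectra <- function(x, seg_len, step, win) {
  starts <- seq(1L, length(x) - seg_len + 1L, by = step)
  idx <- outer(0:(seg_len - 1L), starts, "+")
  segs <- matrix(x[idx], seg_len, length(starts))
  segs <- sweep(segs, 2, colMeans(segs))
  segs <- segs * win
  stats::mvfft(segs)[1:(seg_len %/% 2 + 1L), , drop = FALSE]
}

## internal: coherence from per-segment spectra of x and y, by mean or by
## median across segments (median taken on Pxx, Pyy and on the real and
## imaginary parts of Pxy separately)
coherence_from_segs <- function(X, Y, averaging = c("mean", "median")) {
  averaging <- match.arg(averaging)
  pxx <- Mod(X)^2
  pyy <- Mod(Y)^2
  pxy <- Conj(X) * Y
  if (averaging == "mean") {
    sxx <- rowMeans(pxx); syy <- rowMeans(pyy)
    sxy <- rowMeans(Re(pxy)) + 1i * rowMeans(Im(pxy))
  } else {
    ## median of each row via one radix sort (fast path for many bins)
    rowmed <- function(m) {
      k <- ncol(m)
      s <- matrix(m[order(row(m), m)], nrow(m), k, byrow = TRUE)
      if (k %% 2) s[, (k + 1) %/% 2] else (s[, k %/% 2] + s[, k %/% 2 + 1]) / 2
    }
    sxx <- rowmed(pxx); syy <- rowmed(pyy)
    sxy <- rowmed(Re(pxy)) + 1i * rowmed(Im(pxy))
  }
  denom <- sxx * syy
  coh <- ifelse(denom > 0, Mod(sxy)^2 / denom, 0)
  pmin(pmax(coh, 0), 1)
}

#' Welch magnitude-squared coherence with mean or median averaging
#'
#' Standard Welch estimation (Hann window, constant detrending per
#' segment, overlapping segments) of \eqn{C_{xy} = |P_{xy}|^2 /
#' (P_{xx} P_{yy})}, where the per-segment auto- and cross-periodograms are
#' aggregated across segments either by the mean (classical) or by the
#' median (robust to transient outliers; the median of the cross-spectrum
#' is taken on real and imaginary parts separately). Zero-power bins are
#' reported as 0 coherence; values are clipped to [0, 1].
#'
#' @param x,y equal-length numeric signals
#' @param fs sampling rate (Hz)
#' @param segment_s segment length (s); the frequency resolution is
#'   \code{1/segment_s}
#' @param overlap fractional segment overlap
#' @param averaging \code{"mean"} or \code{"median"}
#' @return list with \code{freqs} (Hz) and \code{coherence}
#' @export
welch_coherence <- function(x, y, fs, segment_s, overlap = 0.8,
                            averaging = c("mean", "median")) {
  stopifnot(length(x) == length(y))
  seg_len <- round(segment_s * fs)
  step <- max(1L, round(seg_len * (1 - overlap)))
  if (length(x) < seg_len + step) stop("fewer than 2 segments")
  win <- hann_window(seg_len)
  X <- seg_spectra(x, seg_len, step, win)
  Y <- seg_spectra(y, seg_len, step, win)
  coh <- coherence_from_segs(X, Y, averaging)
  list(freqs = (seq_len(nrow(X)) - 1L) * fs / seg_len, coherence = coh)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Corticokinematic coherence spectra for one recording
#'
#' Coherence between every EEG channel and one accelerometer summary, as a
#' channels x frequencies matrix.
#'
#' @param eeg channels x samples matrix (typically CSD-transformed)
#' @param accel a \code{\link{ckc_accel_summary}} (or numeric vector)
#' @param fs sampling rate
#' @param segment_s segment length (s)
#' @param overlap fractional overlap
#' @param averaging \code{"mean"} or \code{"median"}
#' @param fmax highest frequency retained (Hz)
#' @param labels channel labels (default rownames)
#' @return object of class \code{ckc_cohspec}: list with \code{values}
#'   (channels x freqs), \code{freqs_hz}, \code{resolution_hz},
#'   \code{averaging}, \code{accel_method}, \code{segment_s},
#'   \code{overlap}, \code{labels}
#' @export
ckc_coherence <- function(eeg, accel, fs, segment_s, overlap = 0.8,
                          averaging = c("mean", "median"), fmax = 100,
                          labels = rownames(eeg)) {
  averaging <- match.arg(averaging)
  acc_sig <- if (inherits(accel, "ckc_accel_summary")) accel$signal else accel
  acc_method <- if (inherits(accel, "ckc_accel_summary")) accel$method else "raw"
  stopifnot(ncol(eeg) == length(acc_sig))
  seg_len <- round(segment_s * fs)
  step <- max(1L, round(seg_len * (1 - overlap)))
  if (ncol(eeg) < seg_len + step) stop("fewer than 2 segments")
  win <- hann_window(seg_len)
  freqs <- (seq_len(seg_len %/% 2 + 1L) - 1L) * fs / seg_len
  keep <- which(freqs <= fmax)
  Y <- seg_spectra(acc_sig, seg_len, step, win)[keep, , drop = FALSE]
  vals <- matrix(0, nrow(eeg), length(keep),
                 dimnames = list(labels, NULL))
  for (i in seq_len(nrow(eeg))) {
    X <- seg_spectra(eeg[i, ], seg_len, step, win)[keep, , drop = FALSE]
    vals[i, ] <- coherence_from_segs(X, Y, averaging)
  }
  structure(list(values = vals, freqs_hz = freqs[keep],
                 resolution_hz = 1 / segment_s, averaging = averaging,
                 accel_method = acc_method, segment_s = segment_s,
                 overlap = overlap, labels = labels),
            class = "ckc_cohspec")
}

#' @export
print.ckc_cohspec <- function(x, ...) {
  cat("<ckc_cohspec> ", nrow(x$values), " channels x ", ncol(x$values),
      " bins; ", x$accel_method, "-", x$averaging, " @ ", x$resolution_hz,
      " Hz resolution\n", sep = "")
  invisible(x)
}

#' Full method-by-resolution CKC grid
#'
#' Computes coherence for the four method combinations (accelerometer
#' summarized by Euclidean magnitude or first principal component; spectra
#' aggregated by mean or median) at the four segment lengths 1, 2, 4 and
#' 8 s (frequency resolutions 1, 0.5, 0.25 and 0.125 Hz), i.e. 16 spectra.
#'
#' @param rec a CSD-transformed \code{ckc_recording}
#' @param segment_lengths_s segment lengths (s)
#' @param fmax highest retained frequency (Hz)
#' @return list of 16 \code{ckc_cohspec}, named
#'   \code{<method>-<averaging>-<resolution>}
#' @export
ckc_grid <- function(rec, segment_lengths_s = c(1, 2, 4, 8), fmax = 50) {
  summaries <- list(
    magnitude = prepare_accel(rec$accel, rec$events, rec$fs_hz,
                              ncol(rec$eeg), "magnitude"),
    pca = prepare_accel(rec$accel, rec$events, rec$fs_hz,
                        ncol(rec$eeg), "pca"))
  out <- list()
  for (seg_s in segment_lengths_s) {
    seg_len <- round(seg_s * rec$fs_hz)
    step <- max(1L, round(seg_len * 0.2))
    win <- hann_window(seg_len)
    freqs <- (seq_len(seg_len %/% 2 + 1L) - 1L) * rec$fs_hz / seg_len
    keep <- which(freqs <= fmax)
    ## channel spectra once per segment length, shared by all four methods
    Xs <- lapply(seq_len(nrow(rec$eeg)), function(i)
      seg_spectra(rec$eeg[i, ], seg_len, step, win)[keep, , drop = FALSE])
    for (mth in names(summaries)) {
      Y <- seg_spectra(summaries[[mth]]$signal, seg_len, step,
                       win)[keep, , drop = FALSE]
      vals <- list(mean = matrix(0, nrow(rec$eeg), length(keep),
                                 dimnames = list(rec$labels, NULL)),
                   median = matrix(0, nrow(rec$eeg), length(keep),
                                   dimnames = list(rec$labels, NULL)))
      for (i in seq_len(nrow(rec$eeg))) {
        vals$mean[i, ] <- coherence_from_segs(Xs[[i]], Y, "mean")
        vals$median[i, ] <- coherence_from_segs(Xs[[i]], Y, "median")
      }
      for (avg in c("mean", "median")) {
        key <- sprintf("%s-%s-%g", mth, avg, 1 / seg_s)
        out[[key]] <- structure(
          list(values = vals[[avg]], freqs_hz = freqs[keep],
               resolution_hz = 1 / seg_s, averaging = avg,
               accel_method = mth, segment_s = seg_s, overlap = 0.8,
               labels = rec$labels),
          class = "ckc_cohspec")
      }
    }
    rm(Xs)
  }
  out
}

## internal: index of an exact frequency bin
freq_bin <- function(spec, f) {
  i <- which(abs(spec$freqs_hz - f) < 1e-9)
  if (!length(i)) stop("frequency ", f, " Hz is not on the ",
                       spec$resolution_hz, " Hz grid")
  i
}

#' Coherence SNR in dB relative to a baseline frequency
#'
#' \code{20 * log10(C(f_target) / C(f_baseline))} per channel. The 3 Hz
#' baseline bin exists at every tested resolution. Channels with zero
#' baseline coherence give \code{Inf}.
#'
#' @param spec a \code{ckc_cohspec}
#' @param f_target target frequency (Hz)
#' @param f_baseline baseline frequency (Hz)
#' @return named numeric vector of per-channel SNR (dB)
#' @export
snr_db <- function(spec, f_target, f_baseline = 3) {
  ct <- spec$values[, freq_bin(spec, f_target)]
  cb <- spec$values[, freq_bin(spec, f_baseline)]
  20 * log10(ct / cb)
}

#' Peak CKC metrics for one spectrum
#'
#' Maximum coherence and its channel at F0 and F1 over the analysis
#' subset, SNR (vs 3 Hz) at the peak channels, mean coherence over the
#' left and right 12-channel sets, and the contra/ipsilateral assignment
#' given the moved hand.
#'
#' @param spec a \code{ckc_cohspec}
#' @param montage the recording's montage (provides the subsets)
#' @param hand moved hand, \code{"left"} or \code{"right"}
#' @param f0,f1 fundamental and harmonic frequencies (Hz)
#' @param profile_freqs frequencies at which the subset-max coherence is
#'   profiled (NA where off-grid)
#' @return one-row data frame of metrics
#' @export
peak_metrics <- function(spec, montage, hand = c("right", "left"),
                         f0 = 2, f1 = 4,
                         profile_freqs = c(1.5, 2, 2.5, 3, 3.5, 4, 4.5)) {
  hand <- match.arg(hand)
  sub <- intersect(montage$subsets$analysis, spec$labels)
  if (length(sub) < length(montage$subsets$analysis))
    stop("analysis subset channels missing from the spectrum")
  v <- spec$values[sub, , drop = FALSE]
  snr <- snr_db(spec, f0)[sub]
  snr1 <- snr_db(spec, f1)[sub]
  i0 <- freq_bin(spec, f0); i1 <- freq_bin(spec, f1)
  ch0 <- sub[which.max(v[, i0])]
  ch1 <- sub[which.max(v[, i1])]
  lft <- intersect(montage$subsets$left, spec$labels)
  rgt <- intersect(montage$subsets$right, spec$labels)
  mean_left0 <- mean(spec$values[lft, i0])
  mean_right0 <- mean(spec$values[rgt, i0])
  mean_left1 <- mean(spec$values[lft, i1])
  mean_right1 <- mean(spec$values[rgt, i1])
  contra0 <- if (hand == "right") mean_left0 else mean_right0
  ipsi0 <- if (hand == "right") mean_right0 else mean_left0
  contra1 <- if (hand == "right") mean_left1 else mean_right1
  ipsi1 <- if (hand == "right") mean_right1 else mean_left1
  prof <- vapply(profile_freqs, function(f) {
    i <- which(abs(spec$freqs_hz - f) < 1e-9)
    if (length(i)) max(v[, i]) else NA_real_
  }, numeric(1))
  names(prof) <- paste0("coh_", profile_freqs)
  out <- cbind(data.frame(
    accel_method = spec$accel_method, averaging = spec$averaging,
    resolution = spec$resolution_hz, hand = hand,
    f0_peak = max(v[, i0]), f0_peak_channel = ch0,
    f1_peak = max(v[, i1]), f1_peak_channel = ch1,
    snr_f0_db = snr[ch0], snr_f1_db = snr1[ch1],
    mean_left = mean_left0, mean_right = mean_right0,
    mean_left_f1 = mean_left1, mean_right_f1 = mean_right1,
    contra = contra0, ipsi = ipsi0,
    contra_f1 = contra1, ipsi_f1 = ipsi1,
    stringsAsFactors = FALSE), as.data.frame(as.list(prof)))
  rownames(out) <- NULL
  out
}
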