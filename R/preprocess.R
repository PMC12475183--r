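#' Drop channels from a recording
#'
#' Removes channels from the data and the montage consistently. Typical
#' use: dropping the noisy mastoid-adjacent TP9/TP10 electrodes and, where
#' montages differ across sessions, O1/O2.
#'
#' @param rec a \code{ckc_recording}
#' @param labels channels to drop (may be empty)
#' @return the reduced recording
#' @export
exclude_channels <- function(rec, labels) {
  if (!length(labels)) return(rec)
  missing <- setdiff(labels, rec$labels)
  if (length(missing))
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  keep <- setdiff(rec$labels, labels)
  rec$eeg <- rec$eeg[keep, , drop = FALSE]
  rec$montage <- montage_subset(rec$montage, keep)
  rec$labels <- keep
  rec$provenance$excluded <- c(rec$provenance$excluded, labels)
  rec
}

#' Detect gel-bridged electrode pairs by electrical distance
#'
#' The electrical distance of a channel pair is the variance of its
#' pairwise difference signal, computed over non-overlapping windows and
#' summarized by the median across windows. Pairs whose median electrical
#' distance falls below a small fraction of the across-pairs median are
#' flagged as bridged, up to a per-recording cap. The statistic is
#' symmetric in channel order and invariant to global amplitude scaling
#' (the cutoff is relative).
#'
#' @param rec a \code{ckc_recording}
#' @param window_s window length (s)
#' @param cutoff_frac flag pairs below \code{cutoff_frac} times the
#'   across-pairs median electrical distance
#' @param max_pairs cap on the number of flagged pairs
#' @return data frame with columns \code{ch1, ch2, electrical_distance},
#'   one row per flagged pair (0 rows if none)
#' @export
detect_bridges <- function(rec, window_s = 2, cutoff_frac = 1 / 16,
                           max_pairs = 10L) {
  n <- ncol(rec$eeg)
  wlen <- round(window_s * rec$fs_hz)
  n_win <- floor(n / wlen)
  if (n_win < 2) stop("recording too short for bridge detection windows")
  n_ch <- nrow(rec$eeg)
  ed <- array(0, c(n_ch, n_ch, n_win))
  for (w in seq_len(n_win)) {
    seg <- rec$eeg[, ((w - 1L) * wlen + 1L):(w * wlen), drop = FALSE]
    seg <- seg - rowMeans(seg)
    cv <- tcrossprod(seg) / (wlen - 1)
    v <- diag(cv)
    ed[, , w] <- outer(v, v, "+") - 2 * cv
  }
  med_ed <- apply(ed, c(1, 2), stats::median)
  ut <- upper.tri(med_ed)
  cutoff <- cutoff_frac * stats::median(med_ed[ut])
  idx <- which(ut & med_ed < cutoff, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(ch1 = character(0), ch2 = character(0),
                      electrical_distance = numeric(0)))
  out <- data.frame(ch1 = rec$labels[idx[, 1]], ch2 = rec$labels[idx[, 2]],
                    electrical_distance = med_ed[idx])
  out <- out[order(out$electrical_distance), , drop = FALSE]
  out[seq_len(min(nrow(out), max_pairs)), , drop = FALSE]
}

#' Re-estimate channels by spherical-spline interpolation
#'
#' Replaces the listed channels with spherical-spline estimates from the
#' remaining channels (voltage domain).
#'
#' @param rec a \code{ckc_recording}
#' @param labels channels to re-estimate (empty = no-op)
#' @param lambda regularization constant for the interpolation spline
#' @param m,nterms spline stiffness and Legendre terms
#' @return the recording with those channels replaced
#' @export
interpolate_channels <- function(rec, labels, lambda = 1e-5, m = 3,
                                 nterms = 50) {
  if (!length(labels)) return(rec)
  missing <- setdiff(labels, rec$labels)
  if (length(missing))
    stop("unknown channel label(s): ", paste(missing, collapse = ", "))
  bad <- match(labels, rec$labels)
  donors <- setdiff(seq_along(rec$labels), bad)
  if (length(donors) < 4) stop("too few donor channels for interpolation")
  w <- spline_interp_weights(rec$montage$positions[donors, , drop = FALSE],
                             rec$montage$positions[bad, , drop = FALSE],
                             lambda, m, nterms)
  rec$eeg[bad, ] <- w %*% rec$eeg[donors, , drop = FALSE]
  rec$provenance$interpolated <- c(rec$provenance$interpolated, labels)
  rec
}

#' Repair bridged pairs by interpolating one member of each pair
#'
#' From each flagged pair the member whose broadband variance is higher
#' relative to its non-bridged neighbours is re-estimated (the more likely
#' contaminated one); ties fall to the first member.
#'
#' @param rec a \code{ckc_recording}
#' @param bridges output of \code{\link{detect_bridges}}
#' @param ... passed to \code{\link{interpolate_channels}}
#' @return the repaired recording
#' @export
repair_bridges <- function(rec, bridges, ...) {
  if (!nrow(bridges)) return(rec)
  bridged <- unique(c(bridges$ch1, bridges$ch2))
  v <- apply(rec$eeg, 1, stats::var)
  names(v) <- rec$labels
  pos <- rec$montage$positions
  rel_var <- function(ch) {
    d <- colSums((t(pos) - pos[ch, ])^2)
    nb <- names(sort(d))[-1]
    nb <- setdiff(nb, bridged)[1:4]
    v[ch] / stats::median(v[nb])
  }
  to_fix <- vapply(seq_len(nrow(bridges)), function(i) {
    a <- bridges$ch1[i]; b <- bridges$ch2[i]
    if (rel_var(b) > rel_var(a)) b else a
  }, character(1))
  interpolate_channels(rec, unique(to_fix), ...)
}

## internal: zero-phase Butterworth filtering of a channels x samples matrix
butter_filtfilt <- function(x, flt) {
  if (is.matrix(x)) {
    for (i in seq_len(nrow(x)))
      x[i, ] <- signal::filtfilt(flt, x[i, ])
    x
  } else signal::filtfilt(flt, x)
}

#' Zero-phase bandpass filter for EEG
#'
#' Butterworth high-pass and low-pass applied forward-backward
#' (\code{filtfilt}), so the net response is zero-phase and the stopband
#' attenuation is doubled.
#'
#' @param rec a \code{ckc_recording}
#' @param lo,hi band edges (Hz)
#' @param order_hp,order_lp Butterworth orders (before the
#'   forward-backward doubling)
#' @return the filtered recording
#' @export
bandpass <- function(rec, lo = 0.5, hi = 195, order_hp = 2, order_lp = 4) {
  nyq <- rec$fs_hz / 2
  if (hi >= nyq) stop("upper band edge must be below Nyquist")
  hp <- signal::butter(order_hp, lo / nyq, type = "high")
  lp <- signal::butter(order_lp, hi / nyq, type = "low")
  rec$eeg <- butter_filtfilt(butter_filtfilt(rec$eeg, hp), lp)
  if (!is.null(rec$eog)) rec$eog <- butter_filtfilt(butter_filtfilt(rec$eog, hp), lp)
  rec$provenance$bandpass <- c(lo = lo, hi = hi)
  rec
}

#' Remove blink artifacts by EOG regression
#'
#' Deterministic ocular-artifact correction: the regression coefficients of
#' each EEG channel on the EOG channels are estimated on high-pass filtered
#' copies (default 1 Hz, which suppresses the spurious low-frequency
#' coupling that 1/f signals otherwise produce), and the fitted EOG
#' contribution is subtracted from the unfiltered signal. An ICA-based
#' route can be substituted upstream where available; the regression path
#' keeps the pipeline free of stochastic decomposition steps. The method
#' used is recorded in the recording's provenance.
#'
#' @param rec a \code{ckc_recording} with EOG channels
#' @param fit_hp_hz high-pass edge for the copies the fit runs on
#' @param cor_threshold EEG-EOG correlation (on the filtered copies) below
#'   which a regressor is left out of a channel's correction; keeps
#'   EOG-uncorrelated channels untouched
#' @return the cleaned recording
#' @export
remove_blinks <- function(rec, fit_hp_hz = 1, cor_threshold = 0.1) {
  if (is.null(rec$eog) || !nrow(rec$eog)) {
    warning("no EOG channels; blink removal skipped")
    return(rec)
  }
  hp <- signal::butter(2, fit_hp_hz / (rec$fs_hz / 2), type = "high")
  Xf <- butter_filtfilt(rec$eog, hp)
  Yf <- butter_filtfilt(rec$eeg, hp)
  beta <- t(solve(tcrossprod(Xf), Xf %*% t(Yf)))   # n_eeg x n_eog
  r <- stats::cor(t(Yf), t(Xf))
  beta[abs(r) < cor_threshold] <- 0
  rec$eeg <- rec$eeg - beta %*% (rec$eog - rowMeans(rec$eog))
  rec$provenance$blink_removal <- list(method = "eog_regression",
                                       fit_hp_hz = fit_hp_hz,
                                       cor_threshold = cor_threshold,
                                       beta = beta)
  rec
}

#' Standard preprocessing chain for one recording
#'
#' Channel exclusion, blink removal, bandpass, bridge detection and repair,
#' cross-validated selection of the CSD regularization constant, and CSD
#' transform.
#'
#' @param rec a \code{ckc_recording}
#' @param drop channels to exclude first
#' @param params a \code{\link{csd_params}}
#' @param detect_bridged run bridge detection/repair
#' @return the CSD-transformed recording; the selected lambda and bridge
#'   report are in \code{$provenance}
#' @export
preprocess_recording <- function(rec, drop = c("TP9", "TP10"),
                                 params = csd_params(),
                                 detect_bridged = TRUE) {
  rec <- exclude_channels(rec, intersect(drop, rec$labels))
  rec <- remove_blinks(rec)
  rec <- bandpass(rec)
  if (detect_bridged) {
    br <- detect_bridges(rec)
    rec$provenance$bridges <- br
    rec <- repair_bridges(rec, br)
  }
  params <- select_lambda(rec, params)
  csd_transform(rec, params)
}
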