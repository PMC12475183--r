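#' Assemble a tidy per-subject CKC table
#'
#' Binds per-subject, per-condition rows of \code{\link{peak_metrics}}
#' output together with subject metadata into the long table that every
#' group-level contrast consumes: one row per subject x hand x block x
#' method x resolution.
#'
#' @param metric_rows list of data frames from \code{\link{peak_metrics}},
#'   each carrying columns \code{subject}, \code{block} (add them before or
#'   pass via \code{meta})
#' @param meta optional data frame with per-subject columns
#'   \code{subject}, \code{dominant_hand}, \code{laterality_quotient}
#' @return a data frame of class \code{ckc_subject_table}
#' @export
subject_table <- function(metric_rows, meta = NULL) {
  tab <- do.call(rbind, metric_rows)
  if (!is.null(meta)) tab <- merge(tab, meta, by = "subject", sort = FALSE)
  class(tab) <- c("ckc_subject_table", class(tab))
  tab
}

## internal: per-subject contra/ipsi means at a frequency, derived from the
## lateralized set means and the moved hand (so relabeling hands exchanges
## the two, as it must)
contra_ipsi <- function(table, freq) {
  lcol <- if (freq == 2) "mean_left" else "mean_left_f1"
  rcol <- if (freq == 2) "mean_right" else "mean_right_f1"
  contra <- ifelse(table$hand == "right", table[[lcol]], table[[rcol]])
  ipsi <- ifelse(table$hand == "right", table[[rcol]], table[[lcol]])
  data.frame(subject = table$subject, hand = table$hand,
             contra = contra, ipsi = ipsi)
}

#' Contralateral-vs-ipsilateral CKC contrast
#'
#' Per-subject paired contra minus ipsi differences of the mean coherence
#' over the lateralized electrode sets for one moved-hand condition,
#' screened for normality (Shapiro-Wilk) and tested with a Wilcoxon
#' signed-rank test (the primary test; the paired t statistic is reported
#' alongside).
#'
#' @param table a \code{\link{subject_table}}
#' @param freq 2 or 4 (Hz)
#' @param hand moved-hand condition to test
#' @return list with \code{pairs} (per-subject contra/ipsi),
#'   \code{median_difference}, \code{shapiro}, \code{wilcoxon},
#'   \code{t_test} and \code{direction}
#' @export
lateralization_contrast <- function(table, freq = 4,
                                    hand = c("right", "left")) {
  hand <- match.arg(hand)
  if (!hand %in% table$hand) stop("hand condition '", hand, "' missing")
  rows <- table[table$hand == hand, , drop = FALSE]
  ci <- contra_ipsi(rows, freq)
  ci <- stats::aggregate(cbind(contra, ipsi) ~ subject, ci, mean)
  if (nrow(ci) < 2) stop("paired test undefined for a single subject")
  d <- ci$contra - ci$ipsi
  degenerate <- stats::sd(d) == 0
  sh <- if (length(d) >= 3 && !degenerate) stats::shapiro.test(d) else NULL
  wt <- if (degenerate) list(statistic = NA_real_, p.value = 1)
        else stats::wilcox.test(ci$contra, ci$ipsi, paired = TRUE, exact = FALSE)
  tt <- if (degenerate) list(statistic = NA_real_, p.value = 1)
        else stats::t.test(ci$contra, ci$ipsi, paired = TRUE)
  list(pairs = ci, median_difference = stats::median(d), shapiro = sh,
       wilcoxon = wt, t_test = tt,
       direction = c("ipsi > contra", "none", "contra > ipsi")[sign(stats::median(d)) + 2])
}

#' Frequency specificity of CKC at a target frequency
#'
#' Compares per-subject coherence at the target frequency against each
#' neighbouring frequency. The normality of the paired differences
#' (Shapiro-Wilk, alpha = 0.05) selects the headline test (paired t when
#' normal, Wilcoxon signed-rank otherwise); both are reported.
#'
#' @param table a \code{\link{subject_table}} with \code{coh_<f>} columns
#' @param f_target target frequency (Hz)
#' @param f_neighbors neighbour frequencies (Hz)
#' @param alpha normality-screen level
#' @return data frame with one row per neighbour: mean difference, Shapiro
#'   W and p, selected test, both test statistics and p values
#' @export
frequency_specificity <- function(table, f_target = 2,
                                  f_neighbors = c(1.5, 2.5),
                                  alpha = 0.05) {
  col_of <- function(f) {
    nm <- paste0("coh_", f)
    if (!nm %in% names(table) || anyNA(table[[nm]]))
      stop("frequency ", f, " Hz absent at this resolution")
    nm
  }
  tcol <- col_of(f_target)
  agg <- stats::aggregate(table[, vapply(c(f_target, f_neighbors), col_of,
                                         character(1))],
                          by = list(subject = table$subject), FUN = mean)
  out <- lapply(f_neighbors, function(f) {
    d <- agg[[col_of(f_target)]] - agg[[col_of(f)]]
    if (stats::sd(d) == 0) {
      sh <- list(statistic = NA_real_, p.value = NA_real_)
      tt <- list(statistic = NA_real_, p.value = NA_real_)
      wt <- list(statistic = NA_real_, p.value = NA_real_)
      chosen <- "none (constant differences)"
    } else {
      sh <- stats::shapiro.test(d)
      tt <- stats::t.test(d)
      wt <- stats::wilcox.test(d, exact = FALSE)
      chosen <- if (sh$p.value >= alpha) "paired-t" else "wilcoxon"
    }
    data.frame(target_hz = f_target, neighbor_hz = f,
               mean_difference = mean(d),
               shapiro_w = unname(sh$statistic), shapiro_p = sh$p.value,
               test_used = chosen,
               t_statistic = unname(tt$statistic), t_p = tt$p.value,
               wilcoxon_v = unname(wt$statistic), wilcoxon_p = wt$p.value)
  })
  do.call(rbind, out)
}

#' Method-by-resolution-by-averaging SNR summary
#'
#' Per-cell mean and SD of the dB SNR over subjects for the 16-cell
#' method grid, with marginal means per factor, plus the tidy long table
#' that a repeated-measures ANOVA consumes.
#'
#' @param table a \code{\link{subject_table}} covering the full grid
#' @param snr_col which SNR column to summarize
#' @return list with \code{cells} (16-row summary), \code{marginals}
#'   (named list of per-factor means) and \code{long} (subject-level rows)
#' @export
snr_method_table <- function(table, snr_col = "snr_f0_db") {
  need <- c("accel_method", "averaging", "resolution", "subject", snr_col)
  stopifnot(all(need %in% names(table)))
  long <- stats::aggregate(table[[snr_col]],
                           by = list(subject = table$subject,
                                     accel_method = table$accel_method,
                                     averaging = table$averaging,
                                     resolution = table$resolution),
                           FUN = mean)
  names(long)[5] <- "snr_db"
  n_cells <- nrow(unique(long[, c("accel_method", "averaging", "resolution")]))
  if (n_cells != 16)
    stop("incomplete method grid: ", n_cells, " cells, expected 16")
  cells <- stats::aggregate(snr_db ~ accel_method + averaging + resolution,
                            long, function(z) c(mean = mean(z), sd = stats::sd(z)))
  cells <- cbind(cells[1:3], as.data.frame(cells$snr_db))
  marginals <- list(
    averaging = tapply(long$snr_db, long$averaging, mean),
    accel_method = tapply(long$snr_db, long$accel_method, mean),
    resolution = tapply(long$snr_db, long$resolution, mean))
  list(cells = cells, marginals = marginals, long = long)
}

#' Map laterality quotient to the dominant hand
#'
#' Right-dominant above a laterality quotient of 40, left-dominant below
#' -40; in the ambidextrous band the sign of the quotient decides (a
#' negative quotient maps to left dominance).
#'
#' @param lq Edinburgh laterality quotient in [-100, 100]
#' @return "left" or "right"
#' @export
dominant_hand <- function(lq) {
  ifelse(lq > 40, "right", ifelse(lq < -40, "left",
                                  ifelse(lq >= 0, "right", "left")))
}

#' Cross-condition Spearman correlations of peak CKC
#'
#' Spearman rank correlations between the left- and right-hand (and
#' dominant / non-dominant) peak coherence at F0 and F1, and between the
#' absolute laterality quotient and dominant/non-dominant peaks. P values
#' are uncorrected for multiple comparisons, as flagged in the output.
#'
#' @param table a \code{\link{subject_table}} with both hand conditions and
#'   (optionally) \code{laterality_quotient}
#' @param p_adjust \code{"none"} (default, mirroring common practice in
#'   this literature, flagged in the output) or \code{"holm"}
#' @return data frame of pairwise correlations (rho, p, n), with attribute
#'   \code{p_adjustment}
#' @export
condition_correlations <- function(table, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  agg <- stats::aggregate(cbind(f0_peak, f1_peak) ~ subject + hand, table, max)
  wide <- merge(agg[agg$hand == "right", c("subject", "f0_peak", "f1_peak")],
                agg[agg$hand == "left", c("subject", "f0_peak", "f1_peak")],
                by = "subject", suffixes = c("_right", "_left"))
  if (nrow(wide) < 5) stop("need at least 5 subjects with both conditions")
  if ("laterality_quotient" %in% names(table)) {
    lq <- unique(table[, c("subject", "laterality_quotient")])
    wide <- merge(wide, lq, by = "subject")
    wide$dom <- dominant_hand(wide$laterality_quotient)
    for (f in c("f0_peak", "f1_peak")) {
      wide[[paste0(f, "_dominant")]] <-
        ifelse(wide$dom == "right", wide[[paste0(f, "_right")]],
               wide[[paste0(f, "_left")]])
      wide[[paste0(f, "_nondominant")]] <-
        ifelse(wide$dom == "right", wide[[paste0(f, "_left")]],
               wide[[paste0(f, "_right")]])
    }
  }
  pairs <- list(
    c("f0_peak_right", "f0_peak_left"),
    c("f1_peak_right", "f1_peak_left"),
    c("f0_peak_right", "f1_peak_right"),
    c("f0_peak_left", "f1_peak_left"))
  if ("dom" %in% names(wide)) {
    pairs <- c(pairs, list(
      c("f0_peak_dominant", "f0_peak_nondominant"),
      c("f1_peak_dominant", "f1_peak_nondominant")))
    wide$abs_lq <- abs(wide$laterality_quotient)
    pairs <- c(pairs, list(c("abs_lq", "f0_peak_dominant"),
                           c("abs_lq", "f0_peak_nondominant"),
                           c("abs_lq", "f1_peak_dominant"),
                           c("abs_lq", "f1_peak_nondominant")))
  }
  out <- do.call(rbind, lapply(pairs, function(p) {
    ct <- suppressWarnings(
      stats::cor.test(wide[[p[1]]], wide[[p[2]]], method = "spearman"))
    data.frame(var1 = p[1], var2 = p[2], rho = unname(ct$estimate),
               p = ct$p.value, n = nrow(wide))
  }))
  if (p_adjust == "holm") out$p <- stats::p.adjust(out$p, "holm")
  attr(out, "p_adjustment") <- p_adjust
  out
}
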