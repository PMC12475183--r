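# synthetic subject tables: cheap, fully controlled inputs for the
# group-level contrasts

make_table <- function(n_subj = 12, seed = 1, contra_boost = 0.1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subj)) for (h in c("left", "right")) {
    base <- stats::runif(1, 0.05, 0.2)
    lft <- base + ifelse(h == "right", contra_boost, 0) + stats::rnorm(1, 0, 0.01)
    rgt <- base + ifelse(h == "left", contra_boost, 0) + stats::rnorm(1, 0, 0.01)
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, hand = h, block = 1L,
      accel_method = "magnitude", averaging = "median", resolution = 0.5,
      f0_peak = base + 0.3, f1_peak = base + 0.2,
      snr_f0_db = stats::rnorm(1, 15, 2), snr_f1_db = stats::rnorm(1, 12, 2),
      mean_left = lft, mean_right = rgt,
      mean_left_f1 = lft, mean_right_f1 = rgt,
      coh_1.5 = base * 0.3, coh_2 = base + 0.3, coh_2.5 = base * 0.31,
      coh_3 = base * 0.3, coh_3.5 = base * 0.32, coh_4 = base + 0.2,
      coh_4.5 = base * 0.3,
      laterality_quotient = stats::runif(1, 50, 100))
  }
  subject_table(rows)
}

test_that("lateralization contrast: null table gives zero difference", {
  tab <- make_table(contra_boost = 0)
  tab$mean_left <- tab$mean_right <- tab$mean_left_f1 <-
    tab$mean_right_f1 <- 0.1
  lc <- lateralization_contrast(tab, freq = 4, hand = "right")
  expect_equal(lc$median_difference, 0)
  expect_equal(lc$wilcoxon$p.value, 1)
  expect_equal(lc$direction, "none")
})

test_that("lateralization contrast detects contralateral dominance", {
  tab <- make_table(contra_boost = 0.1)
  for (h in c("left", "right")) {
    lc <- lateralization_contrast(tab, freq = 4, hand = h)
    expect_gt(lc$median_difference, 0)
    expect_lt(lc$wilcoxon$p.value, 0.01)
    expect_equal(lc$direction, "contra > ipsi")
  }
})

test_that("lateralization contrast is antisymmetric under hand relabeling", {
  tab <- make_table(contra_boost = 0.07)
  lc <- lateralization_contrast(tab, freq = 2, hand = "right")
  swapped <- tab
  swapped$hand <- ifelse(tab$hand == "right", "left", "right")
  lc_sw <- lateralization_contrast(swapped, freq = 2, hand = "left")
  expect_equal(lc_sw$median_difference, -lc$median_difference)
})

test_that("lateralization contrast enforces its preconditions", {
  tab <- make_table()
  expect_error(lateralization_contrast(tab[tab$hand == "left", ],
                                       hand = "right"), "missing")
  one <- tab[tab$subject == 1, ]
  expect_error(lateralization_contrast(one, hand = "right"),
               "single subject")
})

test_that("frequency specificity: identical columns give zero differences", {
  tab <- make_table()
  tab$coh_2.5 <- tab$coh_2
  fs <- frequency_specificity(tab, 2, c(1.5, 2.5))
  expect_equal(fs$mean_difference[fs$neighbor_hz == 2.5], 0)
  expect_match(fs$test_used[fs$neighbor_hz == 2.5], "constant")
  # genuine target > neighbour structure is detected
  fs2 <- frequency_specificity(tab, 2, c(1.5, 2.5))
  expect_gt(fs2$mean_difference[1], 0)
})

test_that("frequency specificity refuses off-grid neighbours", {
  tab <- make_table()
  tab$coh_1.5 <- NA_real_                # 1.5 Hz absent at 1 Hz resolution
  expect_error(frequency_specificity(tab, 2, c(1.5)), "absent")
})

test_that("SNR method table reconstructs cell means and demands 16 cells", {
  rows <- list()
  combos <- expand.grid(accel_method = c("magnitude", "pca"),
                        averaging = c("mean", "median"),
                        resolution = c(1, 0.5, 0.25, 0.125),
                        stringsAsFactors = FALSE)
  set.seed(4)
  for (s in 1:6) for (i in seq_len(nrow(combos))) {
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, combos[i, ],
      snr_f0_db = 10 + 4 * (combos$averaging[i] == "median") + rnorm(1, 0, 0.5))
  }
  tab <- do.call(rbind, rows)
  out <- snr_method_table(tab)
  expect_equal(nrow(out$cells), 16)
  # marginal means reconstruct cell means on balanced input
  expect_equal(unname(out$marginals$averaging["median"] -
                        out$marginals$averaging["mean"]),
               mean(out$cells$mean[out$cells$averaging == "median"]) -
                 mean(out$cells$mean[out$cells$averaging == "mean"]))
  expect_gt(out$marginals$averaging["median"],
            out$marginals$averaging["mean"])
  expect_error(snr_method_table(tab[tab$resolution != 1, ]), "incomplete")
})

test_that("median-averaging advantage shows up from simulated spectra", {
  # one corrupted-segment block, both estimators on the same data
  set.seed(8)
  fs <- 200; dur <- 60
  tt <- (0:(dur * fs - 1)) / fs
  s <- sin(2 * pi * 2 * tt)
  x <- s + rnorm(length(tt)); y <- s + rnorm(length(tt))
  seg_len <- 2 * fs; step <- round(0.2 * seg_len)
  for (k in sample(1:140, 15)) {
    i0 <- (k - 1) * step + 1
    x[i0:(i0 + seg_len - 1)] <- x[i0:(i0 + seg_len - 1)] + rnorm(seg_len, 0, 15)
  }
  sn <- vapply(c("mean", "median"), function(avg) {
    co <- welch_coherence(x, y, fs, 2, averaging = avg)
    20 * log10(co$coherence[co$freqs == 2] / co$coherence[co$freqs == 3])
  }, numeric(1))
  expect_gt(sn["median"], sn["mean"])
})

test_that("dominant-hand mapping follows the laterality quotient rules", {
  expect_equal(dominant_hand(77), "right")
  expect_equal(dominant_hand(-100), "left")
  expect_equal(dominant_hand(-9.1), "left")   # ambidextrous, negative LQ
  expect_equal(dominant_hand(20), "right")
})

test_that("condition correlations: identical columns give rho = 1", {
  tab <- make_table(n_subj = 10, seed = 3)
  # force right == left per subject
  for (s in unique(tab$subject)) {
    v <- tab$f0_peak[tab$subject == s][1]
    tab$f0_peak[tab$subject == s] <- v
    tab$f1_peak[tab$subject == s] <- v / 2
  }
  cc <- condition_correlations(tab)
  expect_equal(cc$rho[cc$var1 == "f0_peak_right" & cc$var2 == "f0_peak_left"], 1)
  expect_equal(attr(cc, "p_adjustment"), "none")
  cch <- condition_correlations(tab, p_adjust = "holm")
  expect_equal(attr(cch, "p_adjustment"), "holm")
  expect_true(all(cch$p >= cc$p - 1e-12))
  expect_error(condition_correlations(make_table(n_subj = 3)), "5 subjects")
})

test_that("condition correlations are centred on zero under independence", {
  set.seed(12)
  rhos <- replicate(40, {
    tab <- make_table(n_subj = 12, seed = sample.int(1e6, 1))
    tab$f0_peak <- stats::runif(nrow(tab))      # destroy any coupling
    cc <- condition_correlations(tab)
    cc$rho[cc$var1 == "f0_peak_right" & cc$var2 == "f0_peak_left"]
  })
  expect_lt(abs(mean(rhos)), 0.15)
  # null spread consistent with Spearman SD ~ 1/sqrt(n - 1)
  expect_lt(stats::quantile(abs(rhos), 0.95), 3 / sqrt(11))
})

test_that("a simulated mini-cohort shows contralateral dominance at F1", {
  rows <- fixture("cohort_rows", {
    out <- list()
    for (s in 1:10) {
      hand <- if (s %% 2) "right" else "left"
      src <- if (hand == "right") "C3" else "C4"
      rec <- simulate_recording(sim_config(duration_s = 30, seed = 500 + s,
                                           hand = hand, source_channel = src))
      eegc <- csd_operator(rec$montage$positions, 1e-5) %*% rec$eeg
      acc <- prepare_accel(rec$accel, rec$events, rec$fs_hz, ncol(rec$eeg),
                           "magnitude")
      sub <- unique(c(rec$montage$subsets$analysis))
      spec <- ckc_coherence(eegc[sub, ], acc, rec$fs_hz, 2,
                            averaging = "median", labels = sub)
      pm <- peak_metrics(spec, rec$montage, hand = hand)
      pm$subject <- s
      pm$block <- 1L
      out[[s]] <- pm
    }
    out
  })
  tab <- subject_table(rows)
  for (h in c("right", "left")) {
    lc <- lateralization_contrast(tab, freq = 4, hand = h)
    expect_gt(lc$median_difference, 0)
  }
})
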