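test_that("accelerometer synchronization recovers the simulated clock map", {
  cfg <- sim_config(duration_s = 20, seed = 2, accel_clock_offset_s = 0.2,
                    accel_clock_drift = 1e-4)
  rec <- simulate_recording(cfg)
  acc <- prepare_accel(rec$accel, rec$events, rec$fs_hz, ncol(rec$eeg),
                       "magnitude")
  t_true <- rec$accel$timestamps / (1 + cfg$accel_clock_drift) -
    cfg$accel_clock_offset_s
  t_est <- acc$provenance$sync_offset +
    rec$accel$timestamps * acc$provenance$sync_slope
  expect_lt(max(abs(t_true - t_est)), 1e-3)   # < 1 ms residual
  tr_nosync <- rec$accel; tr_nosync$sync_events <- numeric(0)
  expect_error(prepare_accel(tr_nosync, rec$events, 2000, 100), "sync events")
})

test_that("magnitude summary removes gravity; pca summary recovers single-axis motion", {
  fs <- 1094
  t <- (0:(10 * fs - 1)) / fs
  still <- accel_trace(rbind(0 * t, 0 * t, 0 * t + 8192), t,
                       sync_events = c(1, 9))
  acc <- prepare_accel(still, c(1, 9), 2000, 20000, "magnitude")
  expect_lt(max(abs(acc$signal)), 1e-6 * 8192)
  x <- 500 * sin(2 * pi * 2 * t)
  one_axis <- accel_trace(rbind(0 * t, x, 0 * t + 8192), t,
                          sync_events = c(1, 9))
  accp <- prepare_accel(one_axis, c(1, 9), 2000, 18000, "pca")
  ref <- 500 * sin(2 * pi * 2 * (0:17999) / 2000)
  expect_gt(abs(stats::cor(accp$signal, ref)), 0.999)
})

test_that("coherence of a signal with itself is 1 wherever power is nonzero", {
  set.seed(5)
  x <- rnorm(4000)
  co <- welch_coherence(x, x, fs = 100, segment_s = 2, averaging = "mean")
  expect_true(all(abs(co$coherence - 1) < 1e-12))
  com <- welch_coherence(x, x, fs = 100, segment_s = 2, averaging = "median")
  expect_true(all(com$coherence <= 1))
  expect_gt(min(com$coherence), 0.9)
})

test_that("coherence is symmetric, scale-invariant and bounded", {
  set.seed(6)
  t <- (0:7999) / 100
  x <- sin(2 * pi * 3 * t) + rnorm(8000)
  y <- sin(2 * pi * 3 * t) + rnorm(8000)
  for (avg in c("mean", "median")) {
    a <- welch_coherence(x, y, 100, 2, averaging = avg)
    b <- welch_coherence(y, x, 100, 2, averaging = avg)
    expect_equal(a$coherence, b$coherence, tolerance = 1e-12)
    s <- welch_coherence(-3 * x, 0.5 * y, 100, 2, averaging = avg)
    expect_equal(a$coherence, s$coherence, tolerance = 1e-9)
    expect_true(all(a$coherence >= 0 & a$coherence <= 1))
  }
  expect_error(welch_coherence(x[1:150], y[1:150], 100, 2), "2 segments")
})

test_that("mean-averaged Welch coherence matches a naive reference implementation", {
  set.seed(7)
  fs <- 100
  x <- rnorm(3000); y <- rnorm(3000)
  co <- welch_coherence(x, y, fs, segment_s = 1, overlap = 0.5,
                        averaging = "mean")
  # independent straight-line reference: loop over segments
  L <- 100; step <- 50
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
  starts <- seq(1, length(x) - L + 1, by = step)
  sxx <- syy <- rep(0, L / 2 + 1); sxy <- complex(real = rep(0, L / 2 + 1))
  for (s in starts) {
    xs <- x[s:(s + L - 1)]; ys <- y[s:(s + L - 1)]
    X <- fft((xs - mean(xs)) * w)[1:(L / 2 + 1)]
    Y <- fft((ys - mean(ys)) * w)[1:(L / 2 + 1)]
    sxx <- sxx + Mod(X)^2; syy <- syy + Mod(Y)^2; sxy <- sxy + Conj(X) * Y
  }
  ref <- Mod(sxy / length(starts))^2 /
    ((sxx / length(starts)) * (syy / length(starts)))
  expect_equal(co$coherence, pmin(ref, 1), tolerance = 1e-10)
})

test_that("independent-noise coherence matches the known estimator bias", {
  fs <- 100; dur <- 140
  # effective segment count from the Hann overlap correlations
  keff <- function(L, step, n) {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
    k <- floor((n - L) / step) + 1
    rho2 <- vapply(1:(k - 1), function(j) {
      sh <- j * step
      if (sh >= L) return(0)
      (sum(w[1:(L - sh)] * w[(sh + 1):L]) / sum(w^2))^2
    }, numeric(1))
    k^2 / (k + 2 * sum((k - (1:(k - 1))) * rho2))
  }
  set.seed(9)
  mean80 <- mean(replicate(6, {
    co <- welch_coherence(rnorm(dur * fs), rnorm(dur * fs), fs, 2,
                          averaging = "mean")
    mean(co$coherence[co$freqs > 5 & co$freqs < 45])
  }))
  expected <- 1 / keff(200, 40, dur * fs)
  expect_lt(abs(mean80 - expected) / expected, 0.15)
  # without overlap the bias is the classical 1/K
  mean0 <- mean(replicate(6, {
    co <- welch_coherence(rnorm(dur * fs), rnorm(dur * fs), fs, 2,
                          overlap = 0, averaging = "mean")
    mean(co$coherence[co$freqs > 5 & co$freqs < 45])
  }))
  expect_lt(abs(mean0 - 1 / 70) * 70, 0.15)
})

test_that("median averaging degrades less than mean under segment transients", {
  set.seed(3)
  fs <- 200; dur <- 60
  tt <- (0:(dur * fs - 1)) / fs
  devs <- replicate(6, {
    s <- sin(2 * pi * 2 * tt)
    x <- s + rnorm(length(tt)); y <- s + rnorm(length(tt))
    at <- function(co) co$coherence[co$freqs == 2]
    cl_mean <- at(welch_coherence(x, y, fs, 2, averaging = "mean"))
    cl_med <- at(welch_coherence(x, y, fs, 2, averaging = "median"))
    xc <- x
    seg_len <- 2 * fs; step <- round(0.2 * seg_len)
    for (k in sample(1:140, 20)) {          # corrupt k << K/2 segments
      i0 <- (k - 1) * step + 1
      xc[i0:(i0 + seg_len - 1)] <- xc[i0:(i0 + seg_len - 1)] +
        rnorm(seg_len, 0, 20)
    }
    c(mean = abs(at(welch_coherence(xc, y, fs, 2, averaging = "mean")) - cl_mean),
      med = abs(at(welch_coherence(xc, y, fs, 2, averaging = "median")) - cl_med))
  })
  expect_gte(sum(devs["med", ] < devs["mean", ]), 5)
  expect_lt(mean(devs["med", ]), mean(devs["mean", ]))
})

test_that("SNR in dB follows its definition", {
  spec <- structure(list(
    values = matrix(c(0.4, 0.4, 0.1, 0.4, 0.04, 0), 3, 2,
                    dimnames = list(c("a", "b", "c"), NULL)),
    freqs_hz = c(2, 3), resolution_hz = 1, averaging = "mean",
    accel_method = "magnitude", segment_s = 1, overlap = 0.8,
    labels = c("a", "b", "c")), class = "ckc_cohspec")
  s <- snr_db(spec, 2, 3)
  expect_equal(unname(s[1]), 0)                      # equal -> 0 dB
  expect_equal(unname(s[2]), 20)                     # 10x baseline -> +20 dB
  expect_true(is.infinite(s[3]))                     # zero baseline flagged
  expect_error(snr_db(spec, 2.25), "not on the")
})

test_that("the method grid yields 16 valid spectra focused near the source", {
  rec <- fixture("grid60", {
    r <- exclude_channels(simulate_recording(sim_config(duration_s = 60,
                                                        seed = 21)),
                          c("TP9", "TP10"))
    r$eeg <- csd_operator(r$montage$positions, 1e-5) %*% r$eeg
    list(rec = r, grid = ckc_grid(r))
  })
  grid <- rec$grid; r <- rec$rec
  expect_length(grid, 16)
  combos <- unique(vapply(grid, function(s)
    paste(s$accel_method, s$averaging, s$resolution_hz), character(1)))
  expect_length(combos, 16)
  for (s in grid) {
    expect_true(all(s$values >= 0 & s$values <= 1))
    expect_equal(unique(round(diff(s$freqs_hz), 9)), s$resolution_hz)
    expect_equal(s$segment_s * s$resolution_hz, 1)
  }
  # argmax channel at F0 within one electrode neighbourhood of the source
  m <- r$montage
  d <- colSums((t(m$positions) - m$positions["C3", ])^2)
  nbhd <- names(sort(d))[1:7]
  hits <- vapply(grid, function(s) {
    sub <- m$subsets$analysis
    i0 <- which(abs(s$freqs_hz - 2) < 1e-9)
    sub[which.max(s$values[sub, i0])] %in% nbhd
  }, logical(1))
  expect_gte(sum(hits), 14)
})

test_that("F0 coherence SNR exceeds 6 dB at every tested resolution", {
  run <- full_run()
  for (res in c(1, 0.5, 0.25, 0.125)) {
    s <- run$grid[[sprintf("magnitude-median-%g", res)]]
    sub <- run$csd$montage$subsets$analysis
    snr <- snr_db(s, 2)[sub]
    expect_gt(max(snr), 6)
  }
})

test_that("coupling strength orders the recovered F0 coherence and SNR", {
  stats_by_snr <- vapply(c(0.3, 1, 3), function(snr) {
    rec <- simulate_recording(sim_config(duration_s = 30, seed = 42,
                                         source_snr = snr))
    sub <- rec$montage$subsets$analysis
    eegc <- (csd_operator(rec$montage$positions, 1e-5) %*% rec$eeg)[sub, ]
    acc <- prepare_accel(rec$accel, rec$events, rec$fs_hz, ncol(rec$eeg),
                         "magnitude")
    spec <- ckc_coherence(eegc, acc, rec$fs_hz, 2, averaging = "median",
                          labels = sub)
    c(coh = stats::median(spec$values[, spec$freqs_hz == 2]),
      snr = stats::median(snr_db(spec, 2)))
  }, numeric(2))
  expect_true(all(diff(stats_by_snr["coh", ]) > 0))
  expect_gt(stats_by_snr["snr", 3], stats_by_snr["snr", 1])
})

test_that("peak metrics pick the right channel and hand assignment", {
  m <- ckc_montage()
  labs <- m$labels
  vals <- matrix(0, length(labs), 9, dimnames = list(labs, NULL))
  freqs <- seq(0.5, 4.5, by = 0.5)
  vals["C4", ] <- 0.05
  vals["C4", freqs == 2] <- 0.6               # single strong channel
  vals["C4", freqs == 4] <- 0.3
  spec <- structure(list(values = vals, freqs_hz = freqs,
                         resolution_hz = 0.5, averaging = "median",
                         accel_method = "magnitude", segment_s = 2,
                         overlap = 0.8, labels = labs),
                    class = "ckc_cohspec")
  pm <- peak_metrics(spec, m, hand = "left")
  expect_equal(pm$f0_peak_channel, "C4")
  expect_equal(pm$f0_peak, 0.6)
  # left-hand condition: contralateral is the right electrode set
  expect_equal(pm$contra, mean(vals[m$subsets$right, freqs == 2]))
  expect_equal(pm$ipsi, mean(vals[m$subsets$left, freqs == 2]))
  bad <- spec; bad$values <- vals[1:10, ]; bad$labels <- labs[1:10]
  expect_error(peak_metrics(bad, m), "missing")
})
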