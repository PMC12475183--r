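# shared fixtures, built once per test session and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# a short default-condition recording for module-level checks
short_recording <- function() fixture("short_rec", {
  simulate_recording(sim_config(duration_s = 30, seed = 7))
})

# the full study-scale run: 140 s block at the protocol conditions through
# the complete pipeline (used by the end-to-end and acceptance checks)
full_run <- function() fixture("full_run", {
  cfg <- sim_config(duration_s = 140, seed = 1)
  rec <- simulate_recording(cfg)
  csd <- preprocess_recording(rec)
  grid <- ckc_grid(csd)
  list(cfg = cfg, rec = rec, csd = csd, grid = grid)
})

# argmax frequency of the subset-max coherence within a band
band_argmax <- function(spec, montage, f_lo, f_hi) {
  sub <- intersect(montage$subsets$analysis, spec$labels)
  band <- spec$freqs_hz >= f_lo & spec$freqs_hz <= f_hi
  v <- spec$values[sub, band, drop = FALSE]
  spec$freqs_hz[band][which(v == max(v), arr.ind = TRUE)[2]]
}

# sign-agnostic fraction of true peak times matched by detected times
peak_match_rate <- function(detected_max, detected_min, truth, tol = 0.05) {
  rate <- function(det) mean(vapply(truth, function(t) min(abs(det - t)) < tol,
                                    logical(1)))
  max(rate(detected_max), rate(detected_min))
}
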