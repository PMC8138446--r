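square_pulse_trace <- function(n_beats = 10, width_s = 0.4, period_s = 1,
                               fs = 100) {
  tt <- seq(0, n_beats * period_s, by = 1 / fs)
  y <- numeric(length(tt))
  for (k in seq_len(n_beats)) {
    t0 <- (k - 1) * period_s + 0.2
    y[tt >= t0 & tt < t0 + width_s] <- 1
  }
  voltage_trace(y, fs)
}

test_that("square-pulse trains segment into the right number of beats", {
  beats <- segment_beats(square_pulse_trace())
  expect_equal(nrow(beats), 10)
  expect_equal(stats::median(beats$rr_s, na.rm = TRUE), 1.0,
               tolerance = 0.011)
  expect_warning(flat <- segment_beats(voltage_trace(rep(3, 500), 100)),
                 "no beats")
  expect_equal(nrow(flat), 0)
})

test_that("all APD levels coincide on an ideal square pulse", {
  tr <- square_pulse_trace()
  beats <- segment_beats(tr)
  a30 <- apd(tr, beats, 30)
  a80 <- apd(tr, beats, 80)
  a90 <- apd(tr, beats, 90)
  # the entire fall happens within one inter-sample interval
  expect_lt(max(abs(a30 - a80), abs(a30 - a90), na.rm = TRUE), 10)
  expect_equal(stats::median(a80), 400, tolerance = 0.05)
  expect_error(apd(tr, beats, 120), "level")
})

test_that("APDs are recovered from synthetic traces within one sample period", {
  for (seed in 1:3) {
    spec <- ap_template_spec(beat_rate_bpm = 30, apd30_ms = 200,
                             apd80_ms = 350, apd90_ms = 400,
                             noise_sd = 0, drift_rate = 0.01, seed = seed)
    ap <- make_ap_trace(spec, duration_s = 10)
    bm <- beat_metrics(ap$trace)
    expect_equal(nrow(bm), nrow(ap$truth))
    samp_ms <- 1000 / spec$sampling_rate_hz
    expect_lt(max(abs(bm$apd30 - 200)), samp_ms)
    expect_lt(max(abs(bm$apd80 - 350)), samp_ms)
    expect_lt(max(abs(bm$apd90 - 400)), samp_ms)
    expect_equal(stats::median(bm$rr_s), 2.0, tolerance = 0.011)
  }
})

test_that("APD is monotone in the repolarization level on synthetic beats", {
  ap <- make_ap_trace(ap_template_spec(noise_sd = 0.01, seed = 4),
                      duration_s = 10)
  beats <- segment_beats(ap$trace)
  levels <- c(20, 30, 50, 80, 90)
  mat <- sapply(levels, function(l) apd(ap$trace, beats, l))
  for (k in seq_len(nrow(mat))) {
    expect_true(all(diff(mat[k, ]) >= 0))
  }
})

test_that("a non-repolarizing beat yields a flagged missing value", {
  fs <- 100
  y <- c(rep(0, 2 * fs), rep(1, 4 * fs)) # steps up, never comes down
  tr <- voltage_trace(y, fs)
  beats <- segment_beats(tr, baseline_window_s = 1000)
  expect_equal(nrow(beats), 1)
  a <- apd(tr, beats, 90)
  expect_true(is.na(a[1]))
  expect_true(attr(a, "flagged")[1])
})

test_that("traces round-trip through delimited text", {
  ap <- make_ap_trace(ap_template_spec(noise_sd = 0.01, seed = 8),
                      duration_s = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(time_s = seq_along(ap$trace$samples) / 100 - 0.01,
               fluorescence = ap$trace$samples),
    path, row.names = FALSE, col.names = FALSE, sep = "\t")
  tr <- read_voltage_trace(path)
  expect_equal(tr$sampling_rate_hz, 100, tolerance = 1e-6)
  expect_equal(tr$samples, ap$trace$samples)
})

test_that("Fridericia correction has the documented algebra", {
  expect_equal(fridericia(350, 1), 350)
  expect_equal(fridericia(350, 0.5), 350 / 0.5^(1 / 3), tolerance = 1e-12)
  expect_equal(fridericia(350, 0.5), 441, tolerance = 1e-3)
  expect_equal(fridericia(2 * 350, 0.8), 2 * fridericia(350, 0.8))
  # monotone decreasing in RR
  rr <- seq(0.4, 2, by = 0.2)
  expect_true(all(diff(fridericia(350, rr)) < 0))
  expect_error(fridericia(350, 0), "rr_s")
})

test_that("triangulation metric matches its definition", {
  expect_equal(triangulation(250, 250), 0)
  expect_equal(triangulation(100, 250), 0.6)
  capd80 <- seq(150, 400, by = 50)
  expect_true(all(diff(triangulation(100, capd80)) > 0))
  expect_error(triangulation(300, 250), "capd30 > capd80")
  # invariance: scaling APD30, APD80 and RR so both cAPDs scale together
  c30 <- fridericia(200, 2); c80 <- fridericia(350, 2)
  c30s <- fridericia(200 * 1.3, 2); c80s <- fridericia(350 * 1.3, 2)
  expect_equal(triangulation(c30s, c80s), triangulation(c30, c80))
})

test_that("Hill fit recovers parameters exactly from noise-free data", {
  for (ec50 in c(3.2, 9.63, 40)) {
    dr <- make_dose_response(ec50_nM = ec50, floor = 1, ceiling = 1.6,
                             noise_cv = 0, n_reps = 1)
    fit <- fit_hill(dr$dose_nM, dr$response)
    expect_true(fit$converged)
    expect_lt(abs(fit$ec50 - ec50) / ec50, 1e-6)
    expect_lt(abs(fit$floor - 1), 1e-6)
    expect_lt(abs(fit$ceiling - 1.6), 1e-6)
  }
  # four-parameter mode recovers a non-unit slope
  dr2 <- make_dose_response(ec50_nM = 12, slope = 1.7, noise_cv = 0,
                            n_reps = 1)
  fit2 <- fit_hill(dr2$dose_nM, dr2$response, slope = "free")
  expect_lt(abs(fit2$ec50 - 12) / 12, 1e-4)
  expect_lt(abs(fit2$slope - 1.7) / 1.7, 1e-3)
})

test_that("Hill fit is accurate under replicate noise and robust to junk", {
  ec50s <- vapply(1:20, function(seed) {
    dr <- make_dose_response(ec50_nM = 9.63, floor = 1, ceiling = 1.5,
                             doses = c(1, 3, 10, 30, 100, 300),
                             noise_cv = 0.05, n_reps = 4, seed = seed)
    fit_hill(dr$dose_nM, dr$response)$ec50
  }, numeric(1))
  expect_lt(abs(stats::median(ec50s) - 9.63) / 9.63, 0.10)
  flat <- fit_hill(c(1, 10, 100, 1000), rep(2, 4))
  expect_true(flat$no_fit)
  expect_error(fit_hill(c(0, 0, 0, 0), 1:4), "zero")
  expect_error(fit_hill(c(1, 10, 100), c(1, 2, 3)), "4 distinct")
})

test_that("margin of safety reproduces the printed fold values", {
  expect_equal(margin_of_safety(9.63, 2.6), 3.7, tolerance = 0.01)
  expect_equal(margin_of_safety(9.63, 4.9), 1.97, tolerance = 0.01)
  expect_equal(margin_of_safety(5, 5), 1.0)
  expect_error(margin_of_safety(-1, 2), "> 0")
})
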