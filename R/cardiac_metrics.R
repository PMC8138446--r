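#' Optical voltage trace
#'
#' Container for a fluorescence recording of membrane potential (e.g. a
#' far-red voltage-sensitive dye imaged at ~100 Hz). Samples are arbitrary
#' fluorescence units; only relative amplitude within a beat matters.
#'
#' @param samples Numeric vector of fluorescence samples.
#' @param sampling_rate_hz Sampling rate (Hz, > 0).
#' @param t0_s Time of the first sample (s).
#' @param metadata Optional named list (dye, device id, ...).
#' @return An object of class `mps_voltage_trace`.
#' @export
voltage_trace <- function(samples, sampling_rate_hz, t0_s = 0,
                          metadata = list()) {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("samples must be finite numeric", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be > 0", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz,
                 t0_s = t0_s, metadata = metadata),
            class = "mps_voltage_trace")
}

#' @export
print.mps_voltage_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Read a voltage trace from delimited text
#'
#' Reads a two-column delimited file (time in seconds, fluorescence) such
#' as exported optical recordings; the sampling rate is inferred from the
#' median time step unless given.
#'
#' @param path File path.
#' @param sampling_rate_hz Override for the sampling rate (Hz).
#' @param ... Passed to [utils::read.table()] (e.g. `sep`, `header`).
#' @return An [voltage_trace()] object.
#' @export
read_voltage_trace <- function(path, sampling_rate_hz = NULL, ...) {
  tab <- utils::read.table(path, ...)
  if (ncol(tab) < 2) stop("expected two columns: time_s, fluorescence",
                          call. = FALSE)
  tt <- as.numeric(tab[[1]]); y <- as.numeric(tab[[2]])
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- 1 / stats::median(diff(tt))
  }
  voltage_trace(y, sampling_rate_hz, t0_s = tt[1],
                metadata = list(source = path))
}

.trace_time <- function(trace) {
  trace$t0_s + (seq_along(trace$samples) - 1) / trace$sampling_rate_hz
}

# rolling lower-percentile baseline (robust to slow drift); window in samples
.rolling_baseline <- function(y, window, prob = 0.1) {
  n <- length(y)
  if (window >= n) { # window covers the trace: constant global baseline
    return(rep(stats::quantile(y, prob, names = FALSE, type = 7), n))
  }
  window <- max(3L, as.integer(window))
  half <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- stats::quantile(y[lo:hi], prob, names = FALSE, type = 7)
  }
  out
}

#' Segment a voltage trace into beats
#'
#' Detrends the trace with a rolling-percentile baseline, detects beats as
#' upward crossings of a fractional-amplitude threshold separated by a
#' refractory period, and assigns one non-overlapping window per beat. The
#' activation time of each beat is the time of the maximum upstroke
#' derivative inside its window.
#'
#' @param trace An [voltage_trace()] object.
#' @param threshold_frac Detection threshold as a fraction of the detrended
#'   signal's amplitude (default 0.5).
#' @param refractory_s Minimum separation between detected upstrokes (s).
#' @param baseline_window_s Window of the rolling-percentile detrend (s).
#' @param min_amplitude Minimum absolute detrended amplitude for the trace
#'   to count as beating at all (guards against detecting noise on a flat
#'   recording).
#' @param activation Activation-time reference: `"max_derivative"`
#'   (default) or `"upstroke50"` (time of the 50 % upstroke crossing).
#' @return A tibble with one row per beat: `beat`, `t_start_s`, `t_end_s`,
#'   `activation_time_s`, `rr_s` (interval to the next activation; `NA` for
#'   the last beat) — empty (with a warning) if no beats are found. The
#'   detrended signal is attached as attribute `"detrended"`.
#' @export
segment_beats <- function(trace, threshold_frac = 0.5, refractory_s = 0.25,
                          baseline_window_s = 1.5, min_amplitude = 1e-8,
                          activation = c("max_derivative", "upstroke50")) {
  stopifnot(inherits(trace, "mps_voltage_trace"))
  activation <- match.arg(activation)
  y <- trace$samples
  fs <- trace$sampling_rate_hz
  tt <- .trace_time(trace)
  base <- .rolling_baseline(y, round(baseline_window_s * fs))
  d <- y - base
  amp <- stats::quantile(d, 0.98, names = FALSE) # robust peak amplitude
  empty <- tibble::tibble(beat = integer(), t_start_s = numeric(),
                          t_end_s = numeric(), activation_time_s = numeric(),
                          rr_s = numeric())
  if (!is.finite(amp) || amp < min_amplitude) {
    warning("no beats detected (flat trace)", call. = FALSE)
    attr(empty, "detrended") <- d
    return(empty)
  }
  thr <- threshold_frac * amp
  up <- which(d[-1] >= thr & d[-length(d)] < thr) + 1L
  if (length(up) > 1) { # enforce refractory period
    keep <- c(TRUE, diff(tt[up]) >= refractory_s)
    while (!all(keep)) {
      up <- up[keep]
      keep <- c(TRUE, diff(tt[up]) >= refractory_s)
    }
  }
  if (length(up) == 0) {
    warning("no beats detected", call. = FALSE)
    attr(empty, "detrended") <- d
    return(empty)
  }
  # windows: from just before each upstroke to just before the next
  pre <- pmax(1L, up - as.integer(round(0.4 * refractory_s * fs)))
  w_start <- pre
  w_end <- c(pre[-1] - 1L, length(y))
  act <- numeric(length(up))
  for (k in seq_along(up)) {
    seg <- w_start[k]:w_end[k]
    if (activation == "max_derivative") {
      dd <- diff(d[seg])
      act[k] <- tt[seg[which.max(dd)]] + 0.5 / fs
    } else {
      peak_i <- seg[which.max(d[seg])]
      lvl <- 0.5 * d[peak_i]
      ci <- seg[seg <= peak_i]
      j <- which(d[ci] >= lvl)[1]
      act[k] <- if (is.na(j) || j == 1) tt[ci[1]] else {
        i0 <- ci[j - 1]; i1 <- ci[j]
        tt[i0] + (lvl - d[i0]) / (d[i1] - d[i0]) * (tt[i1] - tt[i0])
      }
    }
  }
  out <- tibble::tibble(
    beat = seq_along(up),
    t_start_s = tt[w_start],
    t_end_s = tt[w_end],
    activation_time_s = act,
    rr_s = c(diff(act), NA_real_)
  )
  attr(out, "detrended") <- d
  out
}

#' Action potential duration at a repolarization level
#'
#' Duration from the beat's activation time to the first crossing of
#' `amplitude * (1 - level/100)` on the repolarizing flank, with linear
#' interpolation between samples. The per-beat amplitude is peak minus
#' diastolic baseline, the baseline being the median of the last 10 % of
#' the preceding diastolic interval (robust to drift).
#'
#' @param trace An [voltage_trace()] object.
#' @param beats A beat table from [segment_beats()].
#' @param level Percent repolarization in (0, 100); typically 30, 80 or 90.
#' @return Numeric vector of APDs in ms, one per beat; `NA` (with attribute
#'   `"flagged"`) where the beat never repolarizes to the level inside its
#'   window.
#' @export
apd <- function(trace, beats, level) {
  stopifnot(inherits(trace, "mps_voltage_trace"))
  if (level <= 0 || level >= 100) {
    stop("level must be in (0, 100)", call. = FALSE)
  }
  d <- attr(beats, "detrended")
  if (is.null(d)) stop("beats must come from segment_beats()", call. = FALSE)
  tt <- .trace_time(trace)
  fs <- trace$sampling_rate_hz
  out <- rep(NA_real_, nrow(beats))
  flagged <- logical(nrow(beats))
  for (k in seq_len(nrow(beats))) {
    seg <- which(tt >= beats$t_start_s[k] & tt <= beats$t_end_s[k])
    act_i <- which.min(abs(tt[seg] - beats$activation_time_s[k]))
    # diastolic baseline: median of the last 10 % of the pre-upstroke part
    pre <- seg[seg < seg[act_i]]
    baseline <- if (length(pre) >= 2) {
      stats::median(d[utils::tail(pre, max(1L, ceiling(length(pre) * 0.1)))])
    } else 0
    post <- seg[seg >= seg[act_i]]
    peak_rel <- which.max(d[post])
    amp_k <- d[post[peak_rel]] - baseline
    if (amp_k <= 0) { flagged[k] <- TRUE; next }
    lvl <- baseline + amp_k * (1 - level / 100)
    flank <- post[peak_rel:length(post)]
    below <- which(d[flank] <= lvl)
    if (length(below) == 0) { flagged[k] <- TRUE; next }
    j <- below[1]
    t_cross <- if (j == 1) tt[flank[1]] else {
      i0 <- flank[j - 1]; i1 <- flank[j]
      tt[i0] + (lvl - d[i0]) / (d[i1] - d[i0]) * (tt[i1] - tt[i0])
    }
    out[k] <- (t_cross - beats$activation_time_s[k]) * 1000
  }
  attr(out, "flagged") <- flagged
  out
}

#' Fridericia rate correction
#'
#' Cube-root rate correction normalizing an action potential duration to a
#' 60-BPM beat rate, the in vitro analog of the QTc correction:
#' `cAPD = APD / RR^(1/3)` with RR in seconds (RR = 1 s is the identity).
#'
#' @param apd_ms APD (ms).
#' @param rr_s RR interval (s, > 0).
#' @return Corrected APD (ms).
#' @export
fridericia <- function(apd_ms, rr_s) {
  if (any(!is.na(rr_s) & rr_s <= 0)) {
    stop("rr_s must be > 0", call. = FALSE)
  }
  apd_ms / rr_s^(1 / 3)
}

#' Repolarization triangulation
#'
#' `(cAPD80 - cAPD30) / cAPD80`: 0 for a rectangular action potential,
#' approaching 1 as the beat becomes triangular. Rising triangulation is a
#' proarrhythmic signature.
#'
#' @param capd30,capd80 Rate-corrected APDs (ms); requires
#'   `capd30 <= capd80` (a violation flags a segmentation failure).
#' @return Dimensionless triangulation in `[0, 1)`.
#' @export
triangulation <- function(capd30, capd80) {
  if (any(!is.na(capd80) & capd80 <= 0)) {
    stop("capd80 must be > 0", call. = FALSE)
  }
  bad <- !is.na(capd30) & !is.na(capd80) & capd30 > capd80
  if (any(bad)) {
    stop("invalid metric: capd30 > capd80 (check beat segmentation)",
         call. = FALSE)
  }
  (capd80 - capd30) / capd80
}

#' Per-beat action potential metrics
#'
#' Convenience wrapper: segments the trace, measures APD30/80/90 per beat,
#' applies the Fridericia correction using each beat's RR interval (the last
#' beat, which has no RR, borrows the median RR) and computes triangulation.
#'
#' @param trace An [voltage_trace()] object.
#' @param ... Passed to [segment_beats()].
#' @return A tibble with one row per beat: activation time, RR, beat rate
#'   (BPM), APD30/80/90, cAPD30/80/90 (ms) and triangulation.
#' @examples
#' ap <- make_ap_trace(ap_template_spec(noise_sd = 0), duration_s = 8)
#' beat_metrics(ap$trace)
#' @export
beat_metrics <- function(trace, ...) {
  beats <- segment_beats(trace, ...)
  if (nrow(beats) == 0) {
    return(tibble::tibble(beat = integer(), activation_time_s = numeric(),
                          rr_s = numeric(), beat_rate_bpm = numeric(),
                          apd30 = numeric(), apd80 = numeric(),
                          apd90 = numeric(), capd30 = numeric(),
                          capd80 = numeric(), capd90 = numeric(),
                          triangulation = numeric()))
  }
  rr <- beats$rr_s
  rr[is.na(rr)] <- stats::median(rr, na.rm = TRUE)
  a30 <- apd(trace, beats, 30)
  a80 <- apd(trace, beats, 80)
  a90 <- apd(trace, beats, 90)
  tibble::tibble(
    beat = beats$beat,
    activation_time_s = beats$activation_time_s,
    rr_s = rr,
    beat_rate_bpm = 60 / rr,
    apd30 = as.numeric(a30), apd80 = as.numeric(a80),
    apd90 = as.numeric(a90),
    capd30 = fridericia(as.numeric(a30), rr),
    capd80 = fridericia(as.numeric(a80), rr),
    capd90 = fridericia(as.numeric(a90), rr),
    triangulation = triangulation(fridericia(as.numeric(a30), rr),
                                  fridericia(as.numeric(a80), rr))
  )
}

#' Hill-equation dose-response fit
#'
#' Least-squares fit of the log-logistic (Hill) model
#' `response = floor + (ceiling - floor) / (1 + 10^(slope * (log10(EC50) -
#' log10(dose))))`. The default is the three-parameter form (EC50 and the
#' two asymptotes free, slope fixed at 1); `slope = "free"` fits the
#' four-parameter form. For a fixed slope the model is linear in the two
#' asymptotes, so the fit profiles them out with a weighted linear solve and
#' optimizes only log10(EC50) — robust, derivative-free, no starting values
#' needed.
#'
#' @param doses Dose vector (nM, > 0 for finite log-dose; zero doses are
#'   kept and enter the Hill denominator exactly).
#' @param responses Response vector (same length).
#' @param slope Numeric fixed Hill slope (default 1) or `"free"`.
#' @return An object of class `mps_hill_fit`: list with `ec50`, `slope`,
#'   `floor`, `ceiling`, `residual_norm`, `converged`, `no_fit` (degenerate
#'   flat responses), and `fitted`.
#' @export
fit_hill <- function(doses, responses, slope = 1) {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses)) {
    stop("doses and responses must have equal length", call. = FALSE)
  }
  if (any(!is.finite(responses)) || any(!is.finite(doses)) ||
      any(doses < 0)) {
    stop("doses must be finite and >= 0; responses finite", call. = FALSE)
  }
  if (all(doses == 0)) stop("all doses are zero", call. = FALSE)
  if (length(unique(doses)) < 4) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  out <- list(ec50 = NA_real_, slope = if (identical(slope, "free"))
    NA_real_ else slope, floor = NA_real_, ceiling = NA_real_,
    residual_norm = NA_real_, converged = FALSE, no_fit = FALSE,
    fitted = rep(NA_real_, length(doses)))
  class(out) <- "mps_hill_fit"
  if (diff(range(responses)) < 1e-12 * max(1, abs(mean(responses)))) {
    out$no_fit <- TRUE
    return(out)
  }
  # fractional occupancy at a given log10-EC50 and slope; exact at dose 0
  occ <- function(le, sl) {
    f <- numeric(length(doses))
    pos <- doses > 0
    f[pos] <- 1 / (1 + 10^(sl * (le - log10(doses[pos]))))
    f
  }
  sse <- function(le, sl) {
    f <- occ(le, sl)
    X <- cbind(1 - f, f)
    # extreme EC50 probes make X rank-deficient; those probes are simply
    # scored as unusable rather than warned about
    cf <- tryCatch(
      suppressWarnings(
        stats::lsfit(X, responses, intercept = FALSE)$coefficients),
      error = function(e) c(NA, NA))
    if (any(abs(cf) > 1e12)) cf <- c(NA, NA)
    if (any(!is.finite(cf))) return(list(sse = Inf, cf = cf))
    r <- responses - X %*% cf
    list(sse = sum(r^2), cf = cf)
  }
  lr <- range(log10(doses[doses > 0]))
  lo <- lr[1] - 2; hi <- lr[2] + 2
  if (identical(slope, "free")) {
    obj <- function(p) sse(p[1], exp(p[2]))$sse
    best <- NULL
    for (le0 in seq(lo, hi, length.out = 5)) {
      o <- stats::optim(c(le0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    le <- best$par[1]; sl <- exp(best$par[2])
    conv <- best$convergence == 0
  } else {
    sl <- slope
    grid <- seq(lo, hi, length.out = 121)
    g <- vapply(grid, function(le) sse(le, sl)$sse, numeric(1))
    k <- which.min(g)
    o <- stats::optimize(function(le) sse(le, sl)$sse,
                         interval = c(grid[max(1, k - 1)],
                                      grid[min(length(grid), k + 1)]),
                         tol = 1e-12)
    le <- o$minimum
    conv <- TRUE
  }
  fin <- sse(le, sl)
  out$ec50 <- 10^le
  out$slope <- sl
  out$floor <- unname(fin$cf[1])
  out$ceiling <- unname(fin$cf[2])
  out$residual_norm <- sqrt(fin$sse)
  out$converged <- conv && is.finite(fin$sse)
  f <- occ(le, sl)
  out$fitted <- as.numeric(cbind(1 - f, f) %*% fin$cf)
  out
}

#' @export
print.mps_hill_fit <- function(x, ...) {
  if (x$no_fit) {
    cat("Hill fit: degenerate (flat response range), no fit\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Hill fit: EC50 = %.4g nM, slope = %.3g, floor = %.4g, ceiling = %.4g\n",
    x$ec50, x$slope, x$floor, x$ceiling))
  cat(sprintf("  residual norm %.3g, converged: %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

#' Margin of safety
#'
#' Ratio of the measured EC50 to the estimated therapeutic plasma
#' concentration (ETPC). With the device EC50 of 9.63 nM and an ETPC of
#' 2.6 nM for cisapride this gives about 3.7-fold.
#'
#' @param ec50_nM EC50 (nM, > 0).
#' @param etpc_nM Estimated therapeutic plasma concentration (nM, > 0).
#' @return Fold margin (dimensionless).
#' @export
margin_of_safety <- function(ec50_nM, etpc_nM) {
  if (any(ec50_nM <= 0) || any(etpc_nM <= 0)) {
    stop("ec50_nM and etpc_nM must be > 0", call. = FALSE)
  }
  ec50_nM / etpc_nM
}
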