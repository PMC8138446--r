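# run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards: generators are pure functions of (spec, seed)
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Template for synthetic optical action potentials
#'
#' Describes the ground truth of a generated voltage trace: beat rate, the
#' three target repolarization durations, amplitude, slow baseline drift
#' and additive Gaussian noise. Defaults emulate a spontaneously beating
#' cardiac MPS imaged with a voltage dye: 30 BPM, APD30/80/90 of
#' 200/350/400 ms, unit amplitude, mild drift and noise.
#'
#' @param beat_rate_bpm Beat rate (BPM).
#' @param apd30_ms,apd80_ms,apd90_ms Target APDs (ms); must satisfy
#'   `apd30 < apd80 < apd90 < RR`.
#' @param amplitude Beat amplitude (a.u.); 0 produces a flat trace.
#' @param drift_rate Linear baseline drift (a.u./s).
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param seed Integer seed; the generator is a pure function of
#'   (spec, seed).
#' @return An object of class `mps_ap_spec`.
#' @export
ap_template_spec <- function(beat_rate_bpm = 30, apd30_ms = 200,
                             apd80_ms = 350, apd90_ms = 400,
                             amplitude = 1, drift_rate = 0.01,
                             noise_sd = 0.02, sampling_rate_hz = 100,
                             seed = 1L) {
  rr_ms <- 60000 / beat_rate_bpm
  if (!(apd30_ms < apd80_ms && apd80_ms < apd90_ms && apd90_ms < rr_ms)) {
    stop("inconsistent spec: need APD30 < APD80 < APD90 < RR",
         call. = FALSE)
  }
  if (noise_sd < 0 || amplitude < 0) {
    stop("amplitude and noise_sd must be >= 0", call. = FALSE)
  }
  structure(list(beat_rate_bpm = beat_rate_bpm, apd30_ms = apd30_ms,
                 apd80_ms = apd80_ms, apd90_ms = apd90_ms,
                 amplitude = amplitude, drift_rate = drift_rate,
                 noise_sd = noise_sd, sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)), class = "mps_ap_spec")
}

#' Generate a synthetic optical action potential trace
#'
#' Builds a beat template with a half-cosine upstroke (20 ms; the maximum
#' derivative, the activation reference, falls exactly at its midpoint) and
#' a repolarizing flank interpolated by a monotone cubic through the three
#' specified crossing points, so the 30/80/90 % repolarization times equal
#' the spec's APDs by construction — no root-finding, exact ground truth.
#' Linear baseline drift and Gaussian noise are added on top.
#'
#' @param spec An [ap_template_spec()].
#' @param duration_s Trace duration (s); must cover at least 3 beats.
#' @return A list with `trace` (an [voltage_trace()]) and `truth` (tibble
#'   of per-beat activation time, RR, APDs, Fridericia-corrected APDs and
#'   triangulation).
#' @export
make_ap_trace <- function(spec, duration_s = 10) {
  stopifnot(inherits(spec, "mps_ap_spec"))
  rr_s <- 60 / spec$beat_rate_bpm
  fs <- spec$sampling_rate_hz
  if (duration_s < 3 * rr_s) {
    stop("duration must cover at least 3 beats", call. = FALSE)
  }
  up_ms <- min(20, 0.5 * spec$apd30_ms)
  tail_ms <- spec$apd90_ms + 0.5 * (spec$apd90_ms - spec$apd80_ms)
  tail_ms <- min(tail_ms, 0.98 * 1000 * rr_s - up_ms / 2)
  A <- spec$amplitude
  kx <- c(up_ms / 2, 0.6 * spec$apd30_ms, spec$apd30_ms,
          spec$apd80_ms, spec$apd90_ms, tail_ms)
  ky <- c(A, A, 0.7 * A, 0.2 * A, 0.1 * A, 0)
  flank <- stats::splinefun(kx, ky, method = "monoH.FC")
  beat_wave <- function(tau_ms) { # tau relative to activation time
    v <- numeric(length(tau_ms))
    i_up <- tau_ms >= -up_ms / 2 & tau_ms < up_ms / 2
    v[i_up] <- A * (1 - cos(pi * (tau_ms[i_up] + up_ms / 2) / up_ms)) / 2
    i_fl <- tau_ms >= up_ms / 2 & tau_ms <= tail_ms
    v[i_fl] <- pmax(0, flank(tau_ms[i_fl]))
    v
  }
  tt <- seq(0, duration_s, by = 1 / fs)
  t_act <- seq(0.5 * rr_s, duration_s - 1.2 * rr_s + 0.5 * rr_s, by = rr_s)
  t_act <- t_act[t_act + tail_ms / 1000 <= duration_s]
  y <- numeric(length(tt))
  for (ta in t_act) y <- y + beat_wave((tt - ta) * 1000)
  y <- y + spec$drift_rate * tt
  if (spec$noise_sd > 0) {
    y <- y + .with_seed(spec$seed, stats::rnorm(length(y), 0, spec$noise_sd))
  }
  truth <- tibble::tibble(
    beat = seq_along(t_act),
    activation_time_s = t_act,
    rr_s = rr_s,
    apd30 = spec$apd30_ms, apd80 = spec$apd80_ms, apd90 = spec$apd90_ms,
    capd30 = fridericia(spec$apd30_ms, rr_s),
    capd80 = fridericia(spec$apd80_ms, rr_s),
    capd90 = fridericia(spec$apd90_ms, rr_s)
  )
  truth$triangulation <- triangulation(truth$capd30, truth$capd80)
  list(trace = voltage_trace(y, fs, metadata = list(synthetic = TRUE)),
       truth = truth)
}

#' Specification of a synthetic contraction video
#'
#' A random smooth texture rigidly translated by a periodic displacement
#' waveform `s(t) = amplitude * sin(pi t / period)^2` (one
#' contraction-relaxation excursion per period), rounded to whole pixels
#' per frame — so exhaustive block matching can recover the motion exactly.
#'
#' @param shape Frame size in pixels, `c(rows, cols)`.
#' @param granularity_px Correlation length of the texture (pixels).
#' @param amplitude_px Peak displacement (pixels); keep within the intended
#'   search radius.
#' @param period_s Displacement period (s), i.e. one beat; must exceed two
#'   frame periods.
#' @param frame_rate_hz Frame rate (Hz).
#' @param seed Integer seed.
#' @return An object of class `mps_video_spec`.
#' @export
video_spec <- function(shape = c(64, 64), granularity_px = 4,
                       amplitude_px = 3, period_s = 2,
                       frame_rate_hz = 100, seed = 1L) {
  if (period_s <= 2 / frame_rate_hz) {
    stop("period must exceed two frame periods", call. = FALSE)
  }
  if (amplitude_px < 0) stop("amplitude_px must be >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape),
                 granularity_px = granularity_px,
                 amplitude_px = amplitude_px, period_s = period_s,
                 frame_rate_hz = frame_rate_hz, seed = as.integer(seed)),
            class = "mps_video_spec")
}

#' Video stack container
#'
#' @param frames 3-D numeric array `[rows, cols, frames]` of grayscale
#'   intensities; at least 6 frames.
#' @param frame_rate_hz Frame rate (Hz).
#' @param pixel_size_um Optional pixel size (um/px).
#' @return An object of class `mps_video`.
#' @export
video_stack <- function(frames, frame_rate_hz, pixel_size_um = NA_real_) {
  if (!is.array(frames) || length(dim(frames)) != 3 || dim(frames)[3] < 6) {
    stop("frames must be a [rows, cols, >=6 frames] array", call. = FALSE)
  }
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um), class = "mps_video")
}

#' @export
print.mps_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Video stack: %d x %d px, %d frames at %g Hz\n",
              d[1], d[2], d[3], x$frame_rate_hz))
  invisible(x)
}

# smooth random texture via repeated box blur of white noise
.smooth_texture <- function(nr, nc, granularity) {
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  w <- max(1L, as.integer(round(granularity)))
  if (w > 1) {
    k <- rep(1 / w, w)
    for (pass in 1:2) {
      m <- apply(m, 2, function(col)
        stats::filter(col, k, circular = TRUE))
      m <- t(apply(m, 1, function(row)
        stats::filter(row, k, circular = TRUE)))
    }
  }
  (m - min(m)) / (max(m) - min(m))
}

#' Generate a synthetic contraction video
#'
#' @param spec A [video_spec()].
#' @param duration_s Video duration (s).
#' @return A list with `video` (a [video_stack()]) and `truth` (tibble of
#'   per-frame integer displacement `dx` applied along the column axis).
#' @export
make_contraction_video <- function(spec, duration_s = 4) {
  stopifnot(inherits(spec, "mps_video_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  nframes <- max(6L, as.integer(floor(duration_s * spec$frame_rate_hz)))
  tt <- (seq_len(nframes) - 1) / spec$frame_rate_hz
  shift <- as.integer(round(
    spec$amplitude_px * sin(pi * tt / spec$period_s)^2))
  pad <- max(shift) + 1L
  tex <- .with_seed(spec$seed, .smooth_texture(nr, nc + 2L * pad,
                                               spec$granularity_px))
  frames <- array(0, dim = c(nr, nc, nframes))
  for (f in seq_len(nframes)) {
    # crop window slides with the waveform: rigid translation of the scene
    frames[, , f] <- tex[, (pad + 1L - shift[f]):(pad + nc - shift[f])]
  }
  truth <- tibble::tibble(frame = seq_len(nframes), time_s = tt,
                          dx = shift, dy = 0L)
  list(video = video_stack(frames, spec$frame_rate_hz), truth = truth)
}

#' Generate Hill-shaped dose-response data
#'
#' Hill-model means with multiplicative Gaussian noise, in tidy long
#' format — the format [fit_hill()] consumes.
#'
#' @param ec50_nM EC50 of the generating curve (nM).
#' @param slope Hill slope.
#' @param floor,ceiling Lower and upper asymptotes (response units).
#' @param doses Dose levels (nM, > 0).
#' @param noise_cv Coefficient of variation of multiplicative noise.
#' @param n_reps Replicates per dose.
#' @param seed Integer seed.
#' @return A tibble with columns `dose_nM`, `replicate`, `response`.
#' @export
make_dose_response <- function(ec50_nM, slope = 1, floor = 1, ceiling = 1.5,
                               doses = c(1, 3, 10, 30, 100, 300),
                               noise_cv = 0.05, n_reps = 4, seed = 1L) {
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  tab <- expand.grid(replicate = seq_len(n_reps), dose_nM = doses)
  tab <- tab[order(tab$dose_nM, tab$replicate), ]
  mu_all <- floor + (ceiling - floor) /
    (1 + 10^(slope * (log10(ec50_nM) - log10(tab$dose_nM))))
  noise <- if (noise_cv > 0) {
    .with_seed(seed, stats::rnorm(nrow(tab), 0, noise_cv))
  } else 0
  tibble::tibble(dose_nM = tab$dose_nM, replicate = tab$replicate,
                 response = mu_all * (1 + noise))
}
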