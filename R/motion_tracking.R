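#' Exhaustive-search block matching between two frames
#'
#' Tiles `frame_i` into square macroblocks (8 x 8 px by default) and, for
#' each block, finds the integer displacement within `search_radius` that
#' minimizes the matching cost (sum of absolute differences by default)
#' against `frame_j` — the full search window is evaluated, so the reported
#' displacement is the global cost minimum by construction. Ties are broken
#' by smaller displacement magnitude, then lexicographically (dx, then dy).
#' A true shift beyond the radius yields a clamped best match at the window
#' edge, flagged in the output; low-texture blocks (intensity variance
#' below `var_threshold`) are marked invalid rather than contributing noise
#' vectors.
#'
#' @param frame_i,frame_j Numeric matrices of equal shape (grayscale).
#' @param block_size Macroblock edge (px, >= 2; default 8).
#' @param search_radius Maximum displacement searched per axis (px, >= 1).
#' @param stride Block tiling step (px); defaults to `block_size`
#'   (non-overlapping tiles).
#' @param cost `"sad"` (default) or `"ssd"`.
#' @param var_threshold Minimum block intensity variance for a valid vector.
#' @return A tibble with one row per block: `row`, `col` (1-based top-left
#'   corner), `dy`, `dx` (px), `cost`, `clamped`, `valid`.
#' @export
block_match <- function(frame_i, frame_j, block_size = 8, search_radius = 7,
                        stride = block_size, cost = c("sad", "ssd"),
                        var_threshold = 0) {
  cost <- match.arg(cost)
  if (!is.matrix(frame_i) || !is.matrix(frame_j) ||
      !all(dim(frame_i) == dim(frame_j))) {
    stop("frames must be matrices of identical shape", call. = FALSE)
  }
  if (block_size < 2 || search_radius < 1 || stride < 1) {
    stop("need block_size >= 2, search_radius >= 1, stride >= 1",
         call. = FALSE)
  }
  if (any(dim(frame_i) < block_size)) {
    stop("frame smaller than one block", call. = FALSE)
  }
  m <- .block_match_core(frame_i, frame_j, as.integer(block_size),
                         as.integer(search_radius), as.integer(stride),
                         cost == "ssd", var_threshold)
  tibble::tibble(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
                 dy = as.integer(m[, 3]), dx = as.integer(m[, 4]),
                 cost = m[, 5], clamped = m[, 6] > 0, valid = m[, 7] > 0)
}

#' Mean contraction speed over a video
#'
#' Applies [block_match()] to the frame pairs `(i, i + frame_lag)` and
#' reports, per pair, the mean displacement magnitude over valid blocks
#' divided by the lag — a motion-magnitude time series whose peaks mark
#' contraction and relaxation strokes. The conventional lag of 5 frames at
#' a 100 Hz recording compares positions 50 ms apart.
#'
#' @param video A [video_stack()].
#' @param frame_lag Frame offset between compared frames (default 5).
#' @param ... Passed to [block_match()].
#' @return A tibble with `frame`, `time_s`, and `mean_speed_px_frame`
#'   (mean |displacement| / lag over valid blocks).
#' @export
motion_series <- function(video, frame_lag = 5, ...) {
  stopifnot(inherits(video, "mps_video"))
  nframes <- dim(video$frames)[3]
  if (frame_lag >= nframes) {
    stop("frame_lag must be smaller than the number of frames",
         call. = FALSE)
  }
  n_pairs <- nframes - frame_lag
  speed <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    mf <- block_match(video$frames[, , i], video$frames[, , i + frame_lag],
                      ...)
    ok <- mf$valid
    speed[i] <- if (any(ok)) {
      mean(sqrt(mf$dx[ok]^2 + mf$dy[ok]^2)) / frame_lag
    } else NA_real_
  }
  tibble::tibble(frame = seq_len(n_pairs),
                 time_s = (seq_len(n_pairs) - 1) / video$frame_rate_hz,
                 mean_speed_px_frame = speed)
}

# motion strokes: contiguous runs of above-threshold speed, with gaps
# shorter than merge_gap_s bridged (whole-pixel quantization chops one
# stroke into several short bumps); returns the speed-weighted centroid
# time of each stroke
.motion_strokes <- function(t, y, frac = 0.3, merge_gap_s = 0.3) {
  y[is.na(y)] <- 0
  if (max(y) <= 0) return(numeric(0))
  active <- y >= frac * max(y)
  idx <- which(active)
  if (length(idx) == 0) return(numeric(0))
  brk <- c(0, which(t[idx[-1]] - t[idx[-length(idx)]] > merge_gap_s),
           length(idx))
  vapply(seq_len(length(brk) - 1), function(k) {
    run <- idx[(brk[k] + 1):brk[k + 1]]
    sum(t[run] * y[run]) / sum(y[run])
  }, numeric(1))
}

#' Beat rate from a motion-magnitude series
#'
#' Each beat produces two motion peaks (contraction and relaxation).
#' Successive peaks are paired into beats and the rate is 60 over the
#' median inter-beat interval; with too few peaks to pair, twice the median
#' inter-peak interval is used as the beat period.
#'
#' @param series A tibble from [motion_series()] (columns `time_s`,
#'   `mean_speed_px_frame`).
#' @param peak_frac Stroke detection threshold as a fraction of the
#'   maximum speed.
#' @param merge_gap_s Above-threshold episodes separated by less than this
#'   gap (s) are treated as one stroke.
#' @return Beat rate in BPM, or `NA` (with a warning) when fewer than two
#'   motion strokes are present (e.g. a static video).
#' @export
beat_rate_from_motion <- function(series, peak_frac = 0.3,
                                  merge_gap_s = 0.3) {
  pk <- .motion_strokes(series$time_s, series$mean_speed_px_frame,
                        frac = peak_frac, merge_gap_s = merge_gap_s)
  if (length(pk) < 2) {
    warning("fewer than 2 motion strokes: beat rate unavailable",
            call. = FALSE)
    return(NA_real_)
  }
  if (length(pk) >= 4) {
    beat_t <- pk[seq(1, length(pk) - 1, by = 2)] # contraction onsets
    60 / stats::median(diff(beat_t))
  } else {
    60 / (2 * stats::median(diff(pk)))
  }
}
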