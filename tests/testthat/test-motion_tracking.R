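shift_frame <- function(f, dy, dx) {
  # rigid integer translation with wrap-around (interior blocks see a pure
  # shift; tests only assert on blocks away from the wrapped margin)
  nr <- nrow(f); nc <- ncol(f)
  f[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

random_texture <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(stats::runif(nr * nc), nr, nc)
}

test_that("identical frames give all-zero displacement at zero cost", {
  f <- random_texture(40, 40, 1)
  mf <- block_match(f, f, search_radius = 5)
  expect_true(all(mf$dx == 0 & mf$dy == 0))
  expect_true(all(mf$cost == 0))
})

test_that("integer shifts within the radius are recovered bit-exactly", {
  f <- random_texture(48, 48, 2)
  for (case in list(c(3, 2), c(-2, 4), c(0, -5), c(5, 5))) {
    g <- shift_frame(f, case[1], case[2])
    mf <- block_match(f, g, search_radius = 5)
    interior <- mf$row > 8 & mf$row < 32 & mf$col > 8 & mf$col < 32
    expect_true(all(mf$dy[interior] == case[1]))
    expect_true(all(mf$dx[interior] == case[2]))
    expect_true(all(mf$cost[interior] == 0))
  }
})

test_that("matching equals the brute-force R oracle, including tie-breaks", {
  for (seed in 1:3) {
    f <- random_texture(24, 24, seed)
    set.seed(100 + seed)
    g <- f + matrix(stats::rnorm(24 * 24, 0, 0.1), 24, 24)
    mf <- block_match(f, g, block_size = 6, search_radius = 3, stride = 6)
    or <- block_match_oracle(f, g, block = 6, radius = 3, stride = 6)
    expect_equal(mf$dy, or$dy)
    expect_equal(mf$dx, or$dx)
    expect_equal(mf$cost, or$cost, tolerance = 1e-12)
  }
})

test_that("the reported displacement is the global cost minimum", {
  f <- random_texture(20, 20, 9)
  g <- shift_frame(f, 1, -2) + 0.05
  mf <- block_match(f, g, block_size = 8, search_radius = 2, stride = 8)
  sad <- function(r0, c0, dy, dx) {
    sum(abs(f[r0:(r0 + 7), c0:(c0 + 7)] -
              g[(r0 + dy):(r0 + dy + 7), (c0 + dx):(c0 + dx + 7)]))
  }
  for (k in seq_len(nrow(mf))) {
    for (dy in -2:2) for (dx in -2:2) {
      tr <- mf$row[k] + dy; tc <- mf$col[k] + dx
      if (tr < 1 || tc < 1 || tr + 7 > 20 || tc + 7 > 20) next
      expect_lte(mf$cost[k], sad(mf$row[k], mf$col[k], dy, dx) + 1e-12)
    }
  }
})

test_that("pure translations are antisymmetric under frame exchange", {
  f <- random_texture(40, 40, 5)
  g <- shift_frame(f, 2, -3)
  a <- block_match(f, g, search_radius = 4)
  b <- block_match(g, f, search_radius = 4)
  interior <- a$row > 8 & a$row < 26 & a$col > 8 & a$col < 26
  expect_equal(a$dy[interior], -b$dy[interior])
  expect_equal(a$dx[interior], -b$dx[interior])
})

test_that("shifts beyond the search radius clamp at the window edge", {
  # smooth texture: the cost landscape decreases toward the true shift, so
  # the exhaustive search pins the best match to the window edge
  f <- outer(seq_len(40), seq_len(40),
             function(a, b) sin(a / 3) + cos(b / 2.5) + 0.1 * sin(a * b / 40))
  g <- shift_frame(f, 0, 6)
  mf <- block_match(f, g, search_radius = 3)
  interior <- mf$row > 8 & mf$row < 26 & mf$col > 8 & mf$col < 26
  expect_true(all(abs(mf$dx[interior]) <= 3))
  expect_true(all(mf$clamped[interior]))
  expect_true(all(mf$cost[interior] > 0))
})

test_that("low-texture blocks are marked invalid", {
  f <- random_texture(32, 32, 7)
  f[1:8, 1:8] <- 0.5 # one flat block
  mf <- block_match(f, f, var_threshold = 1e-6)
  expect_false(mf$valid[mf$row == 1 & mf$col == 1])
  expect_true(all(mf$valid[!(mf$row == 1 & mf$col == 1)]))
  expect_error(block_match(f[1:4, 1:4], f[1:4, 1:4]), "smaller")
})

test_that("motion series and beat rate recover the generated contraction rhythm", {
  v <- make_contraction_video(video_spec(frame_rate_hz = 20, period_s = 2,
                                         amplitude_px = 3, seed = 11),
                              duration_s = 6)
  ms <- motion_series(v$video, frame_lag = 2, search_radius = 4)
  expect_equal(nrow(ms), dim(v$video$frames)[3] - 2)
  bpm <- beat_rate_from_motion(ms)
  expect_equal(bpm, 30, tolerance = 1 / 30) # 30 +- 1 BPM
  # static video: all-zero series, no rate
  v0 <- make_contraction_video(video_spec(frame_rate_hz = 20,
                                          amplitude_px = 0, seed = 3),
                               duration_s = 2)
  ms0 <- motion_series(v0$video, frame_lag = 2, search_radius = 4)
  expect_true(all(ms0$mean_speed_px_frame == 0))
  expect_warning(b0 <- beat_rate_from_motion(ms0), "fewer than 2")
  expect_true(is.na(b0))
  expect_error(motion_series(v0$video, frame_lag = 1000), "frame_lag")
})

test_that("beat rate is invariant to the frame rate of the recording", {
  b <- vapply(c(20, 40), function(fr) {
    v <- make_contraction_video(video_spec(frame_rate_hz = fr,
                                           period_s = 2, amplitude_px = 3,
                                           seed = 12), duration_s = 6)
    beat_rate_from_motion(motion_series(v$video, frame_lag = fr / 10,
                                        search_radius = 4))
  }, numeric(1))
  expect_equal(b[1], b[2], tolerance = 1 / 30)
})
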