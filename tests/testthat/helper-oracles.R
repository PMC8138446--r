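# Independent oracles used by the property tests. These are deliberately
# written as brute-force / dense implementations built directly from the
# definitions, sharing no code with the package internals they check.

# --- dense direct steady solve of the transport equations ------------------
# Node-by-node dense assembly of the finite-volume equations (harmonic-mean
# face diffusivities, first-order upwind advection, Dirichlet inlet on media
# rows, optional ambient Dirichlet on the top row, optional lateral wall
# exchange and Michaelis-Menten sink linearized by outer fixed-point
# iteration), solved with base R's dense `solve`.
dense_steady_oracle <- function(dev, top_dirichlet = NULL, inlet = NULL,
                                ambient = NULL, uptake = FALSE,
                                tol = 1e-12, maxit = 300) {
  nx <- dev$nx; nz <- dev$nz; dx <- dev$dx
  dz <- dev$dz; D <- dev$D_row; u <- dev$u_row
  n <- nx * nz
  id <- function(ix, iz) (ix - 1) * nz + iz
  kms <- km_in_concentration_units(dev$params)
  vmr <- dev$params$VO2max_mol_s_cell * dev$params$rho_cell_per_m3

  cvec <- rep(if (is.null(inlet)) 0 else inlet, n)
  for (outer in seq_len(maxit)) {
    A <- matrix(0, n, n); b <- numeric(n)
    for (ix in seq_len(nx)) {
      for (iz in seq_len(nz)) {
        i <- id(ix, iz)
        # vertical neighbours
        for (s in c(-1, 1)) {
          jz <- iz + s
          if (jz >= 1 && jz <= nz) {
            dzc <- (dz[iz] + dz[jz]) / 2
            Df <- dzc / (dz[iz] / (2 * D[iz]) + dz[jz] / (2 * D[jz]))
            G <- Df * dx / dzc
            A[i, i] <- A[i, i] + G
            A[i, id(ix, jz)] <- A[i, id(ix, jz)] - G
          }
        }
        # horizontal neighbours: diffusion both ways, upwind advection
        for (s in c(-1, 1)) {
          jx <- ix + s
          if (jx >= 1 && jx <= nx) {
            G <- D[iz] * dz[iz] / dx
            A[i, i] <- A[i, i] + G
            A[i, id(jx, iz)] <- A[i, id(jx, iz)] - G
          }
        }
        if (u[iz] > 0) {
          f <- u[iz] * dz[iz]
          if (ix < nx) A[i, i] <- A[i, i] + f       # flux out to the right
          else A[i, i] <- A[i, i] + f               # outflow face
          if (ix > 1) A[i, id(ix - 1, iz)] <- A[i, id(ix - 1, iz)] - f
        }
        # boundaries
        if (iz == nz && !is.null(top_dirichlet)) {
          G <- D[iz] * dx / (dz[iz] / 2)
          A[i, i] <- A[i, i] + G
          b[i] <- b[i] + G * top_dirichlet
        }
        if (ix == 1 && !is.null(inlet) && u[iz] > 0) {
          G <- D[iz] * dz[iz] / (dx / 2)
          A[i, i] <- A[i, i] + G
          b[i] <- b[i] + G * inlet + u[iz] * dz[iz] * inlet
        }
        if (!is.null(ambient) && dev$gamma_row[iz] > 0) {
          gv <- dev$gamma_row[iz] * dz[iz] * dx
          A[i, i] <- A[i, i] + gv
          b[i] <- b[i] + gv * ambient
        }
        if (uptake && dev$layer[iz] == "cell") {
          s_lin <- vmr / (kms + max(cvec[i], 0))
          A[i, i] <- A[i, i] + s_lin * dz[iz] * dx
        }
      }
    }
    cnew <- solve(A, b)
    if (max(abs(cnew - cvec)) <= tol * max(abs(cnew), 1)) {
      return(cnew)
    }
    cvec <- cnew
    if (!uptake) return(cvec) # linear problem: one solve is exact
  }
  cvec
}

# --- brute-force block matching -------------------------------------------
# Definitionally exhaustive SAD/SSD search in plain R loops.
block_match_oracle <- function(a, b, block = 8, radius = 7,
                               stride = block, ssd = FALSE) {
  nr <- nrow(a); nc <- ncol(a)
  res <- NULL
  for (r0 in seq(1, nr - block + 1, by = stride)) {
    for (c0 in seq(1, nc - block + 1, by = stride)) {
      blk <- a[r0:(r0 + block - 1), c0:(c0 + block - 1)]
      best <- Inf; bdy <- 0L; bdx <- 0L; found <- FALSE
      for (dy in -radius:radius) {
        for (dx in -radius:radius) {
          tr <- r0 + dy; tc <- c0 + dx
          if (tr < 1 || tc < 1 || tr + block - 1 > nr ||
              tc + block - 1 > nc) next
          d <- blk - b[tr:(tr + block - 1), tc:(tc + block - 1)]
          cost <- if (ssd) sum(d^2) else sum(abs(d))
          better <- !found || cost < best ||
            (cost == best && (dx^2 + dy^2 < bdx^2 + bdy^2 ||
                                (dx^2 + dy^2 == bdx^2 + bdy^2 &&
                                   (dx < bdx || (dx == bdx && dy < bdy)))))
          if (better) { best <- cost; bdy <- dy; bdx <- dx; found <- TRUE }
        }
      }
      res <- rbind(res, c(r0, c0, bdy, bdx, best))
    }
  }
  colnames(res) <- c("row", "col", "dy", "dx", "cost")
  as.data.frame(res)
}

# --- grid-search calibration of the metabolism kinetics --------------------
# Full 3-D grid over (A, tau, Ki), refined around the running optimum.
metab_grid_oracle <- function(obs, rounds = 4, npts = 13) {
  sse_at <- function(A, tau, Ki) {
    f <- A * (1 - exp(-obs$time_h / tau)) / (1 + obs$inhibitor_uM / Ki)
    sum((obs$fraction_pct - f)^2)
  }
  lims <- list(A = c(1, 60), tau = c(0.5, 200), Ki = c(0.2, 100))
  best <- NULL
  for (round in seq_len(rounds)) {
    As <- exp(seq(log(lims$A[1]), log(lims$A[2]), length.out = npts))
    ts <- exp(seq(log(lims$tau[1]), log(lims$tau[2]), length.out = npts))
    ks <- exp(seq(log(lims$Ki[1]), log(lims$Ki[2]), length.out = npts))
    for (A in As) for (tau in ts) for (Ki in ks) {
      s <- sse_at(A, tau, Ki)
      if (is.null(best) || s < best$sse) {
        best <- list(A = A, tau = tau, Ki = Ki, sse = s)
      }
    }
    shrink <- function(lim, centre) {
      w <- (lim[2] / lim[1])^(1 / (npts - 1)) # one grid step, log scale
      c(centre / w^2, centre * w^2)
    }
    lims <- list(A = shrink(lims$A, best$A),
                 tau = shrink(lims$tau, best$tau),
                 Ki = shrink(lims$Ki, best$Ki))
  }
  best
}

# --- shared fixtures -------------------------------------------------------
default_geometry <- function() device_geometry()
default_params <- function() transport_params()
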