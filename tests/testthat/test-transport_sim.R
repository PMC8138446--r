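coarse_nz <- c(cell = 3, membrane = 3, media = 3, pdms = 3)

test_that("discretization applies the effective-medium and partition rules", {
  geo <- default_geometry(); par <- default_params()
  dev <- discretize_device(geo, par, nx = 20, nz_per_layer = coarse_nz)
  # membrane: porosity-scaled diffusivity and capacity
  expect_equal(unique(dev$D_row[dev$layer == "membrane"]), 0.056 * 3.0e-9)
  expect_equal(unique(dev$theta_row[dev$layer == "membrane"]), 0.056)
  # Henry partition at the media-PDMS interface: 1.11 / 0.173
  expect_equal(dev$k_part, 1.11 / 0.173, tolerance = 1e-12)
  expect_equal(unique(dev$D_row[dev$layer == "pdms"]),
               dev$k_part * 3.25e-9)
  # transparent membrane limit
  open <- discretize_device(device_geometry(membrane_porosity = 1 - 1e-12),
                            par, nx = 20, nz_per_layer = coarse_nz)
  expect_equal(unique(open$D_row[open$layer == "membrane"]), 3.0e-9,
               tolerance = 1e-9)
  # no flow outside the media channel; discrete flow rate is exact
  expect_true(all(dev$u_row[dev$layer != "media"] == 0))
  g <- mpsddi:::.geo_m(geo)
  expect_equal(sum(dev$u_row * dev$dz) * g$W, 20e-9 / 3600,
               tolerance = 1e-12)
  expect_error(discretize_device(geo, par, nx = 5), "nx")
  expect_error(discretize_device(geo, par, nx = 20,
                                 nz_per_layer = c(cell = 2, membrane = 3,
                                                  media = 3, pdms = 3)),
               "refinement")
})

test_that("Michaelis-Menten sink follows the printed uptake law", {
  par <- default_params()
  kms <- km_in_concentration_units(par)
  vmr <- par$VO2max_mol_s_cell * par$rho_cell_per_m3
  expect_equal(mm_uptake(0, par), 0)
  expect_equal(mm_uptake(kms, par), -vmr / 2)
  # saturation: the product of the printed constants, ~6.7e-3 mol/m^3/s
  expect_equal(mm_uptake(100, par), -vmr, tolerance = 1e-3)
  expect_equal(vmr, 6.7e-3, tolerance = 0.01)
  expect_error(mm_uptake(-0.1, par), "must be >= 0")
})

test_that("with no uptake and no PDMS flux the field equilibrates at the inlet value", {
  dev <- discretize_device(default_geometry(), default_params(),
                           nx = 15, nz_per_layer = coarse_nz)
  st <- solve_steady_oxygen(dev, pdms_flux = "off", uptake = FALSE)
  expect_equal(st$summary$min, 0.173, tolerance = 1e-9)
  expect_equal(st$summary$max, 0.173, tolerance = 1e-9)
})

test_that("steady solver agrees with a dense direct-solve oracle on a coarse grid", {
  par <- default_params()
  dev <- discretize_device(default_geometry(), par, nx = 12,
                           nz_per_layer = coarse_nz)
  st <- solve_steady_oxygen(dev, tol = 1e-12)
  c_amb <- par$c_sat_pdms_mM / dev$k_part
  oracle <- dense_steady_oracle(dev, top_dirichlet = c_amb,
                                inlet = par$c_inlet_O2_mol_m3,
                                ambient = c_amb, uptake = TRUE)
  expect_lt(max(abs(st$field - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("steady flux bookkeeping closes: boundary supply equals uptake", {
  par <- default_params()
  dev <- discretize_device(default_geometry(), par, nx = 15,
                           nz_per_layer = coarse_nz)
  st <- solve_steady_oxygen(dev, tol = 1e-12)
  d <- st$device
  cm <- matrix(st$field, d$nz, d$nx) # rows = z, cols = x
  c_in <- par$c_inlet_O2_mol_m3
  c_amb <- par$c_sat_pdms_mM / d$k_part
  med <- which(d$layer == "media")
  influx <- sum((d$D_row[med] * d$dz[med] / (d$dx / 2)) *
                  (c_in - cm[med, 1])) +
    sum(d$u_row[med] * d$dz[med] * c_in)
  outflux <- sum(d$u_row[med] * d$dz[med] * cm[med, d$nx])
  top <- sum(d$D_row[d$nz] * d$dx / (d$dz[d$nz] / 2) *
               (c_amb - cm[d$nz, ]))
  walls <- sum((d$gamma_row * d$dz) %o% rep(d$dx, d$nx) * (c_amb - cm))
  cellr <- which(d$layer == "cell")
  uptake <- -sum(mm_uptake(cm[cellr, ], par) * d$dz[cellr] * d$dx)
  net <- influx - outflux + top + walls - uptake
  expect_lt(abs(net) / uptake, 1e-8)
})

test_that("flow off + uptake off reduces to the layered-slab analytic profile", {
  par <- transport_params(flow_rate_ul_per_h = 0)
  dev <- discretize_device(default_geometry(), par, nx = 10,
                           nz_per_layer = c(cell = 4, membrane = 3,
                                            media = 4),
                           include_pdms = FALSE)
  c_bot <- 1; c_top <- 0.2
  sys <- mpsddi:::.fv_assemble(dev, bc = list(top = list(value = c_top),
                                              bottom = list(value = c_bot)),
                               NULL)
  cvec <- as.numeric(Matrix::solve(sys$A, sys$b))
  cm <- matrix(cvec, dev$nz, dev$nx)
  # analytic: constant flux through series resistances, linear per layer
  res_to <- cumsum(c(0, dev$dz / dev$D_row))          # to each face
  r_node <- res_to[-length(res_to)] + dev$dz / (2 * dev$D_row)
  r_tot <- sum(dev$dz / dev$D_row)
  analytic <- unname(c_bot + (c_top - c_bot) * r_node / r_tot)
  for (ix in seq_len(dev$nx)) {
    expect_equal(cm[, ix], analytic, tolerance = 1e-10)
  }
  # flux continuity across the membrane: J = -D dC/dz equal in every layer
  J <- (c_bot - c_top) / r_tot
  for (ly in c("cell", "membrane", "media")) {
    rows <- which(dev$layer == ly)
    grad <- unname(diff(cm[rows, 1]) / diff(dev$zc[rows]))
    expect_equal(grad,
                 rep(-J / unique(dev$D_row[rows]), length(grad)),
                 tolerance = 1e-8)
  }
})

test_that("transient stepping conserves mass to near machine precision", {
  dev <- discretize_device(default_geometry(), default_params(),
                           nx = 15, nz_per_layer = coarse_nz)
  tr <- solve_transient_oxygen(dev, pdms_flux = "off", t_end = 60, dt = 2)
  expect_lt(tr$conservation_residual, 1e-8)
  devt <- discretize_device(default_geometry(), default_params(),
                            nx = 15, nz_per_layer = coarse_nz,
                            species = "tracer")
  wa <- solve_tracer_washin(devt, t_end = 60, dt = 2)
  expect_lt(wa$conservation_residual, 1e-8)
})

test_that("transient oxygen stays positive and depletes without PDMS flux", {
  dev <- discretize_device(default_geometry(), default_params(),
                           nx = 20, nz_per_layer = coarse_nz)
  tr <- solve_transient_oxygen(dev, pdms_flux = "off", t_end = 400, dt = 1)
  expect_true(all(tr$field >= 0))
  expect_true(all(tr$summary$min >= 0))
  expect_false(is.na(tr$time_to_depletion_s))
  expect_lte(tr$time_to_depletion_s, 300)
  # no uptake, no PDMS: concentration stays at the initial/inlet value
  ctl <- solve_transient_oxygen(dev, pdms_flux = "off", t_end = 30, dt = 5,
                                uptake = FALSE)
  expect_equal(ctl$summary$min, rep(0.173, nrow(ctl$summary)),
               tolerance = 1e-9)
})

test_that("steady cell-chamber O2 responds monotonically to uptake and flow", {
  geo <- default_geometry()
  mean_at <- function(par) {
    dev <- discretize_device(geo, par, nx = 15, nz_per_layer = coarse_nz)
    solve_steady_oxygen(dev)$summary$mean
  }
  base <- mean_at(default_params())
  expect_lt(mean_at(transport_params(VO2max_mol_s_cell = 3 * 1.04e-16)),
            base)
  expect_gt(mean_at(transport_params(flow_rate_ul_per_h = 200)) + 1e-12,
            base)
})

test_that("steady solution is grid-converged at the default resolution", {
  geo <- default_geometry(); par <- default_params()
  m1 <- solve_steady_oxygen(discretize_device(geo, par))$summary$mean
  m2 <- solve_steady_oxygen(
    discretize_device(geo, par, nx = 120,
                      nz_per_layer = c(cell = 12, membrane = 6,
                                       media = 12, pdms = 16)))$summary$mean
  expect_lt(abs(m2 - m1) / m1, 0.02)
})

test_that("tracer wash-in behaves physically", {
  geo <- default_geometry(); par <- default_params()
  dev <- discretize_device(geo, par, nx = 20, nz_per_layer = coarse_nz,
                           species = "tracer")
  wa <- solve_tracer_washin(dev, t_end = 500, dt = 2)
  expect_false(is.na(wa$time_to_uniformity_s))
  # starting at the inlet concentration: already uniform
  wa0 <- solve_tracer_washin(dev, c_init = 1, t_end = 20, dt = 5)
  expect_equal(wa0$time_to_uniformity_s, 0)
  # halving the diffusivity slows equilibration of the dead-end chamber
  slow <- transport_params(D_small_molecule_m2_s = 0.5e-9)
  dev2 <- discretize_device(geo, slow, nx = 20, nz_per_layer = coarse_nz,
                            species = "tracer")
  wa2 <- solve_tracer_washin(dev2, t_end = 500, dt = 2)
  expect_gt(wa2$time_to_uniformity_s, wa$time_to_uniformity_s)
  expect_error(solve_tracer_washin(dev, uniformity_fraction = 1.2),
               "uniformity_fraction")
  expect_error(solve_tracer_washin(dev, dt = -1), "dt")
})

test_that("a starved iteration cap raises an informative convergence error", {
  dev <- discretize_device(default_geometry(), default_params(),
                           nx = 12, nz_per_layer = coarse_nz)
  expect_error(solve_steady_oxygen(dev, maxit = 2), "converge")
})
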