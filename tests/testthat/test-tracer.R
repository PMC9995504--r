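# Tracer: reference profile, conservative monotone advection, vertical flux
# and the canopy-top exchange integral.

test_that("the reference profile is linear and vanishes at the canopy top", {
  expect_equal(tracer_reference(0.5, 0.5), 0)
  expect_equal(tracer_reference(0.487, 0), 0.974)
  expect_equal(tracer_reference(0.5, 1), -1)
  p <- sim_params(N_i = 8L, L_r = 1.6, L = 1.2, x_a = 0.2, x_b = 1.0)
  m <- build_mapping(rep(0.5, 8), rep(1, 8), p)
  C <- init_tracer(0.5, m)
  expect_equal(C, 2 * (0.5 - m$z_c))
})

test_that("advection conserves mass in a closed box and creates no new extrema", {
  p <- sim_params(N_i = 16L, L_r = 3.2, L = 2.4, x_a = 0.2, x_b = 2.0)
  m <- build_mapping(rep(0.5, 16), rep(1, 16), p)
  geom <- monami:::solver_geometry(m)
  fl <- closed_box_fluxes(m, seed = 3)
  set.seed(11)
  C <- matrix(stats::runif(16 * 48), 16)
  V <- p$dx * m$dz
  mass0 <- sum(C * V)
  r0 <- range(C)
  for (i in 1:50) C <- advect_tracer(C, fl, geom, m, p)
  expect_lt(abs(sum(C * V) - mass0), 1e-10 * abs(mass0))
  expect_gte(min(C), r0[1] - 1e-12)
  expect_lte(max(C), r0[2] + 1e-12)
})

test_that("a quiescent field leaves the tracer untouched", {
  p <- sim_params(N_i = 8L, L_r = 1.6, L = 1.2, x_a = 0.2, x_b = 1.0)
  m <- build_mapping(rep(0.5, 8), rep(1, 8), p)
  geom <- monami:::solver_geometry(m)
  fl <- list(Qx = matrix(0, 9, 48), Qz = matrix(0, 8, 49))
  C <- init_tracer(0.5, m)
  expect_equal(advect_tracer(C, fl, geom, m, p), C)
})

test_that("a Gaussian blob translates at the flow speed with small amplitude loss", {
  # uniform u = 1 in a long channel at baseline resolution; 10 time units
  ncols <- 150L
  p <- sim_params(N_i = ncols, L_r = 30, L = 25, x_a = 1, x_b = 20)
  m <- build_mapping(rep(0.5, ncols), rep(1, ncols), p)
  geom <- monami:::solver_geometry(m)
  fl <- list(Qx = matrix(1, ncols + 1L, 48) * geom$dzf_u,
             Qz = matrix(0, ncols, 49))
  x <- x_centers(p)
  C <- matrix(exp(-(x - 8)^2 / (2 * 2^2)), ncols, 48)
  c0in <- rep(0, 48)
  for (i in 1:100) C <- advect_tracer(C, fl, geom, m, p, c0_inlet = c0in)
  prof <- C[, 24]
  expect_lt(abs(x[which.max(prof)] - 18), 0.3)       # translated by 10
  expect_gt(max(prof), 0.98)                          # < 2% amplitude loss
  expect_gt(min(prof), -1e-12)                        # monotone
})

test_that("the vertical flux is the pointwise product w C'", {
  run_params <- sim_params(N_i = 8L, L_r = 1.6, L = 1.2, x_a = 0.2,
                           x_b = 1.0)
  m <- build_mapping(rep(0.5, 8), rep(1, 8), run_params)
  st <- list(w = matrix(0.1, 8, 49),
             C = init_tracer(0.5, m) + 0.2,
             mapping = m,
             steady = list(h_bar_g = 0.5))
  class(st) <- "monami_state"
  phi <- vertical_flux(st)
  expect_equal(phi, matrix(0.1 * 0.2, 8, 48), tolerance = 1e-14)
  st$w[] <- 0
  expect_equal(max(abs(vertical_flux(st))), 0)
})

test_that("the exchange integral matches analytic windows", {
  p <- sim_params()
  m <- build_mapping(rep(0.487, p$N_i), rep(1, p$N_i), p)
  # phi constant in z so the level interpolation is exact
  x <- x_centers(p)
  phi_sin <- matrix(sin(2 * pi * x / 15), p$N_i, p$N_k)
  got <- exchange(phi_sin, m, 20, 35, 0.487)
  expect_equal(got, 15 * 2 / pi, tolerance = 2e-3)
  # half-period window: integral of |sin| over [20, 27.5] = 15/pi
  expect_equal(exchange(phi_sin, m, 20, 27.5, 0.487), 15 / pi,
               tolerance = 2e-3)
  phi_c <- matrix(-0.3, p$N_i, p$N_k)
  expect_equal(exchange(phi_c, m, 20, 35, 0.487), 0.3 * 15,
               tolerance = 1e-12)
  expect_equal(exchange(0 * phi_c, m, 20, 35, 0.487), 0)
  # sign flip of phi leaves the exchange unchanged
  expect_equal(exchange(-phi_sin, m, 20, 35, 0.487), got)
})
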