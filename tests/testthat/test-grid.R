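# Terrain-following mapping, metric terms, and the columnwise
# monotone-cubic re-mapping.

test_that("piecewise-uniform sigma layers honour the three interfaces", {
  p <- sim_params()
  m <- build_mapping(rep(0.5, p$N_i), rep(1, p$N_i), p)
  expect_equal(max(abs(m$dz - 1 / 48)), 0)
  expect_equal(m$z_f[, 25], rep(0.5, p$N_i))   # canopy top on face N_kg
  m2 <- build_mapping(rep(0.4, p$N_i), rep(1, p$N_i), p)
  expect_equal(m2$dz[1, 1], 0.4 / 24)
  expect_equal(m2$dz[1, 48], 0.6 / 24)
  expect_equal(rowSums(m2$dz), rep(1, p$N_i), tolerance = 1e-14)
  expect_equal(m2$z_f[, 1], rep(0, p$N_i))
  expect_equal(m2$z_f[, 49], rep(1, p$N_i))
  expect_true(all(diff(t(m2$z_c)) > 0))        # strictly increasing in k
  expect_error(build_mapping(rep(1.1, p$N_i), rep(1, p$N_i), p),
               "invalid geometry")
  expect_error(build_mapping(rep(0, p$N_i), rep(1, p$N_i), p),
               "invalid geometry")
})

test_that("metric slope matches the analytic surface tilt to second order", {
  p <- sim_params()
  x <- x_centers(p)
  h <- 1 + 0.01 * sin(2 * pi * x / p$L)
  m <- build_mapping(rep(0.5, p$N_i), h, p)
  expect_equal(rowSums(m$dz), h, tolerance = 1e-14)
  analytic <- 0.01 * (2 * pi / p$L) * cos(2 * pi * x / p$L)
  inner <- 2:(p$N_i - 1)
  # the top cell center lies at hg/48 + (47/48) h, so its slope is
  # (47/48) dh/dx; central differencing is second order in dx
  expect_lt(max(abs(m$dzdx_c[inner, 48] - (47 / 48) * analytic[inner])),
            2e-6)
})

test_that("degenerate geometry recovers the uniform rectangular grid", {
  p <- sim_params(N_i = 8L, L_r = 1.6, L = 1.2, x_a = 0.2, x_b = 1.0)
  m <- build_mapping(rep(0.5, 8), rep(1, 8), p)
  expect_equal(m$z_c, matrix(rep((1:48 - 0.5) / 48, each = 8), 8),
               tolerance = 1e-14)
  expect_equal(max(abs(m$dzdx_c)), 0)
})

test_that("monotone-cubic row interpolation matches splinefun monoH.FC", {
  set.seed(7)
  z <- sort(stats::runif(20, 0, 1))
  y <- cumsum(stats::rnorm(20))        # non-monotone data, monotone knots
  zq <- stats::runif(200, -0.05, 1.05)
  mine <- monami:::interp_mono_rows(matrix(z, 1), matrix(y, 1),
                                    matrix(zq, 1))
  sf <- stats::splinefun(z, y, method = "monoH.FC")
  ref <- sf(pmin(pmax(zq, z[1]), z[20]))
  expect_equal(as.numeric(mine), ref, tolerance = 1e-12)
})

test_that("re-mapping is exact on identity and on linear fields", {
  p <- sim_params(N_i = 12L, L_r = 2.4, L = 2, x_a = 0.2, x_b = 1.8)
  a <- build_mapping(rep(0.5, 12), rep(1, 12), p)
  b <- build_mapping(0.5 + 0.01 * sin(1:12), rep(1, 12), p)
  f <- matrix(stats::rnorm(12 * 48), 12)
  expect_identical(remap_field(f, a, a), f)
  lin <- 0.3 + 1.7 * a$z_c
  got <- remap_field(lin, a, b)
  # exact wherever the query lies inside the old range (the first and last
  # cells may fall outside it and take the nearest old value)
  inside <- b$z_c >= a$z_c[, 1] & b$z_c <= a$z_c[, 48]
  expect_equal(got[inside], (0.3 + 1.7 * b$z_c)[inside], tolerance = 1e-12)
})

test_that("round-trip re-mapping of a smooth field is accurate", {
  # grid displacement of the size the canopy moves in one time step
  p <- sim_params(N_i = 12L, L_r = 2.4, L = 2, x_a = 0.2, x_b = 1.8)
  a <- build_mapping(rep(0.49, 12), rep(1, 12), p)
  b <- build_mapping(0.49 + 3e-4 * sin(1:12), rep(1 + 3e-5, 12), p)
  f <- sin(3 * a$z_c) + 0.2 * cos(5 * a$z_c)
  back <- remap_field(remap_field(f, a, b), b, a)
  expect_lt(max(abs(back - f)[, 2:47]), 1e-6)
})

test_that("the velocity sampler is exact on fields linear in z with a no-slip bed", {
  p <- sim_params(N_i = 12L, L_r = 2.4, L = 2, x_a = 0.2, x_b = 1.8)
  m <- build_mapping(rep(0.5, 12), rep(1, 12), p)
  uc <- 2 * m$z_c                       # linear through the bed anchor
  wc <- 0 * uc
  s <- monami:::make_velocity_sampler(uc, wc, m)
  X <- matrix(seq(0.3, 2.0, length.out = 5), 1)
  Z <- matrix(seq(0.05, 0.9, length.out = 5), 1)
  v <- s(X, Z)
  expect_equal(as.numeric(v$u), as.numeric(2 * Z), tolerance = 1e-12)
  expect_equal(as.numeric(v$w), rep(0, 5))
})
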