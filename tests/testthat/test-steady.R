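# The coupled 1D base state: analytic drag-free limit, pointwise residual,
# rigid-canopy limit against an independent shooting solution, and the
# buoyancy trends of canopy height and canopy-top shear.

test_that("without canopy drag the base state is the analytic half-Poiseuille profile", {
  p <- sim_params(lam = 0)
  s <- solve_steady(p)
  expect_equal(s$forcing_G, 2 / p$Re, tolerance = 1e-10)
  expect_lt(max(abs(s$u_bar - s$z_levels * (2 - s$z_levels))), 1e-8)
  # blades still deflect (lambda only scales the force on the fluid)
  expect_gt(max(s$blade$theta), 0.1)
})

test_that("the pointwise momentum residual vanishes on the analytic solution", {
  p <- sim_params(lam = 0)
  zc <- monami:::column_z_centers(p$r, 1, p)
  r0 <- steady_momentum_residual(zc * (2 - zc), rep(0, p$N_k), 2 / p$Re, p)
  expect_lt(max(abs(r0)), 1e-12)
  # zero flow, zero forcing
  r1 <- steady_momentum_residual(rep(0, p$N_k), rep(0, p$N_k), 0, p)
  expect_equal(r1, rep(0, p$N_k))
})

test_that("the residual applies quadratic drag only inside the canopy", {
  p <- sim_params(lam = 1)
  zc <- monami:::column_z_centers(p$r, 1, p)
  u <- zc * (2 - zc)
  G <- 0.004
  r <- steady_momentum_residual(u, rep(0, p$N_k), G, p)
  # hand evaluation: (1/Re) u'' = -2/Re for the quadratic, drag u^2/2 below
  # the canopy top
  expected <- -2 / p$Re + G - ifelse(zc <= p$r, 0.5 * u^2, 0)
  for (k in c(3L, 20L, 40L)) {
    expect_equal(r[k], expected[k], tolerance = 1e-12)
  }
})

test_that("the rigid-canopy limit matches an independent shooting solution", {
  p <- sim_params(beta = 1e6)
  s <- solve_steady(p)
  expect_lt(max(abs(s$theta_bar)), 1e-4)
  expect_equal(s$h_bar_g, 0.5, tolerance = 1e-9)
  # oracle: RK4 shooting on (1/Re) u'' + G - [z <= 0.5] u^2/2 = 0 with
  # u(0) = 0, u'(1) = 0, then G adjusted by bisection so u(1) = 1
  shoot <- function(G, n = 4000L) {
    hstep <- 1 / n
    rhs <- function(z, u, v) {
      drag <- if (z <= 0.5) 0.5 * u * abs(u) else 0
      p$Re * (drag - G)
    }
    u <- 0; v0 <- NA
    # secant on the initial slope so that u'(1) = 0
    slope_res <- function(v_init) {
      u <- 0; v <- v_init; z <- 0
      for (i in seq_len(n)) {
        k1u <- v;                k1v <- rhs(z, u, v)
        k2u <- v + hstep * k1v / 2; k2v <- rhs(z + hstep / 2, u + hstep * k1u / 2, 0)
        k3u <- v + hstep * k2v / 2; k3v <- rhs(z + hstep / 2, u + hstep * k2u / 2, 0)
        k4u <- v + hstep * k3v;  k4v <- rhs(z + hstep, u + hstep * k3u, 0)
        u <- u + hstep * (k1u + 2 * k2u + 2 * k3u + k4u) / 6
        v <- v + hstep * (k1v + 2 * k2v + 2 * k3v + k4v) / 6
        z <- z + hstep
      }
      c(v, u)
    }
    lo <- 0; hi <- 50
    for (it in 1:60) {
      mid <- 0.5 * (lo + hi)
      if (slope_res(mid)[1] > 0) hi <- mid else lo <- mid
    }
    slope_res(0.5 * (lo + hi))[2]   # u(1)
  }
  glo <- 0.001; ghi <- 0.05
  for (it in 1:40) {
    gm <- 0.5 * (glo + ghi)
    if (shoot(gm) < 1) glo <- gm else ghi <- gm
  }
  G_oracle <- 0.5 * (glo + ghi)
  expect_equal(s$forcing_G, G_oracle, tolerance = 0.02)
})

test_that("canopy height and canopy-top shear both grow with blade buoyancy", {
  hg <- sh <- numeric(0)
  for (be in c(0.01, 0.02, 0.04, 0.10)) {
    s <- solve_steady(sim_params(beta = be))
    hg <- c(hg, s$h_bar_g)
    sh <- c(sh, canopy_top_shear(s))
  }
  expect_true(all(diff(hg) > 0))
  expect_true(all(diff(sh) > 0))
  expect_true(all(hg > 0 & hg <= 0.5))
})

test_that("the steady velocity interpolator anchors the bed and the surface", {
  s <- solve_steady(sim_params())
  uf <- steady_velocity_fun(s)
  expect_equal(uf(0), 0)
  expect_equal(uf(s$z_levels), s$u_bar, tolerance = 1e-12)
  expect_gt(uf(1), 0.99)
  expect_true(all(diff(uf(seq(0, 1, by = 0.01))) >= 0))
})
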