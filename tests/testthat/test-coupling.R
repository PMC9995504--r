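# Fluid-blade coupling: canopy equilibration, kernel force deposition,
# conservation, linearity, and the sign of the fluid reaction.

make_uniform_setup <- function(u0 = 1, N_i = 12L) {
  p <- sim_params(N_i = N_i, L_r = N_i * 0.2, L = N_i * 0.2 * 5 / 6,
                  x_a = 0.2, x_b = N_i * 0.2 * 0.5)
  m <- build_mapping(rep(0.5, N_i), rep(1, N_i), p)
  uc <- matrix(u0, N_i, p$N_k)
  wc <- matrix(0, N_i, p$N_k)
  list(p = p, m = m, uc = uc, wc = wc)
}

test_that("a quiescent canopy stands vertical at full height", {
  s <- make_uniform_setup(u0 = 0)
  can <- equilibrate_canopy(s$uc, s$wc, s$m, s$p)
  expect_equal(max(abs(can$blades$theta)), 0)
  expect_equal(can$h_g, rep(0.5, 12))
  drag <- distribute_drag(can$blades, s$m, s$p)
  expect_equal(max(abs(drag$Fx)), 0)
  expect_equal(max(abs(drag$Fz)), 0)
})

test_that("the kernel conserves the total blade force exactly", {
  # single blade far from the boundaries: all its weight lands on the grid
  s <- make_uniform_setup(u0 = 0.8)
  can <- equilibrate_canopy(s$uc, s$wc, s$m, s$p)
  b <- can$blades
  keep <- 6L   # blade in the middle; zero out all others
  b$fx[-keep, ] <- 0; b$fz[-keep, ] <- 0
  drag <- distribute_drag(b, s$m, s$p)
  vol <- s$p$dx * s$m$dz
  tot_x <- sum(drag$Fx * vol)
  tot_z <- sum(drag$Fz * vol)
  # reference: per-segment trapezoid of -lambda sec(theta) f
  nn <- ncol(b$theta)
  ds <- b$ell / b$nseg
  sec_t <- 1 / cos(pmin(abs(b$theta[keep, ]), s$p$sec_clamp))
  gx <- -s$p$lam * sec_t * b$fx[keep, ]
  gz <- -s$p$lam * sec_t * b$fz[keep, ]
  ref_x <- sum(0.5 * ds * (gx[-nn] + gx[-1]))
  ref_z <- sum(0.5 * ds * (gz[-nn] + gz[-1]))
  expect_lt(abs(tot_x - ref_x), 1e-10 * abs(ref_x))
  expect_lt(abs(tot_z - ref_z), 1e-10 * max(abs(ref_z), 1e-12))
  # drag on the fluid opposes the flow
  expect_lt(tot_x, 0)
})

test_that("a vertical blade in unit flow deposits the closed-form total force", {
  s <- make_uniform_setup(u0 = 1)
  p <- s$p
  b <- structure(list(theta = matrix(0, 12, p$blade_nseg + 1L),
                      x_g = matrix(0, 12, p$blade_nseg + 1L),
                      z_g = matrix(blade_s_nodes(0.5, p$blade_nseg), 12,
                                   p$blade_nseg + 1L, byrow = TRUE),
                      fx = matrix(0.5, 12, p$blade_nseg + 1L),
                      fz = matrix(0, 12, p$blade_nseg + 1L),
                      root_x = x_centers(p), ell = p$r,
                      nseg = p$blade_nseg),
                 class = "monami_blades")
  bb <- b
  bb$fx[-6L, ] <- 0
  drag <- distribute_drag(bb, s$m, p)
  vol <- p$dx * s$m$dz
  expect_equal(sum(drag$Fx * vol), -p$lam * 0.5 * 0.5, tolerance = 1e-12)
  expect_equal(sum(abs(drag$Fz) * vol), 0)
  # no force above the canopy interface
  expect_true(all(drag$Fx[, (p$N_kg + 1L):p$N_k] == 0))
})

test_that("the deposited force is exactly linear in the drag density", {
  s <- make_uniform_setup(u0 = 0.7)
  can <- equilibrate_canopy(s$uc, s$wc, s$m, s$p)
  d1 <- distribute_drag(can$blades, s$m, s$p)
  p2 <- s$p; p2$lam <- 2 * s$p$lam
  d2 <- distribute_drag(can$blades, s$m, p2)
  expect_equal(d2$Fx, 2 * d1$Fx, tolerance = 1e-14)
  expect_equal(d2$Fz, 2 * d1$Fz, tolerance = 1e-14)
  # lambda = 0: no force on the fluid, blades still deflected
  p0 <- s$p; p0$lam <- 0
  d0 <- distribute_drag(can$blades, s$m, p0)
  expect_equal(max(abs(d0$Fx)), 0)
  expect_gt(max(abs(can$blades$theta)), 0.5)
})

test_that("a local velocity deficit makes the blade below it more erect", {
  s <- make_uniform_setup(u0 = 0.8)
  uc <- s$uc
  uc[6, ] <- 0.3
  can <- equilibrate_canopy(uc, s$wc, s$m, s$p)
  tips <- can$blades$z_g[, ncol(can$blades$z_g)]
  expect_gt(tips[6], tips[3])
  expect_gt(tips[6], tips[9])
})

test_that("repeated coupling passes on a frozen field are idempotent", {
  s <- make_uniform_setup(u0 = 0.6)
  c1 <- couple_step(s$uc, s$wc, s$m, s$p, tol = 1e-12)
  c2 <- couple_step(s$uc, s$wc, s$m, s$p, theta0 = c1$blades$theta,
                    tol = 1e-12)
  expect_equal(c2$blades$theta, c1$blades$theta, tolerance = 1e-10)
  expect_equal(c2$h_g, c1$h_g, tolerance = 1e-10)
  expect_equal(c2$drag$Fx, c1$drag$Fx, tolerance = 1e-9)
})

test_that("a uniform canopy yields an exactly uniform drag profile", {
  s <- make_uniform_setup(u0 = 0.8)
  can <- equilibrate_canopy(s$uc, s$wc, s$m, s$p)
  drag <- distribute_drag(can$blades, s$m, s$p)
  # ghost padding makes every column identical, including the edges
  for (k in seq_len(s$p$N_k)) {
    expect_lt(diff(range(drag$Fx[, k])), 1e-13)
  }
})
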