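# Blade statics: drag law, tension, angle, shape, and the equilibrium
# fixed point against the closed-form straight-blade solution.

test_that("quadratic normal drag has the stated magnitude, direction and symmetries", {
  expect_equal(blade_drag_per_length(0, 0.3), cbind(fx = 0, fz = 0))
  # vertical blade in unit flow: u_normal = -1, drag (0.5, 0) downstream
  f <- blade_drag_per_length(-1, 0)
  expect_equal(as.numeric(f), c(0.5, 0))
  # reversed flow reverses the drag
  f2 <- blade_drag_per_length(1, 0)
  expect_equal(as.numeric(f2), c(-0.5, 0))
  # |f| = u_normal^2 / 2 and the component formula fx = u^2 cos^3(theta)/2
  # for horizontal flow (u_normal = -u cos theta)
  th <- seq(-1.2, 1.2, length.out = 7)
  u <- 0.8
  f3 <- blade_drag_per_length(-u * cos(th), th)
  expect_equal(sqrt(rowSums(f3^2)), 0.5 * (u * cos(th))^2)
  expect_equal(f3[, "fx"], 0.5 * u^2 * cos(th)^3)
  # orientation invariance: with the flipped normal the signed component
  # flips and the basis flips, so f(un, nhat) = -f(-un, nhat)
  set.seed(4)
  un <- stats::rnorm(20); tha <- stats::runif(20, -1.4, 1.4)
  expect_equal(blade_drag_per_length(un, tha),
               -blade_drag_per_length(-un, tha),
               tolerance = 1e-14)
})

test_that("tension integrates tip-to-root with an exact trapezoid", {
  s <- blade_s_nodes(0.5, 25)
  # pure buoyancy
  T0 <- integrate_tension(cbind(rep(0, 26), rep(0, 26)), 0.1, s)
  expect_equal(T0[, "Tx"], rep(0, 26))
  expect_equal(T0[, "Tz"], 0.1 * (0.5 - s))
  expect_equal(unname(T0[26, ]), c(0, 0))   # tip tension exactly zero
  # constant drag: linear integrand, trapezoid exact
  T1 <- integrate_tension(cbind(rep(0.5, 26), rep(0, 26)), 0.1, s)
  expect_equal(unname(T1[1, ]), c(0.25, 0.05))
  # beta = 0, no drag: identically zero
  T2 <- integrate_tension(cbind(rep(0, 26), rep(0, 26)), 0, s)
  expect_true(all(T2 == 0))
  # overturning flagged when the vertical tension is dragged negative
  expect_error(integrate_tension(cbind(rep(0, 26), rep(-1, 26)), 0.1, s),
               "overturning")
})

test_that("angle follows the tension direction and rejects overturning", {
  expect_equal(tension_to_angle(cbind(c(0, 0), c(2, 1)),
                                tip_direction = c(0, 1)),
               c(0, 0))
  expect_equal(tension_to_angle(cbind(c(1, 1), c(1, 1)))[1], pi / 4)
  expect_equal(tension_to_angle(cbind(c(0.25, 0.1), c(0.05, 0.02)))[1],
               atan(5), tolerance = 1e-12)
  expect_error(tension_to_angle(cbind(c(1, 1), c(-1, 1))), "overturning")
})

test_that("shape integration is exactly inextensible and second order", {
  s <- blade_s_nodes(0.5, 25)
  sh0 <- integrate_shape(rep(0, 26), s)
  expect_equal(unname(sh0[26, ]), c(0, 0.5))
  shh <- integrate_shape(rep(pi / 2, 26), s)
  expect_equal(unname(shh[26, ]), c(0.5, 0), tolerance = 1e-12)
  sh6 <- integrate_shape(rep(pi / 6, 26), s)
  expect_equal(unname(sh6[26, ]), c(0.25, 0.25 * sqrt(3)))
  # curved blade: discrete arc length equals ell to machine precision
  shc <- integrate_shape(seq(0, 1.2, length.out = 26), s)
  arc <- sum(sqrt(diff(shc[, 1])^2 + diff(shc[, 2])^2))
  expect_lt(abs(arc - 0.5) / 0.5, 1e-12)
})

test_that("uniform-flow equilibrium matches the scalar root-find oracle", {
  # straight blade: theta* solves tan(th) (beta - u^2 cos^2 th sin th / 2)
  # = u^2 cos^3 th / 2, solved independently by bisection
  for (u0 in c(0.3, 0.6, 1.0)) for (be in c(0.05, 0.1, 0.3)) {
    b <- equilibrate_blade(uniform_sampler(u0), beta = be)
    expect_lt(diff(range(b$theta)), 1e-6)   # straight
    expect_lt(abs(b$theta[1] - uniform_flow_angle(u0, be)), 1e-6)
  }
})

test_that("zero flow leaves the blade vertical at full height", {
  b <- equilibrate_blade(uniform_sampler(0), beta = 0.05)
  expect_equal(max(abs(b$theta)), 0)
  expect_equal(b$tip_height, 0.5)
  expect_equal(b$iterations, 1L)
})

test_that("equilibrium angle falls with buoyancy and rises with speed", {
  u0s <- seq(0.2, 1.0, length.out = 5)
  bes <- c(0.08, 0.12, 0.18, 0.27, 0.4)
  th <- outer(u0s, bes, Vectorize(function(u, b) {
    equilibrate_blade(uniform_sampler(u), beta = b)$theta[1]
  }))
  expect_true(all(diff(t(th)) < 0))   # decreasing in beta at fixed u0
  expect_true(all(apply(th, 2, diff) > 0))  # increasing in u0 at fixed beta
})

test_that("infinitely buoyant blades stand vertical", {
  b <- equilibrate_blade(uniform_sampler(1.2), beta = 1e6)
  expect_lt(max(abs(b$theta)), 1e-6)
  expect_equal(b$tip_height, 0.5, tolerance = 1e-10)
})

test_that("shear-flow equilibrium self-converges under s-grid refinement", {
  shear <- function(x, z) list(u = pmax(z, 0), w = rep(0, length(x)))
  b1 <- equilibrate_blade(shear, beta = 0.1, nseg = 25, tol = 1e-10)
  b2 <- equilibrate_blade(shear, beta = 0.1, nseg = 250, tol = 1e-10)
  tip1 <- b1$coords[nrow(b1$coords), ]
  tip2 <- b2$coords[nrow(b2$coords), ]
  expect_lt(max(abs(tip1 - tip2)), 1e-4)
})
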