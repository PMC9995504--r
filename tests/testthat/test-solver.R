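# Channel solver: discrete steady states, projection, budget closure,
# sponge, vorticity, initialization determinism.

test_that("the drag-free analytic profile persists as a discrete steady state", {
  p <- sim_params(lam = 0, noise_amplitude = 0, T_end = 10)
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  u0 <- st$u
  for (i in 1:100) st <- step_flow(st)
  expect_lt(max(abs(st$u - u0)), 1e-8)
  expect_lt(max(abs(st$w)), 1e-10)
  expect_lt(max(abs(st$h - 1)), 1e-10)
})

test_that("the fully coupled base state persists as a discrete steady state", {
  p <- sim_params(noise_amplitude = 0, T_end = 10)
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  u0 <- st$u
  for (i in 1:100) st <- step_flow(st)
  expect_lt(max(abs(st$u - u0)), 1e-8)
  expect_lt(max(abs(st$w)), 1e-8)
  expect_lt(max(abs(st$hg - s$h_bar_g)), 1e-8)
})

test_that("every projection leaves the divergence at round-off", {
  p <- sim_params(N_i = 54L, L_r = 10.8, L = 9, x_a = 1, x_b = 8,
                  noise_amplitude = 1e-3, rng_seed = 2L, T_end = 5)
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  for (i in 1:50) {
    st <- step_flow(st)
    expect_lt(st$last_divergence, 1e-8)
  }
})

test_that("initialization is deterministic and has the stated noise level", {
  p <- sim_params(noise_amplitude = 1e-6, rng_seed = 42L)
  s <- solve_steady(p)
  a <- initialize_state(p, s)
  b <- initialize_state(p, s)
  expect_identical(a$u, b$u)
  expect_identical(a$w, b$w)
  expect_identical(a$C, b$C)
  # uniform noise on [-a, a]: rms a/sqrt(3)
  wn <- a$w[, 2:p$N_k]
  expect_lt(abs(sqrt(mean(wn^2)) - 1e-6 / sqrt(3)) / (1e-6 / sqrt(3)), 0.05)
  p0 <- sim_params(noise_amplitude = 0)
  z <- initialize_state(p0, s)
  expect_equal(max(abs(z$w)), 0)
})

test_that("the sponge restores exactly at the outlet and is idle on the base state", {
  p <- sim_params(noise_amplitude = 0, T_end = 5)   # sponge_rate dt = 1
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  st2 <- apply_sponge(st)
  expect_equal(st2$u, st$u, tolerance = 1e-12)   # already the base state
  # perturbed state: the outlet-adjacent face is reset to u_bar exactly
  stp <- st
  stp$u <- st$u + 0.3
  stp$w <- st$w + 0.1
  sp <- apply_sponge(stp)
  expect_equal(sp$u[p$N_i + 1L, ], st$u[p$N_i + 1L, ], tolerance = 1e-12)
  # the last w column sits half a cell before the outlet face: strongly
  # damped though not exactly zero
  expect_lt(max(abs(sp$w[p$N_i, ])), 0.001)
  # no effect upstream of x = L
  up <- which(x_centers(p) < p$L)
  expect_equal(sp$w[up, ], stp$w[up, ])
})

test_that("vorticity reduces to analytic fields on simple states", {
  p <- sim_params(lam = 0, noise_amplitude = 0)
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  z <- vorticity(st)    # u = z(2-z): zeta = 2 - 2z, exact on quadratics
  expect_lt(max(abs(z - (2 - 2 * st$mapping$z_c))), 1e-8)
  # rigid-rotation-like patch on the uniform grid: zeta = -2
  st$u[] <- -(monami:::solver_geometry(st$mapping)$z_u - 0.5)
  st$w[] <- 0.3
  zz <- vorticity(st)
  inner <- 2:(p$N_i - 1)
  expect_lt(max(abs(zz[inner, 2:47] + 1)), 1e-8)   # du/dz = -1, dw/dx = 0
  st$u[] <- 0; st$w[] <- 0
  expect_equal(max(abs(vorticity(st))), 0)
})

test_that("the x-momentum budget closes over a 50-step window", {
  p <- sim_params(N_i = 54L, L_r = 10.8, L = 9, x_a = 1, x_b = 8,
                  beta = 1e6, lam = 0, noise_amplitude = 0, T_end = 10,
                  collect_budget = TRUE)
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  # smooth x-dependent perturbation of the base flow
  xs <- (seq_len(p$N_i + 1L) - 1L) * p$dx
  st$u <- st$u * (1 + 1e-3 * sin(2 * pi * xs / p$L))
  resid <- scale <- 0
  for (i in 1:50) {
    st <- step_flow(st)
    b <- st$budget
    dU <- b$U1 - b$U0
    terms <- b$pred + b$visc_z + b$slope + b$proj + b$sponge + b$remap
    resid <- max(resid, abs(dU - terms))
    scale <- max(scale, abs(b$forc), abs(b$pred), abs(dU))
    if (i == 1) {
      # Euler first step: the predictor is exactly the sum of its parts
      expect_equal(b$pred, b$adv + b$visc + b$drag + b$forc,
                   tolerance = 1e-10)
      # no canopy force with lam = 0
      expect_equal(b$drag, 0)
    }
  }
  expect_lt(resid / scale, 1e-6)
})

test_that("a CFL violation aborts with a diagnostic", {
  p <- sim_params(noise_amplitude = 0, T_end = 5)
  s <- solve_steady(p)
  st <- initialize_state(p, s)
  st$u[] <- 3            # dt |u| / dx = 1.5
  expect_error(step_flow(st), "CFL")
})
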