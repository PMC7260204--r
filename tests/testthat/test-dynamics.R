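# drag, friction, effective mass and the equation of motion

test_that("water viscosity correlation is near handbook values and monotone", {
  expect_equal(viscosity_water(20), 1.002e-3, tolerance = 0.01)
  expect_lt(viscosity_water(22), viscosity_water(20))
  expect_error(viscosity_water(-5), "0-100")
  # explicit override bypasses the correlation exactly
  env <- environment_spec(22, eta = 1.234e-3)
  expect_identical(env$eta, 1.234e-3)
})

test_that("drag coefficient, wall factors and effective mass match formulas", {
  bead <- bead_spec(4e-6, 0.0256)
  env <- environment_spec(eta = 1e-3)
  expect_equal(drag_gamma(bead, env), 6 * pi * 1e-3 * 4e-6)
  expect_equal(drag_gamma(bead_spec(8e-6, 0.0256), env),
               2 * drag_gamma(bead, env))                     # linear in r
  expect_equal(drag_gamma(bead, environment_spec(eta = 2e-3)),
               2 * drag_gamma(bead, env))                     # linear in eta

  expect_equal(wall_drag_factors(4e-6, 0), c(1.5625, 1.5625, 2.125))
  far <- wall_drag_factors(4e-6, 1e6 * 4e-6)
  expect_equal(far, c(1, 1, 1), tolerance = 1e-5)
  for (z in c(0, 1e-6, 5e-6)) {
    f <- wall_drag_factors(4e-6, z)
    expect_equal(f[3] - 1, 2 * (f[1] - 1))                    # fz-1 = 2(fx-1)
  }

  b1 <- bead_spec(1e-6, 0, density = 1000)
  e1 <- environment_spec(rho_water = 1000, eta = 1e-3)
  expect_equal(effective_mass(b1, e1), (4 * pi / 3) * 1e-18 * 1500)
  expect_equal(effective_mass(bead_spec(2e-6, 0, density = 1000), e1),
               8 * effective_mass(b1, e1))                    # cubic in r
  expect_equal(effective_mass(b1, environment_spec(rho_water = 1e-9, eta = 1e-3)),
               (4 * pi / 3) * 1e-18 * 1000, tolerance = 1e-9) # bare mass
})

test_that("friction acts only at ground contact, only against motion", {
  bead <- bead_spec(4e-6, 0.0256, friction = 0.03)
  expect_equal(friction_force(bead, c(0, 0, -1e-12), c(1e-6, 0, 0), z = 1e-6),
               c(0, 0, 0))                                    # off the ground
  expect_equal(friction_force(bead, c(0, 0, -1e-12), c(1e-6, 0, 0), z = 0),
               c(-3e-14, 0, 0))
  expect_equal(friction_force(bead, c(0, 0, 1e-12), c(1e-6, 0, 0), z = 0),
               c(0, 0, 0))                                    # upward pull: none
  expect_equal(friction_force(bead, c(0, 0, -1e-12), c(0, 0, 0), z = 0),
               c(0, 0, 0))                                    # at rest: none
})

make_flat_fit <- function(L = 20e-6, n = 7) {
  spec <- potential_grid_spec(c(-L, L), c(-L, L), n, n, 0)
  fit_space(fit_time(potential_map(array(0, c(n, n, 1, 1)), spec), 0), 3)
}

make_tilt_fit <- function(Fx, L = 40e-6, n = 11) {
  # U = -Fx * x: constant in-plane force Fx
  spec <- potential_grid_spec(c(-L, L), c(-L, L), n, n, 0)
  U <- array(outer(spec$x, spec$y, function(x, y) -Fx * x), c(n, n, 1, 1))
  fit_space(fit_time(potential_map(U, spec), 0), 3)
}

make_trap_fit <- function(k, L = 30e-6, n = 31) {
  spec <- potential_grid_spec(c(-L, L), c(-L, L), n, n, 0)
  U <- array(outer(spec$x, spec$y, function(x, y) 0.5 * k * (x^2 + y^2)),
             c(n, n, 1, 1))
  fit_space(fit_time(potential_map(U, spec), 0), 3)
}

bead0 <- bead_spec(4e-6, 0.0256, friction = 0)
env0 <- environment_spec(22)

test_that("a bead at rest on a flat potential stays at rest", {
  tr <- simulate_bead(make_flat_fit(), bead0, env0, c(0, 0, 0), 0.05)
  expect_lt(max(abs(tr$x)), 1e-12)
  expect_lt(max(abs(tr$y)), 1e-12)
  expect_true(all(tr$z >= 0))
  expect_lt(max(tr$z), 1e-12)
})

test_that("constant in-plane force reaches the wall-corrected terminal speed", {
  Fx <- 1e-12
  gam <- drag_gamma(bead0, env0)
  vt <- Fx / (gam * 1.5625)
  tr <- simulate_bead(make_tilt_fit(Fx), bead0, env0, c(-30e-6, 0, 0), 7e-3)
  expect_equal(tail(tr$vx, 1), vt, tolerance = 1e-6)
  expect_lt(max(abs(tr$vy)), 1e-12)
})

test_that("overdamped harmonic relaxation has rate k / (1.5625 Gamma)", {
  k <- 1e-6
  fit <- make_trap_fit(k)
  gam <- drag_gamma(bead0, env0)
  rate <- k / (1.5625 * gam)
  # two decades of decay: ln(100) / rate
  tr <- simulate_bead(fit, bead0, env0, c(10e-6, 0, 0), log(100) / rate)
  sel <- tr$t > 0 & tr$x > 0
  est <- -stats::coef(stats::lm(log(tr$x[sel]) ~ tr$t[sel]))[[2]]
  expect_equal(est, rate, tolerance = 0.01)
})

test_that("energy is non-increasing in a static potential without friction", {
  k <- 1e-6
  fit <- make_trap_fit(k)
  meff <- effective_mass(bead0, env0)
  tr <- simulate_bead(fit, bead0, env0, c(10e-6, 5e-6, 0), 0.5)
  E <- 0.5 * k * (tr$x^2 + tr$y^2) + 0.5 * meff * (tr$vx^2 + tr$vy^2)
  expect_true(all(diff(E) <= 1e-10 * E[1]))
})

test_that("halving the macro step barely moves the harmonic endpoint", {
  k <- 1e-6
  fit <- make_trap_fit(k)
  tr1 <- simulate_bead(fit, bead0, env0, c(10e-6, 0, 0), 0.3, max_dt = 7e-4)
  tr2 <- simulate_bead(fit, bead0, env0, c(10e-6, 0, 0), 0.3, max_dt = 3.5e-4)
  expect_lt(abs(tail(tr1$x, 1) - tail(tr2$x, 1)), 0.01 * bead0$r_mb)
})

test_that("a rotating harmonic trap drags the bead at a frequency-linear lag", {
  k <- 1e-6
  R <- 8e-6
  L <- 30e-6; n <- 31
  gam <- drag_gamma(bead0, env0)
  om_crit <- k / (gam * 1.5625)      # rad/s at which the lag reaches 45 deg
  spec <- potential_grid_spec(c(-L, L), c(-L, L), n, n, 0)
  om_rel <- c(0.1, 0.2, 0.3)
  lags <- sapply(om_crit * om_rel, function(om) {
    nstates <- 24
    period <- 2 * pi / om
    times <- (0:(nstates - 1)) * period / nstates
    arr <- array(0, c(n, n, 1, nstates))
    for (j in seq_len(nstates)) {
      cx <- R * cos(om * times[j]); cy <- R * sin(om * times[j])
      arr[, , 1, j] <- outer(spec$x, spec$y, function(x, y)
        0.5 * k * ((x - cx)^2 + (y - cy)^2))
    }
    fit <- fit_space(fit_time(potential_map(arr, spec, times = times,
                                            omega = om), 2), 3)
    # transient decays at rate om_crit; average the lag once settled
    t_end <- 10 / om_crit
    tr <- simulate_bead(fit, bead0, env0, c(R, 0, 0), t_end)
    sel <- tr$t > 0.6 * t_end
    th_field <- om * tr$t[sel]
    th_bead <- atan2(tr$y[sel], tr$x[sel])
    mean((th_field - th_bead + pi) %% (2 * pi) - pi)
  })
  expect_true(all(lags > 0))
  # sin(lag) is proportional to omega below the critical frequency
  s <- sin(lags)
  chat <- sum(s * om_rel) / sum(om_rel^2)
  expect_lt(max(abs(s - chat * om_rel)) / max(s), 0.02)
})

test_that("periodic wrapping reproduces the single-cell trajectory", {
  # tilted periodic landscape, one cell vs the same landscape evaluated
  # with the bead starting one period over
  L <- 10e-6; n <- 10
  spec <- potential_grid_spec(c(0, L), c(0, L), n, n, 0,
                              periodic = c(TRUE, TRUE))
  U <- array(outer(spec$x, spec$y, function(x, y)
    1e-18 * sin(2 * pi * x / L) * cos(2 * pi * y / L)), c(n, n, 1, 1))
  fit <- fit_space(fit_time(potential_map(U, spec), 0), 3)
  t1 <- simulate_bead(fit, bead0, env0, c(2e-6, 3e-6, 0), 0.2)
  t2 <- simulate_bead(fit, bead0, env0, c(2e-6 + L, 3e-6, 0), 0.2)
  expect_lt(max(abs((t2$x_unwrapped - L) - t1$x_unwrapped)), 1e-9)
  expect_lt(max(abs(t2$x - t1$x)), 1e-9)
})

test_that("the floor clamp keeps z >= 0 and zeroes the vertical speed", {
  # downhill-in-z landscape pushes the bead toward the floor from above
  L <- 20e-6; n <- 7
  spec <- potential_grid_spec(c(-L, L), c(-L, L), n, n,
                              seq(-2e-6, 6e-6, length.out = 5))
  kz <- 1e-6
  U <- array(0, c(n, n, 5))
  for (iz in 1:5) U[, , iz] <- 0.5 * kz * spec$z_layers[iz]^2 +
    outer(spec$x, spec$y, function(x, y) 0 * x)
  fit <- fit_space(fit_time(potential_map(U, spec), 0), 3)
  tr <- simulate_bead(fit, bead0, env0, c(0, 0, 4e-6), 0.5)
  expect_true(all(tr$z >= 0))
  expect_lt(tail(tr$z, 1), 1e-8)
  expect_equal(tail(tr$vz, 1), 0)
  ev <- attr(tr, "events")
  expect_true(is.data.frame(ev))
})
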