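# oracle and invariant tests for the bioheat finite-difference core

test_that("uniform field at arterial temperature is a fixed point", {
  mf <- tiny_field(w_perf = 0.001, q_met = 0, T_init = 300)
  T0 <- array(mf$T_a, dim = mf$dims)
  out <- step_heat(T0, mf, NULL, dt = 0.9 * stability_dt(mf), nsteps = 20,
                   boundary = "insulated", radiative = FALSE)
  expect_equal(out$T, T0, tolerance = 1e-12)
})

test_that("energy is conserved in a closed, source-free box", {
  set.seed(7)
  mf <- tiny_field(n = c(16, 16, 8))
  T0 <- array(300 + rnorm(prod(mf$dims)), dim = mf$dims)
  E0 <- sum(mf$rho * mf$cp * T0)
  out <- step_heat(T0, mf, NULL, dt = 0.9 * stability_dt(mf), nsteps = 1000,
                   boundary = "insulated", radiative = FALSE)
  E1 <- sum(mf$rho * mf$cp * out$T)
  expect_lt(abs(E1 - E0) / E0, 1e-6)
})

test_that("the spatial maximum never grows without sources", {
  set.seed(8)
  mf <- tiny_field(n = c(12, 12, 6))
  Tc <- array(300 + abs(rnorm(prod(mf$dims))), dim = mf$dims)
  dt <- 0.9 * stability_dt(mf)
  mx <- max(Tc)
  for (i in 1:40) {
    Tc <- step_heat(Tc, mf, NULL, dt = dt, nsteps = 1,
                    boundary = "insulated", radiative = FALSE)$T
    expect_lte(max(Tc), mx + 1e-12)
    mx <- max(Tc)
  }
})

test_that("impulse response matches the analytic 3D heat kernel", {
  n <- 51L; dx <- 1e-4
  mf <- material_field(c(n, n, n), dx, rho = 1000, cp = 3000, k = 0.35,
                       mu_a = 0, mu_s = 0, w_perf = 0, q_met = 0,
                       T_init = 300, T_amb = 300)
  alpha <- 0.35 / 3e6
  E <- 1e-3
  cidx <- (n + 1L) / 2L
  T0 <- array(300, dim = mf$dims)
  T0[cidx, cidx, cidx] <- 300 + E / (3e6 * dx^3)
  dt <- 0.9 * stability_dt(mf)
  co <- grid_coords(mf)
  r2 <- outer(outer(co$x^2, co$y^2, `+`), (co$z - mean(co$z))^2, `+`)
  for (t_target in c(1, 2)) {
    ns <- round(t_target / dt)
    num <- step_heat(T0, mf, NULL, dt = dt, nsteps = ns,
                     boundary = "insulated", radiative = FALSE)$T - 300
    t_act <- ns * dt
    ana <- E / (3e6 * (4 * pi * alpha * t_act)^1.5) * exp(-r2 / (4 * alpha * t_act))
    rel_l2 <- sqrt(sum((num - ana)^2) / sum(ana^2))
    expect_lt(rel_l2, 0.02)
  }
})

test_that("perfusion steady state matches Q_m / (rho_b c_b w)", {
  # conduction-weak medium so the perfusion/metabolism balance dominates
  mf <- material_field(c(6, 6, 6), 1e-4, k = 1e-3, mu_a = 0, mu_s = 0,
                       w_perf = 1e-3, q_met = 200,
                       T_init = 303.45, T_amb = 296.45)
  dt <- 0.9 * stability_dt(mf)
  out <- step_heat(array(303.45, mf$dims), mf, NULL, dt = dt,
                   nsteps = round(8000 / dt), boundary = "insulated",
                   radiative = FALSE)
  offset <- mean(out$T) - 303.45
  expect_equal(offset, 200 / 3000, tolerance = 0.01)
})

test_that("time steps above the stability bound are rejected by name", {
  mf <- tiny_field()
  dt_max <- stability_dt(mf)
  expect_error(step_heat(array(300, mf$dims), mf, NULL, dt = 2 * dt_max),
               "stability bound")
  expect_error(step_heat(array(c(NaN, rep(300, prod(mf$dims) - 1)), mf$dims),
                         mf, NULL, dt = 0.5 * dt_max),
               "non-finite")
})

test_that("equilibration reaches near-steadiness on baseline tissue", {
  mf <- make_baseline(dims = c(30, 30, 30), spacing = 2e-4)
  eq <- equilibrate(mf, 120)
  expect_lt(eq$residual, 0.01)   # K/s
  # surface cooled below core by the radiative loss
  expect_lt(eq$T[15, 15, 1], eq$T[15, 15, 30])
})

test_that("a passive medium at ambient temperature stays at its initial field", {
  mf <- tiny_field(T_init = 296.45, T_amb = 296.45)
  eq <- equilibrate(mf, 5)
  expect_equal(eq$T, array(296.45, mf$dims), tolerance = 1e-12)
  expect_equal(eq$residual, 0, tolerance = 1e-12)
})

test_that("metabolism drives the field monotonically toward the perfusion steady state", {
  mf <- tiny_field(w_perf = 1e-3, q_met = 200, T_init = 300)
  dt <- 0.9 * stability_dt(mf)
  steady <- mf$T_a + 200 / (3e6 * 1e-3)
  Tc <- array(300, mf$dims)
  prev <- 300
  for (i in 1:30) {
    Tc <- step_heat(Tc, mf, NULL, dt = dt, nsteps = 5,
                    boundary = "insulated", radiative = FALSE)$T
    expect_gt(mean(Tc), prev)
    expect_lte(max(Tc), steady + 1e-9)
    prev <- mean(Tc)
  }
})

test_that("1D and 3D equilibration agree on a homogeneous medium", {
  mf <- make_baseline(dims = c(10, 10, 20), spacing = 2e-4)
  dt <- 0.5 * stability_dt(mf)
  eq1 <- equilibrate(mf, 10, dt = dt)   # column fast path
  eq3 <- step_heat(array(mf$T_init, mf$dims), mf, NULL, dt = dt,
                   nsteps = round(10 / dt), boundary = "insulated")
  expect_equal(eq1$T, eq3$T, tolerance = 1e-10)
})

test_that("doubling the beam power doubles the excess amplitude", {
  mf <- make_baseline(dims = c(30, 30, 16), spacing = 2e-4)
  cam <- camera_model(pitch = 2e-4, noise_sd = 0)
  pr <- sim_protocol(equilibration = 20, pre = 0.5, exposure = 3, post = 0)
  eq <- equilibrate(mf, 20)$T
  amp <- sapply(c(5e-3, 10e-3), function(P) {
    v <- run_fdti_protocol(mf, laser_beam(power = P), cam, pr, eq_field = eq)
    max(v$frames[, , dim(v$frames)[3]]) - max(v$frames[, , 1])
  })
  expect_equal(amp[2] / amp[1], 2, tolerance = 0.02)
})

test_that("peak excess is grid-converged on the baseline scenario", {
  # same 4 x 4 x 2 mm domain at 200 um and 100 um, observed at 200 um pixels
  pr <- sim_protocol(equilibration = 10, pre = 0.2, exposure = 2, post = 0)
  amp <- sapply(c(2e-4, 1e-4), function(h) {
    mf <- make_baseline(dims = round(c(4e-3, 4e-3, 2e-3) / h), spacing = h)
    cam <- camera_model(pitch = 2e-4, noise_sd = 0)
    v <- run_fdti_protocol(mf, laser_beam(), cam, pr)
    max(v$frames[, , dim(v$frames)[3]]) - max(v$frames[, , 1])
  })
  expect_equal(amp[1], amp[2], tolerance = 0.10)
})

test_that("zero-power protocol yields baseline-only frames", {
  mf <- make_baseline(dims = c(20, 20, 10), spacing = 2e-4)
  cam <- camera_model(pitch = 2e-4, noise_sd = 0.02)
  pr <- sim_protocol(equilibration = 10, pre = 0.5, exposure = 2, post = 1,
                     seed = 3)
  v <- run_fdti_protocol(mf, laser_beam(power = 0), cam, pr)
  ex <- v$frames - as.numeric(v$frames[, , 1])
  expect_lt(abs(mean(ex)), 0.01)
  expect_lt(max(abs(ex)), 6 * 0.02 * 2)
})

test_that("maximum temperature rises during exposure and decays after (noise-free)", {
  mf <- make_baseline(dims = c(30, 30, 16), spacing = 2e-4)
  cam <- camera_model(pitch = 2e-4, noise_sd = 0)
  pr <- sim_protocol(equilibration = 20, pre = 0.5, exposure = 4, post = 4)
  v <- run_fdti_protocol(mf, laser_beam(), cam, pr)
  pk <- apply(v$frames, 3, max)
  on <- v$timestamps > v$laser_on[1] + 1e-9 & v$timestamps <= v$laser_on[2]
  post <- v$timestamps > v$laser_on[2]
  expect_true(all(diff(pk[on]) > 0))
  expect_true(all(diff(pk[post]) < 0))
})
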