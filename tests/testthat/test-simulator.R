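# Exact-in-bout simulator: within-bout flow map, trajectory generation,
# closed-form cross-checks and the ensemble estimators.

test_that("within-bout advance reproduces the constant-force solution", {
  # at rest with no forcing: stays put
  st <- motion_state(a_current = 0, bout_end = 10)
  st2 <- advance_within_bout(st, 3, gamma = 1)
  expect_equal(c(st2$y, st2$v), c(0, 0))
  # force balancing drag: terminal velocity a/gamma is a fixed point
  st <- motion_state(v = 2, a_current = 2 * 0.7, bout_end = 50)
  for (dt in c(0.1, 1, 10)) {
    expect_equal(advance_within_bout(st, dt, gamma = 0.7)$v, 2,
                 tolerance = 1e-12)
  }
  # v0 = 0, a = 1, gamma = 1, dt = 1: v = 1 - e^-1, y = e^-1
  st <- motion_state(a_current = 1, bout_end = 2)
  st2 <- advance_within_bout(st, 1, gamma = 1)
  expect_equal(st2$v, 1 - exp(-1), tolerance = 1e-14)
  expect_equal(st2$y, exp(-1), tolerance = 1e-14)
  expect_error(advance_within_bout(st, 5, gamma = 1), "overruns")
})

test_that("within-bout advance agrees with an ODE integrator", {
  # independent oracle: high-accuracy Runge-Kutta on v' = -gamma v + a
  gamma <- 0.9; a <- 1.3; v0 <- -0.4; dt <- 1.7
  sol <- deSolve::ode(y = c(y = 0, v = v0), times = c(0, dt),
                      func = function(t, s, p) list(c(s[["v"]],
                                                      -gamma * s[["v"]] + a)),
                      parms = NULL, method = "ode45",
                      rtol = 1e-12, atol = 1e-12)
  st <- motion_state(v = v0, a_current = a, bout_end = 10)
  st2 <- advance_within_bout(st, dt, gamma)
  expect_equal(st2$y, unname(sol[2, "y"]), tolerance = 1e-9)
  expect_equal(st2$v, unname(sol[2, "v"]), tolerance = 1e-9)
})

test_that("the flow map is additive: dt1 then dt2 equals dt1 + dt2", {
  set.seed(99)
  for (i in 1:20) {
    gamma <- runif(1, 0, 3)
    st <- motion_state(y = rnorm(1), v = rnorm(1), a_current = rnorm(1),
                       bout_end = 10)
    dt1 <- runif(1, 0, 4); dt2 <- runif(1, 0, 4)
    one <- advance_within_bout(advance_within_bout(st, dt1, gamma), dt2, gamma)
    two <- advance_within_bout(st, dt1 + dt2, gamma)
    expect_equal(one$y, two$y, tolerance = 1e-12)
    expect_equal(one$v, two$v, tolerance = 1e-12)
  }
})

test_that("trajectories are deterministic given a seed", {
  p <- unit_params(gamma = 0.5)
  ts <- c(0.5, 2, 7)
  expect_identical(simulate_positions(p, ts, seed = 3),
                   simulate_positions(p, ts, seed = 3))
  m1 <- ensemble_msd(p, ts, n = 500, seed = 4)
  m2 <- ensemble_msd(p, ts, n = 500, seed = 4)
  expect_identical(m1$msd_hat, m2$msd_hat)
  expect_identical(simulate_positions(p, numeric(0), seed = 1), numeric(0))
})

test_that("a single uncut bout follows the constant-force position formula", {
  # predetermined bout list: a = 1, duration beyond every sample time
  ts <- c(0.3, 0.9, 1.8)
  pos <- positions_closed_form(accelerations = 1, durations = 5, gamma = 1,
                               t_query = ts)
  expect_equal(pos, ts + exp(-ts) - 1, tolerance = 1e-12)
})

test_that("sequential simulation equals the closed-form bout sum", {
  for (gamma in c(0.3, 1, 2.5)) {
    p <- unit_params(gamma)
    ts <- c(0.5, 1.5, 4, 9, 20)
    x <- simulate_positions(p, ts, seed = 17, keep_bouts = TRUE)
    cf <- positions_closed_form(attr(x, "bout_accelerations"),
                                attr(x, "bout_durations"), gamma, ts)
    expect_equal(as.numeric(x), cf, tolerance = 1e-10)
  }
})

test_that("R and compiled trajectory engines draw identical paths", {
  ts <- c(0.3, 1.7, 6.2)
  for (fam in c("gaussian", "uniform", "two_point")) {
    p <- model_params(1.3, 1.1, 0.7, accel_dist = fam)
    expect_equal(simulate_positions(p, ts, seed = 11),
                 drop(ensemble_positions(p, ts, n = 1, seed = 11)),
                 tolerance = 1e-12)
  }
})

test_that("drag-free trajectories use the exact gamma = 0 closed forms", {
  pos <- positions_closed_form(c(1, -2), c(1, 1), gamma = 0, t_query = c(1, 2))
  # bout 1: y(1) = 1/2, v(1) = 1; bout 2: y(2) = 1/2 + 1 - 1 = 1/2
  expect_equal(pos, c(0.5, 0.5))
  p <- unit_params(gamma = 0)
  em <- ensemble_msd(p, tau_grid(0.1, 10, 7), n = 2e4, seed = 5)
  expect_true(all(abs(em$msd_hat - msd_zero_drag(em$tau)) <= 4 * em$se))
})

test_that("ensemble MSD tracks the exact formula within Monte Carlo error", {
  p <- unit_params(gamma = 1)
  taus <- tau_grid(1e-2, 1e2, 21)
  em <- ensemble_msd(p, taus, n = 2e4, seed = 21)
  exact <- msd_exact(1, taus)
  expect_gte(mean(abs(em$msd_hat - exact) <= 4 * em$se), 0.95)
  # degenerate ensemble: finite standard error, no crash
  em2 <- ensemble_msd(p, c(1, 2), n = 2, seed = 1)
  expect_true(all(is.finite(em2$se)))
  expect_true(all(em2$msd_hat >= 0))
})

test_that("MSD is invariant across acceleration families (equal variance)", {
  taus <- tau_grid(0.1, 30, 9)
  base <- ensemble_msd(unit_params(1, "gaussian"), taus, n = 3e4, seed = 31)
  for (fam in c("uniform", "two_point")) {
    alt <- ensemble_msd(unit_params(1, fam), taus, n = 3e4, seed = 32)
    comb <- sqrt(base$se^2 + alt$se^2)
    expect_true(all(abs(base$msd_hat - alt$msd_hat) <= 4 * comb),
                label = paste("family invariance:", fam))
  }
})

test_that("two independent coordinates give <r^2> = 2 <x^2>", {
  p <- unit_params(1)
  n <- 2e4
  x <- drop(ensemble_positions(p, 10, n, seed = 41))
  y <- drop(ensemble_positions(p, 10, n, seed = 42))
  r2 <- x^2 + y^2
  se <- sd(r2) / sqrt(n)
  expect_lt(abs(mean(r2) - 2 * msd_exact(1, 10)), 4 * se)
})

test_that("dispersal kernel estimate is a symmetric density, heavy-tailed early", {
  p <- unit_params(1)
  pdf1 <- ensemble_pdf(p, tau = 1, n = 1e5, n_bins = 81, seed = 51,
                       half_width = NULL)
  width <- diff(pdf1$bin_centers[1:2])
  expect_equal(sum(pdf1$density) * width, 1, tolerance = 1e-2)
  central <- (length(pdf1$bin_centers) + 1) %/% 2
  expect_equal(pdf1$density_renorm[central], 1)
  # isotropic forcing: no skew
  expect_lt(abs(sample_skewness(pdf1$positions)), 5 * se_skewness(pdf1$n))
  # early-time kernel has exponential tails: positive excess kurtosis
  k <- sample_excess_kurtosis(pdf1$positions)
  expect_gt(k, 5 * sqrt(24 / pdf1$n))
  # central-bin warning when the bins are far too narrow for the sample size
  expect_warning(ensemble_pdf(p, tau = 1024, n = 1000, n_bins = 20001,
                              seed = 52), "central bin")
})

test_that("large-time kernel converges to the Gaussian dispersal kernel", {
  # reduced-scale Gaussianity check; the acceptance suite runs n = 1e6
  p <- unit_params(1)
  x <- drop(ensemble_positions(p, 256, n = 5e4, seed = 61))
  v <- diffusive_asymptote(1, 256)
  ks <- suppressWarnings(ks.test(x, "pnorm", 0, sqrt(v)))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("empirical forcing autocovariance matches nu_a2 e^{-omega lag}", {
  p <- model_params(nu_a2 = 2, omega = 1, gamma = 1)
  ac <- empirical_acc_autocov(p, lags = c(0, 1, 5, 20), total_time = 5e4,
                              seed = 71)
  expect_true(all(abs(ac$autocov - ac$theory) <= 5 * ac$se))
  # zero lag recovers the variance; long lags decorrelate
  expect_lt(abs(ac$autocov[1] - 2), 5 * ac$se[1])
  expect_lt(abs(ac$autocov[4]), 5 * ac$se[4])
})
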