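# Closed-form MSD and its limits. The frozen reference values were computed
# from the same closed form evaluated in 60-digit arithmetic (independent of
# the package's double-precision evaluation regions).

test_that("exact MSD matches a high-precision reference across all regions", {
  ref <- rbind(
    c(0.015625, 0.3, 0.0018667571216353103),
    c(0.001, 1.5, 0.88344556891333843),
    c(0.2, 0.05, 1.5316368464406894e-6),
    c(0.5, 1.0, 0.14105926555008104),
    c(1.0, 1.0, 0.10469732128000684),
    c(1.0, 0.001, 2.4976679161747596e-13),
    c(2.0, 5.0, 1.7150711786226228),
    c(4.0, 100.0, 12.340625),
    c(64.0, 0.01, 1.663593527164569e-9),
    c(1.0, 0.25, 0.00077643546702315229),
    c(0.25, 10.0, 132.74062897993875),
    c(16.0, 2.0, 0.0084376515637364832))
  got <- msd_exact(ref[, 1], ref[, 2])
  expect_equal(got, ref[, 3], tolerance = 1e-10)
})

test_that("process started at rest has zero MSD at tau = 0", {
  expect_identical(msd_exact(zeta_grid_4n, 0), rep(0, 7))
  expect_identical(msd_zero_drag(0), 0)
  expect_identical(msd_small_time(0), 0)
})

test_that("MSD scales as eta^2 and rejects zeta <= 0", {
  expect_equal(msd_exact(2, 1, eta = 3), 9 * msd_exact(2, 1))
  expect_error(msd_exact(0, 1), "zero_drag")
  expect_error(msd_exact(-1, 1), "zero_drag")
})

test_that("exact MSD is continuous across the removable zeta = 1 point", {
  for (tau in c(0.1, 1, 10)) {
    two_sided <- (msd_exact(1 + 1e-6, tau) + msd_exact(1 - 1e-6, tau)) / 2
    expect_equal(msd_exact(1, tau), two_sided, tolerance = 1e-8)
    # deviation shrinks linearly with the offset
    d1 <- abs(msd_exact(1 + 1e-2, tau) - msd_exact(1, tau))
    d2 <- abs(msd_exact(1 + 1e-3, tau) - msd_exact(1, tau))
    expect_lt(d2, 0.2 * d1)
  }
})

test_that("exact MSD is strictly increasing in tau", {
  taus <- c(10^seq(-4, 2, length.out = 80), seq(1, 100, length.out = 60))
  taus <- sort(unique(taus))
  for (z in zeta_grid_4n) {
    v <- msd_exact(z, taus)
    expect_true(all(diff(v) > 0), label = paste("monotone at zeta =", z))
  }
})

test_that("zero-drag curve is the zeta -> 0 limit and an upper envelope", {
  # limit consistency
  expect_equal(msd_exact(1e-6, 1), msd_zero_drag(1), tolerance = 1e-4)
  # small-time Taylor: (eta^2/4) tau^4 leading order
  for (tau in c(1e-4, 1e-3, 1e-2)) {
    expect_equal(msd_zero_drag(tau) / msd_small_time(tau), 1,
                 tolerance = 0.3 * tau)
  }
  # envelope: drag only slows the spread, and the ratio -> 1 as tau -> 0
  taus <- 10^seq(-3, 2, length.out = 40)
  for (z in c(0.01, 0.25, 1, 4, 64)) {
    ratio <- msd_exact(z, taus) / msd_zero_drag(taus)
    expect_true(all(ratio <= 1 + 1e-9), label = paste("envelope, zeta =", z))
    expect_equal(ratio[1], 1, tolerance = 2 * z * 1e-3)
  }
})

test_that("small-time asymptote: arithmetic and agreement with the exact MSD", {
  expect_equal(msd_small_time(2, eta = 3), 36)  # 9 * 16 / 4
  r <- msd_exact(1, 1e-3) / msd_small_time(1e-3)
  expect_gt(r, 0.999); expect_lt(r, 1.001)
})

test_that("diffusive asymptote is linear with slope 2 eta^2/zeta^2", {
  for (z in c(0.25, 1, 4)) {
    slope <- diffusive_asymptote(z, 11) - diffusive_asymptote(z, 10)
    expect_equal(slope, 2 / z^2)
  }
  # term-by-term arithmetic at zeta = 1, eta = 1, tau = 10:
  # 2*10/1 - [1 + 2*(2)^2]/(1*2) = 20 - 4.5
  expect_equal(diffusive_asymptote(1, 10), 15.5)
  # exact MSD converges to the asymptote at large tau
  for (z in c(0.25, 1, 4)) {
    tau <- 400 / z
    expect_equal(msd_exact(z, tau) / diffusive_asymptote(z, tau), 1,
                 tolerance = 1e-8)
  }
})

test_that("Gaussian kernel is a normalized density with variance Delta_d^2", {
  z <- 1; tau <- 50
  v <- diffusive_asymptote(z, tau)
  expect_equal(gaussian_kernel(2.5, z, tau), gaussian_kernel(-2.5, z, tau))
  total <- integrate(function(x) gaussian_kernel(x, z, tau),
                     -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  second <- integrate(function(x) x^2 * gaussian_kernel(x, z, tau),
                      -Inf, Inf, rel.tol = 1e-9)$value
  expect_equal(second, v, tolerance = 1e-6)
  expect_error(gaussian_kernel(0, 1, 0.1), "not yet valid")
})

test_that("low-drag form reduces to the Wiener-limit MSD and its t^3 onset", {
  expect_equal(msd_low_drag(1, 1, 1, 0), 0)
  # Taylor oracle: bracket = (gamma t)^3/3 + O((gamma t)^4)
  g <- 1; t <- 1e-3
  r <- msd_low_drag(g, 1, 1, t) / ((2 / 3) * t^3)
  expect_gt(r, 0.999); expect_lt(r, 1.001)
  # regime overlap: tau >> 1 with zeta*tau << 1. The neglected terms decay
  # like 3/(2 tau), so the 1% window opens around tau ~ 300.
  expect_equal(msd_low_drag(1e-3, 1, 1, 300) / msd_exact(1e-3, 300), 1,
               tolerance = 0.01)
  expect_equal(msd_low_drag(1e-4, 1, 1, 1e3) / msd_exact(1e-4, 1e3), 1,
               tolerance = 0.002)
})

test_that("high-drag form matches the velocity jump MSD and its t^2 onset", {
  expect_equal(msd_high_drag(1, 1, 1, 0), 0)
  g <- 10; t <- 1e-3  # omega t = 1e-3
  r <- msd_high_drag(g, 1, 1, t) / (t^2 / g^2)
  expect_gt(r, 0.999); expect_lt(r, 1.001)
  # regime overlap: zeta = 1e3, tau = 0.5 (zeta*tau >> 1, tau small)
  expect_equal(msd_high_drag(1e3, 1, 1, 0.5) / msd_exact(1e3, 0.5), 1,
               tolerance = 0.01)
})

test_that("small-time exponent taxonomy follows the drag intensity", {
  slope_at <- function(z, tau) loglog_slope(function(tt) msd_exact(z, tt), tau)
  # low drag: tau^4 -> tau^3 -> tau
  expect_equal(slope_at(1e-3, 1e-4), 4, tolerance = 0.05)
  expect_equal(slope_at(1e-3, 50), 3, tolerance = 0.05)
  expect_equal(slope_at(1e-3, 1e7), 1, tolerance = 0.05)
  # high drag: tau^4 -> tau^2 -> tau (the t^2 window needs zeta*tau >> 1,
  # tau << 1, comfortably satisfied at zeta*tau = 50..100)
  expect_equal(slope_at(1e3, 1e-4), 4, tolerance = 0.05)
  expect_equal(slope_at(1e3, 0.05), 2, tolerance = 0.05)
  expect_equal(slope_at(1e4, 1e-2), 2, tolerance = 0.05)
  expect_equal(slope_at(1e3, 1e6), 1, tolerance = 0.05)
})

test_that("msd_curve tabulates each formula consistently", {
  taus <- tau_grid(1e-2, 1e2, 9)
  cv <- msd_curve(zeta = 2, tau = taus)
  expect_s3_class(cv, "msd_curve")
  expect_equal(cv$msd, msd_exact(2, taus))
  expect_equal(msd_curve(2, taus, formula = "zero_drag")$msd,
               msd_zero_drag(taus))
  expect_equal(msd_curve(2, taus, formula = "high_drag")$msd,
               msd_high_drag(2, 1, 1, taus))
})
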