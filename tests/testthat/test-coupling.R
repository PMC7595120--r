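test_that("windowed cross-correlation is a true correlation", {
  set.seed(11)
  x <- rnorm(100)
  cc <- cross_correlation(x, x, tau_max = 5)
  expect_equal(cc$rho[cc$tau == 0], 1, tolerance = 1e-9)
  expect_true(all(abs(cc$rho) <= 1 + 1e-9))

  # y follows x by 3 samples (y(t) = x(t-3)): peak exactly at tau = 3
  z <- rnorm(200)
  xs <- z[4:153]
  ys <- z[1:150]
  cc <- cross_correlation(xs, ys, tau_max = 10)
  expect_identical(cc$tau[which.max(abs(cc$rho))], 3L)
  expect_equal(max(abs(cc$rho)), 1, tolerance = 1e-9)

  # matches a brute-force lagged Pearson at every scanned delay
  set.seed(12)
  a <- rnorm(80)
  b <- rnorm(80)
  cc <- cross_correlation(a, b, tau_max = 8, include_negative = TRUE)
  for (i in seq_len(nrow(cc))) {
    expect_equal(cc$rho[i], bf_lag_cor(a, b, cc$tau[i]), tolerance = 1e-12)
  }
})

test_that("independent long segments show only small lagged correlation", {
  set.seed(21)
  x <- rnorm(1000)
  y <- rnorm(1000)
  cc <- cross_correlation(x, y, tau_max = 10)
  expect_lt(max(abs(cc$rho)), 0.15)
})

test_that("partial cross-correlation reduces correctly in edge cases", {
  set.seed(31)
  x <- rnorm(200)
  y <- rnorm(200)
  # empty control set: identical to the plain curve
  p0 <- partial_cross_correlation(x, y, controls = NULL, taus = 0:6)
  c0 <- cross_correlation(x, y, tau_max = 6)
  expect_equal(p0$rho, c0$rho, tolerance = 1e-12)

  # control exactly orthogonal to both members (at lag 0): no effect
  z <- rnorm(200)
  z <- stats::resid(stats::lm(z ~ x + y))
  p1 <- partial_cross_correlation(x, y, controls = cbind(z), taus = 0L,
                                  control_shifts = 0L)
  expect_equal(p1$rho, stats::cor(x, y), tolerance = 1e-10)
})

test_that("recursion agrees with the literal first-order identity", {
  set.seed(41)
  x <- rnorm(200)
  y <- rnorm(200)
  z <- 0.5 * x + 0.5 * rnorm(200)
  p <- partial_cross_correlation(x, y, controls = cbind(z), taus = 4L,
                                 control_shifts = 0L)
  L <- 200
  rxy <- stats::cor(x[1:(L - 4)], y[5:L])
  rxz <- stats::cor(x, z)
  rzy <- stats::cor(z[1:(L - 4)], y[5:L])
  expect_equal(p$rho, bf_partial1(rxy, rxz, rzy), tolerance = 1e-10)
})

test_that("recursion matches the regression-residual oracle", {
  set.seed(51)
  for (rep in 1:40) {
    N <- sample(1:4, 1)
    tau <- sample(0:8, 1)
    L <- 200
    x <- rnorm(L)
    y <- 0.4 * x + rnorm(L)
    Z <- matrix(rnorm(L * N), L, N) + 0.3 * x
    shifts <- sample(-3:3, N, replace = TRUE)
    p <- partial_cross_correlation(x, y, controls = Z, taus = tau,
                                   control_shifts = shifts)
    o <- residual_partial_correlation(x, y, controls = Z, tau = tau,
                                      control_shifts = shifts)
    expect_equal(p$rho, o, tolerance = 1e-6)
  }
})

test_that("oracle equals lm() residual correlation at lag zero", {
  set.seed(61)
  L <- 150
  x <- rnorm(L)
  y <- rnorm(L)
  Z <- matrix(rnorm(L * 3), L, 3)
  o <- residual_partial_correlation(x, y, controls = Z, tau = 0L,
                                    control_shifts = 0L)
  rx <- stats::resid(stats::lm(x ~ Z))
  ry <- stats::resid(stats::lm(y ~ Z))
  expect_equal(o, stats::cor(rx, ry), tolerance = 1e-10)
})

test_that("recursion is invariant to control ordering", {
  set.seed(71)
  L <- 200
  x <- rnorm(L)
  y <- 0.5 * x + rnorm(L)
  Z <- matrix(rnorm(L * 4), L, 4) + 0.2 * x
  sh <- c(1L, -2L, 0L, 3L)
  p1 <- partial_cross_correlation(x, y, Z, taus = 3L, control_shifts = sh)
  perm <- c(3L, 1L, 4L, 2L)
  p2 <- partial_cross_correlation(x, y, Z[, perm], taus = 3L,
                                  control_shifts = sh[perm])
  expect_equal(p1$rho, p2$rho, tolerance = 1e-5)
})

test_that("independent controls leave the correlation nearly unchanged", {
  set.seed(81)
  L <- 5000
  x <- rnorm(L)
  y <- 0.6 * x + rnorm(L)
  Z <- matrix(rnorm(L * 3), L, 3)
  p <- partial_cross_correlation(x, y, Z, taus = 0L, control_shifts = 0L)
  expect_equal(p$rho, stats::cor(x, y), tolerance = 0.05)
})

test_that("near-singular controls exclude the segment instead of exploding", {
  set.seed(91)
  x <- rnorm(100)
  y <- rnorm(100)
  p <- partial_cross_correlation(x, y, controls = cbind(x + 1e-9 * rnorm(100)),
                                 taus = 0:3, control_shifts = 0L)
  expect_true(attr(p, "excluded"))
  expect_true(all(is.na(p$rho)))
})

test_that("delay-aligned controls cancel a lag-mediated chain", {
  # x -> z (lag 2) -> y (lag 3): the spurious x-y correlation at lag 5 is
  # removed once z enters at its coupling lag, but not at lag 0
  set.seed(101)
  n <- 2000
  x <- rnorm(n)
  z <- c(rep(0, 2), 0.9 * x[1:(n - 2)]) + 0.4 * rnorm(n)
  y <- c(rep(0, 3), 0.9 * z[1:(n - 3)]) + 0.4 * rnorm(n)
  keep <- 11:n
  x <- x[keep]; z <- z[keep]; y <- y[keep]
  plain <- cross_correlation(x, y, tau_max = 8)
  expect_gt(abs(plain$rho[plain$tau == 5]), 0.4)
  aligned <- partial_cross_correlation(x, y, controls = cbind(z), taus = 5L)
  lag0 <- partial_cross_correlation(x, y, controls = cbind(z), taus = 5L,
                                    control_shifts = 0L)
  expect_lt(abs(aligned$rho), 0.1)
  expect_gt(abs(lag0$rho), 0.3)
  expect_identical(attr(aligned, "shifts"), 2)
})
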