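test_that("noiseless shift yields the exact delay in every segment", {
  set.seed(1)
  z <- rnorm(140)
  rec <- mc_record(cbind(x = z[4:123], y = z[1:120]))
  pr <- optimal_delays(rec, "x", "y", method = "mtds", L = 20, tau_max = 8)
  expect_true(all(pr$tau0 == 3L))
  expect_true(all(pr$rho0 > 0.999))
  # full stability and strength 100%
  ls <- link_strength(stability_mask(pr))
  expect_equal(ls$strength, 100)
  expect_identical(ls$delay, 3L)
})

test_that("identical channels give zero delay under the undirected scan", {
  set.seed(2)
  z <- rnorm(100)
  rec <- mc_record(cbind(x = z, y = z))
  pr <- optimal_delays(rec, "x", "y", method = "tds", L = 20, tau_max = 5)
  expect_true(all(pr$tau0 == 0L))
})

test_that("stability rule marks 4-of-5 windows as specified", {
  prof <- tibble::tibble(tau0 = c(3L, 3L, 3L, 3L, 3L),
                         excluded = rep(FALSE, 5))
  expect_true(all(stability_mask(prof)$stable))

  prof2 <- tibble::tibble(tau0 = c(3L, 3L, 9L, 3L, 3L),
                          excluded = rep(FALSE, 5))
  inband <- stability_mask(prof2, tolerance = 2, marking = "inband")
  expect_identical(inband$stable, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # window marking counts the whole qualifying period
  expect_true(all(stability_mask(prof2, tolerance = 2,
                                 marking = "window")$stable))

  expect_error(stability_mask(tibble::tibble(tau0 = 1:4,
                                             excluded = rep(FALSE, 4))),
               class = "ctdsnet_error_undefined_stability")
})

test_that("random delays over a wide range are rarely stable", {
  set.seed(3)
  fracs <- replicate(200, {
    prof <- tibble::tibble(tau0 = sample(0:50, 100, replace = TRUE),
                           excluded = rep(FALSE, 100))
    mean(stability_mask(prof, tolerance = 2, marking = "inband")$stable)
  })
  expect_lt(mean(fracs), 0.15)
})

test_that("link strength handles the all-stable and never-stable extremes", {
  prof <- tibble::tibble(tau0 = rep(2L, 8), excluded = rep(FALSE, 8))
  expect_equal(link_strength(stability_mask(prof))$strength, 100)
  prof2 <- tibble::tibble(tau0 = c(0L, 9L, 2L, 14L, 5L, 11L, 7L, 1L),
                          excluded = rep(FALSE, 8))
  ls <- link_strength(stability_mask(prof2, tolerance = 1))
  expect_equal(ls$strength, 0)
  expect_true(is.na(ls$delay))
})

test_that("network matrices have the right structure", {
  sim <- simulate_fixed_network(seed = 5)
  for (m in c("ctds", "mtds", "tds")) {
    net <- build_network(sim$record, method = m)
    expect_true(all(diag(net$strength) == 0))
    s <- net$strength[row(net$strength) != col(net$strength)]
    expect_true(all(s >= 0 & s <= 100, na.rm = TRUE))
    if (m == "tds") {
      expect_identical(net$strength, t(net$strength))
    }
  }
  td <- tidy(build_network(sim$record, method = "ctds"))
  expect_identical(nrow(td), 20L)
  expect_s3_class(td, "tbl_df")
})

test_that("relabelling channels permutes the strength matrix consistently", {
  rec <- make_record(7, n_ch = 4, n_samples = 120)
  net <- build_network(rec, method = "ctds")
  perm <- c(3L, 1L, 4L, 2L)
  rec2 <- mc_record(rec$data[, perm])
  net2 <- build_network(rec2, method = "ctds")
  expect_equal(net2$strength, net$strength[perm, perm], tolerance = 1e-12)
})

test_that("two-channel controlled network equals the directional one", {
  rec <- make_record(9, n_ch = 2, n_samples = 150)
  expect_equal(build_network(rec, method = "ctds")$strength,
               build_network(rec, method = "mtds")$strength)
})

test_that("a strongly driven pair recovers its simulated lag", {
  sim <- simulate_fixed_network(seed = 3, noise_sd = 0.1)
  pr <- optimal_delays(sim$record, "x3", "x2", method = "ctds")
  tau <- pr$tau0[!is.na(pr$tau0)]
  expect_identical(as.integer(names(sort(table(tau), decreasing = TRUE))[1]),
                   1L)
})

test_that("white-noise networks stay below the null's upper tail", {
  set.seed(13)
  base <- replicate(30, {
    net <- build_network(matrix(rnorm(500), 100, 5), method = "ctds")
    net$strength[row(net$strength) != col(net$strength)]
  })
  q95 <- stats::quantile(base, 0.95)
  net <- build_network(matrix(rnorm(500), 100, 5), method = "ctds")
  s <- net$strength[row(net$strength) != col(net$strength)]
  expect_lte(mean(s > q95), 0.25)
})
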