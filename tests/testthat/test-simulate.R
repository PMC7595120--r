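test_that("fixed network follows the printed recursions", {
  # homogeneous system with zero noise and zero history stays at zero
  sim0 <- simulate_fixed_network(seed = 1, noise_sd = 1e-300)
  expect_lt(max(abs(sim0$record$data)), 1e-200)

  sim <- simulate_fixed_network(seed = 1)
  expect_identical(dim(sim$record$data), c(100L, 5L))
  expect_identical(nrow(sim$truth), 7L)
  key <- paste(sim$truth$source, sim$truth$target, sim$truth$lag)
  expect_setequal(key, c("2 1 1", "5 1 3", "3 2 1", "4 3 3",
                         "2 4 2", "3 4 2", "1 5 3"))
  # bidirectional pairs 1-5 and 3-4 are both present
  expect_true(all(c("5 1 3", "1 5 3", "4 3 3", "3 4 2") %in% key))

  # the generated series satisfies the recursion exactly
  X <- sim$record$data
  w4 <- X[, 4] - c(0, 0, 0.3 * X[1:98, 2] - 0.5 * X[1:98, 3])
  x1_pred <- c(0, 0.7 * X[1:99, 2]) + c(0, 0, 0, 0.8 * X[1:97, 5])
  expect_equal(stats::sd(X[, 1] - x1_pred), 1, tolerance = 0.2)
  expect_equal(stats::sd(w4), 1, tolerance = 0.2)

  expect_identical(simulate_fixed_network(seed = 42)$record$data,
                   simulate_fixed_network(seed = 42)$record$data)
})

test_that("random networks honour density, decay and noise semantics", {
  sim <- simulate_random_network(n = 5, k = 1, link_prob = 0, seed = 2)
  expect_identical(nrow(sim$truth), 0L)

  sim <- simulate_random_network(n = 6, k = 1, seed = 3)
  expect_true(all(abs(sim$truth$coefficient) <= 1))
  expect_equal(sim$truth$effective,
               abs(sim$truth$coefficient) * exp(-0.1 * sim$truth$lag),
               tolerance = 1e-12)
  # a linked ordered pair carries coefficients at every lag
  links <- dplyr::distinct(sim$truth, source, target)
  expect_identical(nrow(sim$truth), nrow(links) * 3L)

  expect_identical(simulate_random_network(n = 4, k = 2, seed = 9)$record$data,
                   simulate_random_network(n = 4, k = 2, seed = 9)$record$data)
})

test_that("noise amplitude k scales the innovations", {
  sim <- simulate_random_network(n = 3, k = 2.5, link_prob = 0,
                                 n_samples = 1e4, seed = 4)
  expect_equal(stats::sd(sim$record$data), 2.5, tolerance = 0.05 * 2.5)
})

test_that("physiological fixture cohorts are reproducible and disjoint", {
  co <- generate_physio_fixture(n_subjects = 3, n_channels = 5,
                                states = c("rest", "task"), seed = 5,
                                n_samples = 120)
  expect_identical(nrow(co), 6L)
  expect_identical(dim(co$record[[1]]$data), c(120L, 5L))

  link_keys <- function(tr) paste(tr$source, tr$target)
  rest <- link_keys(co$truth[[which(co$state == "rest")[1]]])
  task <- link_keys(co$truth[[which(co$state == "task")[1]]])
  expect_length(intersect(rest, task), 0L)

  # truth is shared across subjects within a state
  rest2 <- link_keys(co$truth[[which(co$state == "rest")[2]]])
  expect_setequal(rest, rest2)

  co2 <- generate_physio_fixture(n_subjects = 3, n_channels = 5,
                                 states = c("rest", "task"), seed = 5,
                                 n_samples = 120)
  expect_identical(co$record[[1]]$data, co2$record[[1]]$data)

  # 14-channel default uses physiological labels
  co14 <- generate_physio_fixture(n_subjects = 1, seed = 6, n_samples = 120)
  expect_true(all(c("HR", "Resp", "L_alpha", "R_gamma") %in%
                    co14$record[[1]]$labels))
})
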