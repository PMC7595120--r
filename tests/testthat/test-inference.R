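test_that("rank-sum comparison behaves at the extremes", {
  expect_gte(mww_compare(c(1, 2, 3), c(1, 2, 3)), 0.9)
  expect_lt(mww_compare(1:7, 8:20), 1e-3)
  expect_error(mww_compare(numeric(0), 1:3),
               class = "ctdsnet_error_empty_sample")
})

test_that("exact branch equals independent enumerations, ties included", {
  set.seed(1)
  for (rep in 1:30) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    a <- sample(1:6, na, replace = TRUE) + if (rep %% 2) 0 else rnorm(na)
    b <- sample(1:6, nb, replace = TRUE) + if (rep %% 2) 0 else rnorm(nb)
    expect_equal(mww_compare(a, b), bf_mww_p(a, b), tolerance = 1e-12)
  }
  # untied case against the exact Wilcoxon distribution
  for (rep in 1:20) {
    a <- rnorm(4)
    b <- rnorm(5)
    expect_equal(mww_compare(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normality check is calibrated and has power", {
  set.seed(2)
  pn <- replicate(40, normality_check(rnorm(5000))$p.value)
  expect_gte(mean(pn > 0.01), 0.95)
  pt <- replicate(10, normality_check(rt(5000, df = 2))$p.value)
  expect_true(all(pt < 0.01))
  # symmetric two-point mass: extreme (negative excess) kurtosis term
  jb <- normality_check(rep(c(-1, 1), 50))
  expect_gt(jb$statistic, 15)
  expect_error(normality_check(rnorm(5)),
               class = "ctdsnet_error_sample_too_small")
})

test_that("delta strength follows its definition", {
  truth <- tibble::tibble(source = c(1L, 2L), target = c(2L, 3L),
                          lag = c(1L, 1L), coefficient = c(0.5, 0.5),
                          effective = c(0.45, 0.45))
  s <- matrix(50, 3, 3)
  diag(s) <- 0
  flat <- delta_strength(truth, fake_network(s))
  expect_equal(flat$delta, 0)

  s2 <- matrix(20, 3, 3)
  s2[1, 2] <- 80
  s2[2, 3] <- 80
  diag(s2) <- 0
  d <- delta_strength(truth, fake_network(s2))
  expect_equal(d$delta, 60)
  expect_identical(d$n_primary, 2L)
  expect_identical(d$n_other, 4L)

  expect_error(delta_strength(truth[0, ], fake_network(s)),
               class = "ctdsnet_error_no_primary_links")
})

test_that("coefficient-strength correlation is exact for a linear map", {
  sims <- list()
  nets <- list()
  set.seed(3)
  for (i in 1:3) {
    n <- 4
    truth <- tibble::tibble(source = c(1L, 2L, 3L), target = c(2L, 3L, 4L),
                            lag = 1L, coefficient = runif(3),
                            effective = NA_real_)
    truth$effective <- abs(truth$coefficient) * exp(-0.1)
    s <- matrix(0, n, n)
    s[cbind(truth$source, truth$target)] <- 100 * truth$effective
    sims[[i]] <- structure(list(truth = truth), class = "ctds_sim")
    nets[[i]] <- fake_network(s)
  }
  res <- strength_coefficient_correlation(sims, nets)
  expect_equal(res$estimate, 1, tolerance = 1e-12)
})

test_that("consensus rule is strict and monotone", {
  set.seed(4)
  n_units <- 110
  nets <- lapply(seq_len(n_units), function(u) {
    s <- matrix(stats::runif(9, 0, 100), 3, 3)
    diag(s) <- 0
    fake_network(s)
  })
  # engineered fractions: link 1->2 above threshold in exactly 44 units (40%),
  # link 1->3 in 45 (≈40.9%), link 2->3 in all units
  for (u in seq_len(n_units)) {
    nets[[u]]$strength[1, 2] <- if (u <= 44) 80 else 10
    nets[[u]]$strength[1, 3] <- if (u <= 45) 80 else 10
    nets[[u]]$strength[2, 3] <- 90
  }
  cons <- consensus_network(nets, threshold = 19, min_fraction = 0.4)
  keys <- paste(cons$edges$source, cons$edges$target)
  expect_false("n1 n2" %in% keys) # exactly 40% is NOT more than 40%
  expect_true("n1 n3" %in% keys)
  expect_equal(cons$edges$fraction[cons$edges$source == "n1" &
                                     cons$edges$target == "n3"],
               45 / 110, tolerance = 1e-12)
  expect_equal(cons$fraction[2, 3], 1)
  # inclusive variant admits the exactly-40% link
  inc <- consensus_network(nets, threshold = 19, min_fraction = 0.4,
                           strict = FALSE)
  expect_true("n1 n2" %in% paste(inc$edges$source, inc$edges$target))

  # monotonicity: raising threshold or min_fraction never adds edges
  base <- nrow(cons$edges)
  for (th in c(30, 60, 85)) {
    e1 <- nrow(consensus_network(nets, threshold = th, min_fraction = 0.4)$edges)
    expect_lte(e1, base)
  }
  for (mf in c(0.5, 0.7, 0.95)) {
    e2 <- nrow(consensus_network(nets, threshold = 19, min_fraction = mf)$edges)
    expect_lte(e2, base)
  }
  expect_error(consensus_network(list(nets[[1]], fake_network(matrix(0, 2, 2))),
                                 threshold = 19),
               class = "ctdsnet_error_node_set_mismatch")
})

test_that("surrogate test separates constructed real/surrogate strengths", {
  set.seed(5)
  n <- 3
  make_net <- function(s) fake_network(s)
  # surrogate strengths ~ U(10, 30); real uniformly 30 points higher
  surr <- lapply(1:40, function(i) {
    s <- matrix(stats::runif(n * n, 10, 30), n, n)
    diag(s) <- 0
    make_net(s)
  })
  real <- lapply(1:12, function(i) {
    s <- matrix(stats::runif(n * n, 10, 30) + 30, n, n)
    diag(s) <- 0
    make_net(s)
  })
  st <- surrogate_test(real, surr, alpha = 1e-3)
  expect_true(all(st$links$significant))
  # brute-force threshold: smallest cutoff with all occurring links significant
  mean_real <- st$links$mean_real
  bf <- NA_integer_
  for (cut in 1:99) {
    occ <- mean_real > cut
    tail_ok <- vapply(cut:99, function(c2) {
      o <- mean_real > c2
      !any(o) || all(st$links$significant[o])
    }, logical(1))
    if (any(mean_real > cut) && all(tail_ok)) { bf <- cut; break }
  }
  expect_identical(st$threshold, bf)
  expect_false(is.na(st$threshold))

  # exchangeable case: same distribution on both sides -> threshold absent
  same <- lapply(1:12, function(i) {
    s <- matrix(stats::runif(n * n, 10, 30), n, n)
    diag(s) <- 0
    make_net(s)
  })
  st0 <- surrogate_test(same, surr, alpha = 1e-3)
  expect_false(any(st0$links$significant))
  expect_true(is.na(st0$threshold))

  expect_error(surrogate_test(real[1], surr),
               class = "ctdsnet_error_insufficient_units")
})

test_that("surrogate pairing requires enough units and mixes subjects", {
  co <- generate_physio_fixture(n_subjects = 6, n_channels = 4,
                                states = "rest", seed = 6, n_samples = 120)
  expect_error(surrogate_networks(co$record[1:3], n_surrogates = 2, seed = 1),
               class = "ctdsnet_error_insufficient_units")
  sn <- surrogate_networks(co$record, n_surrogates = 3, seed = 1, L = 20)
  expect_length(sn, 3L)
  expect_s3_class(sn[[1]], "ctds_network")
})
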