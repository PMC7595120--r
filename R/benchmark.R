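# Benchmarking engines: the (n, k) grid comparison of directional estimators
# on random lagged networks, and the pooled coefficient-vs-strength
# correlation protocol on a fixed-size ensemble.

derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Grid benchmark of link recovery on random networks
#'
#' For every combination of network size `n` and noise amplitude `k`,
#' simulates `reps` random lagged networks, estimates them with each method,
#' and summarises recovery: per-network average strength of primary
#' (simulated) links and of all other ordered pairs, their difference
#' (delta, in percentage points), and a rank-sum comparison of the two sets
#' of per-network averages across the replicates.
#'
#' @param ns Integer vector of network sizes.
#' @param ks Numeric vector of noise amplitudes.
#' @param reps Networks per cell (default 10).
#' @param methods Estimators to compare (default mtds and ctds).
#' @param seed Integer seed; all per-network seeds derive from it.
#' @inheritParams build_network
#' @inheritParams simulate_random_network
#' @return A tibble with one row per (n, k, method): `mww_p`, `mean_delta`,
#'   `min_delta`, `max_delta`, `reps`.
#' @examples
#' run_benchmark(ns = 4, ks = 1, reps = 3, seed = 1)
#' @export
run_benchmark <- function(ns = 4:8, ks = c(0.01, 0.1, 1, 10, 100), reps = 10,
                          methods = c("mtds", "ctds"), seed,
                          L = 20, tau_max = NULL, tolerance = 2,
                          n_samples = 100, D = 3, link_prob = NULL) {
  cells <- expand.grid(n = ns, k = ks)
  seeds <- matrix(derive_seeds(seed, nrow(cells) * reps), nrow = nrow(cells))
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]
    k <- cells$k[ci]
    per_method <- stats::setNames(
      lapply(methods, function(m) list(primary = numeric(0), other = numeric(0))),
      methods)
    for (r in seq_len(reps)) {
      sim <- simulate_random_network(n = n, k = k, D = D,
                                     link_prob = link_prob,
                                     n_samples = n_samples,
                                     seed = seeds[ci, r])
      if (nrow(sim$truth) == 0L ||
          nrow(dplyr::distinct(sim$truth, .data$source, .data$target)) ==
            n * (n - 1)) {
        # no primary or no non-primary pairs: redraw deterministically
        retry <- 1L
        while (nrow(sim$truth) == 0L ||
               nrow(dplyr::distinct(sim$truth, .data$source, .data$target)) ==
                 n * (n - 1)) {
          sim <- simulate_random_network(n = n, k = k, D = D,
                                         link_prob = link_prob,
                                         n_samples = n_samples,
                                         seed = (seeds[ci, r] + retry) %%
                                           .Machine$integer.max)
          retry <- retry + 1L
        }
      }
      for (m in methods) {
        net <- build_network(sim$record, method = m, L = L,
                             tau_max = tau_max, tolerance = tolerance)
        ds <- delta_strength(sim, net)
        per_method[[m]]$primary <- c(per_method[[m]]$primary, ds$mean_primary)
        per_method[[m]]$other <- c(per_method[[m]]$other, ds$mean_other)
      }
    }
    for (m in methods) {
      pm <- per_method[[m]]
      deltas <- pm$primary - pm$other
      out[[length(out) + 1L]] <- tibble::tibble(
        n = n, k = k, method = m,
        mww_p = mww_compare(pm$primary, pm$other),
        mean_delta = mean(deltas),
        min_delta = min(deltas),
        max_delta = max(deltas),
        reps = reps)
    }
  }
  dplyr::bind_rows(out)
}

#' Coefficient-vs-strength correlation ensemble
#'
#' Simulates `reps` random networks of `n` nodes for every noise amplitude in
#' `ks`, estimates them with each method, and computes the pooled Pearson
#' correlation between effective coefficient magnitude and estimated link
#' strength via [strength_coefficient_correlation()].
#'
#' @inheritParams run_benchmark
#' @param n Network size (default 6).
#' @return A tibble with one row per method: `method`, `estimate`, `p.value`,
#'   `n_pairs`.
#' @export
coefficient_correlation_ensemble <- function(n = 6,
                                             ks = c(0.01, 0.1, 1, 10, 100),
                                             reps = 10,
                                             methods = c("mtds", "ctds"),
                                             seed, L = 20, tau_max = NULL,
                                             tolerance = 2, n_samples = 100) {
  seeds <- derive_seeds(seed, length(ks) * reps)
  sims <- list()
  i <- 0L
  for (k in ks) {
    for (r in seq_len(reps)) {
      i <- i + 1L
      sims[[i]] <- simulate_random_network(n = n, k = k, seed = seeds[i],
                                           n_samples = n_samples)
    }
  }
  out <- lapply(methods, function(m) {
    nets <- lapply(sims, function(s)
      build_network(s$record, method = m, L = L, tau_max = tau_max,
                    tolerance = tolerance))
    res <- strength_coefficient_correlation(sims, nets)
    tibble::tibble(method = m, estimate = res$estimate,
                   p.value = res$p.value, n_pairs = res$n_pairs)
  })
  dplyr::bind_rows(out)
}

#' Fixed-network recovery summary over seeds
#'
#' Simulates the five-node benchmark system for each seed, estimates it with
#' the requested method, and reports the mean strength over the 7 true
#' directed links and whether every true link is stronger than every absent
#' ordered pair (full rank separation).
#'
#' @param seeds Integer vector of simulation seeds.
#' @param method Estimator (default `"ctds"`).
#' @inheritParams build_network
#' @inheritParams simulate_fixed_network
#' @return A tibble with one row per seed: `seed`, `mean_true_strength`,
#'   `min_true`, `max_absent`, `separated` (logical).
#' @export
fixed_network_recovery <- function(seeds, method = "ctds", L = 20,
                                   tau_max = NULL, tolerance = 2,
                                   noise_sd = 1) {
  out <- lapply(seeds, function(s) {
    sim <- simulate_fixed_network(seed = s, noise_sd = noise_sd)
    net <- build_network(sim$record, method = method, L = L,
                         tau_max = tau_max, tolerance = tolerance)
    n <- length(net$nodes)
    primary <- matrix(FALSE, n, n)
    primary[cbind(sim$truth$source, sim$truth$target)] <- TRUE
    offdiag <- row(primary) != col(primary)
    st <- net$strength[primary]
    sa <- net$strength[!primary & offdiag]
    tibble::tibble(seed = s,
                   mean_true_strength = mean(st, na.rm = TRUE),
                   min_true = min(st, na.rm = TRUE),
                   max_absent = max(sa, na.rm = TRUE),
                   separated = min(st, na.rm = TRUE) > max(sa, na.rm = TRUE))
  })
  dplyr::bind_rows(out)
}
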