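# Shared fixtures and independent mini-oracles used across the suite.

# Random multichannel record, seeded.
make_record <- function(seed, n_ch = 3, n_samples = 100) {
  set.seed(seed)
  mc_record(matrix(rnorm(n_ch * n_samples), n_samples, n_ch,
                   dimnames = list(NULL, paste0("c", seq_len(n_ch)))))
}

# Brute-force lagged Pearson correlation on the overlap (independent of the
# package's vectorised path).
bf_lag_cor <- function(x, y, tau) {
  L <- length(x)
  if (tau >= 0) {
    stats::cor(x[seq_len(L - tau)], y[seq_len(L - tau) + tau])
  } else {
    stats::cor(x[seq_len(L + tau) - tau], y[seq_len(L + tau)])
  }
}

# Literal first-order partial-correlation identity.
bf_partial1 <- function(rxy, rxz, rzy) {
  (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
}

# Two-sided rank-sum p-value by enumeration over index subsets of the pooled
# raw values, with the U statistic computed from pairwise comparisons
# (independent of the package's midrank route).
bf_mww_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  splits <- utils::combn(n, na)
  u_all <- apply(splits, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Minimal network object for group-statistics tests.
fake_network <- function(strength, nodes = NULL) {
  n <- nrow(strength)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  dimnames(strength) <- list(nodes, nodes)
  structure(list(method = "ctds", nodes = nodes, strength = strength,
                 delay = matrix(NA_integer_, n, n,
                                dimnames = dimnames(strength)),
                 n_stable = matrix(0L, n, n),
                 n_usable = matrix(5L, n, n),
                 n_near_singular = 0L,
                 params = list(L = 20L, tau_max = 10L, tolerance = 2,
                               align_range = 5L, control_scope = "global",
                               marking = "window", fs = 1,
                               n_segments = 9L, n_segments_scanned = 7L)),
            class = "ctds_network")
}
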