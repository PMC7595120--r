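# Surrogate-based significance thresholding, group statistics and
# consensus-network construction.

#' Mann–Whitney–Wilcoxon rank-sum comparison
#'
#' Two-sided rank-sum test. For combined sample sizes up to `exact_max`
#' (default 12) the p-value is computed by exact enumeration over all
#' `choose(n_a + n_b, n_a)` splits of the pooled midranks (so ties are handled
#' exactly); larger samples use the normal approximation with tie correction
#' via [stats::wilcox.test()].
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest combined size for the exact branch.
#' @return The two-sided p-value.
#' @examples
#' mww_compare(1:7, 8:20)
#' @export
mww_compare <- function(a, b, exact_max = 12) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_ctds("empty_sample", "Both samples must be non-empty.")
  }
  na <- length(a)
  nb <- length(b)
  if (na + nb <= exact_max) {
    r <- rank(c(a, b))
    u_obs <- sum(r[seq_len(na)])
    splits <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[splits], nrow = na))
    p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
    return(min(1, p))
  }
  suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  )
}

#' Jarque–Bera normality check
#'
#' Tests departure from normality through sample skewness and excess
#' kurtosis: `JB = n/6 * (S^2 + (K - 3)^2 / 4)`, referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x Numeric sample of at least 8 observations.
#' @return A one-row tibble with `statistic`, `p.value`, `skewness`,
#'   `kurtosis`, `n`.
#' @examples
#' normality_check(rnorm(5000))
#' @export
normality_check <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop_ctds("sample_too_small", "Need at least 8 observations.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop_ctds("degenerate_variance", "Sample has zero variance.")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  tibble::tibble(statistic = jb,
                 p.value = stats::pchisq(jb, df = 2, lower.tail = FALSE),
                 skewness = s, kurtosis = k, n = n)
}

#' Delta strength: primary minus non-primary link strength
#'
#' Difference, in percentage points, between the average estimated strength
#' of the true (primary) directed links of a simulation and the average
#' strength over all remaining ordered pairs (indirect or absent links).
#'
#' @param sim A `ctds_sim` (or a truth tibble with `source`/`target` columns,
#'   matching the network's node labels or 1-based indices).
#' @param network A `ctds_network` on the same nodes.
#' @return A one-row tibble: `delta`, `mean_primary`, `mean_other`,
#'   `n_primary`, `n_other`.
#' @export
delta_strength <- function(sim, network) {
  truth <- if (inherits(sim, "ctds_sim")) sim$truth else tibble::as_tibble(sim)
  if (nrow(truth) == 0L) stop_ctds("no_primary_links", "Truth has no links.")
  nodes <- network$nodes
  src <- if (is.character(truth$source)) match(truth$source, nodes) else truth$source
  tgt <- if (is.character(truth$target)) match(truth$target, nodes) else truth$target
  if (any(is.na(src)) || any(is.na(tgt))) {
    stop_ctds("node_set_mismatch", "Truth links name unknown nodes.")
  }
  n <- length(nodes)
  primary <- matrix(FALSE, n, n)
  primary[cbind(src, tgt)] <- TRUE
  offdiag <- row(primary) != col(primary)
  sp <- network$strength[primary & offdiag]
  so <- network$strength[!primary & offdiag]
  if (length(sp) == 0L) stop_ctds("no_primary_links", "Truth has no links.")
  tibble::tibble(
    delta = mean(sp, na.rm = TRUE) - mean(so, na.rm = TRUE),
    mean_primary = mean(sp, na.rm = TRUE),
    mean_other = mean(so, na.rm = TRUE),
    n_primary = length(sp),
    n_other = length(so)
  )
}

#' Pooled correlation between simulated coefficients and estimated strength
#'
#' Over an ensemble of simulations with known ground truth, correlates the
#' effective coefficient magnitude of every directed pair — `|W| * exp(-0.1 d)`
#' maximised over lags, 0 for absent links — with the strength estimated for
#' that pair, pooling all pairs of all ensemble members, and returns the
#' Pearson correlation with its test.
#'
#' @param sims List of `ctds_sim` objects.
#' @param networks List of matching `ctds_network` objects.
#' @return A one-row tibble: `estimate` (Pearson rho), `p.value`, `n_pairs`.
#' @export
strength_coefficient_correlation <- function(sims, networks) {
  stopifnot(length(sims) == length(networks))
  coefs <- numeric(0)
  strengths <- numeric(0)
  for (i in seq_along(sims)) {
    sim <- sims[[i]]
    net <- networks[[i]]
    n <- length(net$nodes)
    eff <- matrix(0, n, n)
    tr <- sim$truth
    if (nrow(tr) > 0L) {
      src <- if (is.character(tr$source)) match(tr$source, net$nodes) else tr$source
      tgt <- if (is.character(tr$target)) match(tr$target, net$nodes) else tr$target
      for (r in seq_len(nrow(tr))) {
        eff[src[r], tgt[r]] <- max(eff[src[r], tgt[r]], tr$effective[r])
      }
    }
    offdiag <- row(eff) != col(eff)
    coefs <- c(coefs, eff[offdiag])
    strengths <- c(strengths, net$strength[offdiag])
  }
  ok <- is.finite(coefs) & is.finite(strengths)
  if (sum(ok) < 3L) stop_ctds("bad_input", "Need at least 3 pairs.")
  if (sd(coefs[ok]) == 0 || sd(strengths[ok]) == 0) {
    stop_ctds("degenerate_variance", "Zero variance in coefficients or strengths.")
  }
  ct <- stats::cor.test(coefs[ok], strengths[ok], method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p.value = ct$p.value,
                 n_pairs = sum(ok))
}

#' Build surrogate networks by cross-subject channel pairing
#'
#' Destroys within-subject coupling while preserving each channel's dynamics:
#' for every surrogate, each channel is taken from a different subject
#' (random distinct circular offsets across the unit indices, so any two
#' channels of a surrogate record come from different units), and a network
#' is estimated from the chimeric record. Requires at least as many units as
#' channels.
#'
#' @param records List of [mc_record()]s sharing labels and lengths (one per
#'   unit/subject).
#' @param n_surrogates Number of surrogate networks (default 100).
#' @param seed Integer seed.
#' @inheritParams build_network
#' @return List of `ctds_network` objects of length `n_surrogates`.
#' @export
surrogate_networks <- function(records, n_surrogates = 100, seed,
                               method = "ctds", L = 20, tau_max = NULL,
                               tolerance = 2) {
  U <- length(records)
  if (U < 2L) stop_ctds("insufficient_units", "Need at least 2 units.")
  labels <- records[[1L]]$labels
  n_ch <- length(labels)
  if (!all(vapply(records, function(r) identical(r$labels, labels), logical(1)))) {
    stop_ctds("node_set_mismatch", "All unit records must share channel labels.")
  }
  if (U < n_ch) {
    stop_ctds("insufficient_units", sprintf(
      "Surrogate pairing needs >= %d units for %d channels.", n_ch, n_ch))
  }
  set.seed(as.integer(seed))
  lapply(seq_len(n_surrogates), function(s) {
    base <- sample.int(U, 1L)
    offsets <- sample.int(U, n_ch) - 1L # distinct offsets 0..U-1
    data <- vapply(seq_len(n_ch), function(c) {
      u <- ((base - 1L + offsets[c]) %% U) + 1L
      records[[u]]$data[, c]
    }, numeric(nrow(records[[1L]]$data)))
    colnames(data) <- labels
    build_network(mc_record(data, fs = records[[1L]]$fs), method = method,
                  L = L, tau_max = tau_max, tolerance = tolerance)
  })
}

#' Surrogate significance test and threshold selection
#'
#' Per directed link, compares the strengths observed across real units with
#' the strengths of cross-unit surrogate networks by a one-sided Welch t-test
#' (real stronger than surrogate; links are declared significant at
#' `p < alpha`). A strength cutoff is then scanned on an integer-percent grid:
#' the chosen threshold is the smallest grid value such that at every cutoff
#' at or above it, all links still occurring (mean real strength across
#' units above the cutoff) are significant. If no cutoff qualifies, the
#' threshold is reported absent (`NA`).
#'
#' @param real_networks List of `ctds_network`s, one per unit.
#' @param surrogate_nets List of `ctds_network`s from [surrogate_networks()].
#' @param alpha Significance level for the per-link t-test (default `1e-3`).
#' @param grid Candidate strength cutoffs in percent (default `1:99`).
#' @return A `ctds_surrogate` object: list with `links` (per-link tibble:
#'   `source`, `target`, `p.value`, `significant`, mean real/surrogate
#'   strengths), `scan` (per-cutoff tibble: `threshold`, `n_occurring`,
#'   `frac_significant`), `threshold` (chosen cutoff or `NA`), `alpha`.
#' @export
surrogate_test <- function(real_networks, surrogate_nets, alpha = 1e-3,
                           grid = 1:99) {
  if (length(real_networks) < 2L) {
    stop_ctds("insufficient_units", "Need at least 2 real units.")
  }
  nodes <- real_networks[[1L]]$nodes
  same <- vapply(c(real_networks, surrogate_nets),
                 function(nw) identical(nw$nodes, nodes), logical(1))
  if (!all(same)) {
    stop_ctds("node_set_mismatch", "All networks must share the node set.")
  }
  n <- length(nodes)
  idx <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
  real_mat <- vapply(real_networks, function(nw) nw$strength[idx],
                     numeric(nrow(idx)))
  surr_mat <- vapply(surrogate_nets, function(nw) nw$strength[idx],
                     numeric(nrow(idx)))
  pvals <- vapply(seq_len(nrow(idx)), function(r) {
    a <- real_mat[r, ]
    b <- surr_mat[r, ]
    a <- a[is.finite(a)]
    b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    tryCatch(stats::t.test(a, b, alternative = "greater")$p.value,
             error = function(e) 1)
  }, numeric(1))
  links <- tibble::tibble(
    source = nodes[idx[, 1L]],
    target = nodes[idx[, 2L]],
    p.value = pvals,
    significant = !is.na(pvals) & pvals < alpha,
    mean_real = rowMeans(real_mat, na.rm = TRUE),
    mean_surrogate = rowMeans(surr_mat, na.rm = TRUE)
  )
  mean_real_link <- rowMeans(real_mat, na.rm = TRUE)
  scan <- lapply(grid, function(cut) {
    occurring <- is.finite(mean_real_link) & mean_real_link > cut
    tibble::tibble(threshold = cut, n_occurring = sum(occurring),
                   frac_significant = if (any(occurring))
                     mean(links$significant[occurring]) else NA_real_)
  })
  scan <- dplyr::bind_rows(scan)
  all_sig_from <- vapply(seq_along(grid), function(i) {
    f <- scan$frac_significant[seq.int(i, nrow(scan))]
    all(is.na(f) | f == 1) && any(!is.na(f))
  }, logical(1))
  chosen <- if (any(all_sig_from)) grid[which(all_sig_from)[1L]] else NA_integer_
  structure(list(links = links, scan = scan, threshold = chosen,
                 alpha = alpha, n_units = length(real_networks),
                 n_surrogates = length(surrogate_nets)),
            class = "ctds_surrogate")
}

#' @export
print.ctds_surrogate <- function(x, ...) {
  cat(sprintf(
    "<ctds_surrogate> %d units vs %d surrogates, alpha=%g; %d/%d links significant; threshold=%s%%\n",
    x$n_units, x$n_surrogates, x$alpha, sum(x$links$significant),
    nrow(x$links), ifelse(is.na(x$threshold), "absent", x$threshold)))
  invisible(x)
}

#' @describeIn surrogate_test Per-link tibble of the surrogate comparison.
#' @param x A `ctds_surrogate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ctds_surrogate <- function(x, ...) x$links

#' @describeIn surrogate_test One-row summary with the chosen threshold.
#' @exportS3Method generics::glance
glance.ctds_surrogate <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, alpha = x$alpha,
                 n_units = x$n_units, n_surrogates = x$n_surrogates,
                 n_links = nrow(x$links),
                 n_significant = sum(x$links$significant))
}

#' Consensus network across units
#'
#' Keeps a directed edge iff its strength exceeds `threshold` in that
#' direction for more than `min_fraction` of the units (strict inequality by
#' default, matching the "more than 40% of cases" rule; set
#' `strict = FALSE` for the inclusive variant).
#'
#' @param networks List of `ctds_network`s sharing the node set.
#' @param threshold Strength cutoff in percent.
#' @param min_fraction Minimal fraction of units carrying the link (default
#'   0.4).
#' @param strict Use strict inequality on the fraction (default `TRUE`).
#' @return A `ctds_consensus` object: `fraction` and `mean_strength`
#'   node-by-node matrices, `edges` tibble (`source`, `target`, `fraction`,
#'   `mean_strength`), and the rule parameters.
#' @export
consensus_network <- function(networks, threshold, min_fraction = 0.4,
                              strict = TRUE) {
  if (length(networks) < 1L) stop_ctds("insufficient_units", "No networks given.")
  nodes <- networks[[1L]]$nodes
  if (!all(vapply(networks, function(nw) identical(nw$nodes, nodes), logical(1)))) {
    stop_ctds("node_set_mismatch", "All networks must share the node set.")
  }
  n <- length(nodes)
  above <- Reduce(`+`, lapply(networks, function(nw) {
    m <- nw$strength > threshold
    m[!is.finite(nw$strength)] <- FALSE
    m + 0
  }))
  fraction <- above / length(networks)
  mean_strength <- Reduce(`+`, lapply(networks, function(nw) {
    s <- nw$strength
    s[!is.finite(s)] <- 0
    s
  })) / length(networks)
  dimnames(fraction) <- dimnames(mean_strength) <- list(nodes, nodes)
  keep <- if (strict) fraction > min_fraction else fraction >= min_fraction
  diag(keep) <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    source = nodes[idx[, 1L]],
    target = nodes[idx[, 2L]],
    fraction = fraction[idx],
    mean_strength = mean_strength[idx]
  ) |> dplyr::arrange(.data$source, .data$target)
  structure(list(nodes = nodes, fraction = fraction,
                 mean_strength = mean_strength, edges = edges,
                 threshold = threshold, min_fraction = min_fraction,
                 strict = strict, n_units = length(networks)),
            class = "ctds_consensus")
}

#' @export
print.ctds_consensus <- function(x, ...) {
  cat(sprintf(
    "<ctds_consensus> %d units, threshold %g%%, fraction %s %g: %d edges\n",
    x$n_units, x$threshold, ifelse(x$strict, ">", ">="), x$min_fraction,
    nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' @describeIn consensus_network Edge tibble of the consensus graph.
#' @param x A `ctds_consensus`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ctds_consensus <- function(x, ...) x$edges

#' @describeIn consensus_network Consensus-fraction matrix plot.
#' @param object A `ctds_consensus`.
#' @exportS3Method ggplot2::autoplot
autoplot.ctds_consensus <- function(object, ...) {
  df <- expand.grid(source = object$nodes, target = object$nodes,
                    stringsAsFactors = FALSE)
  df$fraction <- as.vector(object$fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = 100 * .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "units with link (%)") +
    ggplot2::scale_y_discrete(limits = rev(object$nodes)) +
    ggplot2::scale_x_discrete(limits = object$nodes) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
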