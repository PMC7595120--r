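# Segment-wise lagged (partial) cross-correlation.
#
# The windowed cross-correlation of two series at delay tau is the Pearson
# correlation between the source window and the tau-shifted target window
# (each window normalised to mean 0, population sd 1, so the 1/L inner
# product of the normalised windows IS the correlation). When estimators run
# over a full record the shifted window is drawn from the full series, so
# there is no truncation and no attenuation at large delays; the
# segment-level functions below, which only see two equal-length windows,
# use the same estimator restricted to the overlapping samples
# (renormalised on the overlap).

EPS_SINGULAR <- 1e-6 # |rho| this close to 1 in a denominator => near-singular
EPS_CLIP <- 1e-9     # floating-point overshoot beyond 1 tolerated and clipped

# Lagged Pearson correlation of two equal-length segments: the overlapping
# parts are re-centred and re-scaled, so |rho| <= 1 at every lag. Lags are
# clamped to |s| <= L/2 so at least half the window supports the estimate.
seg_corr <- function(a, b, s) {
  L <- length(a)
  s <- max(min(s, L %/% 2L), -(L %/% 2L))
  if (s >= 0) {
    av <- a[seq_len(L - s)]
    bv <- b[seq_len(L - s) + s]
  } else {
    av <- a[seq_len(L + s) - s]
    bv <- b[seq_len(L + s)]
  }
  if (stats::sd(av) < 1e-12 || stats::sd(bv) < 1e-12) return(NA_real_)
  stats::cor(av, bv)
}

# Alignment lag of a control z relative to the source x: the delay in
# [-range, range] maximising |rho_xz| (ties: smallest |lag|, positive first).
# Aligning each control at its own coupling lag is what lets the
# partialisation cancel lag-mediated indirect paths (a chain x -> z -> y has
# rho_xy(tau) ~ rho_xz(a) * rho_zy(tau - a) at the chain lags); with all
# alignment lags forced to 0 the estimator reduces to the plain textbook
# partial correlation.
align_shift <- function(x, z, range) {
  lags <- seq.int(-range, range)
  vals <- vapply(lags, function(s) seg_corr(x, z, s), numeric(1))
  cand <- which(abs(vals) == max(abs(vals)))
  cand <- cand[order(abs(lags[cand]), -lags[cand])]
  lags[cand[1L]]
}

# Core recursion on correlation moments.
#
# M:    (1 + N) x (1 + N) correlation matrix among (x, z_1, ..., z_N), each
#       control taken at its alignment lag.
# Ycol: (1 + N) x K matrix; Ycol[a, t] = lagged correlation of variable a with
#       y at the t-th delay (minus the variable's alignment lag).
# Controls are removed one at a time (ascending, i.e. column 2 first). At each
# step the remaining entries are residualised on the removed control via the
# first-order partial-correlation identity; the last surviving row of Ycol is
# the Nth-order partial cross-correlation curve of (x, y).
#
# Returns list(rho = numeric(K), excluded = logical(1)). A pair-segment is
# excluded when any denominator correlation reaches 1 - EPS_SINGULAR in
# magnitude (near-singular controls: catastrophic cancellation), or when the
# final curve overshoots |rho| = 1 by more than EPS_CLIP.
partial_from_moments <- function(M, Ycol) {
  n_ctrl <- nrow(M) - 1L
  K <- ncol(Ycol)
  if (n_ctrl > 0L) {
    for (k in seq_len(n_ctrl)) {
      u <- M[, 2L]          # lag-0 correlations with the control being removed
      yz <- Ycol[2L, ]      # lagged correlations of that control with y
      keep <- setdiff(seq_len(nrow(M)), 2L)
      if (any(abs(u[keep]) >= 1 - EPS_SINGULAR) ||
          any(abs(yz) >= 1 - EPS_SINGULAR)) {
        return(list(rho = rep(NA_real_, K), excluded = TRUE))
      }
      su <- sqrt(1 - u[keep]^2)
      sy <- sqrt(1 - yz^2)
      Ycol <- (Ycol[keep, , drop = FALSE] - outer(u[keep], yz)) / outer(su, sy)
      M <- (M[keep, keep, drop = FALSE] - tcrossprod(u[keep])) /
        tcrossprod(su)
      diag(M) <- 1
    }
  }
  rho <- Ycol[1L, ]
  over <- abs(rho) > 1
  if (any(abs(rho) > 1 + EPS_CLIP, na.rm = TRUE)) {
    return(list(rho = rep(NA_real_, K), excluded = TRUE))
  }
  rho[over] <- sign(rho[over])
  list(rho = rho, excluded = FALSE)
}

# Build the moment inputs for one (x, y, controls) pair-segment and run the
# recursion. x, y are normalised length-L segments; Z an L x N matrix of
# normalised control segments (or NULL). shifts holds one alignment lag per
# control (z enters as z(t + shift)); NULL means align automatically over
# [-align_range, align_range]. taus may include negative delays (used by the
# original, undirected estimator with an empty control set).
partial_xcorr_curve <- function(x, y, Z, taus, shifts = NULL,
                                align_range = NULL) {
  L <- length(x)
  if (is.null(Z) || ncol(as.matrix(Z)) == 0L) {
    rho <- vapply(taus, function(t) seg_corr(x, y, t), numeric(1))
    return(partial_from_moments(matrix(1, 1L, 1L),
                                matrix(rho, nrow = 1L)))
  }
  Z <- as.matrix(Z)
  N <- ncol(Z)
  if (is.null(align_range)) align_range <- L %/% 4L
  if (is.null(shifts)) {
    shifts <- vapply(seq_len(N), function(j) align_shift(x, Z[, j], align_range),
                     numeric(1))
  }
  sh <- c(0, shifts)
  V <- cbind(x, Z)
  m <- ncol(V)
  M <- diag(1, m)
  for (i in seq_len(m - 1L)) {
    for (j in seq.int(i + 1L, m)) {
      M[i, j] <- M[j, i] <- seg_corr(V[, i], V[, j], sh[j] - sh[i])
    }
  }
  Ycol <- vapply(taus, function(t)
    vapply(seq_len(m), function(i) seg_corr(V[, i], y, t - sh[i]), numeric(1)),
    numeric(m))
  Ycol <- matrix(Ycol, nrow = m)
  partial_from_moments(M, Ycol)
}

#' Windowed cross-correlation curve of two segments
#'
#' Computes the lagged Pearson correlation `rho(tau)` of two equal-length
#' segments for all integer delays `tau` from 0 (or `-tau_max`, see
#' `include_negative`) to `tau_max`: the overlapping parts of the two windows
#' are re-centred, re-scaled and correlated, so `|rho| <= 1` at every lag and
#' `rho(0)` of a segment with itself is exactly 1. (Estimators running over a
#' full record instead shift the target window through the full series, so no
#' overlap restriction applies there.)
#'
#' @param x_seg,y_seg Numeric vectors of equal length.
#' @param tau_max Largest delay scanned, in samples; at most `L/2` for
#'   segment-level curves.
#' @param include_negative If `TRUE`, negative delays (`y` leading `x`) are
#'   scanned as well, as in the original undirected estimator.
#' @return A tibble with columns `tau` and `rho` and attribute `order = 0`.
#' @examples
#' x <- rnorm(100)
#' cross_correlation(x, x, tau_max = 5)
#' @export
cross_correlation <- function(x_seg, y_seg, tau_max, include_negative = FALSE) {
  L <- length(x_seg)
  if (length(y_seg) != L) {
    stop_ctds("bad_input", "Segments must have equal length.")
  }
  if (tau_max < 0 || tau_max > L / 2) {
    stop_ctds("tau_range", sprintf(
      "`tau_max` = %s outside [0, L/2] = [0, %s].", tau_max, L / 2))
  }
  taus <- if (include_negative) seq.int(-tau_max, tau_max) else seq.int(0, tau_max)
  res <- partial_xcorr_curve(x_seg, y_seg, NULL, taus)
  structure(tibble::tibble(tau = taus, rho = res$rho), order = 0L)
}

#' Nth-order partial cross-correlation
#'
#' Lagged correlation of two segments while controlling for `N` other
#' channels, computed by the recursive first-order identity: at each step the
#' next control `z` is removed via
#' `(rho_xy - rho_xz * rho_zy) / sqrt((1 - rho_xz^2) * (1 - rho_zy^2))`,
#' where correlations involving `y` are taken at delay `tau` and all others at
#' delay 0. With an empty control set this reduces to [cross_correlation()].
#' Controls are removed in column order (callers pass them in ascending
#' channel order); the result is invariant to that order up to floating-point
#' error on non-degenerate input.
#'
#' Each control enters at an alignment lag: by default the delay in
#' `[-align_range, align_range]` that maximises its absolute correlation with
#' `x_seg`, so that lag-mediated indirect paths through the control are
#' cancelled; the correlation of the control with `y_seg` then carries
#' `tau` minus that alignment lag. Passing `control_shifts = 0` for every
#' control recovers the plain textbook convention in which all control
#' correlations are taken at lag 0.
#'
#' If any intermediate correlation used in a denominator reaches magnitude
#' `1 - 1e-6` (near-singular control), the segment is flagged excluded and all
#' values are `NA`: such segments are dropped from delay searches.
#'
#' @inheritParams cross_correlation
#' @param controls `NULL`, or a numeric matrix with one column per normalised
#'   control segment (same length as `x_seg`).
#' @param taus Integer vector of delays to evaluate (non-negative for the
#'   directional estimators).
#' @param control_shifts Integer vector of alignment lags, one per control;
#'   `NULL` (default) aligns each control at its strongest correlation with
#'   `x_seg`.
#' @param align_range Scan range for automatic alignment; defaults to `L/4`.
#' @return A tibble with columns `tau` and `rho`, attribute
#'   `order = ncol(controls)`, attribute `excluded`, and attribute `shifts`
#'   (the alignment lags used).
#' @export
partial_cross_correlation <- function(x_seg, y_seg, controls = NULL,
                                      taus = 0L, control_shifts = NULL,
                                      align_range = NULL) {
  L <- length(x_seg)
  if (length(y_seg) != L) {
    stop_ctds("bad_input", "Segments must have equal length.")
  }
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (nrow(controls) != L) {
      stop_ctds("bad_input", "Control segments must have the pair's length.")
    }
    if (is.null(align_range)) align_range <- L %/% 4L
    if (is.null(control_shifts)) {
      control_shifts <- vapply(seq_len(ncol(controls)), function(j)
        align_shift(x_seg, controls[, j], align_range), numeric(1))
    } else if (length(control_shifts) == 1L) {
      control_shifts <- rep(control_shifts, ncol(controls))
    }
  }
  if (any(abs(taus) > L / 2)) {
    stop_ctds("tau_range", "All |tau| must be <= L/2.")
  }
  res <- partial_xcorr_curve(x_seg, y_seg, controls, as.integer(taus),
                             shifts = control_shifts)
  structure(tibble::tibble(tau = as.integer(taus), rho = res$rho),
            order = if (is.null(controls)) 0L else ncol(controls),
            excluded = res$excluded,
            shifts = control_shifts)
}

#' Regression-residual partial correlation (reference implementation)
#'
#' Computes the same quantity as [partial_cross_correlation()] through the
#' regression route: both the `x` segment and the `tau`-shifted `y` segment
#' are projected on the control segments by ordinary least squares (normal
#' equations on the lag-aligned correlation moments), and the correlation of
#' the two residual series is returned. At `tau = 0` this is literally the
#' correlation of `lm()` residuals. It exists as an independent cross-check of
#' the recursion and is used as a test oracle, not by the estimators.
#'
#' @inheritParams partial_cross_correlation
#' @param tau Single integer delay.
#' @return A single correlation value.
#' @export
residual_partial_correlation <- function(x_seg, y_seg, controls = NULL,
                                         tau = 0L, control_shifts = NULL,
                                         align_range = NULL) {
  L <- length(x_seg)
  if (is.null(controls) || ncol(as.matrix(controls)) == 0L) {
    return(seg_corr(x_seg, y_seg, tau))
  }
  Z <- as.matrix(controls)
  N <- ncol(Z)
  if (is.null(align_range)) align_range <- L %/% 4L
  if (is.null(control_shifts)) {
    control_shifts <- vapply(seq_len(N), function(j)
      align_shift(x_seg, Z[, j], align_range), numeric(1))
  } else if (length(control_shifts) == 1L) {
    control_shifts <- rep(control_shifts, N)
  }
  Czz <- diag(1, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (i != j) {
        Czz[i, j] <- seg_corr(Z[, i], Z[, j],
                              control_shifts[j] - control_shifts[i])
      }
    }
  }
  if (rcond(Czz) < 1e-12) {
    stop_ctds("rank_deficient", "Control segments are collinear.")
  }
  czx <- vapply(seq_len(N), function(j)
    seg_corr(x_seg, Z[, j], control_shifts[j]), numeric(1))
  czy <- vapply(seq_len(N), function(j)
    seg_corr(Z[, j], y_seg, tau - control_shifts[j]), numeric(1))
  cxy <- seg_corr(x_seg, y_seg, tau)
  bx <- solve(Czz, czx)
  by <- solve(Czz, czy)
  num <- cxy - sum(czx * by)
  vx <- 1 - sum(czx * bx)
  vy <- 1 - sum(czy * by)
  num / sqrt(vx * vy)
}
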