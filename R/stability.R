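# Delay optimisation per segment, the 4-of-5 stability rule, link strength,
# and assembly of full coupling networks.
#
# Estimator variants:
#   tds  - original undirected estimator: plain lagged cross-correlation, the
#          delay scan covers [-tau_max, tau_max]; one profile per unordered
#          pair, the strength matrix is symmetric.
#   mtds - directional variant: plain cross-correlation, delays restricted to
#          [1, tau_max] (strictly positive), each ordering of the pair
#          scanned separately.
#   ctds - controlled variant: Nth-order partial cross-correlation with all
#          remaining channels as controls, delays in [1, tau_max].
#
# All windowed correlations are Pearson correlations between the source
# window and the shifted target window drawn from the full series (both
# normalised), so delays are not limited by the window length and carry no
# attenuation bias. Windows whose shifted counterparts would run outside the
# series are dropped from the delay search.

CTDS_METHODS <- c("ctds", "mtds", "tds")

# Shifted-window correlation structure. For every usable window start s
# (those keeping all shifts in [shift_lo, shift_hi] inside the series), the
# normalised windows of every channel at every shift are assembled and the
# full correlation matrix across (channel, shift) columns computed, so any
# lagged correlation between any two channels is one lookup.
shifted_corr <- function(record, L, shift_lo, shift_hi) {
  n_samples <- nrow(record$data)
  n_ch <- ncol(record$data)
  spec <- segment_spec(L, n_samples)
  usable <- which(spec$starts + shift_lo >= 0 &
                    spec$starts + shift_hi + L <= n_samples)
  shifts <- seq.int(shift_lo, shift_hi)
  n_sh <- length(shifts)
  n_seg <- length(usable)
  n_cols <- n_ch * n_sh
  starts <- spec$starts[usable]
  Wbig <- array(NA_real_, dim = c(L, n_seg, n_cols))
  degen <- matrix(FALSE, n_seg, n_cols)
  for (ch in seq_len(n_ch)) {
    xc <- record$data[, ch]
    for (k in seq_len(n_sh)) {
      col <- (ch - 1L) * n_sh + k
      idx <- outer(seq_len(L), starts + shifts[k], "+")
      Wm <- matrix(xc[idx], L)
      mu <- colMeans(Wm)
      Wm <- Wm - rep(mu, each = L)
      sdv <- sqrt(colMeans(Wm^2))
      bad <- sdv < 1e-12
      sdv[bad] <- NA_real_
      degen[, col] <- bad
      Wbig[, , col] <- Wm / rep(sdv, each = L)
    }
  }
  C <- lapply(seq_len(n_seg), function(v)
    crossprod(matrix(Wbig[, v, ], nrow = L)) / L)
  list(C = C, degen = degen, shifts = shifts, n_sh = n_sh,
       shift_lo = shift_lo, usable = usable, spec = spec, n_ch = n_ch)
}

# Column index of (channel, shift) in a shifted_corr structure.
cidx <- function(cm, ch, s) (ch - 1L) * cm$n_sh + (s - cm$shift_lo + 1L)

# Deterministic argmax of |rho|: ties broken by smallest |tau|, then by
# positive sign (zero/positive delay carries the directional reading).
pick_tau0 <- function(taus, rho) {
  ok <- !is.na(rho)
  if (!any(ok)) return(list(tau0 = NA_integer_, rho0 = NA_real_))
  mx <- max(abs(rho[ok]))
  cand <- which(ok & abs(rho) == mx)
  cand <- cand[order(abs(taus[cand]), -taus[cand])]
  list(tau0 = taus[cand[1L]], rho0 = rho[cand[1L]])
}

# Most frequent delay; ties -> smallest |tau|, then positive.
modal_delay <- function(vals) {
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_integer_)
  tab <- table(vals)
  best <- as.integer(names(tab)[tab == max(tab)])
  best[order(abs(best), -best)][1L]
}

# Global (whole-series) lagged Pearson correlations used to fix each
# control's alignment lag: galign[[x]][z] is the lag in
# [-align_range, align_range] at which |cor(x(t), z(t+lag))| over the full
# series is largest. Estimating the alignment globally keeps the
# partialisation consistent across segments.
global_alignment <- function(record, align_range) {
  X <- record$data
  n_samples <- nrow(X)
  n <- ncol(X)
  lags <- seq.int(-align_range, align_range)
  out <- matrix(0L, n, n)
  cmat <- array(NA_real_, dim = c(n, n, length(lags)))
  for (k in seq_along(lags)) {
    s <- lags[k]
    if (s >= 0) {
      a <- X[seq_len(n_samples - s), , drop = FALSE]
      b <- X[seq_len(n_samples - s) + s, , drop = FALSE]
    } else {
      a <- X[seq_len(n_samples + s) - s, , drop = FALSE]
      b <- X[seq_len(n_samples + s), , drop = FALSE]
    }
    cmat[, , k] <- suppressWarnings(stats::cor(a, b))
  }
  for (x in seq_len(n)) {
    for (z in seq_len(n)) {
      vals <- cmat[x, z, ]
      if (all(is.na(vals))) next
      cand <- which(!is.na(vals) & abs(vals) == max(abs(vals), na.rm = TRUE))
      cand <- cand[order(abs(lags[cand]), -lags[cand])]
      out[x, z] <- lags[cand[1L]]
    }
  }
  out
}

# Delay profile of one ordered pair across all usable segments.
# galign: global alignment-lag matrix (NULL = per-segment alignment).
pair_profile <- function(cm, x, y, controls, method, tau_max, align_range,
                         galign = NULL) {
  n_seg <- length(cm$C)
  taus <- if (method == "tds") seq.int(-tau_max, tau_max) else seq.int(1L, tau_max)
  tau0 <- rep(NA_integer_, n_seg)
  rho0 <- rep(NA_real_, n_seg)
  excluded <- rep(FALSE, n_seg)
  n_singular <- 0L
  x0 <- cidx(cm, x, 0L)
  ycols <- cidx(cm, y, taus)
  align_lags <- seq.int(-align_range, align_range)
  for (v in seq_len(n_seg)) {
    cv <- cm$C[[v]]
    if (method == "ctds" && length(controls) > 0L) {
      # align every control with the source at its strongest coupling lag;
      # this is what lets the partialisation cancel lag-mediated indirect
      # paths (rho_xy(tau) ~ rho_xz(a) * rho_zy(tau - a) along a chain)
      sh <- if (!is.null(galign)) {
        as.numeric(galign[x, controls])
      } else {
        vapply(controls, function(z) {
          vals <- cv[x0, cidx(cm, z, align_lags)]
          if (all(is.na(vals))) return(NA_real_)
          cand <- which(!is.na(vals) & abs(vals) == max(abs(vals), na.rm = TRUE))
          cand <- cand[order(abs(align_lags[cand]), -align_lags[cand])]
          align_lags[cand[1L]]
        }, numeric(1))
      }
      if (anyNA(sh)) {
        excluded[v] <- TRUE
        next
      }
      vc <- c(x0, cidx(cm, controls, as.integer(sh)))
      M <- cv[vc, vc, drop = FALSE]
      diag(M) <- 1
      Ycol <- cv[vc, ycols, drop = FALSE]
      if (anyNA(M) || anyNA(Ycol)) {
        excluded[v] <- TRUE
        next
      }
      res <- partial_from_moments(M, Ycol)
      if (res$excluded) {
        excluded[v] <- TRUE
        n_singular <- n_singular + 1L
        next
      }
      rho <- res$rho
    } else {
      rho <- cv[x0, ycols]
    }
    best <- pick_tau0(taus, rho)
    if (is.na(best$tau0)) {
      excluded[v] <- TRUE
      next
    }
    tau0[v] <- best$tau0
    rho0[v] <- best$rho0
  }
  list(tau0 = tau0, rho0 = rho0, excluded = excluded, n_singular = n_singular)
}

# 4-of-5 stability rule on a vector of per-segment optimal delays.
# A 5-segment sliding window qualifies when at least 4 of its non-excluded
# members have tau0 within +/- tolerance of the window's modal delay. With
# marking = "window" (default) every non-excluded member of a qualifying
# window counts as stable time (the whole period shows stable coupling);
# with "inband" only the members inside the tolerance band are marked.
mask_stable <- function(tau0, excluded, tolerance, marking = "window") {
  n <- length(tau0)
  if (sum(!excluded) < 5L) {
    stop_ctds("undefined_stability",
              "Fewer than 5 usable segments: stability undefined.")
  }
  mask <- rep(FALSE, n)
  for (w in seq_len(n - 4L)) {
    mem <- seq.int(w, w + 4L)
    ok <- !excluded[mem] & !is.na(tau0[mem])
    if (sum(ok) < 4L) next
    md <- modal_delay(tau0[mem][ok])
    inband <- ok & !is.na(tau0[mem]) & abs(tau0[mem] - md) <= tolerance
    if (sum(inband) >= 4L) {
      if (marking == "window") mask[mem[ok]] <- TRUE else mask[mem[inband]] <- TRUE
    }
  }
  mask
}

default_tau_max <- function(L) L %/% 2L

# Globally residualise one channel against a set of controls, each control
# entered at its alignment lag (galign row). Returns the residual series on
# the valid sample range together with that range.
residualize_channel <- function(X, ch, controls, lags) {
  n_samples <- nrow(X)
  lo <- 1L + max(0L, -min(lags, 0L))
  hi <- n_samples - max(0L, max(lags, 0L))
  t_idx <- seq.int(lo, hi)
  y <- X[t_idx, ch]
  Z <- vapply(seq_along(controls), function(j) X[t_idx + lags[j], controls[j]],
              numeric(length(t_idx)))
  Z <- cbind(1, matrix(Z, nrow = length(t_idx)))
  fit <- stats::.lm.fit(Z, y)
  list(resid = fit$residuals, range = c(lo, hi))
}

# Residual pair series for the controlled estimator in global scope: source
# and target are each regressed on all controls at the controls' own
# alignment lags (relative to that channel), and the two residual series are
# returned on their common sample range.
residual_pair <- function(record, x, y, controls, galign) {
  X <- record$data
  rx <- residualize_channel(X, x, controls, as.integer(galign[x, controls]))
  ry <- residualize_channel(X, y, controls, as.integer(galign[y, controls]))
  lo <- max(rx$range[1L], ry$range[1L])
  hi <- min(rx$range[2L], ry$range[2L])
  ex <- rx$resid[seq.int(lo - rx$range[1L] + 1L, hi - rx$range[1L] + 1L)]
  ey <- ry$resid[seq.int(lo - ry$range[1L] + 1L, hi - ry$range[1L] + 1L)]
  cbind(ex, ey)
}

#' Per-segment optimal delays for one channel pair
#'
#' For every usable segment, finds the delay `tau0` maximising the absolute
#' (partial) cross-correlation of the ordered pair, together with the peak
#' value. Ties are broken by smallest `|tau|`, then by positive sign. Segments
#' excluded because of zero variance or near-singular controls carry `NA`.
#'
#' @inheritParams build_network
#' @param source,target Channel labels (or indices) of the ordered pair; for
#'   `method = "tds"` the ordering only fixes the sign convention of the
#'   delay.
#' @return A tibble with one row per usable segment: `segment` (index in the
#'   record's segment grid), `tau0`, `rho0`, `excluded`, plus attributes
#'   `method` and `pair`.
#' @examples
#' sim <- simulate_fixed_network(seed = 1)
#' optimal_delays(sim$record, "x3", "x2", method = "ctds")
#' @export
optimal_delays <- function(data, source, target,
                           method = c("ctds", "mtds", "tds"),
                           L = 20, tau_max = NULL, align_range = 5, fs = 1) {
  method <- match.arg(method)
  record <- as_mc_record(data, fs = fs)
  if (is.null(tau_max)) tau_max <- default_tau_max(L)
  tau_max <- as.integer(tau_max)
  if (tau_max < 1) stop_ctds("tau_range", "`tau_max` must be >= 1.")
  x <- if (is.character(source)) match(source, record$labels) else as.integer(source)
  y <- if (is.character(target)) match(target, record$labels) else as.integer(target)
  if (is.na(x) || is.na(y) || x == y) {
    stop_ctds("bad_input", "`source` and `target` must name two distinct channels.")
  }
  controls <- if (method == "ctds") {
    sort(setdiff(seq_along(record$labels), c(x, y)))
  } else {
    integer(0)
  }
  shift_lo <- switch(method, tds = -tau_max,
                     ctds = if (length(controls)) -as.integer(align_range) else 0L,
                     mtds = 0L)
  cm <- shifted_corr(record, L, shift_lo, tau_max)
  if (length(cm$C) < 5L) {
    stop_ctds("tau_range", sprintf(
      "Only %d windows support the +/-%d delay scan; need at least 5.",
      length(cm$C), tau_max))
  }
  galign <- if (method == "ctds" && length(controls) > 0L) {
    global_alignment(record, as.integer(align_range))
  }
  pr <- pair_profile(cm, x, y, controls, method, tau_max,
                     as.integer(align_range), galign)
  structure(
    tibble::tibble(segment = cm$usable, tau0 = pr$tau0,
                   rho0 = pr$rho0, excluded = pr$excluded),
    method = method, pair = c(record$labels[x], record$labels[y]),
    tau_max = tau_max
  )
}

#' Stability mask over a delay profile
#'
#' Applies the 4-of-5 consecutive-segments rule: a segment counts as stable
#' iff it belongs to some 5-segment sliding window in which at least four
#' non-excluded segments have optimal delays within `tolerance` samples of the
#' window's modal delay; exactly those in-band segments are marked.
#'
#' @param profile A delay profile from [optimal_delays()] (or any data frame
#'   with columns `tau0` and `excluded`).
#' @param tolerance Band half-width in samples within which two delays count
#'   as the same stable delay (default 2).
#' @param marking `"window"` (default) marks every non-excluded member of a
#'   qualifying window as stable time; `"inband"` marks only the members
#'   inside the tolerance band.
#' @return The profile tibble with an added logical column `stable`.
#' @export
stability_mask <- function(profile, tolerance = 2,
                           marking = c("window", "inband")) {
  marking <- match.arg(marking)
  out <- tibble::as_tibble(profile)
  out$stable <- mask_stable(out$tau0, out$excluded, tolerance, marking)
  out
}

#' Link strength from a stability mask
#'
#' Strength is the percentage of non-excluded segments marked stable; the
#' representative delay is the modal optimal delay over stable segments.
#'
#' @param masked A profile with a `stable` column, from [stability_mask()].
#' @return A one-row tibble: `strength` (percent), `delay`, `n_stable`,
#'   `n_usable`, `n_excluded`.
#' @export
link_strength <- function(masked) {
  n_usable <- sum(!masked$excluded)
  n_stable <- sum(masked$stable)
  tibble::tibble(
    strength = 100 * n_stable / n_usable,
    delay = modal_delay(masked$tau0[masked$stable]),
    n_stable = n_stable,
    n_usable = n_usable,
    n_excluded = sum(masked$excluded)
  )
}

#' Build a coupling network from a multichannel record
#'
#' Evaluates every channel pair of a record with the chosen estimator and
#' assembles the directed strength and delay matrices. For `method = "ctds"`
#' each ordered pair is estimated while controlling for all remaining
#' channels (with two channels the control set is empty and CTDS coincides
#' with `mtds`). For `method = "tds"` the matrix is symmetric and delays carry
#' opposite signs across the diagonal.
#'
#' @param data A data frame / matrix of channels (samples in rows) or an
#'   [mc_record()].
#' @param method One of `"ctds"`, `"mtds"`, `"tds"`.
#' @param L Window length in samples (even, >= 4).
#' @param tau_max Largest scanned delay in samples; defaults to `L/2`. The
#'   shifted target window is drawn from the full series, so `tau_max` is
#'   limited by the series length, not by `L`; windows that cannot be shifted
#'   by the full range are dropped from the delay search.
#' @param tolerance Stability band half-width in samples (default 2).
#' @param align_range Scan range (samples) for aligning each control channel
#'   with the source before partialisation (default 5).
#' @param marking Stability marking rule; see [stability_mask()].
#' @param control_scope For `method = "ctds"`: `"global"` (default) regresses
#'   source and target on the aligned control signals over the full series
#'   and runs the delay-stability machinery on the residual series;
#'   `"segment"` computes the Nth-order partial cross-correlation within each
#'   segment by the recursive identity.
#' @param fs Sampling rate in Hz (used when `data` is not an `mc_record`).
#' @return A `ctds_network` object: list with `method`, `nodes`, `strength`
#'   and `delay` matrices, per-link counts, and the analysis parameters.
#'   Pairs with fewer than 5 usable segments get `NA` strength.
#' @examples
#' sim <- simulate_fixed_network(seed = 1)
#' net <- build_network(sim$record, method = "ctds")
#' tidy(net)
#' @export
build_network <- function(data, method = c("ctds", "mtds", "tds"),
                          L = 20, tau_max = NULL, tolerance = 2,
                          align_range = 5, marking = c("window", "inband"),
                          control_scope = c("global", "segment"),
                          fs = 1) {
  method <- match.arg(method)
  marking <- match.arg(marking)
  control_scope <- match.arg(control_scope)
  record <- as_mc_record(data, fs = fs)
  if (is.null(tau_max)) tau_max <- default_tau_max(L)
  tau_max <- as.integer(tau_max)
  if (tau_max < 1) stop_ctds("tau_range", "`tau_max` must be >= 1.")
  n <- length(record$labels)
  if (n < 2L) stop_ctds("bad_input", "At least two channels required.")
  shift_lo <- switch(method, tds = -tau_max,
                     ctds = if (n > 2L) -as.integer(align_range) else 0L,
                     mtds = 0L)
  cm <- shifted_corr(record, L, shift_lo, tau_max)
  if (length(cm$C) < 5L) {
    stop_ctds("tau_range", sprintf(
      "Only %d windows support the +/-%d delay scan; need at least 5.",
      length(cm$C), tau_max))
  }

  galign <- if (method == "ctds" && n > 2L) {
    global_alignment(record, as.integer(align_range))
  }
  strength <- matrix(0, n, n, dimnames = list(record$labels, record$labels))
  delay <- matrix(NA_integer_, n, n, dimnames = dimnames(strength))
  n_stable <- matrix(0L, n, n, dimnames = dimnames(strength))
  n_usable <- matrix(NA_integer_, n, n, dimnames = dimnames(strength))
  n_singular <- 0L

  pairs <- if (method == "tds") {
    which(upper.tri(strength), arr.ind = TRUE)
  } else {
    g <- as.matrix(expand.grid(row = seq_len(n), col = seq_len(n)))
    g[g[, 1L] != g[, 2L], , drop = FALSE]
  }

  for (p in seq_len(nrow(pairs))) {
    x <- pairs[p, 1L]
    y <- pairs[p, 2L]
    controls <- if (method == "ctds") sort(setdiff(seq_len(n), c(x, y))) else integer(0)
    if (method == "ctds" && control_scope == "global" && length(controls) > 0L) {
      # controlled estimator, global scope: delay-stability of the residual
      # series after regressing source and target on the aligned controls
      E <- residual_pair(record, x, y, controls, galign)
      cme <- shifted_corr(list(data = E), L, 0L, tau_max)
      pr <- pair_profile(cme, 1L, 2L, integer(0), "mtds", tau_max,
                         as.integer(align_range))
    } else {
      pr <- pair_profile(cm, x, y, controls, method, tau_max,
                         as.integer(align_range), galign)
    }
    n_singular <- n_singular + pr$n_singular
    # the undirected estimator does not resolve direction, so its stability
    # is assessed on the delay magnitude (the sign IS the direction)
    stab_tau <- if (method == "tds") abs(pr$tau0) else pr$tau0
    res <- tryCatch({
      mask <- mask_stable(stab_tau, pr$excluded, tolerance, marking)
      list(strength = 100 * sum(mask) / sum(!pr$excluded),
           delay = modal_delay(pr$tau0[mask]),
           n_stable = sum(mask), n_usable = sum(!pr$excluded))
    }, ctdsnet_error_undefined_stability = function(e) {
      list(strength = NA_real_, delay = NA_integer_,
           n_stable = NA_integer_, n_usable = sum(!pr$excluded))
    })
    strength[x, y] <- res$strength
    delay[x, y] <- res$delay
    n_stable[x, y] <- res$n_stable
    n_usable[x, y] <- res$n_usable
    if (method == "tds") {
      strength[y, x] <- res$strength
      delay[y, x] <- if (is.na(res$delay)) NA_integer_ else -res$delay
      n_stable[y, x] <- res$n_stable
      n_usable[y, x] <- res$n_usable
    }
  }
  diag(strength) <- 0

  structure(list(
    method = method,
    nodes = record$labels,
    strength = strength,
    delay = delay,
    n_stable = n_stable,
    n_usable = n_usable,
    n_near_singular = n_singular,
    params = list(L = as.integer(L), tau_max = tau_max,
                  tolerance = tolerance,
                  align_range = as.integer(align_range),
                  control_scope = control_scope,
                  marking = marking, fs = record$fs,
                  n_segments = cm$spec$n_segments,
                  n_segments_scanned = length(cm$C))
  ), class = "ctds_network")
}

#' @export
print.ctds_network <- function(x, ...) {
  cat(sprintf(
    "<ctds_network> method=%s, %d nodes, %d/%d segments scanned (L=%d, tau_max=%d)\n",
    x$method, length(x$nodes), x$params$n_segments_scanned,
    x$params$n_segments, x$params$L, x$params$tau_max))
  print(round(x$strength, 1))
  invisible(x)
}

#' @describeIn build_network One row per directed link: `source`, `target`,
#'   `strength`, `delay`, `n_stable`, `n_usable`.
#' @param x A `ctds_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ctds_network <- function(x, ...) {
  idx <- which(row(x$strength) != col(x$strength), arr.ind = TRUE)
  tibble::tibble(
    source = x$nodes[idx[, 1L]],
    target = x$nodes[idx[, 2L]],
    strength = x$strength[idx],
    delay = x$delay[idx],
    n_stable = x$n_stable[idx],
    n_usable = x$n_usable[idx],
    method = x$method
  ) |> dplyr::arrange(.data$source, .data$target)
}

#' @describeIn build_network One-row summary of the network.
#' @exportS3Method generics::glance
glance.ctds_network <- function(x, ...) {
  s <- x$strength[row(x$strength) != col(x$strength)]
  tibble::tibble(
    method = x$method,
    n_nodes = length(x$nodes),
    n_segments = x$params$n_segments,
    n_segments_scanned = x$params$n_segments_scanned,
    L = x$params$L,
    tau_max = x$params$tau_max,
    tolerance = x$params$tolerance,
    mean_strength = mean(s, na.rm = TRUE),
    max_strength = max(s, na.rm = TRUE),
    n_near_singular = x$n_near_singular
  )
}

#' @describeIn build_network Colour-coded strength-matrix plot; with
#'   `rescale = TRUE` strengths from 10% to 95% are mapped linearly onto
#'   `[0, 1]` (values outside are clamped).
#' @param object A `ctds_network`.
#' @param rescale Map the 10--95% strength range onto `[0, 1]` for the fill.
#' @exportS3Method ggplot2::autoplot
autoplot.ctds_network <- function(object, rescale = TRUE, ...) {
  df <- tidy(object)
  df$fill <- if (rescale) pmin(pmax((df$strength - 10) / 85, 0), 1) else df$strength
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(
      name = if (rescale) "strength\n(10-95% → 0-1)" else "strength (%)",
      limits = if (rescale) c(0, 1) else NULL) +
    ggplot2::scale_y_discrete(limits = rev(object$nodes)) +
    ggplot2::scale_x_discrete(limits = object$nodes) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s coupling strength", toupper(object$method)),
                  x = "target", y = "source") +
    ggplot2::theme_minimal()
}
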