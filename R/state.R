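## Composite state variable: delayed difference of the IPD, delay selection,
## per-match unit normalization, and the convex combination S(t).

#' Backward delayed difference
#'
#' \eqn{\Delta D_\tau(t_i) = D(t_i) - D(t_i - \tau)}, a causal surrogate for
#' velocity evaluated at the peaks of the IPD.  The first \eqn{k = \tau/\Delta t}
#' samples are invalid and returned as `NA`.
#'
#' @param ipd an `ipd_series` or numeric vector (with `dt` supplied).
#' @param tau delay in seconds; must be a positive integer multiple of the
#'   sampling interval and shorter than the series.
#' @param dt sampling interval when `ipd` is a bare vector.
#' @return numeric vector, `NA` for the first `k` samples; attribute `lag`.
#' @export
delayed_difference <- function(ipd, tau, dt = NULL) {
  D <- if (is.data.frame(ipd)) ipd$D else ipd
  dt <- dt %||% grid_dt(ipd$time)
  k <- tau / dt
  if (abs(k - round(k)) > 1e-8 || round(k) < 1) {
    stopf("tau = %g s is not a positive integer multiple of dt = %g s", tau, dt)
  }
  k <- as.integer(round(k))
  if (k >= length(D)) stopf("tau = %g s is not shorter than the series", tau)
  out <- c(rep(NA_real_, k), D[(k + 1):length(D)] - D[1:(length(D) - k)])
  attr(out, "lag") <- k
  out
}

#' Select the delay tau from the variance/correlation crossing
#'
#' For each candidate delay the variance of \eqn{\Delta D_\tau} (small at short
#' delays, growing) and the absolute correlation between \eqn{D} and
#' \eqn{\Delta D_\tau} (near 1 at short delays, decaying) are computed and
#' min-max normalized over the grid; the selected delay is the smallest grid
#' value at or after the first crossing of the two normalized curves -- the
#' shortest delay at which the difference channel carries substantial variance
#' while being acceptably independent of the distance channel.
#'
#' @param ipd an `ipd_series` or numeric vector.
#' @param tau_grid candidate delays in seconds (>= 3 values, integer multiples
#'   of the sampling interval), default 0.02-0.5 s.
#' @param dt sampling interval when `ipd` is a bare vector.
#' @return selected tau (seconds), with attribute `curves`: a data frame of
#'   the grid and both normalized curves.
#' @export
select_tau <- function(ipd, tau_grid = seq(0.02, 0.5, by = 0.02), dt = NULL) {
  D <- if (is.data.frame(ipd)) ipd$D else ipd
  dt <- dt %||% grid_dt(ipd$time)
  if (length(tau_grid) < 3L) stopf("tau_grid needs at least 3 delays")
  v <- numeric(length(tau_grid)); r <- numeric(length(tau_grid))
  for (i in seq_along(tau_grid)) {
    dd <- delayed_difference(D, tau_grid[i], dt = dt)
    ok <- !is.na(dd)
    v[i] <- var(dd[ok])
    r[i] <- abs(cor(D[ok], dd[ok]))
  }
  nv <- (v - min(v)) / (max(v) - min(v))
  nr <- (r - min(r)) / (max(r) - min(r))
  curves <- data.frame(tau = tau_grid, norm_var = nv, norm_abs_cor = nr)
  hit <- which(nv >= nr)
  if (!length(hit)) {
    cond <- structure(
      class = c("retmap_no_crossing", "error", "condition"),
      list(message = "variance and |correlation| curves do not cross on the grid",
           call = sys.call(), curves = curves))
    stop(cond)
  }
  structure(tau_grid[hit[1]], curves = curves)
}

#' Normalize to the unit interval
#'
#' `(x - lo) / (hi - lo)` with bounds computed over the whole match (never per
#' scene), so peak amplitudes are comparable across scenes of a match.
#' Values may overshoot \[lo, hi\] by at most `1e-9 * (hi - lo)` (and are
#' clipped); larger excursions are an error.
#'
#' @param x numeric (NA passed through).
#' @param lo,hi bounds, `hi > lo`.
#' @return normalized vector in \[0, 1\].
#' @export
normalize_unit <- function(x, lo, hi) {
  if (!is_number(lo) || !is_number(hi) || hi <= lo) stopf("need hi > lo")
  z <- (x - lo) / (hi - lo)
  tol <- 1e-9
  bad <- !is.na(z) & (z < -tol | z > 1 + tol)
  if (any(bad)) stopf("%d values outside [lo, hi] beyond tolerance", sum(bad))
  pmin(pmax(z, 0), 1)
}

#' Composite state variable
#'
#' Convex combination `S = weight * D_norm + (1 - weight) * dD_norm` of the
#' unit-normalized distance and delayed-difference channels; with both inputs
#' in \[0, 1\], S inherits \[0, 1\] and is monotone in each channel.
#'
#' @param D_norm,dD_norm equal-length vectors in \[0, 1\] (NA allowed).
#' @param weight in \[0, 1\] (default 0.5, the equal-weight combination).
#' @return S.
#' @export
composite_state <- function(D_norm, dD_norm, weight = 0.5) {
  if (!is_number(weight) || weight < 0 || weight > 1) {
    stopf("weight must lie in [0, 1]")
  }
  if (length(D_norm) != length(dD_norm)) stopf("channel lengths differ")
  rng <- range(c(D_norm, dD_norm), na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stopf("inputs must lie in [0, 1]")
  weight * D_norm + (1 - weight) * dD_norm
}

#' Build the full state series for a match
#'
#' Chains [delayed_difference()], match-level [normalize_unit()] and
#' [composite_state()].  Normalization bounds are taken over the whole match
#' (valid samples) unless supplied.
#'
#' @param ipd an `ipd_series` for one match.
#' @param tau delay in seconds (default 0.1).
#' @param weight composite weight (default 0.5).
#' @param bounds optional list with `D = c(lo, hi)`, `dD = c(lo, hi)`.
#' @return a `state_series` data frame: `time`, `D_norm`, `dD_norm`, `S`,
#'   `valid`; attributes `tau`, `bounds`, `match_id`, `group`.
#' @export
build_state_series <- function(ipd, tau = 0.1, weight = 0.5, bounds = NULL) {
  stopifnot(inherits(ipd, "ipd_series"))
  dd <- delayed_difference(ipd, tau)
  valid <- !is.na(dd)
  if (is.null(bounds)) {
    bounds <- list(D = range(ipd$D[valid]), dD = range(dd[valid]))
  }
  D_norm <- rep(NA_real_, length(dd))
  D_norm[valid] <- normalize_unit(ipd$D[valid], bounds$D[1], bounds$D[2])
  dD_norm <- rep(NA_real_, length(dd))
  dD_norm[valid] <- normalize_unit(dd[valid], bounds$dD[1], bounds$dD[2])
  S <- composite_state(D_norm, dD_norm, weight)
  out <- data.frame(time = ipd$time, D_norm = D_norm, dD_norm = dD_norm,
                    S = S, valid = valid)
  class(out) <- c("state_series", "data.frame")
  attr(out, "tau") <- tau
  attr(out, "bounds") <- bounds
  attr(out, "match_id") <- attr(ipd, "match_id")
  attr(out, "group") <- attr(ipd, "group")
  out
}
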