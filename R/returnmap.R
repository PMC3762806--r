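## Return-map analysis: peak detection on the smoothed state signal, the map
## of successive peak amplitudes (y_n, y_{n+1}), moving-window fits (3-6
## points) to linear / exponential / logarithmic maps, chi-square screening
## via the upper regularized incomplete gamma, identity-crossing exclusion for
## intermittency candidates, greedy longest-first overlap resolution, and
## classification into Aa / Ar / Ra / Rr / Exp / Log.

FAMILIES <- c("linear", "exponential", "logarithmic")
CLASSES <- c("Aa", "Ar", "Ra", "Rr", "Exp", "Log")

#' Analysis configuration
#'
#' Tunable parameters of the scene-level return-map analysis, with defaults.
#'
#' @param sigma per-point measurement error (normalized units) entering the
#'   chi-square, or `"auto"` to estimate it as 1.4826 x the median absolute
#'   residual of all 3-point linear fits (default 0.02).
#' @param q_threshold minimal goodness-of-fit probability Q for a candidate
#'   window (default 0.05; candidates below are excluded).
#' @param window_range allowed window lengths in return-map points (default
#'   3:6).
#' @param sg_order,sg_window Savitzky-Golay smoothing order and window
#'   (defaults 2, 9).
#' @param min_separation_s minimal peak separation in seconds (default 0).
#' @param min_prominence minimal peak-to-trough difference (signal units) for
#'   a detected peak (default 0: keep every strict maximum).
#' @param tie_break `"higher_q"` (default) or `"lower_chi2"`; these coincide
#'   at equal degrees of freedom.
#' @param cross_domain_lo lower edge of the state domain on which fitted
#'   exponential/logarithmic curves are tested for an identity-line crossing
#'   (default 0.01); the upper edge is `max(1, window range)`.  A crossing
#'   means the candidate has a fixed point and is therefore not intermittency.
#' @param classify_tol slopes within this tolerance of |c| = 1 are flagged
#'   unclassifiable (default 1e-9).
#' @return a `retmap_config` list.
#' @export
retmap_config <- function(sigma = 0.02, q_threshold = 0.05, window_range = 3:6,
                          sg_order = 2, sg_window = 9, min_separation_s = 0,
                          min_prominence = 0,
                          tie_break = c("higher_q", "lower_chi2"),
                          cross_domain_lo = 0.01, classify_tol = 1e-9) {
  tie_break <- match.arg(tie_break)
  stopifnot(is.numeric(window_range), min(window_range) >= 3)
  structure(list(sigma = sigma, q_threshold = q_threshold,
                 window_range = as.integer(window_range), sg_order = sg_order,
                 sg_window = sg_window, min_separation_s = min_separation_s,
                 min_prominence = min_prominence,
                 tie_break = tie_break, cross_domain_lo = cross_domain_lo,
                 classify_tol = classify_tol),
            class = "retmap_config")
}

## Savitzky-Golay projection row: weights w such that w %*% x[window] equals
## the value at position `at` of the least-squares polynomial through the
## window samples at positions `pos` (relative integer offsets).
sg_row <- function(pos, at, order) {
  A <- outer(pos, 0:order, `^`)
  ## row of A(at) %*% (A'A)^-1 A'
  a_at <- at^(0:order)
  drop(a_at %*% solve(crossprod(A), t(A)))
}

#' Savitzky-Golay smoothing
#'
#' Each output sample is the center value of the least-squares polynomial of
#' the given order fitted over the surrounding window.  Interior samples use
#' the standard convolution weights; edge samples are fitted over the
#' truncated window that remains inside the series.  Polynomial inputs of
#' degree <= `order` are reproduced exactly.
#'
#' @param x numeric series.
#' @param order polynomial order (default 2).
#' @param window odd window length > order (default 9).
#' @return smoothed series, same length.
#' @export
smooth_sg <- function(x, order = 2, window = 9) {
  n <- length(x)
  if (window %% 2 != 1) stopf("window must be odd")
  if (window <= order) stopf("window must exceed the polynomial order")
  if (window > n) stopf("window (%d) exceeds series length (%d)", window, n)
  h <- (window - 1L) %/% 2L
  w <- sg_row(-h:h, 0, order)
  out <- stats::filter(x, rev(w), sides = 2)
  out <- as.numeric(out)
  for (i in seq_len(min(h, n))) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- sum(sg_row((lo:hi) - i, 0, order) * x[lo:hi])
    j <- n - i + 1L
    lo <- max(1L, j - h); hi <- min(n, j + h)
    out[j] <- sum(sg_row((lo:hi) - j, 0, order) * x[lo:hi])
  }
  out
}

#' Detect peaks of a smoothed scene signal
#'
#' Strict local maxima; when two maxima are closer than `min_separation_s`
#' the larger is kept.
#'
#' @param x numeric series (smooth first; see [smooth_sg()]).
#' @param dt sampling interval in seconds (default 0.01).
#' @param min_separation_s minimal separation (default 0: keep all).
#' @param min_prominence minimal peak-to-trough difference (default 0);
#'   low-prominence wiggle pairs are pruned before maxima are returned.
#' @return a `peak_sequence` data frame: `index`, `time`, `amplitude`.
#' @export
detect_peaks <- function(x, dt = 0.01, min_separation_s = 0,
                         min_prominence = 0) {
  ex <- local_extrema(x)
  pk <- enforce_alternation(ex$max, ex$min, x)
  pk <- prune_extrema(pk$pos, pk$neg, x, min_prominence)
  idx <- pk$pos
  if (min_separation_s > 0 && length(idx) > 1L) {
    repeat {
      gaps <- diff(idx) * dt
      close_i <- which(gaps < min_separation_s)
      if (!length(close_i)) break
      i <- close_i[1]
      drop <- if (x[idx[i]] >= x[idx[i + 1L]]) i + 1L else i
      idx <- idx[-drop]
      if (length(idx) < 2L) break
    }
  }
  out <- data.frame(index = idx, time = (idx - 1) * dt, amplitude = x[idx])
  class(out) <- c("peak_sequence", "data.frame")
  out
}

#' Build the return map from a peak sequence
#'
#' @param peaks a `peak_sequence` or numeric amplitude vector (>= 2 peaks).
#' @return data frame with `x` (\eqn{y_n}) and `y` (\eqn{y_{n+1}}), M-1 rows
#'   for M peaks.
#' @export
build_return_map <- function(peaks) {
  a <- if (is.data.frame(peaks)) peaks$amplitude else peaks
  if (length(a) < 2L) stopf("need at least 2 peaks for a return map")
  data.frame(x = a[-length(a)], y = a[-1])
}

## closed-form profile fit of y = a * exp(b * x): for fixed b the optimal
## a(b) = sum(y e^{bx}) / sum(e^{2bx}); SSR(b) is minimized by Brent search
## around the log-linearized initial value.  Deterministic and safe at zero
## residual (unlike Gauss-Newton solvers).
fit_exponential <- function(x, y) {
  ssr_b <- function(b) {
    e <- exp(b * x)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  b0 <- if (all(y > 0)) unname(coef(lm(log(y) ~ x))[2]) else 0
  if (!is.finite(b0)) b0 <- 0
  opt <- optimize(ssr_b, lower = b0 - 5, upper = b0 + 5, tol = 1e-12)
  b <- opt$minimum
  ## polish: the optimum may sit at an interval edge for extreme data
  if (min(abs(b - (b0 + c(-5, 5)))) < 1e-6) {
    opt2 <- optimize(ssr_b, lower = b - 5, upper = b + 5, tol = 1e-12)
    if (opt2$objective < opt$objective) b <- opt2$minimum
  }
  e <- exp(b * x)
  a <- sum(y * e) / sum(e * e)
  list(params = c(a = a, b = b), ssr = sum((y - a * e)^2))
}

#' Fit one return-map window
#'
#' Least squares of \eqn{y_{n+1} = f(y_n)} over `length` consecutive map
#' points from `start`.  Linear and logarithmic families are solved in closed
#' form; the exponential family by a profiled one-dimensional search started
#' from the log-linearized fit.  `chi2 = SSR / sigma^2` with `dof = L - 2`,
#' and `Q = pchisq(chi2, dof, lower.tail = FALSE)` (the upper regularized
#' incomplete gamma of (dof/2, chi2/2)); Q near 1 indicates a credible fit.
#'
#' @param points return map (from [build_return_map()]).
#' @param family `"linear"`, `"exponential"` or `"logarithmic"`.
#' @param sigma per-point measurement error.
#' @param start first map point of the window (1-based).
#' @param length window length L, 3-6.
#' @return a `retmap_fit`: family, params, start, length, chi2, dof, Q,
#'   `fn` (the fitted map as a function), class/fixed_point unset until
#'   [classify_fit()].
#' @export
fit_window <- function(points, family, sigma, start = 1L,
                       length = nrow(points)) {
  L <- as.integer(length)
  if (L < 3L || L > 6L) stopf("window length must be 3-6 points")
  if (start < 1L || start + L - 1L > nrow(points)) stopf("window out of range")
  x <- points$x[start:(start + L - 1L)]
  y <- points$y[start:(start + L - 1L)]
  if (max(x) - min(x) < 1e-12) stopf("singular design: all y_n equal")
  if (!is_number(sigma) || sigma <= 0) stopf("sigma must be a positive number")
  fit <- switch(family,
    linear = {
      cf <- coef(lm(y ~ x))
      list(params = c(c = unname(cf[2]), d = unname(cf[1])),
           ssr = sum((y - cf[1] - cf[2] * x)^2))
    },
    exponential = fit_exponential(x, y),
    logarithmic = {
      if (any(x <= 0)) stopf("logarithmic fit needs all y_n > 0")
      cf <- coef(lm(y ~ log(x)))
      list(params = c(a = unname(cf[1]), b = unname(cf[2])),
           ssr = sum((y - cf[1] - cf[2] * log(x))^2))
    },
    stopf("unknown family '%s'", family)
  )
  chi2 <- fit$ssr / sigma^2
  dof <- L - 2L
  p <- fit$params
  fn <- switch(family,
    linear = function(z) p[[1]] * z + p[[2]],
    exponential = function(z) p[[1]] * exp(p[[2]] * z),
    logarithmic = function(z) p[[1]] + p[[2]] * log(z))
  structure(list(family = family, params = fit$params, start = start,
                 length = L, chi2 = chi2, dof = dof,
                 Q = pchisq(chi2, dof, lower.tail = FALSE),
                 fn = fn, class = NA_character_, fixed_point = NA_real_,
                 x_range = range(x)),
            class = "retmap_fit")
}

## Does the fitted curve cross the identity line on [lo, hi]?  Sign change of
## f(x) - x over a dense grid plus endpoint checks.
crosses_identity <- function(fn, lo, hi, n_grid = 100L) {
  g <- seq(lo, hi, length.out = n_grid)
  d <- fn(g) - g
  d <- d[is.finite(d) & d != 0]
  if (length(d) < 2L) return(FALSE)
  any(diff(sign(d)) != 0)
}

#' Scan all moving windows of a scene's return map
#'
#' Fits every (start, length, family) combination, removes candidates whose
#' goodness-of-fit probability Q falls below the significance threshold, and
#' removes exponential/logarithmic candidates whose fitted curve crosses the
#' identity line on the state domain (such a curve has a fixed point, so the
#' segment is attractor/repeller dynamics, not intermittency).
#'
#' @param points return map (>= 3 points).
#' @param config a [retmap_config()].
#' @return list of surviving (unclassified) `retmap_fit` candidates.
#' @export
scan_windows <- function(points, config = retmap_config()) {
  n <- nrow(points)
  if (n < 3L) stopf("need at least 3 return-map points")
  sigma <- resolve_sigma(config$sigma, points)
  out <- list()
  for (L in config$window_range) {
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      for (fam in FAMILIES) {
        fit <- tryCatch(fit_window(points, fam, sigma, s, L),
                        error = function(e) NULL)
        if (is.null(fit) || !is.finite(fit$Q)) next
        if (fit$Q < config$q_threshold) next
        if (fam != "linear") {
          hi <- max(1, fit$x_range[2])
          if (crosses_identity(fit$fn, config$cross_domain_lo, hi)) next
        }
        out[[length(out) + 1L]] <- fit
      }
    }
  }
  out
}

## sigma = "auto": robust scale (1.4826 * MAD about zero) of residuals of all
## 3-point linear fits, a noise proxy uncontaminated by regime switches.
resolve_sigma <- function(sigma, points) {
  if (identical(sigma, "auto")) {
    n <- nrow(points)
    res <- unlist(lapply(seq_len(max(n - 2L, 0L)), function(s) {
      x <- points$x[s:(s + 2L)]; y <- points$y[s:(s + 2L)]
      if (max(x) - min(x) < 1e-12) return(NULL)
      resid(lm(y ~ x))
    }))
    s <- 1.4826 * median(abs(res))
    max(s, 1e-4)
  } else sigma
}

#' Resolve overlapping candidate fits
#'
#' Greedy selection: longer windows first (the longer series of points is
#' preferred); among equal-length overlapping candidates the better goodness
#' of fit wins (higher Q, equivalently lower chi-square at equal degrees of
#' freedom); every candidate overlapping an accepted window is dropped.
#' Accepted fits are classified (see [classify_fit()]).
#'
#' @param candidates list of `retmap_fit` (from [scan_windows()]).
#' @param config a [retmap_config()].
#' @param n_points number of return-map points in the scene (for bookkeeping).
#' @param scene_id optional identifier.
#' @return a `retmap_segmentation`: accepted non-overlapping classified fits,
#'   `n_functions` (their count), `scene_id`, `n_points`.
#' @export
select_fits <- function(candidates, config = retmap_config(), n_points = NA,
                        scene_id = NA) {
  if (length(candidates)) {
    len <- vapply(candidates, function(f) as.numeric(f$length), 0)
    qv <- vapply(candidates, `[[`, 0, "Q")
    chi <- vapply(candidates, `[[`, 0, "chi2")
    st <- vapply(candidates, function(f) as.numeric(f$start), 0)
    ord <- if (config$tie_break == "higher_q") {
      order(-len, -qv, chi, st)
    } else {
      order(-len, chi, -qv, st)
    }
    covered <- integer(0)
    accepted <- list()
    for (i in ord) {
      f <- candidates[[i]]
      span <- f$start:(f$start + f$length - 1L)
      if (any(span %in% covered)) next
      covered <- c(covered, span)
      accepted[[length(accepted) + 1L]] <- classify_fit(f,
        tol = config$classify_tol)
    }
    accepted <- accepted[order(vapply(accepted,
                                      function(f) as.numeric(f$start), 0))]
  } else accepted <- list()
  structure(list(fits = accepted, n_functions = length(accepted),
                 scene_id = scene_id, n_points = n_points),
            class = "retmap_segmentation")
}

#' Classify an accepted fit
#'
#' Linear maps by slope: `0 < c < 1` asymptotic attractor (`Aa`),
#' `-1 < c < 0` rotational attractor (`Ar`), `c > 1` asymptotic repeller
#' (`Ra`), `c < -1` rotational repeller (`Rr`), with fixed point
#' `d / (1 - c)`.  Exponential and logarithmic fits are intermittency
#' (`Exp`, `Log`).  Slopes within `tol` of |c| = 1 are flagged
#' unclassifiable (class `NA`, `flag = "unclassifiable"`).
#'
#' @param fit a `retmap_fit`.
#' @param tol tolerance around |c| = 1 (default 1e-9).
#' @return the fit with `class` (and `fixed_point` for linear maps) set.
#' @export
classify_fit <- function(fit, tol = 1e-9) {
  stopifnot(inherits(fit, "retmap_fit"))
  if (fit$family == "exponential") {
    fit$class <- "Exp"
  } else if (fit$family == "logarithmic") {
    fit$class <- "Log"
  } else {
    c_ <- fit$params[["c"]]
    if (abs(abs(c_) - 1) <= tol) {
      fit$class <- NA_character_
      fit$flag <- "unclassifiable"
      return(fit)
    }
    fit$fixed_point <- fit$params[["d"]] / (1 - c_)
    fit$class <- if (c_ > 1) "Ra" else if (c_ > 0) "Aa"
      else if (c_ > -1) "Ar" else "Rr"
  }
  fit
}

#' Analyze a peak-amplitude sequence
#'
#' Return-map construction, window scan, overlap resolution, classification.
#'
#' @param amplitudes numeric peak amplitudes (>= 4 so the map has >= 3 points).
#' @param config a [retmap_config()].
#' @param scene_id optional identifier.
#' @return a `retmap_segmentation`.
#' @export
analyze_peaks <- function(amplitudes, config = retmap_config(), scene_id = NA) {
  points <- build_return_map(amplitudes)
  cand <- scan_windows(points, config)
  select_fits(cand, config, n_points = nrow(points), scene_id = scene_id)
}

#' Analyze a continuous scene signal
#'
#' Smooths the detection signal (Savitzky-Golay), detects its strict local
#' maxima, reads the peak amplitudes (from `amplitude_from` at the detected
#' peaks when given -- e.g. peaks located on the normalized distance but
#' amplitudes taken from the composite state -- else from the smoothed
#' detection signal), and runs [analyze_peaks()].
#'
#' @param signal numeric detection signal (one scene).
#' @param config a [retmap_config()].
#' @param dt sampling interval (default 0.01 s).
#' @param amplitude_from optional equal-length series supplying amplitudes.
#' @param scene_id optional identifier.
#' @return a `retmap_segmentation` with attribute `peaks` (the
#'   `peak_sequence`).
#' @export
analyze_scene <- function(signal, config = retmap_config(), dt = 0.01,
                          amplitude_from = NULL, scene_id = NA) {
  sm <- smooth_sg(signal, config$sg_order, config$sg_window)
  pk <- detect_peaks(sm, dt = dt, min_separation_s = config$min_separation_s,
                     min_prominence = config$min_prominence)
  if (!is.null(amplitude_from)) {
    amp <- smooth_sg(amplitude_from, config$sg_order, config$sg_window)
    pk$amplitude <- amp[pk$index]
  }
  seg <- analyze_peaks(pk$amplitude, config, scene_id = scene_id)
  attr(seg, "peaks") <- pk
  seg
}

#' @export
print.retmap_fit <- function(x, ...) {
  cat(sprintf("<fit %s%s> window %d+%d  params (%.4g, %.4g)  chi2 %.3g  Q %.3g%s\n",
              x$family, if (!is.na(x$class)) paste0("/", x$class) else "",
              x$start, x$length, x$params[1], x$params[2], x$chi2, x$Q,
              if (is.finite(x$fixed_point)) sprintf("  fp %.3f", x$fixed_point)
              else ""))
  invisible(x)
}

#' @export
print.retmap_segmentation <- function(x, ...) {
  cat(sprintf("<segmentation%s> %d accepted fit(s) over %s map points\n",
              if (!is.na(x$scene_id)) paste0(" scene ", x$scene_id) else "",
              x$n_functions, x$n_points))
  for (f in x$fits) print(f)
  invisible(x)
}

#' Tabulate accepted fits
#'
#' One row per accepted fit across segmentations (Table-style bookkeeping:
#' class by window length).
#'
#' @param segmentations list of `retmap_segmentation`.
#' @return data frame: scene_id, family, class, start, length, p1, p2, chi2,
#'   Q, fixed_point.
#' @export
fits_table <- function(segmentations) {
  rows <- lapply(segmentations, function(seg) {
    if (!length(seg$fits)) return(NULL)
    do.call(rbind, lapply(seg$fits, function(f) {
      data.frame(scene_id = seg$scene_id, family = f$family,
                 class = f$class, start = f$start, length = f$length,
                 p1 = unname(f$params[1]), p2 = unname(f$params[2]),
                 chi2 = f$chi2, Q = f$Q, fixed_point = f$fixed_point)
    }))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(scene_id = character(0), family = character(0),
                      class = character(0), start = integer(0),
                      length = integer(0), p1 = numeric(0), p2 = numeric(0),
                      chi2 = numeric(0), Q = numeric(0),
                      fixed_point = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
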