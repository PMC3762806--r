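test_that("SG smoothing reproduces polynomials and matches the LSQ oracle", {
  x <- (1:50) * 0.1
  quad <- 0.3 + 0.2 * x - 0.05 * x^2
  expect_equal(smooth_sg(quad), quad, tolerance = 1e-12)
  expect_equal(smooth_sg(rep(3, 30)), rep(3, 30), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:10) {
    r <- rnorm(40)
    expect_lt(max(abs(smooth_sg(r) - sg_oracle(r))), 1e-10)
  }
  expect_error(smooth_sg(rnorm(20), window = 8), "odd")
  expect_error(smooth_sg(rnorm(5), window = 9), "exceeds")
})

test_that("peak detection finds strict maxima with separation and prominence rules", {
  pk <- detect_peaks(c(0, 1, 0, 2, 0))
  expect_equal(pk$index, c(2L, 4L))
  expect_equal(detect_peaks(1:10)$index, integer(0))
  # closer than min_separation: the larger of the two is kept
  x <- c(0, 1, 0.5, 0.8, 0, 2, 0)
  pk2 <- detect_peaks(x, dt = 1, min_separation_s = 3)
  expect_equal(pk2$index, c(2L, 6L))
  # prominence pruning removes a shallow wiggle riding on a shoulder
  y <- c(0, 1, 0.95, 0.97, 0.2, 2, 0)
  expect_equal(detect_peaks(y, min_prominence = 0.1)$index, c(2L, 6L))
  expect_equal(detect_peaks(y)$index, c(2L, 4L, 6L))
})

test_that("the return map pairs successive peaks", {
  pts <- build_return_map(c(1.0, 0.8, 0.7))
  expect_equal(pts$x, c(1.0, 0.8))
  expect_equal(pts$y, c(0.8, 0.7))
  expect_equal(nrow(build_return_map(runif(9))), 8)
  flat <- build_return_map(c(0.5, 0.5, 0.5))
  expect_equal(flat$x, flat$y)
  expect_error(build_return_map(1), "2 peaks")
})

test_that("window fits solve the three families with chi-square screening", {
  pts <- build_return_map(linear_map_points(0.5, 0.3, 1.0, 5))
  f <- fit_window(pts, "linear", sigma = 0.02)
  expect_equal(unname(f$params), c(0.5, 0.3), tolerance = 1e-10)
  expect_equal(f$chi2, 0, tolerance = 1e-16)
  expect_equal(f$Q, 1)
  expect_equal(f$dof, 2L)

  # Q oracle: independent numerical integration of the chi-square upper tail
  q_oracle <- function(chi2, dof) {
    integrate(function(u) u^(dof / 2 - 1) * exp(-u / 2), chi2, Inf,
              rel.tol = 1e-12)$value / (2^(dof / 2) * gamma(dof / 2))
  }
  expect_equal(pchisq(0.1, 1, lower.tail = FALSE), q_oracle(0.1, 1),
               tolerance = 1e-9)
  expect_equal(round(pchisq(0.1, 1, lower.tail = FALSE), 4), 0.7518)

  # exponential parameter recovery on generated points
  set.seed(2)
  x <- seq(0.2, 0.9, length.out = 6)
  y <- 0.5 * exp(0.8 * x) + rnorm(6, 0, 0.002)
  pe <- data.frame(x = x, y = y)
  fe <- fit_window(pe, "exponential", sigma = 0.002)
  expect_equal(unname(fe$params), c(0.5, 0.8), tolerance = 0.05)

  # logarithmic closed form
  yl <- 0.9 + 0.3 * log(x)
  fl <- fit_window(data.frame(x = x, y = yl), "logarithmic", sigma = 0.01)
  expect_equal(unname(fl$params), c(0.9, 0.3), tolerance = 1e-9)

  sing <- data.frame(x = rep(0.4, 3), y = c(0.1, 0.2, 0.3))
  expect_error(fit_window(sing, "linear", sigma = 0.02), "singular")
  neg <- data.frame(x = c(-0.1, 0.2, 0.5), y = c(0.3, 0.4, 0.5))
  expect_error(fit_window(neg, "logarithmic", sigma = 0.02), "> 0")
})

test_that("exponential fitting is exact at zero residual", {
  x <- seq(0.1, 1, length.out = 5)
  pts <- data.frame(x = x, y = 0.35 * exp(1.4 * x))
  f <- fit_window(pts, "exponential", sigma = 0.02)
  expect_equal(unname(f$params), c(0.35, 1.4), tolerance = 1e-6)
  expect_lt(f$chi2, 1e-10)
})

test_that("Q is monotone decreasing in chi-square at fixed dof", {
  chis <- seq(0, 20, by = 0.5)
  for (dof in 1:4) {
    qs <- pchisq(chis, dof, lower.tail = FALSE)
    expect_true(all(diff(qs) < 0))
    expect_equal(qs[1], 1)
  }
})

test_that("the window scan enumerates moving windows and screens candidates", {
  pts <- build_return_map(linear_map_points(0.5, 0.3, 1.2, 6))  # 5 points
  cand <- scan_windows(pts, retmap_config())
  lin <- Filter(function(f) f$family == "linear", cand)
  # 3 three-point + 2 four-point + 1 five-point windows, all perfect
  expect_length(lin, 6)
  expect_true(all(vapply(lin, `[[`, 0, "Q") > 1 - 1e-10))
  lens <- table(vapply(lin, `[[`, 0L, "length"))
  expect_equal(as.integer(lens[c("3", "4", "5")]), c(3L, 2L, 1L))
})

test_that("exp/log candidates crossing the identity line are excluded", {
  # exact exponential with a fixed point inside the window range:
  # a e^{bx} with a = 0.3, b = 1 crosses y = x near 0.49 and 1.5+
  xs <- seq(0.2, 0.9, length.out = 4)
  pts <- data.frame(x = xs, y = 0.3 * exp(xs))
  cand <- scan_windows(pts, retmap_config())
  expect_false(any(vapply(cand, `[[`, "", "family") == "exponential"))
  # a clear channel above the identity line is kept
  rg <- regime_spec("exponential", c(0.45, 1.2), 4, 0.2)
  gp <- generate_peak_sequence(synthetic_spec(list(rg), seed = 1))
  cand2 <- scan_windows(build_return_map(gp$peaks), retmap_config())
  expect_true(any(vapply(cand2, `[[`, "", "family") == "exponential"))
})

test_that("overlap resolution prefers longer windows, then goodness of fit", {
  mkfit <- function(start, len, Q, family = "linear") {
    structure(list(family = family, params = c(c = 0.5, d = 0.2),
                   start = start, length = len, chi2 = 1, dof = len - 2,
                   Q = Q, fn = function(z) z, class = NA_character_,
                   fixed_point = NA_real_, x_range = c(0, 1)),
              class = "retmap_fit")
  }
  sel <- select_fits(list(mkfit(1, 3, 0.9), mkfit(1, 5, 0.5)), n_points = 5)
  expect_equal(sel$n_functions, 1)
  expect_equal(sel$fits[[1]]$length, 5L)
  sel2 <- select_fits(list(mkfit(1, 3, 0.9), mkfit(4, 3, 0.8)), n_points = 6)
  expect_equal(sel2$n_functions, 2)
  # equal length, overlapping: higher Q wins
  sel3 <- select_fits(list(mkfit(1, 4, 0.7), mkfit(2, 4, 0.95)), n_points = 5)
  expect_equal(sel3$fits[[1]]$start, 2L)
  # accepted windows never overlap
  set.seed(8)
  cand <- lapply(1:30, function(i) mkfit(sample(1:10, 1), sample(3:6, 1),
                                         runif(1)))
  selr <- select_fits(cand, n_points = 15)
  spans <- unlist(lapply(selr$fits, function(f) f$start:(f$start + f$length - 1)))
  expect_equal(anyDuplicated(spans), 0)
})

test_that("two planted regimes separate into two fits with correct families", {
  rgs <- list(regime_spec("linear", c(0.6, 0.14), 5, 0.95),   # Aa, fp 0.35
              regime_spec("linear", c(1.6, -0.33), 5, 0.62))  # Ra, fp 0.55
  gp <- generate_peak_sequence(synthetic_spec(rgs, seed = 1))
  seg <- analyze_peaks(gp$peaks)
  expect_equal(seg$n_functions, 2)
  expect_equal(vapply(seg$fits, `[[`, "", "class"), c("Aa", "Ra"))
  expect_equal(seg$fits[[1]]$fixed_point, 0.35, tolerance = 1e-9)
})

test_that("classification follows the slope and agrees with iteration dynamics", {
  clf <- function(c_, d) {
    pts <- build_return_map(linear_map_points(c_, d, d / (1 - c_) + 0.05, 4))
    classify_fit(fit_window(pts, "linear", sigma = 0.02))
  }
  f1 <- clf(0.5, 0.3)
  expect_equal(f1$class, "Aa")
  expect_equal(f1$fixed_point, 0.6, tolerance = 1e-9)
  f2 <- clf(-1.5, 1.5)
  expect_equal(f2$class, "Rr")
  expect_equal(f2$fixed_point, 0.6, tolerance = 1e-6)

  # |c| = 1 is unclassifiable
  u <- structure(list(family = "linear", params = c(c = 1 + 1e-12, d = 0.1),
                      start = 1L, length = 3L, chi2 = 0, dof = 1L, Q = 1,
                      fn = identity, class = NA_character_,
                      fixed_point = NA_real_, x_range = c(0, 1)),
                 class = "retmap_fit")
  expect_equal(classify_fit(u)$flag, "unclassifiable")

  # iteration oracle on random slopes (small version of the consistency check)
  set.seed(5)
  for (i in 1:100) {
    c_ <- runif(1, -2, 2)
    if (abs(abs(c_) - 1) < 0.05) next
    fp <- runif(1, 0.3, 0.7); d <- fp * (1 - c_)
    x <- fp + 0.01
    for (k in 1:50) x <- min(max(c_ * x + d, -1e6), 1e6)
    converged <- abs(x - fp) < 0.01
    cls <- classify_fit(structure(list(family = "linear",
      params = c(c = c_, d = d), start = 1L, length = 3L, chi2 = 0, dof = 1L,
      Q = 1, fn = identity, class = NA_character_, fixed_point = NA_real_,
      x_range = c(0, 1)), class = "retmap_fit"))$class
    expect_equal(converged, cls %in% c("Aa", "Ar"))
    expect_equal(cls %in% c("Aa", "Ra"), c_ > 0)
  }
})

test_that("auto sigma recovers the observation noise scale", {
  set.seed(9)
  p <- linear_map_points(0.6, 0.2, 0.95, 40) + rnorm(40, 0, 0.01)
  pts <- build_return_map(p)
  s <- retmap:::resolve_sigma("auto", pts)
  expect_gt(s, 0.005)
  expect_lt(s, 0.03)
})
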