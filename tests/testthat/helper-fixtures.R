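# shared builders for small deterministic fixtures

# trajectory with a prescribed IPD trace: agents on a horizontal line
traj_from_ipd <- function(D, dt = 0.01, match_id = "T1", group = "A") {
  n <- length(D)
  time <- (seq_len(n) - 1) * dt
  trajectory_pair(time, xA = D / 2, yA = rep(0, n),
                  xB = -D / 2, yB = rep(0, n),
                  match_id = match_id, group = group)
}

ipd_from_values <- function(D, dt = 0.01) {
  out <- data.frame(time = (seq_along(D) - 1) * dt, D = D)
  class(out) <- c("ipd_series", "data.frame")
  attr(out, "match_id") <- "T1"
  attr(out, "group") <- "A"
  out
}

# exact points on a linear map iterated from x0
linear_map_points <- function(c_, d, x0, n_peaks) {
  p <- numeric(n_peaks)
  p[1] <- x0
  for (k in 2:n_peaks) p[k] <- c_ * p[k - 1] + d
  p
}

# per-window polynomial least-squares oracle for Savitzky-Golay smoothing
sg_oracle <- function(x, order = 2, window = 9) {
  n <- length(x)
  h <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    pos <- (lo:hi) - i
    unname(predict(lm(y ~ poly(pos, order, raw = TRUE),
                      data = data.frame(pos = pos, y = x[lo:hi])),
                   newdata = data.frame(pos = 0)))
  }, 0)
}

# independent Fisher oracle: direct factorial enumeration over the support
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[match(tab[1, 1], ks)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# close-approach cut threshold matching the generator's default scaling
default_close_m <- function(spec) spec$base_m + spec$gain_m * 0.1
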