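#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm optimize pchisq quantile resid rnorm runif sd var
#'   cor median dhyper setNames
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's state afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Strict local extrema of a numeric vector: index i is a maximum when
## x[i] > x[i-1] and x[i] > x[i+1] (plateaus yield no extremum).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  i <- 2:(n - 1L)
  d1 <- x[i] - x[i - 1L]
  d2 <- x[i] - x[i + 1L]
  list(max = i[d1 > 0 & d2 > 0], min = i[d1 < 0 & d2 < 0])
}

## Merge maxima/minima into one event list and enforce strict alternation:
## within a run of same-type events keep the most extreme one (ties: first).
enforce_alternation <- function(pos, neg, values) {
  if (!length(pos) && !length(neg)) return(list(pos = integer(0), neg = integer(0)))
  ev <- rbind(
    data.frame(idx = pos, type = rep("pos", length(pos))),
    data.frame(idx = neg, type = rep("neg", length(neg)))
  )
  ev <- ev[order(ev$idx), , drop = FALSE]
  keep <- logical(nrow(ev))
  i <- 1L
  while (i <= nrow(ev)) {
    j <- i
    while (j < nrow(ev) && ev$type[j + 1L] == ev$type[i]) j <- j + 1L
    run <- i:j
    v <- values[ev$idx[run]]
    pick <- if (ev$type[i] == "pos") run[which.max(v)] else run[which.min(v)]
    keep[pick] <- TRUE
    i <- j + 1L
  }
  ev <- ev[keep, , drop = FALSE]
  list(pos = ev$idx[ev$type == "pos"], neg = ev$idx[ev$type == "neg"])
}

## Prune low-prominence wiggles from an alternating extrema sequence:
## repeatedly remove the adjacent max/min pair with the smallest absolute
## value difference while that difference is below min_prom.  Removing an
## adjacent pair preserves alternation.
prune_extrema <- function(pos, neg, values, min_prom) {
  if (min_prom <= 0) return(list(pos = pos, neg = neg))
  ev <- rbind(
    data.frame(idx = pos, type = rep("pos", length(pos))),
    data.frame(idx = neg, type = rep("neg", length(neg)))
  )
  ev <- ev[order(ev$idx), , drop = FALSE]
  repeat {
    if (nrow(ev) < 2L) break
    d <- abs(diff(values[ev$idx]))
    k <- which.min(d)
    if (d[k] >= min_prom) break
    ev <- ev[-c(k, k + 1L), , drop = FALSE]
  }
  list(pos = ev$idx[ev$type == "pos"], neg = ev$idx[ev$type == "neg"])
}

## Sampling interval of a uniform time grid, with a uniformity check.
grid_dt <- function(time, tol = 1e-6) {
  if (length(time) < 2L) stopf("time grid needs at least two samples")
  d <- diff(time)
  dt <- median(d)
  if (dt <= 0 || any(abs(d - dt) > tol * max(dt, 1))) {
    stopf("time grid must be uniform and strictly increasing")
  }
  dt
}
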