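## Hierarchical state-transition statistics: per-match histogram of
## well-fitted peak amplitudes, far/near (F/N) threshold at the histogram
## minimum between the two major modes, second- and third-order conditional
## transition probabilities, and Fisher exact group contrasts.

SUBSTATES <- c("FF", "NF", "NN", "FN")

#' Histogram of well-fitted peak amplitudes
#'
#' Fixed-width, left-closed bins spanning \[0, 1\].  By convention the input
#' is the amplitudes of peaks belonging to accepted *linear* fits (attractors
#' and repellers); intermittency peaks are excluded upstream unless requested.
#'
#' @param values peak amplitudes in \[0, 1\] (>= `min_peaks`).
#' @param bin_width default 0.05.
#' @param min_peaks minimal number of peaks (default 10); fewer is an error
#'   directing to a pooled fallback.
#' @return a `retmap_hist`: `breaks`, `mids`, `counts`.
#' @export
peak_histogram <- function(values, bin_width = 0.05, min_peaks = 10) {
  values <- values[!is.na(values)]
  if (length(values) < min_peaks) {
    stopf(paste0("only %d peaks (< %d): pool matches or lower min_peaks ",
                 "for a global histogram"), length(values), min_peaks)
  }
  if (any(values < 0 | values > 1)) stopf("peak values must lie in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts),
            class = "retmap_hist")
}

## local modes of a count vector: bins strictly higher than the nearest
## differing neighbor on each side (plateaus collapse to their first bin).
hist_modes <- function(counts) {
  n <- length(counts)
  modes <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && counts[j + 1L] == counts[i]) j <- j + 1L
    left_ok <- i == 1L || counts[i - 1L] < counts[i]
    right_ok <- j == n || counts[j + 1L] < counts[i]
    if (left_ok && right_ok && counts[i] > 0) modes <- c(modes, i)
    i <- j + 1L
  }
  modes
}

#' Far/near threshold from a bimodal histogram
#'
#' The threshold is the center of the minimum-count bin strictly between the
#' two largest modes (ties among minima broken toward the midpoint of the
#' modes).  A histogram without two modes is an error directing to a pooled
#' or global threshold.
#'
#' @param hist a `retmap_hist`.
#' @return threshold value; attributes `mode_bins`, `min_bin`.
#' @export
find_threshold <- function(hist) {
  stopifnot(inherits(hist, "retmap_hist"))
  modes <- hist_modes(hist$counts)
  if (length(modes) < 2L) {
    stopf("histogram is unimodal; use a pooled or global threshold instead")
  }
  top2 <- modes[order(-hist$counts[modes], modes)][1:2]
  m1 <- min(top2); m2 <- max(top2)
  between <- (m1 + 1L):(m2 - 1L)
  if (!length(between) || m2 - m1 < 2L) {
    stopf("the two largest modes are adjacent; no interior minimum exists")
  }
  cmin <- min(hist$counts[between])
  cand <- between[hist$counts[between] == cmin]
  midpoint <- (hist$mids[m1] + hist$mids[m2]) / 2
  cand <- cand[order(abs(hist$mids[cand] - midpoint), cand)]
  thr <- hist$mids[cand[1]]
  structure(thr, mode_bins = c(m1, m2), min_bin = cand[1])
}

#' Label peaks as far (F) or near (N) states
#'
#' Amplitudes above the threshold are `F` ("farthest apart", high velocity);
#' at or below, `N` ("nearest together", low velocity) -- equality maps to
#' `N` by declared convention.  Scene order is preserved.
#'
#' @param scene_values list of per-scene amplitude vectors (or one vector).
#' @param threshold from [find_threshold()].
#' @return list of character vectors (`"F"`/`"N"`), class `state_labeling`;
#'   attribute `threshold`.
#' @export
label_states <- function(scene_values, threshold) {
  if (!is.list(scene_values)) scene_values <- list(scene_values)
  out <- lapply(scene_values, function(v) ifelse(v > threshold, "F", "N"))
  structure(out, threshold = as.numeric(threshold), class = "state_labeling")
}

count_pairs <- function(labelings) {
  counts <- matrix(0L, 2, 2, dimnames = list(current = c("F", "N"),
                                             nxt = c("F", "N")))
  for (lab in labelings) {
    if (length(lab) < 2L) next
    for (i in seq_len(length(lab) - 1L)) {
      counts[lab[i], lab[i + 1L]] <- counts[lab[i], lab[i + 1L]] + 1L
    }
  }
  counts
}

#' Second-order state transitions
#'
#' Counts of consecutive within-scene label pairs (pairs never cross scene
#' boundaries) and the conditional probabilities `P(next | current)`.
#'
#' @param labelings list of per-scene label vectors (or a `state_labeling`).
#' @param group optional group label.
#' @return a `transition_model` (order 2): `counts` 2x2, `probs` rows summing
#'   to 1 (rows without observations are `NA`).
#' @export
second_order <- function(labelings, group = NULL) {
  counts <- count_pairs(labelings)
  if (sum(counts) == 0L) stopf("no consecutive within-scene label pairs")
  probs <- counts / rowSums(counts)
  probs[rowSums(counts) == 0L, ] <- NA_real_
  structure(list(order = 2L, counts = counts, probs = probs, group = group),
            class = "transition_model")
}

#' Third-order state transitions
#'
#' The sub-state of peak pair (i-1, i) is one of `FF`, `NF`, `NN`, `FN`
#' (previous label then current); the transition target is peak i+1's label.
#' Sub-states without observations get `NA` probabilities (undefined, not 0).
#'
#' @inheritParams second_order
#' @return a `transition_model` (order 3): `counts` 4x2, `probs`.
#' @export
third_order <- function(labelings, group = NULL) {
  counts <- matrix(0L, 4, 2, dimnames = list(substate = SUBSTATES,
                                             nxt = c("F", "N")))
  for (lab in labelings) {
    if (length(lab) < 3L) next
    for (i in 3:length(lab)) {
      ss <- paste0(lab[i - 2L], lab[i - 1L])
      counts[ss, lab[i]] <- counts[ss, lab[i]] + 1L
    }
  }
  probs <- counts / rowSums(counts)
  probs[rowSums(counts) == 0L, ] <- NA_real_
  structure(list(order = 3L, counts = counts, probs = probs, group = group),
            class = "transition_model")
}

#' Marginalize third-order counts to second-order counts
#'
#' Summing third-order counts over the first label of the sub-state yields
#' the second-order counts restricted to pairs that have a predecessor (i.e.,
#' excluding each scene's first pair); the identity is exact on that set.
#'
#' @param model an order-3 `transition_model`.
#' @return 2x2 integer count matrix (current x next).
#' @export
marginalize_third_order <- function(model) {
  stopifnot(inherits(model, "transition_model"), model$order == 3L)
  out <- matrix(0L, 2, 2, dimnames = list(current = c("F", "N"),
                                          nxt = c("F", "N")))
  for (ss in SUBSTATES) {
    cur <- substr(ss, 2, 2)
    out[cur, ] <- out[cur, ] + model$counts[ss, ]
  }
  out
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact hypergeometric enumeration with the point-probability rule: the
#' two-sided p is the sum of probabilities of all tables (with the observed
#' margins) whose probability does not exceed the observed table's (up to a
#' 1e-7 relative tolerance for floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return p-value in (0, 1\]; a zero margin gives p = 1 with a warning.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  r <- rowSums(tab); cl <- colSums(tab)
  if (any(r == 0) || any(cl == 0)) {
    warning("zero margin; Fisher p is 1 by convention")
    return(1)
  }
  support <- max(0L, cl[1] - r[2]):min(r[1], cl[1])
  probs <- dhyper(support, r[1], r[2], cl[1])
  p_obs <- probs[match(tab[1, 1], support)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Compare transition models between groups
#'
#' For each conditioning state (or sub-state) the 2x2 table of
#' group x next-state counts is tested with the two-sided Fisher exact test.
#'
#' @param model_a,model_b `transition_model`s of the same order.
#' @return a `group_comparison` data frame: state, the four table cells
#'   (`a_F`, `a_N`, `b_F`, `b_N`) and `p`.
#' @export
fisher_compare <- function(model_a, model_b) {
  stopifnot(inherits(model_a, "transition_model"),
            inherits(model_b, "transition_model"),
            model_a$order == model_b$order)
  states <- rownames(model_a$counts)
  rows <- lapply(states, function(st) {
    tab <- rbind(model_a$counts[st, ], model_b$counts[st, ])
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      if (sum(tab) > 0) warning("zero margin for state ", st,
                                "; Fisher p is 1 by convention")
      1
    } else fisher_exact_2x2(tab)
    data.frame(state = st, a_F = tab[1, 1], a_N = tab[1, 2],
               b_F = tab[2, 1], b_N = tab[2, 2], p = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition model, order %d%s>\n", x$order,
              if (!is.null(x$group)) paste0(", group ", x$group) else ""))
  print(round(x$probs, 3))
  invisible(x)
}
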