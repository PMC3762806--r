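## Preprocessing: raw two-agent trajectories -> filtered interpersonal-distance
## (IPD) series -> scenes satisfying the inclusion rules (>= 4 positive peaks,
## quick detachments removed, scenes cut at strike-like close approaches).

#' Construct a trajectory pair
#'
#' @param time seconds, uniform strictly increasing grid.
#' @param xA,yA,xB,yB agent coordinates in meters.
#' @param match_id,group identifiers.
#' @return a `trajectory_pair` data frame.
#' @export
trajectory_pair <- function(time, xA, yA, xB, yB, match_id = "M1", group = "A") {
  n <- length(time)
  if (!all(lengths(list(xA, yA, xB, yB)) == n)) {
    stopf("all coordinate channels must have the length of time")
  }
  if (!all(is.finite(c(time, xA, yA, xB, yB)))) stopf("coordinates must be finite")
  grid_dt(time)
  traj <- data.frame(time = time, xA = xA, yA = yA, xB = xB, yB = yB)
  class(traj) <- c("trajectory_pair", "data.frame")
  attr(traj, "match_id") <- match_id
  attr(traj, "group") <- group
  traj
}

#' Read a trajectory pair from CSV
#'
#' Expects columns `time_s, xA_m, yA_m, xB_m, yB_m` (or the bare names
#' `time, xA, yA, xB, yB`).
#'
#' @param path CSV file.
#' @param match_id,group identifiers (default: file stem, `"A"`).
#' @return a `trajectory_pair`.
#' @export
read_trajectory_csv <- function(path, match_id = NULL, group = "A") {
  if (!file.exists(path)) stopf("trajectory file not found: %s", path)
  d <- read.csv(path)
  cols <- c("time_s", "xA_m", "yA_m", "xB_m", "yB_m")
  if (!all(cols %in% names(d))) cols <- c("time", "xA", "yA", "xB", "yB")
  if (!all(cols %in% names(d))) {
    stopf("%s lacks columns time_s,xA_m,yA_m,xB_m,yB_m", path)
  }
  trajectory_pair(d[[cols[1]]], d[[cols[2]]], d[[cols[3]]], d[[cols[4]]],
                  d[[cols[5]]],
                  match_id = match_id %||% sub("\\.csv$", "", basename(path)),
                  group = group)
}

#' Write a trajectory pair as CSV
#' @param traj a `trajectory_pair`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  d <- data.frame(time_s = traj$time, xA_m = traj$xA, yA_m = traj$yA,
                  xB_m = traj$xB, yB_m = traj$yB)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Low-pass filter agent positions
#'
#' Zero-phase (forward-backward) Butterworth filtering of every coordinate
#' channel; the default 4th order, 6 Hz cutoff suits 100 Hz motion capture of
#' gross body movement.  Zero-phase application preserves peak timing.
#'
#' @param traj a `trajectory_pair`.
#' @param order filter order (default 4).
#' @param cutoff_hz cutoff frequency, must be below Nyquist (default 6).
#' @param zero_phase apply forward-backward (default) or single-pass.
#' @return filtered `trajectory_pair` (same length, attribute `filtered`).
#' @export
lowpass_positions <- function(traj, order = 4, cutoff_hz = 6, zero_phase = TRUE) {
  stopifnot(inherits(traj, "trajectory_pair"))
  dt <- grid_dt(traj$time)
  fs <- 1 / dt
  if (cutoff_hz >= fs / 2) stopf("cutoff %g Hz is not below Nyquist %g Hz",
                                 cutoff_hz, fs / 2)
  if (nrow(traj) < 3 * order) stopf("need at least %d samples to filter", 3 * order)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  ## odd-reflection padding suppresses filtfilt edge transients (the filter
  ## sees a signal continuous in value and slope at both ends); the pad must
  ## outlast the filter's own transient, set by its slowest pole
  p_max <- max(Mod(polyroot(rev(bf$a))))
  pad <- min(nrow(traj) - 1L, ceiling(log(1e-13) / log(p_max)))
  run <- function(x) {
    if (!zero_phase) return(as.numeric(signal::filter(bf, x)))
    n <- length(x)
    head_pad <- 2 * x[1] - x[(pad + 1L):2]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(pad + 1L):(pad + n)]
  }
  out <- traj
  for (ch in c("xA", "yA", "xB", "yB")) out[[ch]] <- run(traj[[ch]])
  attr(out, "filtered") <- TRUE
  out
}

#' Interpersonal distance series
#'
#' Euclidean distance between the two agents at each sample; symmetric in the
#' agents and non-negative by construction.
#'
#' @param traj a `trajectory_pair`.
#' @return an `ipd_series` data frame with columns `time`, `D` (meters).
#' @export
compute_ipd <- function(traj) {
  stopifnot(inherits(traj, "trajectory_pair"))
  D <- sqrt((traj$xA - traj$xB)^2 + (traj$yA - traj$yB)^2)
  out <- data.frame(time = traj$time, D = D)
  class(out) <- c("ipd_series", "data.frame")
  attr(out, "filtered") <- isTRUE(attr(traj, "filtered"))
  attr(out, "match_id") <- attr(traj, "match_id")
  attr(out, "group") <- attr(traj, "group")
  out
}

#' Find alternating IPD peaks
#'
#' Strict local maxima ("positive peaks": moments of farthest separation that
#' precede approach) and minima ("negative peaks": closest approach preceding
#' detachment), with alternation enforced: between two maxima exactly one
#' minimum is kept (the deepest), and vice versa.  Adjacent extremum pairs
#' whose IPD difference falls below `min_prominence` are pruned (smallest
#' first): measurement wiggle, not approach/detachment movement.
#'
#' @param ipd an `ipd_series` or numeric vector.
#' @param min_prominence minimal peak-to-trough difference in meters
#'   (default 0: keep every strict extremum).
#' @return list with integer index vectors `pos` (maxima) and `neg` (minima).
#' @export
find_ipd_peaks <- function(ipd, min_prominence = 0) {
  D <- if (is.data.frame(ipd)) ipd$D else ipd
  if (length(D) < 3L) stopf("need at least 3 samples")
  ex <- local_extrema(D)
  pk <- enforce_alternation(ex$max, ex$min, D)
  prune_extrema(pk$pos, pk$neg, D, min_prominence)
}

#' Remove quick detachments from a peak list
#'
#' A quick detaching movement is a negative peak followed by a positive peak
#' with an IPD increase greater than `spread_m` within less than `window_s`;
#' both peaks of such a movement are removed and alternation re-enforced.
#'
#' @param peaks list with `pos`, `neg` (from [find_ipd_peaks()]).
#' @param ipd the `ipd_series` the indices refer to.
#' @param spread_m spread threshold in meters (default 1, strict `>`).
#' @param window_s time window in seconds (default 1.5, strict `<`).
#' @return filtered peak list, same structure.
#' @export
remove_quick_detachments <- function(peaks, ipd, spread_m = 1, window_s = 1.5) {
  D <- ipd$D; tm <- ipd$time
  ev <- rbind(
    data.frame(idx = peaks$pos, type = rep("pos", length(peaks$pos))),
    data.frame(idx = peaks$neg, type = rep("neg", length(peaks$neg)))
  )
  ev <- ev[order(ev$idx), , drop = FALSE]
  drop <- logical(nrow(ev))
  if (nrow(ev) >= 2) {
    for (i in seq_len(nrow(ev) - 1L)) {
      if (ev$type[i] == "neg" && ev$type[i + 1L] == "pos") {
        i1 <- ev$idx[i]; i2 <- ev$idx[i + 1L]
        if (D[i2] - D[i1] > spread_m && tm[i2] - tm[i1] < window_s) {
          drop[i] <- drop[i + 1L] <- TRUE
        }
      }
    }
  }
  ev <- ev[!drop, , drop = FALSE]
  enforce_alternation(ev$idx[ev$type == "pos"], ev$idx[ev$type == "neg"], D)
}

#' Split an IPD series into scenes
#'
#' Sequences are maximal runs outside the exclusion intervals.  Within each
#' sequence, alternating peaks are detected, quick detachments removed, and
#' the sequence is cut at strike-like close approaches: negative peaks whose
#' IPD falls below a threshold (absolute `close_m` if given, else the
#' `close_quantile` quantile of the match's negative-peak IPD values).  Each
#' scene runs from its maximum-distance positive peak to the cut (or, for the
#' trailing segment, to the sequence end: a slow detachment); scenes with
#' fewer than `min_pos_peaks` positive peaks are discarded.
#'
#' @param ipd an `ipd_series` (filter positions first; see
#'   [lowpass_positions()]).
#' @param exclusion_intervals `NULL`, or data frame with `start_s`, `end_s`
#'   (disjoint stoppage/occlusion windows).
#' @param close_m absolute close-approach threshold in meters (optional).
#' @param close_quantile quantile of negative-peak IPD used when `close_m` is
#'   `NULL` (default 0.25).
#' @param min_pos_peaks minimal positive peaks per scene (default 4).
#' @param spread_m,window_s quick-detachment rule parameters.
#' @param min_prominence peak-pruning threshold in meters passed to
#'   [find_ipd_peaks()] (default 0.03).
#' @return list of `scene` objects: `match_id`, `scene_id`, `start`/`end`
#'   (1-based sample range into `ipd`, end inclusive), `pos_peaks`/`neg_peaks`
#'   (match sample indices), `time`, `D` (the segment).
#' @export
split_scenes <- function(ipd, exclusion_intervals = NULL, close_m = NULL,
                         close_quantile = 0.25, min_pos_peaks = 4,
                         spread_m = 1, window_s = 1.5, min_prominence = 0.03) {
  stopifnot(inherits(ipd, "ipd_series"))
  n <- nrow(ipd)
  excluded <- rep(FALSE, n)
  if (!is.null(exclusion_intervals) && nrow(exclusion_intervals)) {
    for (r in seq_len(nrow(exclusion_intervals))) {
      excluded <- excluded | (ipd$time >= exclusion_intervals$start_s[r] &
                                ipd$time <= exclusion_intervals$end_s[r])
    }
  }
  runs <- rle(!excluded)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  seqs <- Map(c, starts[runs$values], ends[runs$values])
  seqs <- Filter(function(s) s[2] - s[1] + 1L >= 9L, seqs)

  ## peaks per sequence (match-level indices)
  seq_peaks <- lapply(seqs, function(s) {
    sub <- ipd$D[s[1]:s[2]]
    pk <- find_ipd_peaks(sub, min_prominence = min_prominence)
    pk <- remove_quick_detachments(
      list(pos = pk$pos, neg = pk$neg),
      data.frame(time = ipd$time[s[1]:s[2]], D = sub), spread_m, window_s)
    list(pos = pk$pos + s[1] - 1L, neg = pk$neg + s[1] - 1L)
  })
  all_neg <- unlist(lapply(seq_peaks, `[[`, "neg"))
  if (is.null(close_m)) {
    if (!length(all_neg)) return(list())
    close_m <- as.numeric(quantile(ipd$D[all_neg], close_quantile, names = FALSE))
  }

  scenes <- list()
  sid <- 0L
  for (k in seq_along(seqs)) {
    s <- seqs[[k]]; pk <- seq_peaks[[k]]
    if (length(pk$pos) < min_pos_peaks) next
    cuts <- pk$neg[ipd$D[pk$neg] <= close_m]
    bounds <- c(s[1] - 1L, cuts, if (!length(cuts) || max(cuts) < s[2]) s[2])
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b] + 1L; hi <- bounds[b + 1L]
      pos_in <- pk$pos[pk$pos >= lo & pk$pos <= hi]
      if (!length(pos_in)) next
      start_pk <- pos_in[which.max(ipd$D[pos_in])]
      pos_in <- pos_in[pos_in >= start_pk]
      if (length(pos_in) < min_pos_peaks) next
      neg_in <- pk$neg[pk$neg >= start_pk & pk$neg <= hi]
      sid <- sid + 1L
      sc <- list(match_id = attr(ipd, "match_id"), scene_id = sid,
                 start = start_pk, end = hi,
                 pos_peaks = pos_in, neg_peaks = neg_in,
                 time = ipd$time[start_pk:hi], D = ipd$D[start_pk:hi])
      class(sc) <- "scene"
      scenes[[sid]] <- sc
    }
  }
  scenes
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s/%s> samples %d-%d (%.1f s), %d positive peaks\n",
              x$match_id %||% "?", x$scene_id, x$start, x$end,
              x$time[length(x$time)] - x$time[1], length(x$pos_peaks)))
  invisible(x)
}
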