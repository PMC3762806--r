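test_that("zero-phase Butterworth keeps DC and has the expected band edges", {
  n <- 3000; t <- (0:(n - 1)) / 100
  const <- trajectory_pair(t, rep(2, n), rep(1, n), rep(-1, n), rep(0, n))
  out <- lowpass_positions(const)
  expect_equal(out$xA, rep(2, n), tolerance = 1e-9)

  # amplitude after two passes of a 4th-order 6 Hz filter: closed-form
  # magnitude 1/sqrt(1+(f/6)^8), squared for forward-backward
  amp_at <- function(f_hz) {
    tr <- trajectory_pair(t, sin(2 * pi * f_hz * t), rep(0, n),
                          rep(0, n), rep(0, n))
    mid <- 1000:2000
    max(abs(lowpass_positions(tr)$xA[mid]))
  }
  expect_gt(amp_at(1), 0.99)    # < 1% attenuation at 1 Hz
  expect_lt(amp_at(30), 0.01)   # > 99% attenuation at 30 Hz
  expect_error(lowpass_positions(const, cutoff_hz = 60), "Nyquist")
})

test_that("IPD is the Euclidean distance, symmetric and translation invariant", {
  t <- (0:9) / 100
  tr <- trajectory_pair(t, rep(0, 10), rep(0, 10), rep(3, 10), rep(4, 10))
  expect_equal(compute_ipd(tr)$D, rep(5, 10))
  same <- trajectory_pair(t, rep(1, 10), rep(2, 10), rep(1, 10), rep(2, 10))
  expect_equal(compute_ipd(same)$D, rep(0, 10))
  swapped <- trajectory_pair(t, rep(3, 10), rep(4, 10), rep(0, 10), rep(0, 10))
  expect_equal(compute_ipd(swapped)$D, compute_ipd(tr)$D)
  shifted <- trajectory_pair(t, 7 + tr$xA, -2 + tr$yA, 7 + tr$xB, -2 + tr$yB)
  expect_equal(compute_ipd(shifted)$D, compute_ipd(tr)$D)
})

test_that("alternating IPD peaks are found; monotone series have none", {
  pk <- find_ipd_peaks(c(1, 2, 1, 2, 1))
  expect_equal(pk$pos, c(2L, 4L))
  expect_equal(pk$neg, 3L)
  none <- find_ipd_peaks(c(1, 2, 3, 4, 5))
  expect_length(none$pos, 0)
  expect_length(none$neg, 0)
  # alternation: same-type runs collapse to the most extreme member
  D <- c(1, 3, 2, 4, 1, 2.5, 1)   # two maxima (3, 4) around a shallow min
  pk2 <- find_ipd_peaks(D)
  expect_true(all(diff(sort(c(pk2$pos, pk2$neg))) > 0))
  ev <- sort(c(pk2$pos, pk2$neg))
  types <- ifelse(ev %in% pk2$pos, "p", "n")
  expect_true(all(types[-1] != types[-length(types)]))
})

test_that("quick-detachment rule removes exactly the offending pairs", {
  # minimum 1.0 m at t = 0 rising to 2.2 m at t = 1.0 s: spread 1.2 m in
  # 1000 ms -> removed; same spread in 2000 ms -> kept; 0.8 m in 500 ms -> kept
  build <- function(t_peak, d_min, d_max) {
    # V-shaped series: fall to the minimum at t = 0 .. rise to max at t_peak
    lead <- seq(d_min + 0.5, d_min, length.out = 11)
    rise <- seq(d_min, d_max, length.out = round(t_peak * 100) + 1)
    tail <- seq(d_max, d_max - 0.3, length.out = 11)
    ipd_from_values(c(lead, rise[-1], tail[-1]))
  }
  ipd1 <- build(1.0, 1.0, 2.2)
  pk1 <- find_ipd_peaks(ipd1$D)
  out1 <- remove_quick_detachments(pk1, ipd1)
  expect_length(out1$pos, 0)
  expect_length(out1$neg, 0)

  ipd2 <- build(2.0, 1.0, 2.2)
  out2 <- remove_quick_detachments(find_ipd_peaks(ipd2$D), ipd2)
  expect_length(out2$pos, 1)
  expect_length(out2$neg, 1)

  ipd3 <- build(0.5, 1.0, 1.8)
  out3 <- remove_quick_detachments(find_ipd_peaks(ipd3$D), ipd3)
  expect_length(out3$pos, 1)
  expect_length(out3$neg, 1)
})

test_that("scenes with fewer than four positive peaks are never returned", {
  # three oscillations only
  t <- seq(0, 6, by = 0.01)
  D <- 2 + 0.5 * sin(2 * pi * t / 2)
  scn <- split_scenes(ipd_from_values(D), close_m = 0.5)
  expect_length(scn, 0)
})

test_that("planted strikes cut a match into the planted scenes", {
  set.seed(21)
  for (n_scenes in c(1L, 3L)) {
    regimes <- list(); scenes <- list()
    for (s in seq_len(n_scenes)) {
      rg <- random_scene_regimes(1)
      scenes[[s]] <- length(regimes) + seq_along(rg)
      regimes <- c(regimes, rg)
    }
    spec <- synthetic_spec(regimes, scenes = scenes, noise_sigma = 0.01,
                           seed = 100 + n_scenes)
    mt <- generate_match(spec)
    ipd <- compute_ipd(lowpass_positions(mt$traj))
    scn <- split_scenes(ipd, close_m = default_close_m(spec))
    expect_length(scn, n_scenes)
    expect_true(all(vapply(scn, function(s) length(s$pos_peaks), 0L) >= 4))
    # scenes are disjoint and ordered
    if (length(scn) > 1) {
      for (k in 2:length(scn)) expect_gt(scn[[k]]$start, scn[[k - 1]]$end)
    }
    # boundary recovery: scene starts within one oscillation period of the
    # planted entry peak
    for (k in seq_along(scn)) {
      planted_start <- mt$truth$scenes[[k]]$peak_index[1]
      expect_lt(abs(scn[[k]]$start - planted_start),
                spec$oscillation_period * spec$sampling_rate + 1)
    }
  }
})

test_that("exclusion intervals split sequences and drop covered scenes", {
  set.seed(22)
  regimes <- c(random_scene_regimes(1), random_scene_regimes(1))
  spec <- synthetic_spec(regimes, scenes = list(1L, 2L), noise_sigma = 0.01,
                         seed = 5)
  mt <- generate_match(spec)
  ipd <- compute_ipd(lowpass_positions(mt$traj))
  base <- split_scenes(ipd, close_m = default_close_m(spec))
  expect_length(base, 2)
  # exclude an interval covering the first scene entirely
  first_end <- ipd$time[base[[1]]$end]
  excl <- data.frame(start_s = 0, end_s = first_end + 0.5)
  cut <- split_scenes(ipd, exclusion_intervals = excl,
                      close_m = default_close_m(spec))
  expect_length(cut, 1)
  expect_gt(cut[[1]]$start, base[[1]]$end)
})

test_that("trajectory CSV round trip preserves the data", {
  set.seed(3)
  rg <- random_scene_regimes(1)
  spec <- synthetic_spec(rg, seed = 8)
  mt <- generate_match(spec, match_id = "m7", group = "expert")
  p <- tempfile(fileext = ".csv")
  write_trajectory_csv(mt$traj, p)
  back <- read_trajectory_csv(p, match_id = "m7", group = "expert")
  expect_equal(back$xA, mt$traj$xA, tolerance = 1e-12)
  expect_equal(attr(back, "group"), "expert")
  expect_error(read_trajectory_csv(tempfile()), "not found")
})
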