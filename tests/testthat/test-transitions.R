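test_that("peak histograms use fixed left-closed bins over [0,1]", {
  h <- peak_histogram(c(0.41, 0.43, 0.77, runif(10, 0.1, 0.2)), min_peaks = 10)
  expect_equal(h$counts[which(h$breaks == 0.40)], 2L)
  expect_equal(h$counts[which(h$breaks == 0.75)], 1L)
  expect_equal(sum(h$counts), 13L)
  expect_error(peak_histogram(runif(5)), "pool")
  expect_error(peak_histogram(c(runif(10), 1.2)), "\\[0, 1\\]")
  # exact bin edges go to the bin they open (left-closed)
  h2 <- peak_histogram(rep(0.40, 10))
  expect_equal(h2$counts[which(h2$breaks == 0.40)], 10L)
})

test_that("bimodal mixtures yield two modal bins and the planted boundary", {
  set.seed(12)
  labs <- simulate_markov_labels(c(FF = 0.7, NF = 0.5, NN = 0.3, FN = 0.5),
                                 40, 10, seed = 2)
  peaks <- generate_label_peaks(labs, mode_f = 0.75, mode_n = 0.4, seed = 3)
  h <- peak_histogram(unlist(peaks))
  thr <- find_threshold(h)
  expect_lt(abs(as.numeric(thr) - attr(peaks, "boundary")), 0.075)
  modes <- attr(thr, "mode_bins")
  expect_lt(abs(h$mids[modes[1]] - 0.4), 0.075)
  expect_lt(abs(h$mids[modes[2]] - 0.75), 0.075)
})

test_that("threshold picks the interior minimum with the stated tie rule", {
  mk_hist <- function(counts, width = 0.2) {
    breaks <- seq(0, by = width, length.out = length(counts) + 1)
    structure(list(breaks = breaks,
                   mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                   counts = as.integer(counts)), class = "retmap_hist")
  }
  thr <- find_threshold(mk_hist(c(5, 1, 6)))
  expect_equal(as.numeric(thr), 0.3)
  # tie between interior minima: the bin nearer the mode midpoint wins
  thr2 <- find_threshold(mk_hist(c(9, 3, 5, 3, 3, 8)))
  expect_equal(attr(thr2, "min_bin"), 4L)
  expect_error(find_threshold(mk_hist(c(1, 4, 8, 4, 1))), "unimodal")
})

test_that("labels split at the threshold with equality mapping to N", {
  lab <- label_states(list(c(0.7, 0.4)), 0.5)
  expect_equal(lab[[1]], c("F", "N"))
  expect_equal(label_states(list(c(0.8, 0.9)), 0.5)[[1]], c("F", "F"))
  expect_equal(label_states(list(0.5), 0.5)[[1]], "N")
})

test_that("second-order transitions count within-scene pairs only", {
  tm <- second_order(list(c("F", "F", "N", "N", "F")))
  expect_equal(unname(tm$probs["F", ]), c(0.5, 0.5))
  expect_equal(unname(tm$probs["N", ]), c(0.5, 0.5))
  expect_equal(sum(tm$counts), 4L)
  allf <- second_order(list(c("F", "F", "F")))
  expect_equal(unname(allf$probs["F", "F"]), 1)
  expect_true(all(is.na(allf$probs["N", ])))
  # no cross-scene pairs: two scenes of two labels yield two pairs, not three
  two <- second_order(list(c("F", "N"), c("N", "F")))
  expect_equal(sum(two$counts), 2L)
  expect_error(second_order(list("F")), "no consecutive")
  ok <- rowSums(tm$counts) > 0
  expect_equal(unname(rowSums(tm$probs)[ok]), rep(1, sum(ok)))
})

test_that("third-order transitions respect the sub-state overlap structure", {
  tm <- third_order(list(c("F", "F", "N")))
  expect_equal(unname(tm$probs["FF", "N"]), 1)
  expect_true(all(is.na(tm$probs["NN", ])))
  expect_equal(sum(tm$counts), 1L)
  # marginalizing third-order counts reproduces second-order counts on the
  # pairs that have a predecessor (drop each scene's first label)
  labs <- simulate_markov_labels(c(FF = 0.8, NF = 0.6, NN = 0.25, FN = 0.45),
                                 30, 9, seed = 4)
  tm3 <- third_order(labs)
  trimmed <- lapply(labs, function(l) l[-1])
  tm2 <- second_order(trimmed)
  expect_identical(marginalize_third_order(tm3), tm2$counts)
})

test_that("relabeling F and N permutes the transition matrices accordingly", {
  labs <- simulate_markov_labels(c(FF = 0.7, NF = 0.4, NN = 0.2, FN = 0.6),
                                 20, 8, seed = 5)
  swap <- lapply(labs, function(l) ifelse(l == "F", "N", "F"))
  a <- second_order(labs)$counts
  b <- second_order(swap)$counts
  expect_equal(unname(b), unname(a[c(2, 1), c(2, 1)]))
  a3 <- third_order(labs)$counts
  b3 <- third_order(swap)$counts
  expect_equal(unname(b3), unname(a3[c("NN", "FN", "FF", "NF"), c(2, 1)]))
})

test_that("Fisher exact p matches enumeration, closed forms and fisher.test", {
  tab <- matrix(c(10, 3, 5, 12), 2)
  expect_lt(abs(fisher_exact_2x2(tab) - fisher_oracle(tab)), 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(7, 7, 2, 2), 2)), 1)
  # extreme diagonal table: p = 2 / choose(10, 5)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(p0, 1)
  set.seed(6)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 6), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact_2x2(t2), fisher.test(t2)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("group comparison builds the per-state tables with Fisher p", {
  labs_a <- simulate_markov_labels(c(FF = 0.85, NF = 0.7, NN = 0.3, FN = 0.5),
                                   60, 10, seed = 7)
  labs_b <- simulate_markov_labels(c(FF = 0.4, NF = 0.3, NN = 0.7, FN = 0.5),
                                   60, 10, seed = 8)
  cmp <- fisher_compare(second_order(labs_a, "A"), second_order(labs_b, "B"))
  expect_equal(cmp$state, c("F", "N"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  # margins equal the group transition counts
  a <- second_order(labs_a)$counts
  expect_equal(cmp$a_F + cmp$a_N, unname(rowSums(a)))
  # strongly different chains are detected
  expect_lt(max(cmp$p), 1e-3)
  cmp3 <- fisher_compare(third_order(labs_a, "A"), third_order(labs_b, "B"))
  expect_equal(cmp3$state, c("FF", "NF", "NN", "FN"))
})
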