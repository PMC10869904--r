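rmap <- function(vals, state = "raw", ...) {
  if (is.null(rownames(vals)))
    rownames(vals) <- channel_table()$name[seq_len(nrow(vals))]
  relevance_map(vals, state = state, ...)
}

test_that("averaging is a node-wise mean over the selected maps", {
  m0 <- rmap(matrix(0, 2, 5), correct = TRUE)
  m1 <- rmap(matrix(1, 2, 5), correct = TRUE)
  avg <- average_maps(list(m0, m1))
  expect_equal(unclass(avg), matrix(0.5, 2, 5), ignore_attr = TRUE)
  # single map: itself
  expect_equal(unclass(average_maps(list(m1))), matrix(1, 2, 5),
               ignore_attr = TRUE)
  # misclassified maps are excluded under the default selection
  mbad <- rmap(matrix(100, 2, 5), correct = FALSE)
  avg2 <- average_maps(list(m0, m1, mbad))
  expect_equal(attr(avg2, "n_averaged"), 2)
  expect_equal(max(unclass(avg2)), 0.5)
  expect_equal(attr(average_maps(list(m0, m1, mbad), "all"), "n_averaged"), 3)
  expect_error(average_maps(list(mbad)), "no maps")
  # rectification clips negative relevance before averaging
  mneg <- rmap(matrix(-2, 2, 5), correct = TRUE)
  expect_equal(unclass(average_maps(list(m1, mneg))),
               matrix(0.5, 2, 5), ignore_attr = TRUE)
  expect_equal(unclass(average_maps(list(m1, mneg), rectify = FALSE)),
               matrix(-0.5, 2, 5), ignore_attr = TRUE)
})

test_that("smoothing: constant series unchanged, impulse gives 25/50/25", {
  const <- rmap(matrix(3, 1, 11))
  expect_equal(unclass(smooth_rs(const)), matrix(3, 1, 11),
               ignore_attr = TRUE)
  imp <- matrix(0, 1, 11); imp[1, 6] <- 1
  one <- smooth_rs(rmap(imp), smoothing_spec(repetitions = 1))
  expect_equal(unclass(one)[1, 4:8], c(0, 0.25, 0.5, 0.25, 0),
               ignore_attr = TRUE)
  expect_equal(map_state(one), "smoothed")
})

test_that("three passes equal one pass of the kernel's 3-fold self-convolution", {
  k <- c(0.25, 0.5, 0.25)
  k3 <- convolve(convolve(k, rev(k), type = "open"), rev(k), type = "open")
  expect_length(k3, 7)         # independent 7-tap kernel by polynomial product
  imp <- matrix(0, 1, 21); imp[1, 11] <- 1
  three <- smooth_rs(rmap(imp), smoothing_spec(repetitions = 3))
  expect_equal(unclass(three)[1, 8:14], k3, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("renormalized boundary preserves a constant and stays a simplex", {
  x <- matrix(runif(101), 1, 101)
  sm <- smooth_rs(rmap(x))
  # kernel is an average: bounded by the input range
  expect_gte(min(sm), min(x)); expect_lte(max(sm), max(x))
  expect_error(smooth_rs(scale_rs(smooth_rs(rmap(x)))), "already scaled")
})

test_that("min-max scaling maps to [0,1] with documented degenerate case", {
  m <- rmap(matrix(c(2, 4, 6, 2, 2, 6), 2, 3, byrow = TRUE),
            state = "smoothed")
  sc <- scale_rs(m)
  expect_equal(unclass(sc)[1, ], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(range(sc), c(0, 1))
  # already-[0,1] map with global min 0 and max 1 is unchanged
  m01 <- rmap(matrix(c(0, 0.3, 1, 0.2), 2, 2), state = "smoothed")
  expect_equal(unclass(scale_rs(m01)), unclass(m01), ignore_attr = TRUE)
  # per-channel scope scales each row separately
  expect_equal(unclass(scale_rs(m, scope = "channel"))[2, ], c(0, 0, 1),
               ignore_attr = TRUE)
  expect_warning(sc0 <- scale_rs(rmap(matrix(5, 2, 3), state = "smoothed")),
                 "constant")
  expect_equal(unclass(sc0), matrix(0, 2, 3), ignore_attr = TRUE)
  expect_error(scale_rs(rmap(matrix(1:6, 2, 3))), "smoothed")
})

full_scaled_map <- function(vals) {
  rownames(vals) <- channel_table()$name
  relevance_map(vals, state = "scaled")
}

test_that("contribution shares are exact on structured maps", {
  uni <- full_scaled_map(matrix(1, 18, 101))
  ct <- aggregate_contributions(uni)
  expect_equal(ct$channel$share, rep(100 / 18, 18))
  expect_equal(ct$joint$share, rep(100 / 3, 3))
  expect_equal(ct$plane$share, rep(100 / 3, 3))
  expect_equal(ct$early_share, 22 / 101 * 100, tolerance = 1e-9)

  knee_only <- matrix(0, 18, 101)
  knee_rows <- channel_table()$joint == "knee"
  knee_only[knee_rows, ] <- 1
  ct2 <- aggregate_contributions(full_scaled_map(knee_only))
  expect_equal(ct2$joint$share[ct2$joint$joint == "knee"], 100)
  expect_equal(ct2$joint$share[ct2$joint$joint == "ankle"], 0)
  expect_equal(ct2$joint$share[ct2$joint$joint == "hip"], 0)
  expect_error(aggregate_contributions(full_scaled_map(matrix(0, 18, 101))),
               "zero total")
})

test_that("every partition's shares sum to 100 on random maps", {
  set.seed(12)
  for (i in 1:25) {
    ct <- aggregate_contributions(full_scaled_map(matrix(runif(18 * 101),
                                                         18, 101)))
    expect_lt(abs(sum(ct$channel$share) - 100), 1e-6)
    expect_lt(abs(sum(ct$joint$share) - 100), 1e-6)
    expect_lt(abs(sum(ct$plane$share) - 100), 1e-6)
    expect_lt(abs(sum(ct$phase$share) - 100), 1e-6)
    expect_true(all(ct$channel$share >= 0))
  }
})

test_that("high-RS extraction reports maximal runs above the cutoff", {
  vals <- matrix(0.1, 18, 101)
  vals[7, 16:20] <- 0.9          # knee_sagittal_angle, nodes 15..19
  hs <- extract_high_rs(full_scaled_map(vals), 0.7)
  expect_equal(hs$count, 5)
  expect_equal(hs$runs$channel, "knee_sagittal_angle")
  expect_equal(hs$runs$start, 15)
  expect_equal(hs$runs$end, 19)
  # all values at or below threshold: empty set (strict inequality)
  vals2 <- matrix(0.7, 18, 101)
  expect_equal(extract_high_rs(full_scaled_map(vals2), 0.7)$count, 0)
  expect_error(extract_high_rs(rmap(matrix(1, 2, 3)), 0.7), "scaled")
})

test_that("run extraction matches a brute-force node scan on random maps", {
  set.seed(31)
  for (i in 1:10) {
    vals <- matrix(runif(18 * 101), 18, 101)
    hs <- extract_high_rs(full_scaled_map(vals), 0.7)
    expect_equal(hs$count, sum(vals > 0.7))
    # every reported node is above threshold, every boundary is maximal
    for (r in seq_len(nrow(hs$runs))) {
      chn <- which(channel_table()$name == hs$runs$channel[r])
      nodes <- (hs$runs$start[r]:hs$runs$end[r]) + 1L
      expect_true(all(vals[chn, nodes] > 0.7))
      if (hs$runs$start[r] > 0) expect_lte(vals[chn, hs$runs$start[r]], 0.7)
      if (hs$runs$end[r] < 100) expect_lte(vals[chn, hs$runs$end[r] + 2L], 0.7)
    }
  }
})
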