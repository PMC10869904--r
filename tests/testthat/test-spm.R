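test_that("paired-t trajectory matches the t.test oracle and hand values", {
  set.seed(5)
  a <- matrix(rnorm(8 * 20), 8, 20)
  b <- matrix(rnorm(8 * 20), 8, 20)
  tt <- paired_t_trajectory(a, b)
  expect_equal(tt$t, paired_t_oracle(a, b), tolerance = 1e-10)
  expect_equal(tt$df, 7)
  # single node, d = {1,2,3}: t = 2 / (1/sqrt(3)) = 3.464, df = 2
  a1 <- matrix(c(2, 3, 4), 3, 1); b1 <- matrix(c(1, 1, 1), 3, 1)
  t1 <- paired_t_trajectory(a1, b1)
  expect_equal(t1$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(t1$df, 2)
  # antisymmetry and the degenerate cases
  expect_equal(paired_t_trajectory(b, a)$t, -tt$t)
  expect_true(all(paired_t_trajectory(a, a)$zero_variance))
  expect_error(paired_t_trajectory(a[1, , drop = FALSE],
                                   b[1, , drop = FALSE]), "at least 2")
})

test_that("FWHM estimator is monotone in smoothness", {
  set.seed(6)
  r <- matrix(rnorm(10 * 51), 10, 51)
  f_raw <- estimate_fwhm(r)
  # linear upsampling (x2) makes the field strictly smoother in node units
  up <- t(apply(r, 1, function(x) approx(seq_along(x), x,
                                         n = 2 * length(x) - 1)$y))
  expect_gt(estimate_fwhm(up), f_raw)
  # white noise vs the same noise smoothed: repeated-seed majority
  wins <- 0L
  for (s in 1:7) {
    set.seed(s)
    w <- matrix(rnorm(8 * 101), 8, 101)
    sm <- t(apply(w, 1, function(x) stats::filter(x, rep(1 / 7, 7),
                                                  sides = 2, circular = TRUE)))
    if (estimate_fwhm(sm) > estimate_fwhm(w)) wins <- wins + 1L
  }
  expect_gt(wins, 3)
  # constant-in-node residuals: capped, not infinite
  const <- matrix(rep(rnorm(5), 101), 5, 101)
  expect_lte(estimate_fwhm(const), 100 * 101)
  expect_gt(estimate_fwhm(const), 101)
  expect_error(estimate_fwhm(matrix(1, 3, 1)), "2 nodes")
})

test_that("RFT threshold obeys the ordering law and its limits", {
  for (df in c(3, 5, 9, 20, 55)) {
    prev <- Inf
    for (fwhm in c(2, 5, 10, 20, 50, 1e6)) {
      u <- rft_threshold(df, fwhm, 101, 0.05)
      lo <- qt(1 - 0.025, df)
      hi <- qt(1 - 0.05 / (2 * 101), df)      # lattice Bonferroni
      expect_gte(u, lo - 1e-12)
      expect_lte(u, hi + 1e-12)
      expect_lte(u, prev + 1e-12)             # nonincreasing in fwhm
      prev <- u
    }
    # infinitely smooth field: one resel, pointwise quantile
    expect_equal(rft_threshold(df, 1e12, 101, 0.05), qt(1 - 0.025, df),
                 tolerance = 1e-6)
  }
  expect_error(rft_threshold(9, 10, 101, alpha = 1.5), "alpha")
  expect_error(rft_threshold(9, -1, 101), "fwhm")
})

test_that("permutation threshold is deterministic and bounded below", {
  set.seed(9)
  d <- null_fields(10, 51, 10)
  t1 <- permutation_threshold(d, alpha = 0.05, n_perm = 300, seed = 4)
  t2 <- permutation_threshold(d, alpha = 0.05, n_perm = 300, seed = 4)
  expect_identical(t1, t2)
  # alpha = 1: the distribution minimum
  tmin <- permutation_threshold(d, alpha = 1, n_perm = 300, seed = 4)
  expect_lte(tmin, t1)
  expect_warning(permutation_threshold(d[1:3, ], 0.05, 100, 1), "coarse")
})

test_that("permutation and RFT thresholds agree on smooth null fields", {
  rel_diff <- vapply(1:5, function(s) {
    set.seed(s)
    d <- null_fields(12, 101, 12)
    u_perm <- permutation_threshold(d, 0.05, n_perm = 800, seed = s)
    fw <- estimate_fwhm(sweep(d, 2, colMeans(d)))
    u_rft <- rft_threshold(11, fw, 101, 0.05)
    abs(u_perm - u_rft) / u_rft
  }, numeric(1))
  expect_gte(sum(rel_diff < 0.10), 3)   # majority within 10% relative
})

test_that("effect size transform matches its closed form", {
  expect_equal(effect_size_r(0, 9), 0)
  expect_equal(effect_size_r(3, 9), sqrt(9 / 18), tolerance = 1e-12)
  expect_equal(effect_size_r(Inf, 9), 1)
  expect_equal(effect_size_r(1e8, 9), 1, tolerance = 1e-9)
  expect_equal(as.character(effect_size_bands(c(0.2, 0.6, 0.9))),
               c("small", "medium", "large"))
})

test_that("spm_paired_t flags clusters exactly where |t| crosses t_crit", {
  set.seed(13)
  n <- 14
  a <- null_fields(n, 101, 10)
  b <- null_fields(n, 101, 10)
  b[, 41:50] <- b[, 41:50] + 2.5       # strong localized shift
  res <- spm_paired_t(a, b)
  above <- which(abs(res$t) > res$t_crit) - 1L
  expect_setequal(nodes_of_runs <- unlist(Map(seq, res$clusters$start,
                                              res$clusters$end)), above)
  expect_true(any(res$clusters$start <= 45 & res$clusters$end >= 45))
  expect_equal(res$df, n - 1)
})

test_that("concordance computes Jaccard and coverage per channel", {
  mk_spm <- function(cluster_start, cluster_end) {
    structure(list(t = numeric(101), df = 9, fwhm = 10, t_crit = 3,
                   alpha = 0.05, method = "rft",
                   clusters = data.frame(start = cluster_start,
                                         end = cluster_end)),
              class = "spm_result")
  }
  mk_hs <- function(channel, start, end) {
    structure(list(threshold = 0.7, count = end - start + 1,
                   runs = data.frame(channel = channel, start = start,
                                     end = end),
                   n_nodes = 101), class = "high_rs_set")
  }
  # identical sets
  cc <- concordance(mk_hs("knee_sagittal_angle", 15, 25),
                    list(knee_sagittal_angle = mk_spm(15, 25)))
  expect_equal(cc$jaccard, 1.0)
  # disjoint sets
  cc0 <- concordance(mk_hs("knee_sagittal_angle", 0, 5),
                     list(knee_sagittal_angle = mk_spm(50, 60)))
  expect_equal(cc0$jaccard, 0.0)
  # RS run 10-20 (11 nodes), cluster 15-25 (11 nodes): intersection is the
  # 6 nodes 15..20, union 16 nodes, so Jaccard = 6/16
  cc2 <- concordance(mk_hs("knee_sagittal_angle", 10, 20),
                     list(knee_sagittal_angle = mk_spm(15, 25)))
  expect_equal(cc2$jaccard, 6 / 16, tolerance = 1e-12)
  expect_equal(cc2$rs_coverage, 6 / 11)
  expect_equal(cc2$spm_coverage, 6 / 11)
})

test_that("subject class means collapse trials within subject and class", {
  d <- tiny_dataset(n_subjects = 3, n_trials = 4, seed = 17)
  m <- subject_class_means(d)
  expect_equal(dim(m$before_fatigue), c(3, 18, 101))
  rows <- which(d$subject == 2 & d$klass == "after_fatigue")
  expect_equal(m$after_fatigue[2, 5, ],
               colMeans(d$data[rows, 5, ]), tolerance = 1e-12)
})
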