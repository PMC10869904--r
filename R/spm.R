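#' Node-wise paired-samples t trajectory
#'
#' For matched matrices `a`, `b` (subject x node; row i of both matrices is
#' the same subject, typically that subject's trial-mean waveform before and
#' after the intervention), computes `t = mean(d) / (sd(d)/sqrt(n))` per node
#' with `d = a - b` and `df = n - 1`. Nodes with zero difference variance
#' yield `+/-Inf` (or `NaN` when the mean difference is also zero) and are
#' flagged; they are excluded from threshold estimation downstream.
#'
#' @param a,b numeric matrices, same dimensions, matched rows.
#' @return List with `t` (per node), `df`, `diffs` (the difference matrix)
#'   and `zero_variance` (logical per node).
#' @export
paired_t_trajectory <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("'a' and 'b' must have identical dimensions", call. = FALSE)
  n <- nrow(a)
  if (n < 2L) stop("need at least 2 matched subjects", call. = FALSE)
  d <- a - b
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  zv <- sdv == 0
  tval <- mu / (sdv / sqrt(n))
  list(t = tval, df = n - 1L, diffs = d, zero_variance = zv)
}

#' Estimate residual field smoothness (FWHM, in nodes)
#'
#' Standard 1-D random-field smoothness estimator: residuals are normalised
#' node-wise to unit sum of squares, the squared gradient of the normalised
#' residuals is summed over observations per inter-node gap, and the
#' per-gap FWHM `sqrt(4 log 2 / lambda)` is combined over the field
#' reciprocally (resels add). Smoother fields give larger FWHM. Constant
#' fields would give infinite FWHM; the estimate is capped at
#' `100 * n_nodes`.
#'
#' @param residuals matrix (observation x node), e.g. differences minus their
#'   node means.
#' @return FWHM in node units (scalar > 0).
#' @export
estimate_fwhm <- function(residuals) {
  if (!is.matrix(residuals) || ncol(residuals) < 2L)
    stop("'residuals' must be a matrix with at least 2 nodes", call. = FALSE)
  n_nodes <- ncol(residuals)
  ssq <- colSums(residuals^2)
  ssq[ssq == 0] <- Inf
  D <- sweep(residuals, 2, sqrt(ssq), "/")
  G <- D[, -1L, drop = FALSE] - D[, -n_nodes, drop = FALSE]
  v <- colSums(G^2)
  v[!is.finite(v) | v <= 0] <- .Machine$double.eps
  fwhm_per_gap <- sqrt(4 * log(2) / v)
  fwhm <- length(fwhm_per_gap) / sum(1 / fwhm_per_gap)
  min(fwhm, 100 * n_nodes)
}

# 1-D Euler-characteristic density of a t field at height u
ec_density_t <- function(u, df)
  sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)

#' Random-field-theory critical threshold for a 1-D t field
#'
#' Smallest `u` at which the expected Euler characteristic of the two-tailed
#' excursion set, `2 * (P(T > u) + resels * rho1(u))` with
#' `resels = (n_nodes - 1) / fwhm`, falls to `alpha`. The result is floored
#' at the pointwise two-tailed t quantile (the infinitely-smooth limit) and
#' capped at the Bonferroni threshold over the `n_nodes` lattice points,
#' which is a valid family-wise bound for the sampled field and tighter than
#' the continuum correction once `fwhm` approaches the node spacing.
#'
#' @param df degrees of freedom (>= 1).
#' @param fwhm field smoothness in nodes (> 0).
#' @param n_nodes number of field nodes.
#' @param alpha family-wise error level in (0, 1).
#' @return Critical t value (scalar).
#' @export
rft_threshold <- function(df, fwhm, n_nodes, alpha = 0.05) {
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  if (fwhm <= 0) stop("'fwhm' must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  resels <- (n_nodes - 1) / fwhm
  lo <- stats::qt(1 - alpha / 2, df)                    # pointwise floor
  hi <- stats::qt(1 - alpha / (2 * n_nodes), df)        # lattice Bonferroni
  fn <- function(u) 2 * (stats::pt(u, df, lower.tail = FALSE) +
                           resels * ec_density_t(u, df)) - alpha
  if (fn(lo) <= 0) return(lo)
  if (fn(hi) >= 0) return(hi)
  stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
}

#' Sign-flip permutation threshold for the max-|t| statistic
#'
#' Nonparametric cross-check of [rft_threshold()]: under the paired null the
#' sign of each subject's difference curve is exchangeable, so random sign
#' flips generate the null distribution of the field maximum of |t|. Returns
#' its `(1 - alpha)` quantile.
#'
#' @param paired_diffs matrix (subject x node) of difference curves.
#' @param alpha family-wise level.
#' @param n_perm number of random sign-flip draws (>= 100).
#' @param seed integer seed.
#' @return Critical |t| value (scalar).
#' @export
permutation_threshold <- function(paired_diffs, alpha = 0.05, n_perm = 1000L,
                                  seed = 1L) {
  stopifnot(is.matrix(paired_diffs))
  n <- nrow(paired_diffs)
  if (n_perm < 100L) stop("'n_perm' must be >= 100", call. = FALSE)
  if (2^n < 1 / alpha)
    warning("only 2^", n, " distinct sign patterns; threshold at alpha = ",
            alpha, " is coarse", call. = FALSE)
  maxt <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      d <- s * paired_diffs
      mu <- colMeans(d)
      sdv <- sqrt((colSums(d^2) - n * mu^2) / (n - 1))
      tv <- abs(mu / (sdv / sqrt(n)))
      max(tv[is.finite(tv)])
    }, numeric(1))
  })
  unname(stats::quantile(maxt, 1 - alpha, type = 7))
}

#' Rosenthal effect size: t to Pearson r
#'
#' `r = sqrt(t^2 / (t^2 + df))`, applied node-wise; a bounded monotone
#' transform of |t| with `r -> 1` as `t -> Inf`.
#'
#' @param t t value(s).
#' @param df degrees of freedom (>= 1).
#' @return Effect size(s) in `[0, 1)` (1 for infinite t).
#' @export
effect_size_r <- function(t, df) {
  if (df < 1) stop("'df' must be >= 1", call. = FALSE)
  ifelse(is.infinite(t), 1, sqrt(t^2 / (t^2 + df)))
}

#' Band an effect-size trajectory into regions
#'
#' @param r effect sizes in `[0, 1]`.
#' @param cutoffs two increasing cutoffs (default 0.5 and 0.8).
#' @return Factor per node with levels `small` (< first cutoff), `medium`
#'   and `large` (> second cutoff).
#' @export
effect_size_bands <- function(r, cutoffs = c(0.5, 0.8)) {
  stopifnot(length(cutoffs) == 2L, cutoffs[1] < cutoffs[2])
  cut(r, breaks = c(-Inf, cutoffs, Inf),
      labels = c("small", "medium", "large"))
}

supra_clusters <- function(tval, t_crit) {
  above <- is.finite(tval) & abs(tval) > t_crit
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep] - 1L, end = ends[keep] - 1L)
}

#' Full 1-D SPM paired-t test on one channel
#'
#' Combines [paired_t_trajectory()], [estimate_fwhm()] on the mean-centred
#' differences, the critical threshold (`"rft"` default, or `"permutation"`),
#' supra-threshold clusters, and the Rosenthal effect-size trajectory.
#'
#' @inheritParams paired_t_trajectory
#' @param alpha family-wise significance level.
#' @param method `"rft"` or `"permutation"`.
#' @param n_perm,seed passed to [permutation_threshold()] when used.
#' @return An `spm_result`: list with `t`, `df`, `fwhm`, `t_crit`, `alpha`,
#'   `method`, `clusters` (data.frame of 0-based inclusive node runs with
#'   `|t| > t_crit`), `effect_r`, `bands` and `zero_variance`.
#' @export
spm_paired_t <- function(a, b, alpha = 0.05, method = c("rft", "permutation"),
                         n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  tt <- paired_t_trajectory(a, b)
  resid <- sweep(tt$diffs, 2, colMeans(tt$diffs))
  fwhm <- estimate_fwhm(resid)
  t_crit <- if (method == "rft")
    rft_threshold(tt$df, fwhm, length(tt$t), alpha)
  else permutation_threshold(tt$diffs, alpha, n_perm, seed)
  structure(list(t = tt$t, df = tt$df, fwhm = fwhm, t_crit = t_crit,
                 alpha = alpha, method = method,
                 clusters = supra_clusters(tt$t, t_crit),
                 effect_r = effect_size_r(tt$t, tt$df),
                 bands = effect_size_bands(effect_size_r(tt$t, tt$df)),
                 zero_variance = tt$zero_variance),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("spm_result: df=%d fwhm=%.1f t_crit=%.3f (%s, alpha=%g), %d cluster(s)\n",
              x$df, x$fwhm, x$t_crit, x$method, x$alpha, nrow(x$clusters)))
  invisible(x)
}

#' Per-subject class-mean waveforms for the paired design
#'
#' Collapses a dataset's trials to one mean waveform per subject, class and
#' channel — the pairing unit of the SPM analysis.
#'
#' @param dataset a `landing_dataset`.
#' @return List of two arrays `before_fatigue`, `after_fatigue`, each
#'   subject x channel x node (subjects in sorted order).
#' @export
subject_class_means <- function(dataset) {
  stopifnot(inherits(dataset, "landing_dataset"))
  subs <- sort(unique(dataset$subject))
  out <- lapply(class_levels(), function(cls) {
    arr <- array(NA_real_, dim = c(length(subs), dim(dataset$data)[2],
                                   dim(dataset$data)[3]),
                 dimnames = list(NULL, dimnames(dataset$data)[[2]], NULL))
    for (i in seq_along(subs)) {
      rows <- which(dataset$subject == subs[i] & dataset$klass == cls)
      arr[i, , ] <- apply(dataset$data[rows, , , drop = FALSE], c(2, 3), mean)
    }
    arr
  })
  stats::setNames(out, class_levels())
}

#' SPM paired-t analysis of every channel of a dataset
#'
#' @param dataset a `landing_dataset`.
#' @param alpha,method,n_perm,seed passed to [spm_paired_t()].
#' @return Named list of `spm_result`, one per channel (canonical order).
#' @export
spm_dataset <- function(dataset, alpha = 0.05, method = "rft",
                        n_perm = 1000L, seed = 1L) {
  means <- subject_class_means(dataset)
  ch <- channel_table()
  out <- lapply(seq_len(nrow(ch)), function(c)
    spm_paired_t(means$before_fatigue[, c, ], means$after_fatigue[, c, ],
                 alpha = alpha, method = method, n_perm = n_perm,
                 seed = stage_seed(seed, c)))
  stats::setNames(out, ch$name)
}

nodes_of_runs <- function(runs) {
  if (!nrow(runs)) return(integer(0))
  unlist(Map(seq, runs$start, runs$end), use.names = FALSE)
}

#' Concordance between high-relevance regions and SPM clusters
#'
#' Quantifies, per channel, how well the regions the explanation marks as
#' highly relevant coincide with the regions where the class difference is
#' statistically significant: Jaccard index of the two node sets plus
#' coverage fractions in both directions.
#'
#' @param high_rs a [extract_high_rs()] set.
#' @param spm named list of `spm_result` per channel (see [spm_dataset()]),
#'   on the same node grid.
#' @return A data.frame with one row per channel: node counts, Jaccard and
#'   the two coverages (`NA` where both sets are empty).
#' @export
concordance <- function(high_rs, spm) {
  stopifnot(inherits(high_rs, "high_rs_set"))
  rows <- lapply(names(spm), function(chn) {
    res <- spm[[chn]]
    if (length(res$t) != high_rs$n_nodes)
      stop("node grid mismatch for channel ", chn, call. = FALSE)
    rs_nodes <- nodes_of_runs(high_rs$runs[high_rs$runs$channel == chn, ])
    spm_nodes <- nodes_of_runs(res$clusters)
    inter <- length(intersect(rs_nodes, spm_nodes))
    uni <- length(union(rs_nodes, spm_nodes))
    data.frame(channel = chn, n_rs = length(rs_nodes),
               n_spm = length(spm_nodes),
               jaccard = if (uni > 0) inter / uni else NA_real_,
               rs_coverage = if (length(rs_nodes)) inter / length(rs_nodes)
                             else NA_real_,
               spm_coverage = if (length(spm_nodes)) inter / length(spm_nodes)
                              else NA_real_)
  })
  do.call(rbind, rows)
}
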