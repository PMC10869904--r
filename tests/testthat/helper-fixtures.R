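# shared fixtures: tiny datasets, hand-built networks, independent oracles

quiet_cfg <- function(...) generator_config(...)

tiny_dataset <- function(n_subjects = 4, n_trials = 2, effects = list(),
                         subject_sd = 0.3, trial_sd = 0.25, seed = 11) {
  generate_dataset(generator_config(n_subjects = n_subjects,
                                    n_trials = n_trials,
                                    subject_sd = subject_sd,
                                    trial_sd = trial_sd,
                                    effects = effects, seed = seed))
}

knee_effect <- function(amplitude = 2.0, window = c(15, 25))
  effect_template("knee", "sagittal", "angle", window, amplitude)

# hand-built network, bypassing training
make_network <- function(Ws, bs = NULL, activations = NULL,
                         classes = c("a", "b")) {
  L <- length(Ws)
  if (is.null(bs)) bs <- lapply(Ws, function(W) numeric(ncol(W)))
  if (is.null(activations))
    activations <- c(rep("tanh", L - 1L), "identity")
  layers <- Map(function(W, b, act) list(W = W, b = b, activation = act),
                Ws, bs, activations)
  dims <- c(nrow(Ws[[1]]), vapply(Ws, ncol, integer(1)))
  structure(list(layers = layers, dims = dims,
                 classes = classes[seq_len(ncol(Ws[[L]]))],
                 center = NULL, scale = NULL),
            class = "mlp_network")
}

random_network <- function(dims, bias = TRUE, positive = FALSE,
                           activations = NULL) {
  Ws <- lapply(seq_len(length(dims) - 1L), function(l) {
    w <- matrix(stats::rnorm(dims[l] * dims[l + 1L]), dims[l], dims[l + 1L])
    if (positive) abs(w) else w
  })
  bs <- lapply(seq_len(length(dims) - 1L), function(l)
    if (bias) stats::rnorm(dims[l + 1L], sd = 0.3) else numeric(dims[l + 1L]))
  make_network(Ws, bs, activations,
               classes = paste0("c", seq_len(dims[length(dims)])))
}

# literal per-message double-loop LRP oracle: messages R_{i<-j} = z_ij/z_j* R_j
# summed over upper neurons, layer by layer; independent of the vectorized path
lrp_oracle <- function(model, x, target_class, epsilon = 0) {
  tr <- forward(model, x)
  L <- length(model$layers)
  scores <- drop(tr$scores)
  R_up <- numeric(length(scores))
  R_up[target_class] <- scores[target_class]
  for (l in L:1) {
    a_low <- drop(tr$a[[l]])
    W <- model$layers[[l]]$W
    b <- model$layers[[l]]$b
    R_low <- numeric(length(a_low))
    for (j in seq_along(R_up)) {
      zj <- 0
      for (i in seq_along(a_low)) zj <- zj + a_low[i] * W[i, j]
      zj <- zj + b[j]
      zst <- zj + epsilon * (if (zj >= 0) 1 else -1)
      for (i in seq_along(a_low)) {
        if (R_up[j] != 0)
          R_low[i] <- R_low[i] + (a_low[i] * W[i, j] / zst) * R_up[j]
      }
    }
    R_up <- R_low
  }
  R_up
}

# independent paired-t oracle via stats::t.test, node by node
paired_t_oracle <- function(a, b)
  vapply(seq_len(ncol(a)), function(j)
    unname(stats::t.test(a[, j], b[, j], paired = TRUE)$statistic), numeric(1))

# smooth unit-variance null fields for calibration checks
null_fields <- function(m, n, fwhm) {
  sdk <- fwhm / sqrt(8 * log(2))
  pad <- ceiling(4 * sdk)
  k <- stats::dnorm(seq(-pad, pad), sd = sdk)
  k <- k / sqrt(sum(k^2))
  W <- matrix(stats::rnorm(m * (n + 2 * pad)), m)
  t(apply(W, 1, function(x) stats::filter(x, k, sides = 2)[(pad + 1):(pad + n)]))
}

# build a task_matrix by hand (for classifier tests on non-waveform data)
manual_task <- function(X, y, groups, task = "all") {
  fi <- data.frame(channel = 1L, joint = "knee", plane = "sagittal",
                   quantity = "angle", name = "knee_sagittal_angle",
                   node = seq_len(ncol(X)) - 1L)
  structure(list(X = X, y = factor(y, levels = class_levels()),
                 groups = groups, feature_index = fi, task = task),
            class = "task_matrix")
}
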