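#' Hyperparameters for the feed-forward classifier
#'
#' The network is deliberately small and fully transparent: dense layers
#' whose weights, pre-activations and activations are all exposed so the
#' relevance module can decompose any prediction. Defaults: one hidden tanh
#' layer of width `min(64, n_features)`, a linear 2-unit output read through
#' softmax cross-entropy during training and by argmax at decision time,
#' full-batch gradient descent with a fixed learning rate, and early stopping
#' on validation cross-entropy.
#'
#' @param hidden integer vector of hidden-layer widths, or `NULL` for the
#'   default single layer of width `min(64, n_features)`.
#' @param activation hidden activation: `"tanh"` or `"relu"` (the two
#'   monotone nonlinearities supported by the relevance rule).
#' @param learning_rate fixed step size for full-batch gradient descent.
#' @param max_epochs upper bound on epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param l2 ridge penalty on weights (not biases); small, for conditioning.
#' @param standardize if `TRUE`, z-score features using train-fold statistics
#'   only (leakage-free); default `FALSE`, raw waveforms are fed directly so
#'   relevance maps live on the original signal scale.
#' @return An object of class `mlp_control`.
#' @export
mlp_control <- function(hidden = NULL, activation = c("tanh", "relu"),
                        learning_rate = 0.05, max_epochs = 500L,
                        patience = 50L, l2 = 1e-4, standardize = FALSE) {
  activation <- match.arg(activation)
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 1, l2 >= 0)
  structure(list(hidden = hidden, activation = activation,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), l2 = l2,
                 standardize = isTRUE(standardize)),
            class = "mlp_control")
}

act_fun <- function(name) switch(name,
  tanh = list(f = tanh, df = function(a) 1 - a^2),
  relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1),
  identity = list(f = identity, df = function(a) 1),
  stop("unknown activation: ", name, call. = FALSE))

# build an untrained network; weights ~ U(-r, r), r = 1/sqrt(fan_in)
init_network <- function(dims, activation, seed) {
  with_seed(seed, {
    layers <- vector("list", length(dims) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- dims[l]
      r <- 1 / sqrt(fan_in)
      layers[[l]] <- list(
        W = matrix(stats::runif(fan_in * dims[l + 1L], -r, r), fan_in, dims[l + 1L]),
        b = numeric(dims[l + 1L]),
        activation = if (l < length(layers)) activation else "identity")
    }
    structure(list(layers = layers, dims = dims, classes = class_levels(),
                   center = NULL, scale = NULL),
              class = "mlp_network")
  })
}

#' Feed-forward evaluation with a full trace
#'
#' @param model an `mlp_network`.
#' @param x input matrix (trials x features) or a single feature vector.
#' @return A `forward_trace`: list with `a` (list of activations per layer,
#'   `a[[1]]` the input), `z` (pre-activations per layer) and `scores`
#'   (output matrix, one column per class).
#' @export
forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$dims[1])
    stop("input has ", ncol(x), " features, model expects ", model$dims[1],
         call. = FALSE)
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  a <- vector("list", length(model$layers) + 1L)
  z <- vector("list", length(model$layers))
  a[[1]] <- x
  for (l in seq_along(model$layers)) {
    lay <- model$layers[[l]]
    z[[l]] <- sweep(a[[l]] %*% lay$W, 2, lay$b, "+")
    a[[l + 1L]] <- act_fun(lay$activation)$f(z[[l]])
  }
  structure(list(a = a, z = z, scores = a[[length(a)]]),
            class = "forward_trace")
}

#' @rdname forward
#' @param ... unused.
#' @param object an `mlp_network`.
#' @param newdata feature matrix.
#' @return `predict` returns a factor of predicted class labels.
#' @export
predict.mlp_network <- function(object, newdata, ...) {
  s <- forward(object, newdata)$scores
  factor(object$classes[max.col(s, ties.method = "first")],
         levels = object$classes)
}

softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

cross_entropy <- function(p, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
}

# one full-batch gradient step; returns updated layers
gd_step <- function(model, x, y_onehot, lr, l2) {
  tr <- forward(model, x)
  L <- length(model$layers)
  n <- nrow(x)
  p <- softmax(tr$scores)
  delta <- (p - y_onehot) / n                      # dLoss/dz at output
  for (l in L:1) {
    lay <- model$layers[[l]]
    gW <- crossprod(tr$a[[l]], delta) + l2 * lay$W
    gb <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(lay$W)) *
        act_fun(model$layers[[l - 1L]]$activation)$df(tr$a[[l]])
    }
    model$layers[[l]]$W <- lay$W - lr * gW
    model$layers[[l]]$b <- lay$b - lr * gb
  }
  model
}

onehot <- function(y, classes) {
  m <- matrix(0, length(y), length(classes))
  m[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  m
}

#' Train the feed-forward classifier for one cross-validation rotation
#'
#' Trains on the six training folds of the rotation by full-batch gradient
#' descent on softmax cross-entropy, early-stops on the validation fold's
#' cross-entropy, and never touches the test fold (its trials play no part
#' in weight updates, standardisation statistics, or stopping).
#'
#' @param task a [build_task()] matrix.
#' @param fold_plan a [grouped_kfold()] plan.
#' @param rotation 0-based rotation index.
#' @param control an [mlp_control()].
#' @param seed integer seed (weight initialisation).
#' @return A trained `mlp_network`, with attributes `epochs_run` and
#'   `val_history`.
#' @export
train_mlp <- function(task, fold_plan, rotation, control = mlp_control(),
                      seed = 1L) {
  stopifnot(inherits(task, "task_matrix"), inherits(control, "mlp_control"))
  roles <- rotation_roles(fold_plan, rotation)
  idx_tr <- task$groups %in% roles$train
  idx_va <- task$groups %in% roles$validation
  x_tr <- task$X[idx_tr, , drop = FALSE]
  x_va <- task$X[idx_va, , drop = FALSE]
  fit_mlp(x_tr, task$y[idx_tr], x_va, task$y[idx_va], control, seed)
}

# core fitting routine on explicit train/validation sets
fit_mlp <- function(x_tr, y_tr, x_va, y_va, control = mlp_control(),
                    seed = 1L) {
  p <- ncol(x_tr)
  hidden <- control$hidden %||% min(64L, p)
  dims <- c(p, hidden, 2L)
  model <- init_network(dims, control$activation, seed)
  if (control$standardize) {
    model$center <- colMeans(x_tr)
    s <- apply(x_tr, 2, stats::sd)
    model$scale <- ifelse(s > 0, s, 1)
  }
  classes <- model$classes
  yh_tr <- onehot(y_tr, classes)
  yh_va <- onehot(y_va, classes)
  best <- model; best_ce <- Inf; wait <- 0L; hist <- numeric(0)
  for (ep in seq_len(control$max_epochs)) {
    model <- gd_step(model, x_tr, yh_tr, control$learning_rate, control$l2)
    s_tr <- forward(model, x_tr)$scores
    if (!all(is.finite(s_tr)))
      stop("training diverged at epoch ", ep,
           " (non-finite scores); reduce learning_rate", call. = FALSE)
    ce <- cross_entropy(softmax(forward(model, x_va)$scores), yh_va)
    hist <- c(hist, ce)
    if (ce < best_ce - 1e-9) { best_ce <- ce; best <- model; wait <- 0L }
    else { wait <- wait + 1L; if (wait >= control$patience) break }
  }
  attr(best, "epochs_run") <- length(hist)
  attr(best, "val_history") <- hist
  best
}

#' Cross-validated accuracy of the classifier on one task
#'
#' Runs all `k` rotations of the fold plan: trains on 6 folds, early-stops on
#' the validation fold, scores the held-out test fold, and computes the
#' paired Zero-R baseline from the same split.
#'
#' @inheritParams train_mlp
#' @return A `cv_report`: list with `accuracy` (length k), `mean`, `sd`,
#'   `zeror` (length k), `zeror_mean`, `models` (one per rotation),
#'   `predictions` (data.frame trial/rotation/truth/predicted/correct) and
#'   `task`.
#' @export
evaluate_cv <- function(task, fold_plan, control = mlp_control(), seed = 1L) {
  k <- fold_plan$k
  acc <- zr <- numeric(k)
  models <- vector("list", k)
  preds <- vector("list", k)
  for (r in 0:(k - 1L)) {
    model <- tryCatch(
      train_mlp(task, fold_plan, r, control, seed = stage_seed(seed, r)),
      error = function(e) stop("rotation ", r, ": ", conditionMessage(e),
                               call. = FALSE))
    roles <- rotation_roles(fold_plan, r)
    idx_te <- which(task$groups %in% roles$test)
    idx_tr <- task$groups %in% roles$train
    yhat <- predict(model, task$X[idx_te, , drop = FALSE])
    acc[r + 1L] <- mean(yhat == task$y[idx_te])
    zr[r + 1L] <- zeror_baseline(task$y[idx_tr], task$y[idx_te])
    models[[r + 1L]] <- model
    preds[[r + 1L]] <- data.frame(trial = idx_te, rotation = r,
                                  truth = task$y[idx_te], predicted = yhat,
                                  correct = yhat == task$y[idx_te])
  }
  structure(list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 zeror = zr, zeror_mean = mean(zr), models = models,
                 predictions = do.call(rbind, preds), task = task$task),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report [%s]: accuracy %.2f%% +/- %.2f%% (ZeroR %.2f%%) over %d rotations\n",
              x$task, 100 * x$mean, 100 * x$sd, 100 * x$zeror_mean,
              length(x$accuracy)))
  invisible(x)
}
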