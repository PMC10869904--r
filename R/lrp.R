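#' Layer-wise relevance propagation (z-rule) for one input
#'
#' Decomposes one output score of the network into per-input relevances by
#' backward proportional redistribution of pre-activations. With
#' `z_ij = x_i(l) w_ij` the message from upper-layer neuron `j` to lower
#' neuron `i` is `R_{i<-j} = (z_ij / z_j*) R_j`, where `z_j*` is the layer's
#' pre-activation `sum_i z_ij + b_j`; the relevance of a lower neuron is the
#' sum of its incoming messages. Propagation starts at the output layer with
#' all relevance on the decomposed class (its raw score `f(x)`) and ends at
#' the input features.
#'
#' Numerical and conservation conventions:
#' * the denominator is stabilised as `z_j* + epsilon * sign(z_j*)`; with
#'   `epsilon = 0` a vanishing denominator under nonzero relevance is an
#'   error naming the layer and neuron;
#' * biases contribute to `z_j*` but receive no outgoing relevance, so the
#'   amount `R_j (1 - (z_j* - b_j)/(z_j* + eps sign))` leaks out of the
#'   decomposition at each neuron; the summed leakage is reported, and
#'   `sum(R_input) + leakage == f(x)` to floating-point accuracy;
#' * relevance keeps its sign; rectification is deferred to post-processing.
#'
#' @param model an `mlp_network`.
#' @param x one input feature vector (or 1-row matrix).
#' @param target_class class whose score is decomposed; default the model's
#'   predicted class for `x`.
#' @param epsilon denominator stabiliser (default `1e-9`).
#' @return An `lrp_result`: list with `relevance` (per input feature),
#'   `score` (the decomposed output score), `leakage` (total relevance
#'   absorbed by biases/stabiliser), `target_class`, `predicted` and
#'   `correct_fn` left `NA` (filled by [relevance_for_testset()]).
#' @examples
#' net <- list(layers = list(list(W = matrix(c(1, 2)), b = 0,
#'                                activation = "identity")),
#'             dims = c(2L, 1L), classes = "f", center = NULL, scale = NULL)
#' class(net) <- "mlp_network"
#' lrp_propagate(net, c(3, 1), target_class = 1)$relevance  # 3 2
#' @export
lrp_propagate <- function(model, x, target_class = NULL, epsilon = 1e-9) {
  stopifnot(inherits(model, "mlp_network"))
  tr <- forward(model, x)
  scores <- drop(tr$scores)
  predicted <- which.max(scores)
  if (is.null(target_class)) target_class <- predicted
  if (is.character(target_class))
    target_class <- match(target_class, model$classes)
  if (is.na(target_class) || target_class < 1 || target_class > length(scores))
    stop("invalid target_class", call. = FALSE)
  L <- length(model$layers)
  R <- numeric(length(scores))
  R[target_class] <- scores[target_class]
  f0 <- scores[target_class]
  leakage <- 0
  for (l in L:1) {
    lay <- model$layers[[l]]
    a_low <- drop(tr$a[[l]])
    denom <- drop(tr$z[[l]])                     # z_j* = sum_i z_ij + b_j
    if (epsilon > 0) {
      dstab <- denom + epsilon * ifelse(denom >= 0, 1, -1)
    } else {
      bad <- which(denom == 0)
      if (length(bad))
        stop("zero pre-activation denominator at layer ", l, ", neuron ",
             bad[1], " with epsilon = 0", call. = FALSE)
      dstab <- denom
    }
    ratio <- ifelse(R == 0, 0, R / dstab)        # avoids 0/0 on dead units
    R_low <- a_low * drop(lay$W %*% ratio)
    leakage <- leakage + sum(R) - sum(R_low)
    R <- R_low
  }
  structure(list(relevance = R, score = f0, leakage = leakage,
                 target_class = model$classes[target_class],
                 predicted = model$classes[predicted]),
            class = "lrp_result")
}

#' Construct a relevance map on the channel x node grid
#'
#' @param values matrix (channels x nodes), rownames = channel names.
#' @param state processing state flag: `"raw"`, `"smoothed"` or `"scaled"`.
#' @param ... further attributes (provenance) stored on the object.
#' @return A `relevance_map` (matrix with state attribute).
#' @export
relevance_map <- function(values, state = "raw", ...) {
  stopifnot(is.matrix(values))
  extra <- list(...)
  for (nm in names(extra)) attr(values, nm) <- extra[[nm]]
  attr(values, "state") <- state
  class(values) <- c("relevance_map", "matrix", "array")
  values
}

map_state <- function(map) attr(map, "state") %||% "raw"

# fold a feature-vector relevance back onto the task's channel x node grid
fold_to_grid <- function(relevance, feature_index) {
  ch_names <- unique(feature_index$name)
  n_nodes <- max(feature_index$node) + 1L
  m <- matrix(relevance, nrow = length(ch_names), ncol = n_nodes, byrow = TRUE,
              dimnames = list(ch_names, NULL))
  m
}

#' Relevance maps for every held-out test trial
#'
#' Each trial is explained under the model of the rotation whose test fold
#' contains it, so no trial is ever explained by a network that saw it in
#' training. One raw `relevance_map` per test trial is returned, flagged with
#' whether the trial was correctly classified.
#'
#' @param cv a [evaluate_cv()] report (holds the per-rotation models).
#' @param task the [build_task()] matrix the report was computed on.
#' @param target_class `NULL` (decompose the predicted class, default) or a
#'   class label to decompose for every trial.
#' @param epsilon stabiliser passed to [lrp_propagate()].
#' @return List of `relevance_map` objects, one per trial of the dataset, in
#'   trial order; each carries attributes `trial`, `rotation`, `correct`,
#'   `score`, `leakage`, `target_class`.
#' @export
relevance_for_testset <- function(cv, task, target_class = NULL,
                                  epsilon = 1e-9) {
  stopifnot(inherits(cv, "cv_report"), inherits(task, "task_matrix"))
  if (!identical(cv$task, task$task))
    stop("cv report was computed on task '", cv$task, "', not '",
         task$task, "'", call. = FALSE)
  preds <- cv$predictions
  maps <- vector("list", nrow(preds))
  for (i in seq_len(nrow(preds))) {
    trial <- preds$trial[i]
    rot <- preds$rotation[i]
    model <- cv$models[[rot + 1L]]
    if (is.null(model)) stop("missing model for rotation ", rot, call. = FALSE)
    res <- lrp_propagate(model, task$X[trial, ], target_class, epsilon)
    maps[[i]] <- relevance_map(fold_to_grid(res$relevance, task$feature_index),
                               state = "raw", trial = trial, rotation = rot,
                               correct = preds$correct[i], score = res$score,
                               leakage = res$leakage,
                               target_class = res$target_class)
  }
  maps[order(preds$trial)]
}
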