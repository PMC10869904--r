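#' The nine channel-subset classification tasks
#'
#' @return Character vector of the nine task identifiers: `all` (18 channels),
#'   `kinematics` / `kinetics` (9 each), one per joint (6 each) and one per
#'   plane (6 each).
#' @export
task_ids <- function() c("all", "kinematics", "kinetics",
                         "ankle", "knee", "hip",
                         "sagittal", "frontal", "transversal")

#' Channels participating in a task
#'
#' @param task one of [task_ids()].
#' @return The subset of [channel_table()] for that task, in canonical order.
#' @export
task_channels <- function(task) {
  ch <- channel_table()
  switch(task,
         all = ch,
         kinematics = ch[ch$quantity == "angle", ],
         kinetics = ch[ch$quantity == "moment", ],
         ankle = , knee = , hip = ch[ch$joint == task, ],
         sagittal = , frontal = , transversal = ch[ch$plane == task, ],
         stop("unknown task: '", task, "'", call. = FALSE))
}

#' Build the flattened feature matrix for one classification task
#'
#' Features are laid out channel-major (channels in canonical order within
#' the task's subset), then node 0..n_nodes-1 within each channel. The
#' `feature_index` component inverts this map for the relevance module.
#'
#' @param dataset a `landing_dataset`.
#' @param task one of [task_ids()].
#' @return A `task_matrix`: list with `X` (trials x features), `y` (factor),
#'   `groups` (subject per trial), `feature_index` (data.frame channel/joint/
#'   plane/quantity/node per column) and `task`.
#' @examples
#' d <- generate_dataset(generator_config(n_subjects = 3, n_trials = 2))
#' ncol(build_task(d, "ankle")$X)  # 6 channels x 101 nodes
#' @export
build_task <- function(dataset, task) {
  stopifnot(inherits(dataset, "landing_dataset"))
  sub <- task_channels(task)
  n_nodes <- dim(dataset$data)[3]
  n <- dim(dataset$data)[1]
  X <- matrix(NA_real_, nrow = n, ncol = nrow(sub) * n_nodes)
  fi <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    cols <- ((i - 1L) * n_nodes + 1L):(i * n_nodes)
    X[, cols] <- dataset$data[, sub$channel[i], ]
    fi[[i]] <- data.frame(channel = sub$channel[i], joint = sub$joint[i],
                          plane = sub$plane[i], quantity = sub$quantity[i],
                          name = sub$name[i], node = 0:(n_nodes - 1L))
  }
  if (anyNA(X)) stop("dataset contains missing values", call. = FALSE)
  structure(list(X = X, y = dataset$klass, groups = dataset$subject,
                 feature_index = do.call(rbind, fi), task = task),
            class = "task_matrix")
}

#' Subject-grouped k-fold plan
#'
#' All trials of a subject share its fold, so repeated trials never straddle
#' train and test. Subjects are shuffled under `seed` and dealt round-robin,
#' so fold sizes differ by at most one subject. In rotation `r`
#' (0-based), fold `r` is the test set, fold `(r + 1) mod k` the validation
#' set, and the remaining `k - 2` folds the training set.
#'
#' @param dataset a `landing_dataset` (or an integer vector of subject IDs).
#' @param k number of folds (default 8).
#' @param seed integer seed for the subject shuffle.
#' @return A `fold_plan`: list with `k`, `assignment` (named integer vector
#'   subject -> fold, folds 1..k) and `seed`.
#' @export
grouped_kfold <- function(dataset, k = 8L, seed = 1L) {
  subjects <- if (inherits(dataset, "landing_dataset"))
    sort(unique(dataset$subject)) else sort(unique(dataset))
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2", call. = FALSE)
  if (k > length(subjects))
    stop("k = ", k, " exceeds the number of subjects (", length(subjects), ")",
         call. = FALSE)
  shuffled <- with_seed(seed, sample(subjects))
  # fold of the i-th shuffled subject is ((i-1) mod k) + 1
  assignment <- stats::setNames(integer(length(subjects)), subjects)
  assignment[as.character(shuffled)] <- ((seq_along(shuffled) - 1L) %% k) + 1L
  structure(list(k = k, assignment = assignment, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Train / validation / test roles for one cross-validation rotation
#'
#' @param plan a [grouped_kfold()] plan.
#' @param rotation 0-based rotation index in `0..k-1`.
#' @return List of integer subject vectors `train`, `validation`, `test`.
#' @export
rotation_roles <- function(plan, rotation) {
  stopifnot(inherits(plan, "fold_plan"))
  rotation <- as.integer(rotation)
  if (rotation < 0L || rotation >= plan$k)
    stop("rotation must be in 0..", plan$k - 1L, call. = FALSE)
  test_fold <- rotation + 1L
  val_fold <- (rotation + 1L) %% plan$k + 1L
  subj <- as.integer(names(plan$assignment))
  list(train = subj[!plan$assignment %in% c(test_fold, val_fold)],
       validation = subj[plan$assignment == val_fold],
       test = subj[plan$assignment == test_fold])
}

#' Zero-R baseline accuracy
#'
#' Predicts every test trial as the majority class of the training labels;
#' ties resolve to the earlier level in the factor's level order
#' (or [class_levels()] order for character input).
#'
#' @param y_train,y_test non-empty label vectors.
#' @return Fraction of `y_test` equal to the training majority class.
#' @examples
#' zeror_baseline(c(1, 1, 1, 0), c(1, 1, 0, 0))  # 0.5
#' @export
zeror_baseline <- function(y_train, y_test) {
  if (!length(y_train) || !length(y_test))
    stop("label vectors must be non-empty", call. = FALSE)
  counts <- table(y_train)
  majority <- names(counts)[which.max(counts)]  # which.max: first tie wins
  mean(as.character(y_test) == majority)
}
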