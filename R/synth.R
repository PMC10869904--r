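#' Phase-localised class-difference template
#'
#' Describes how the post-fatigue class differs, in expectation, from the
#' pre-fatigue class on one channel: a bump of the given `amplitude` over a
#' half-open phase window `[start, end)` in percent of the landing phase.
#' Node `i` (0-based) of a 101-node series represents phase `i`%.
#'
#' @param joint,plane,quantity channel identity (see [channel_table()]).
#' @param window numeric length-2, half-open `[start, end)` within `[0, 100]`.
#' @param amplitude finite real; the expected class difference at the bump.
#' @param shape `"boxcar"` (constant over the window) or `"raised_cosine"`
#'   (smooth bump, zero at both window edges, peak `amplitude` mid-window).
#' @return An object of class `effect_template`.
#' @export
effect_template <- function(joint, plane, quantity, window, amplitude,
                            shape = c("boxcar", "raised_cosine")) {
  shape <- match.arg(shape)
  ch <- channel_table()
  hit <- ch$joint == joint & ch$plane == plane & ch$quantity == quantity
  if (sum(hit) != 1L)
    stop("unknown channel: ", joint, "/", plane, "/", quantity, call. = FALSE)
  if (length(window) != 2L || !all(is.finite(window)))
    stop("'window' must be two finite numbers", call. = FALSE)
  if (window[1] >= window[2] || window[1] < 0 || window[2] > 100)
    stop("effect window must satisfy 0 <= start < end <= 100, got [",
         window[1], ", ", window[2], ")", call. = FALSE)
  if (!is.finite(amplitude)) stop("'amplitude' must be finite", call. = FALSE)
  structure(list(channel = ch$channel[hit], joint = joint, plane = plane,
                 quantity = quantity, window = as.numeric(window),
                 amplitude = as.numeric(amplitude), shape = shape),
            class = "effect_template")
}

#' Generator configuration for synthetic landing datasets
#'
#' The defaults mirror the design of the motivating study: 56 subjects with
#' 5 successful trials each per class and 101 time-normalised nodes, giving
#' 280 trials per class (560 in total). Noise defaults (`subject_sd` 0.3,
#' `trial_sd` 0.25 on base curves of unit-order amplitude) are the package's
#' declared "realistic" operating point; see the methods vignette.
#'
#' @param n_subjects,n_trials positive integers; trials are per subject and
#'   per class (the design is paired: each subject appears in both classes).
#' @param n_nodes number of phase nodes (>= 3); node i is i% of the phase.
#' @param basis_order number of sinusoidal harmonics in each base curve.
#' @param subject_sd SD of the smooth per-subject offset field (shared by a
#'   subject's two classes, emulating stable individual movement signatures).
#' @param trial_sd SD of the smooth per-trial noise field.
#' @param noise_fwhm smoothness (FWHM, in nodes) of subject/trial noise
#'   fields; noise is white noise convolved with a Gaussian kernel, not
#'   i.i.d. per node, so residual fields satisfy random-field smoothness.
#' @param effects list of [effect_template()]s added to the after-fatigue
#'   class mean.
#' @param seed integer seed; identical configs generate identical datasets.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 56, n_trials = 5, n_nodes = 101,
                             basis_order = 3, subject_sd = 0.3,
                             trial_sd = 0.25, noise_fwhm = 10,
                             effects = list(), seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop("'n_subjects' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_trials) || n_trials < 1 || n_trials != round(n_trials))
    stop("'n_trials' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_nodes) || n_nodes < 3 || n_nodes != round(n_nodes))
    stop("'n_nodes' must be an integer >= 3", call. = FALSE)
  if (!is.numeric(basis_order) || basis_order < 1)
    stop("'basis_order' must be a positive integer", call. = FALSE)
  if (subject_sd < 0 || trial_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  if (noise_fwhm <= 0) stop("'noise_fwhm' must be > 0", call. = FALSE)
  if (inherits(effects, "effect_template")) effects <- list(effects)
  ok <- vapply(effects, inherits, logical(1), what = "effect_template")
  if (!all(ok)) stop("'effects' must be a list of effect_template objects",
                     call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_nodes = as.integer(n_nodes),
                 basis_order = as.integer(basis_order),
                 subject_sd = subject_sd, trial_sd = trial_sd,
                 noise_fwhm = noise_fwhm, effects = effects,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# fixed smooth base curves, one per channel: a few sinusoidal harmonics with
# coefficients drawn once from a constant-seed stream, so the "anatomy" of
# the synthetic world never depends on the user's seed
base_waveforms <- function(n_nodes, basis_order) {
  t <- seq(0, 1, length.out = n_nodes)
  with_seed(902406L, {
    B <- matrix(0, nrow = 18, ncol = n_nodes)
    for (c in 1:18) {
      curve <- rep(stats::runif(1, -0.5, 0.5), n_nodes)  # modest offset
      for (m in seq_len(basis_order)) {
        amp <- stats::runif(1, 0.5, 1.5) / m
        phs <- stats::runif(1, 0, 2 * pi)
        curve <- curve + amp * sin(2 * pi * m * t + phs)
      }
      B[c, ] <- curve
    }
    B
  })
}

# smooth unit-variance Gaussian fields: white noise convolved with a Gaussian
# kernel normalised so the pointwise variance is exactly 1
smooth_fields <- function(n_fields, n_nodes, fwhm) {
  sdk <- fwhm / sqrt(8 * log(2))
  pad <- ceiling(4 * sdk)
  k <- stats::dnorm(seq(-pad, pad), sd = sdk)
  k <- k / sqrt(sum(k^2))
  n_ext <- n_nodes + 2 * pad
  # K[e, j] = kernel weight of extended sample e on output node j
  K <- matrix(0, nrow = n_ext, ncol = n_nodes)
  for (j in seq_len(n_nodes)) K[j:(j + 2 * pad), j] <- k
  matrix(stats::rnorm(n_fields * n_ext), n_fields, n_ext) %*% K
}

# evaluate one template on the node grid (0-based node i = i% phase)
template_curve <- function(eff, n_nodes) {
  nodes <- seq_len(n_nodes) - 1L
  inside <- nodes >= eff$window[1] & nodes < eff$window[2]
  curve <- numeric(n_nodes)
  if (eff$shape == "boxcar") {
    curve[inside] <- eff$amplitude
  } else {
    u <- (nodes[inside] - eff$window[1]) / diff(eff$window)
    curve[inside] <- eff$amplitude * 0.5 * (1 - cos(2 * pi * u))
  }
  curve
}

# 18 x n_nodes matrix of summed class-difference templates
effect_grid <- function(effects, n_nodes) {
  G <- matrix(0, nrow = 18, ncol = n_nodes)
  for (eff in effects)
    G[eff$channel, ] <- G[eff$channel, ] + template_curve(eff, n_nodes)
  G
}

#' Generate a synthetic two-class landing dataset
#'
#' Builds `2 * n_subjects * n_trials` trials on the 18-channel x `n_nodes`
#' grid. Each trial is: fixed per-channel smooth base curve + smooth
#' per-subject offset field (SD `subject_sd`, shared between the subject's
#' two classes) + smooth per-trial noise field (SD `trial_sd`); the
#' after-fatigue class additionally receives the summed effect templates.
#' With both SDs at zero the class-mean difference therefore equals the
#' summed templates exactly.
#'
#' @param config a [generator_config()].
#' @return A `landing_dataset`: list with `data` (array trial x 18 x n_nodes,
#'   dimnames carry channel names), `subject` (integer per trial), `klass`
#'   (factor with levels [class_levels()]) and `config`.
#' @examples
#' d <- generate_dataset(generator_config(n_subjects = 4, n_trials = 2, seed = 7))
#' dim(d$data)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "generator_config"))
    stop("'config' must be a generator_config", call. = FALSE)
  n_sub <- config$n_subjects; n_tr <- config$n_trials; n_nodes <- config$n_nodes
  n_per_class <- n_sub * n_tr
  n_total <- 2L * n_per_class
  base <- base_waveforms(n_nodes, config$basis_order)
  eff <- effect_grid(config$effects, n_nodes)

  with_seed(config$seed, {
    # subject offset fields: one per subject per channel, shared across class
    sub_off <- array(0, dim = c(n_sub, 18, n_nodes))
    if (config$subject_sd > 0) {
      f <- smooth_fields(n_sub * 18L, n_nodes, config$noise_fwhm)
      sub_off <- array(config$subject_sd * f, dim = c(n_sub, 18, n_nodes))
    }
    data <- array(0, dim = c(n_total, 18, n_nodes),
                  dimnames = list(NULL, channel_table()$name, NULL))
    subject <- integer(n_total)
    klass <- character(n_total)
    row <- 0L
    for (cls in class_levels()) {
      for (s in seq_len(n_sub)) {
        for (tr in seq_len(n_tr)) {
          row <- row + 1L
          noise <- if (config$trial_sd > 0)
            config$trial_sd * smooth_fields(18L, n_nodes, config$noise_fwhm)
          else matrix(0, 18, n_nodes)
          x <- base + sub_off[s, , ] + noise
          if (cls == "after_fatigue") x <- x + eff
          data[row, , ] <- x
          subject[row] <- s
          klass[row] <- cls
        }
      }
    }
    structure(list(data = data, subject = subject,
                   klass = factor(klass, levels = class_levels()),
                   config = config),
              class = "landing_dataset")
  })
}

#' @export
print.landing_dataset <- function(x, ...) {
  cat("landing_dataset:", dim(x$data)[1], "trials x", dim(x$data)[2],
      "channels x", dim(x$data)[3], "nodes;",
      length(unique(x$subject)), "subjects,",
      "classes:", paste(table(x$klass), collapse = "/"), "\n")
  invisible(x)
}

dataset_column_names <- function(n_nodes) {
  ch <- channel_table()$name
  unlist(lapply(ch, function(nm) paste(nm, 0:(n_nodes - 1L), sep = "_")),
         use.names = FALSE)
}

#' Write / read a landing dataset as a wide CSV
#'
#' Column layout: `subject`, `class`, then the 18 channels in canonical order
#' (see [channel_table()]), each expanded into `<name>_<node>` for node
#' `0..n_nodes-1`. A JSON sidecar `<path>.json` stores the generator config
#' so a read dataset keeps its provenance. The round trip is exact: values
#' are written with full precision.
#'
#' @param dataset a `landing_dataset`.
#' @param path CSV file path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns a
#'   `landing_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "landing_dataset"))
  n_nodes <- dim(dataset$data)[3]
  n <- dim(dataset$data)[1]
  flat <- matrix(NA_real_, nrow = n, ncol = 18L * n_nodes)  # channel-major, node within
  for (c in 1:18)
    flat[, ((c - 1L) * n_nodes + 1L):(c * n_nodes)] <- dataset$data[, c, ]
  # full "%.17g" precision so the round trip is bit-exact
  chr <- data.table::as.data.table(
    matrix(sprintf("%.17g", flat), nrow = n, ncol = ncol(flat)))
  dt <- data.table::data.table(subject = dataset$subject,
                               class = as.character(dataset$klass))
  dt <- cbind(dt, chr)
  data.table::setnames(dt, c("subject", "class", dataset_column_names(n_nodes)))
  data.table::fwrite(dt, path, quote = FALSE)
  cfg <- dataset$config
  cfg_json <- list(n_subjects = cfg$n_subjects, n_trials = cfg$n_trials,
                   n_nodes = cfg$n_nodes, basis_order = cfg$basis_order,
                   subject_sd = cfg$subject_sd, trial_sd = cfg$trial_sd,
                   noise_fwhm = cfg$noise_fwhm, seed = cfg$seed,
                   effects = lapply(cfg$effects, function(e)
                     list(joint = e$joint, plane = e$plane,
                          quantity = e$quantity, window = e$window,
                          amplitude = e$amplitude, shape = e$shape)))
  jsonlite::write_json(cfg_json, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  nms <- names(dt)
  if (!identical(nms[1:2], c("subject", "class")))
    stop("parse error: expected leading columns 'subject', 'class', got '",
         paste(utils::head(nms, 2), collapse = "', '"), "'", call. = FALSE)
  n_feat <- length(nms) - 2L
  if (n_feat %% 18L != 0L)
    stop("parse error: ", n_feat,
         " waveform columns is not a multiple of 18 channels", call. = FALSE)
  n_nodes <- n_feat %/% 18L
  want <- dataset_column_names(n_nodes)
  got <- nms[-(1:2)]
  bad <- which(got != want)
  if (length(bad))
    stop("parse error: column ", bad[1] + 2L, " is '", got[bad[1]],
         "', expected '", want[bad[1]], "'", call. = FALSE)
  if (!all(as.character(dt$class) %in% class_levels()))
    stop("parse error: unknown class label in 'class' column", call. = FALSE)
  n <- nrow(dt)
  flat <- as.matrix(dt[, -(1:2)])
  data <- array(NA_real_, dim = c(n, 18L, n_nodes),
                dimnames = list(NULL, channel_table()$name, NULL))
  for (c in 1:18)
    data[, c, ] <- flat[, ((c - 1L) * n_nodes + 1L):(c * n_nodes)]
  cfg <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    raw <- jsonlite::read_json(side, simplifyVector = TRUE)
    effs <- list()
    if (length(raw$effects))
      effs <- lapply(seq_len(nrow(as.data.frame(raw$effects))), function(i) {
        e <- raw$effects[i, ]
        effect_template(e$joint, e$plane, e$quantity, unlist(e$window),
                        e$amplitude, e$shape)
      })
    cfg <- generator_config(raw$n_subjects, raw$n_trials, raw$n_nodes,
                            raw$basis_order, raw$subject_sd, raw$trial_sd,
                            raw$noise_fwhm, effs, raw$seed)
  }
  structure(list(data = data, subject = dt$subject,
                 klass = factor(as.character(dt$class), levels = class_levels()),
                 config = cfg),
            class = "landing_dataset")
}
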