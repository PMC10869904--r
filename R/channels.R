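#' Canonical waveform channel table
#'
#' The landing waveform grid carries 18 channels: 3 joints (ankle, knee, hip)
#' x 3 anatomical planes (sagittal, frontal, transversal) x 2 quantities
#' (angle = kinematics, moment = kinetics). The ordering is fixed everywhere
#' in the package: joint-major, then plane, then quantity. Feature matrices,
#' relevance maps and file headers all follow this order.
#'
#' @return A `data.frame` with 18 rows and columns `channel` (1..18), `joint`,
#'   `plane`, `quantity` and `name` (`<joint>_<plane>_<quantity>`).
#' @examples
#' head(channel_table())
#' @export
channel_table <- function() {
  joints <- c("ankle", "knee", "hip")
  planes <- c("sagittal", "frontal", "transversal")
  quantities <- c("angle", "moment")
  tab <- expand.grid(quantity = quantities, plane = planes, joint = joints,
                     stringsAsFactors = FALSE)[, c("joint", "plane", "quantity")]
  tab$channel <- seq_len(nrow(tab))
  tab$name <- paste(tab$joint, tab$plane, tab$quantity, sep = "_")
  tab[, c("channel", "joint", "plane", "quantity", "name")]
}

#' The two class labels, in documented order
#'
#' `before_fatigue` is the reference class; ties (e.g. in the Zero-R
#' baseline) resolve to the earlier label in this vector.
#'
#' @return Character vector of length 2.
#' @export
class_levels <- function() c("before_fatigue", "after_fatigue")

# run code under a local RNG stream without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# derive a per-stage seed from one top-level seed; stage indices are fixed
# package-wide so one integer reproduces a whole pipeline run
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (abs(as.integer(seed)) %% 1000000L) * 1000L + as.integer(stage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
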