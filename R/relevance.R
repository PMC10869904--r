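#' Smoothing specification for relevance series
#'
#' One pass replaces each node by a weighted mean of itself (50%) and its
#' two phase neighbours (25% each); the pass is repeated `repetitions` times
#' (default 3). Three passes of the 1/4-1/2-1/4 binomial kernel approximate a
#' Gaussian filter. At the series ends the truncated kernel is renormalised
#' to sum to 1 (`boundary = "renormalize"`), which avoids endpoint
#' attenuation on 101-node series; `"reflect"` mirrors the series instead.
#'
#' @param repetitions number of smoothing passes (>= 0).
#' @param boundary `"renormalize"` or `"reflect"`.
#' @return A `smoothing_spec`.
#' @export
smoothing_spec <- function(repetitions = 3L,
                           boundary = c("renormalize", "reflect")) {
  boundary <- match.arg(boundary)
  stopifnot(repetitions >= 0)
  structure(list(weights = c(0.25, 0.5, 0.25),
                 repetitions = as.integer(repetitions), boundary = boundary),
            class = "smoothing_spec")
}

smooth_series_once <- function(x, boundary) {
  n <- length(x)
  if (n < 3L) return(x)
  y <- x
  y[2:(n - 1L)] <- 0.25 * x[1:(n - 2L)] + 0.5 * x[2:(n - 1L)] + 0.25 * x[3:n]
  if (boundary == "renormalize") {
    y[1] <- (0.5 * x[1] + 0.25 * x[2]) / 0.75
    y[n] <- (0.5 * x[n] + 0.25 * x[n - 1L]) / 0.75
  } else {  # reflect: x[0] := x[2], x[n+1] := x[n-1]
    y[1] <- 0.25 * x[2] + 0.5 * x[1] + 0.25 * x[2]
    y[n] <- 0.25 * x[n - 1L] + 0.5 * x[n] + 0.25 * x[n - 1L]
  }
  y
}

#' Average relevance maps over trials
#'
#' Node-wise mean over the selected maps. By default only correctly
#' classified test trials enter the average (both classes pooled) and maps
#' are rectified first (negative relevance clipped to zero), since the
#' downstream statistics — contribution shares, [0,1] scaling, the RS > 0.7
#' rule — presuppose nonnegative contributions. Set `rectify = FALSE` to
#' average signed relevance.
#'
#' @param maps list of `relevance_map` objects sharing one grid shape.
#' @param selection `"correct"` (default), `"all"`, or one of
#'   [class_levels()] to average correctly classified trials of that class.
#' @param rectify clip negative relevance to zero before averaging.
#' @return A raw-state `relevance_map` with attribute `n_averaged`.
#' @export
average_maps <- function(maps, selection = "correct", rectify = TRUE) {
  stopifnot(length(maps) > 0)
  dims <- lapply(maps, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("maps do not share a grid shape", call. = FALSE)
  keep <- vapply(maps, function(m) {
    corr <- attr(m, "correct") %||% TRUE
    tgt <- attr(m, "target_class") %||% NA_character_
    switch(selection,
           all = TRUE,
           correct = isTRUE(corr),
           before_fatigue = , after_fatigue = isTRUE(corr) &&
             identical(tgt, selection),
           stop("unknown selection: ", selection, call. = FALSE))
  }, logical(1))
  if (!any(keep)) stop("selection matched no maps", call. = FALSE)
  sel <- maps[keep]
  acc <- matrix(0, nrow(sel[[1]]), ncol(sel[[1]]),
                dimnames = dimnames(sel[[1]]))
  for (m in sel) acc <- acc + if (rectify) pmax(unclass(m), 0) else unclass(m)
  relevance_map(acc / length(sel), state = "raw", n_averaged = length(sel))
}

#' Smooth a relevance map along the phase axis
#'
#' Applies the 25/50/25 kernel of `spec` independently to each channel row,
#' `spec$repetitions` times. Refuses already-scaled maps: the pipeline order
#' is average, smooth, then scale.
#'
#' @param map a raw or smoothed `relevance_map`.
#' @param spec a [smoothing_spec()].
#' @return The map with state `"smoothed"`.
#' @export
smooth_rs <- function(map, spec = smoothing_spec()) {
  stopifnot(inherits(map, "relevance_map"), inherits(spec, "smoothing_spec"))
  if (map_state(map) == "scaled")
    stop("map is already scaled; smoothing must precede scaling", call. = FALSE)
  vals <- unclass(map)
  for (rep in seq_len(spec$repetitions))
    vals <- t(apply(vals, 1, smooth_series_once, boundary = spec$boundary))
  out <- relevance_map(vals, state = "smoothed")
  for (nm in setdiff(names(attributes(map)),
                     c("dim", "dimnames", "class", "state")))
    attr(out, nm) <- attr(map, nm)
  dimnames(out) <- dimnames(map)
  out
}

#' Min-max scale a smoothed relevance map to [0, 1]
#'
#' `(v - min) / (max - min)` over the whole grid by default, so relevance
#' scores are comparable across channels (0 = lowest relevance anywhere on
#' the grid, 1 = highest). `scope = "channel"` rescales each channel row
#' separately. A constant map (max == min) degenerates to all zeros with a
#' warning.
#'
#' @param map a smoothed `relevance_map`.
#' @param scope `"global"` (default) or `"channel"`.
#' @return The map with state `"scaled"`, values in `[0, 1]`.
#' @export
scale_rs <- function(map, scope = c("global", "channel")) {
  scope <- match.arg(scope)
  stopifnot(inherits(map, "relevance_map"))
  if (map_state(map) != "smoothed")
    stop("scale_rs expects a smoothed map (state is '", map_state(map), "')",
         call. = FALSE)
  vals <- unclass(map)
  rescale <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("constant relevance map: scaled to all zeros", call. = FALSE)
      v * 0
    } else (v - rng[1]) / diff(rng)
  }
  vals <- if (scope == "global") rescale(vals) else t(apply(vals, 1, rescale))
  out <- relevance_map(vals, state = "scaled")
  dimnames(out) <- dimnames(map)
  attr(out, "n_averaged") <- attr(map, "n_averaged")
  out
}

#' Aggregate a scaled relevance map into contribution shares
#'
#' Shares are percentages of the grid's total relevance: per channel (sum of
#' the channel's nodes), per joint and per plane (sums over their 6
#' channels), per 1% phase bin (sum over all channels at one node), and an
#' early-phase share over a configurable window (default phases 1-22%
#' inclusive, i.e. 22 of the 101 bins). Each partition sums to 100%.
#'
#' @param map a scaled `relevance_map` on the full 18-channel grid.
#' @param early_window integer length-2, inclusive phase-percent window.
#' @return A `contribution_table`: list of data.frames `channel`, `joint`,
#'   `plane`, `phase` (share per node) and scalar `early_share` (+ window).
#' @export
aggregate_contributions <- function(map, early_window = c(1L, 22L)) {
  stopifnot(inherits(map, "relevance_map"))
  if (map_state(map) != "scaled")
    stop("aggregate_contributions expects a scaled map", call. = FALSE)
  ch <- channel_table()
  if (nrow(map) != 18L || !identical(rownames(map), ch$name))
    stop("map must cover the full 18-channel grid in canonical order",
         call. = FALSE)
  total <- sum(map)
  if (total <= 0) stop("zero total relevance; nothing to aggregate",
                       call. = FALSE)
  vals <- unclass(map)
  ch_share <- rowSums(vals) / total * 100
  channel <- data.frame(ch, share = as.numeric(ch_share))
  joint <- stats::aggregate(share ~ joint, channel, sum)
  plane <- stats::aggregate(share ~ plane, channel, sum)
  nodes <- 0:(ncol(vals) - 1L)
  phase <- data.frame(node = nodes, share = colSums(vals) / total * 100)
  inside <- nodes >= early_window[1] & nodes <= early_window[2]
  structure(list(channel = channel, joint = joint, plane = plane,
                 phase = phase, early_share = sum(phase$share[inside]),
                 early_window = as.integer(early_window)),
            class = "contribution_table")
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("contribution_table\n joints: ",
      paste(sprintf("%s %.2f%%", x$joint$joint, x$joint$share), collapse = ", "),
      "\n planes: ",
      paste(sprintf("%s %.2f%%", x$plane$plane, x$plane$share), collapse = ", "),
      sprintf("\n early phase (%d-%d%%): %.2f%%\n",
              x$early_window[1], x$early_window[2], x$early_share))
  invisible(x)
}

#' Extract highly relevant variables (RS above a threshold)
#'
#' Scans a scaled map for nodes with relevance strictly greater than
#' `threshold` (default 0.7) and reports them per channel as maximal runs of
#' consecutive nodes, expressed as phase-percent intervals.
#'
#' @param map a scaled `relevance_map`.
#' @param threshold relevance cutoff in `[0, 1]`.
#' @return A `high_rs_set`: list with `threshold`, `count` (total nodes above
#'   threshold) and `runs` (data.frame channel/start/end, inclusive phase %).
#' @export
extract_high_rs <- function(map, threshold = 0.7) {
  stopifnot(inherits(map, "relevance_map"))
  if (map_state(map) != "scaled")
    stop("extract_high_rs expects a scaled map", call. = FALSE)
  if (threshold < 0 || threshold > 1)
    stop("'threshold' must be in [0, 1]", call. = FALSE)
  runs <- list()
  for (chn in rownames(map)) {
    above <- unclass(map)[chn, ] > threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values))
      runs[[length(runs) + 1L]] <- data.frame(channel = chn,
                                              start = starts[i] - 1L,
                                              end = ends[i] - 1L)
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(channel = character(0), start = integer(0), end = integer(0))
  structure(list(threshold = threshold,
                 count = sum(runs$end - runs$start + 1L), runs = runs,
                 n_nodes = ncol(map)),
            class = "high_rs_set")
}

#' @export
print.high_rs_set <- function(x, ...) {
  cat("high_rs_set: ", x$count, " nodes with RS > ", x$threshold, " in ",
      nrow(x$runs), " runs\n", sep = "")
  invisible(x)
}
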