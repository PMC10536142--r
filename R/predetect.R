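#' Detection configuration for the sliding-window gate
#'
#' Two empirical thresholds gate the 30-sample sliding window before
#' classification. Both operate on normalized (reference-divided) values, so
#' they are dimensionless ratios and subject-independent.
#'
#' @param t1 Peak threshold: the largest per-channel range over the oldest
#'   `prefix_len` samples must exceed `t1` for the window to count as active
#'   with a sufficiently forward action start. Default 0.05.
#' @param t2 Head-tail threshold: the smallest per-channel absolute
#'   difference between the first and last window sample must fall below `t2`,
#'   rejecting the monotone ramps produced by switching between actions with
#'   different initial postures. Default 0.03.
#' @param window_size Sliding-window length in samples (default 30, i.e. 2 s
#'   at 15 Hz).
#' @param step Window advance per new sample (default 1).
#' @param prefix_len Number of oldest samples inspected by the peak rule
#'   (default 10).
#' @param refractory Samples during which further detections are suppressed
#'   after an accepted window, so one physical action emits one event
#'   (default `window_size`).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(t1 = 0.05, t2 = 0.03, window_size = 30L,
                             step = 1L, prefix_len = 10L,
                             refractory = window_size) {
  if (t1 <= 0 || t2 <= 0) stop_input("thresholds t1 and t2 must be positive")
  window_size <- as.integer(window_size)
  prefix_len <- as.integer(prefix_len)
  if (prefix_len > window_size)
    stop_input("prefix_len must not exceed window_size")
  structure(list(t1 = t1, t2 = t2, window_size = window_size,
                 step = as.integer(step), prefix_len = prefix_len,
                 refractory = as.integer(refractory)),
            class = "detection_config")
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf("Detection config: T1=%g, T2=%g, window=%d, step=%d, prefix=%d, refractory=%d\n",
              x$t1, x$t2, x$window_size, x$step, x$prefix_len, x$refractory))
  invisible(x)
}

check_window <- function(w, cfg) {
  w <- as.matrix(w)
  if (nrow(w) != 3L || ncol(w) != cfg$window_size)
    stop_input("window must be 3 x ", cfg$window_size)
  w
}

#' Peak rule: has an action started sufficiently far forward in the window?
#'
#' True when the largest range (max minus min) over the oldest `prefix_len`
#' samples of any channel exceeds `t1`. Quiescent windows fail, and so do
#' windows where the action has not yet reached the head of the queue.
#'
#' @param w 3 x window_size matrix of normalized values, oldest sample first.
#' @param cfg A [detection_config()].
#' @return Logical scalar.
#' @export
peak_rule <- function(w, cfg = detection_config()) {
  w <- check_window(w, cfg)
  prefix <- w[, seq_len(cfg$prefix_len), drop = FALSE]
  max(apply(prefix, 1, function(v) max(v) - min(v))) > cfg$t1
}

#' Head-tail rule: does the window start and end at a similar level?
#'
#' True when the smallest per-channel absolute difference between the first
#' and last window sample is below `t2`. Rehabilitation actions start and end
#' at the resting posture, so complete actions pass; the monotone ramps caused
#' by posture switches fail on every channel.
#'
#' @inheritParams peak_rule
#' @return Logical scalar.
#' @export
headtail_rule <- function(w, cfg = detection_config()) {
  w <- check_window(w, cfg)
  min(abs(w[, 1] - w[, cfg$window_size])) < cfg$t2
}

#' Pre-detection gate: does the window hold one complete action?
#'
#' The conjunction of [peak_rule()] and [headtail_rule()]. Only windows that
#' pass both are forwarded to the classifier.
#'
#' @inheritParams peak_rule
#' @return Logical scalar.
#' @export
is_action <- function(w, cfg = detection_config()) {
  peak_rule(w, cfg) && headtail_rule(w, cfg)
}
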