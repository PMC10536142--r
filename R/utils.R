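#' @keywords internal
"_PACKAGE"

# Run expr under a fixed RNG seed, restoring the caller's RNG state afterwards
# so library functions never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("rehabband_input_error", "error")))
}

stop_state <- function(...) {
  stop(errorCondition(paste0(...), class = c("rehabband_state_error", "error")))
}

# Canonical ordering of the six one-vs-one class pairs (1,2),(1,3),...,(3,4).
class_pairs <- function(n_classes = 4L) {
  out <- list()
  for (i in seq_len(n_classes - 1L))
    for (j in seq.int(i + 1L, n_classes))
      out[[length(out) + 1L]] <- c(i, j)
  out
}

#' Rehabilitation action labels
#'
#' The four wrist rehabilitation exercises recognized by the pipeline, in
#' their canonical integer coding 1--4.
#'
#' @return Named integer vector of length 4.
#' @export
action_labels <- function() {
  c("stretch_fist" = 1L, "separate_merge_fingers" = 2L,
    "palm_flexion_dorsiflexion" = 3L, "ulnar_deviation" = 4L)
}
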