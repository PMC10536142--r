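#' Fit the full action-recognition pipeline
#'
#' The main fitting function of the package. Takes a labeled dataset of raw
#' three-channel action windows (plus per-subject/round resting references),
#' normalizes and flattens every sample into its 90-value feature vector,
#' trains the autoencoder on those vectors, encodes them, and trains the
#' one-vs-one linear SVM voting ensemble on the codes.
#'
#' @param data Either a dataset list as returned by [generate_dataset()] /
#'   [read_dataset()] (components `samples`, `labels`, `subject`, `round`,
#'   `references`), or a numeric matrix of already-normalized 90-value
#'   feature rows, in which case `labels` must be supplied.
#' @param labels Integer labels 1--4 (only when `data` is a feature matrix).
#' @param hidden_dim,code_dim,epochs,batch_size,lr Autoencoder settings, see
#'   [train_autoencoder()].
#' @param cost SVM soft-margin cost (default 1).
#' @param config A [detection_config()] used by [predict_window()] and
#'   [run_detector()].
#' @param seed Integer seed controlling all training randomness.
#' @return An object of class `rehab_pipeline` with components `autoencoder`,
#'   `ensemble`, `config`, `training` (resubstitution error rate and counts)
#'   and `seed`.
#' @seealso [predict.rehab_pipeline()], [predict_window()], [run_detector()]
#' @export
rehab_pipeline <- function(data, labels = NULL, hidden_dim = 40L,
                           code_dim = 10L, epochs = 500L, batch_size = 200L,
                           lr = 1e-3, cost = 1, config = detection_config(),
                           seed = 1L) {
  if (is.list(data) && !is.null(data$samples)) {
    x <- dataset_features(data)
    labels <- as.integer(data$labels)
  } else {
    x <- as.matrix(data)
    if (is.null(labels)) stop_input("labels must be supplied with a feature matrix")
    labels <- as.integer(labels)
  }
  if (nrow(x) != length(labels))
    stop_input("number of samples and labels differ")

  ae <- train_autoencoder(x, hidden_dim = hidden_dim, code_dim = code_dim,
                          epochs = epochs, batch_size = batch_size, lr = lr,
                          seed = seed)
  codes <- encode(ae, x)
  ens <- train_pairwise(codes, labels, cost = cost)
  pred <- predict(ens, codes)
  structure(list(
    autoencoder = ae, ensemble = ens, config = config,
    training = list(n = nrow(x), error_rate = mean(pred != labels),
                    class_counts = as.integer(table(factor(labels, 1:4)))),
    seed = seed
  ), class = "rehab_pipeline")
}

#' @export
print.rehab_pipeline <- function(x, ...) {
  cat("Wristband action-recognition pipeline\n")
  print(x$autoencoder)
  print(x$ensemble)
  cat(sprintf("Training samples: %d; resubstitution error rate: %.3f\n",
              x$training$n, x$training$error_rate))
  invisible(x)
}

#' @export
summary.rehab_pipeline <- function(object, ...) {
  cat("Wristband action-recognition pipeline\n\n")
  print(object$autoencoder)
  print(object$ensemble)
  print(object$config)
  cat(sprintf("\nTraining samples per class: %s (total %d)\n",
              paste(object$training$class_counts, collapse = ", "),
              object$training$n))
  cat(sprintf("Resubstitution error rate: %.4f\n", object$training$error_rate))
  invisible(object)
}

#' Predict action labels from normalized feature vectors
#'
#' Encodes the feature rows with the pipeline's autoencoder and votes with
#' its SVM ensemble. No pre-detection gating is applied; use
#' [predict_window()] for gated windows.
#'
#' @param object A `rehab_pipeline`.
#' @param newdata Feature vector of length 90, a matrix of feature rows, or
#'   a dataset list as accepted by [rehab_pipeline()] (its samples are
#'   normalized by their own references and flattened first).
#' @param ... Unused.
#' @return Integer label(s) in 1..4.
#' @export
predict.rehab_pipeline <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.null(newdata$samples))
    newdata <- dataset_features(newdata)
  codes <- encode(object$autoencoder, newdata)
  predict(object$ensemble, codes)
}

#' Gate and classify one sliding window
#'
#' Applies the two-rule pre-detection gate to a normalized window; if the
#' window is rejected, returns `NA` (no action). Otherwise the window is
#' flattened, encoded and voted on.
#'
#' @param object A fitted `rehab_pipeline`.
#' @param w 3 x window_size matrix of normalized values, oldest sample first.
#' @return Integer label, or `NA_integer_` when the gate rejects the window;
#'   the vote tallies are attached as attribute `"tallies"` when a label is
#'   returned.
#' @export
predict_window <- function(object, w) {
  stopifnot(inherits(object, "rehab_pipeline"))
  if (!is_action(w, object$config)) return(NA_integer_)
  v <- vote(object$ensemble, encode(object$autoencoder, flatten_sample(w)))
  structure(v$winner, tallies = v$tallies)
}

#' Initialize the resting reference from the head of a stream
#'
#' Mirrors the deployed initialization: the wearer keeps the hand relaxed
#' while the first `n_samples` three-channel readings are averaged per
#' channel.
#'
#' @param stream Data.frame with columns `ch1,ch2,ch3` (a `t` column is
#'   ignored), or a 3-column matrix.
#' @param n_samples Number of leading readings to average (default 30).
#' @return A `resting_reference` (length-3 numeric).
#' @export
initialize_reference <- function(stream, n_samples = 30L) {
  m <- stream_matrix(stream)
  if (ncol(m) < n_samples)
    stop_input("stream has ", ncol(m), " samples; need at least ", n_samples)
  compute_reference(m[, seq_len(n_samples), drop = FALSE])
}

# Coerce a stream (data.frame t,ch1..ch3 or 3-col matrix) to a 3 x n matrix,
# dropping malformed (non-finite) rows with a warning.
stream_matrix <- function(stream, strict = FALSE) {
  if (is.data.frame(stream)) {
    need <- c("ch1", "ch2", "ch3")
    if (!all(need %in% names(stream)))
      stop_input("stream must have columns ch1, ch2, ch3")
    m <- t(as.matrix(stream[, need]))
  } else {
    m <- as.matrix(stream)
    if (nrow(m) != 3L) m <- t(m)
    if (nrow(m) != 3L) stop_input("stream matrix must have 3 channels")
  }
  bad <- !apply(is.finite(m), 2, all)
  if (any(bad)) {
    if (strict) stop_input(sum(bad), " malformed stream rows")
    warning("skipped ", sum(bad), " malformed stream row(s)")
    m <- m[, !bad, drop = FALSE]
  }
  m
}

#' Run the streaming sliding-window detector
#'
#' Maintains the normalized FIFO window exactly as deployed: each incoming
#' three-channel reading is divided by the resting reference and appended to
#' the tail of the window queue while the head is dropped; once full, the
#' window is gated with [is_action()] and, when accepted, classified by the
#' pipeline. After an accepted detection, further detections are suppressed
#' for the configured refractory interval. Single pass, bounded memory.
#'
#' @param object A fitted `rehab_pipeline` (or a bundle from
#'   [load_bundle()]).
#' @param stream Data.frame `t,ch1,ch2,ch3` or 3 x n matrix of AD counts.
#' @param reference Optional length-3 resting reference. When `NULL`, it is
#'   initialized from the first `n_init` stream samples, which are then
#'   excluded from detection.
#' @param n_init Samples used by [initialize_reference()] when `reference`
#'   is `NULL`.
#' @param strict Abort on malformed rows instead of skipping them.
#' @return A data.frame of class `detection_events` with one row per event:
#'   `sample_index` (stream index of the accepting window's newest sample),
#'   `label`, and vote tallies `v1..v4`.
#' @export
run_detector <- function(object, stream, reference = NULL, n_init = 30L,
                         strict = FALSE) {
  stopifnot(inherits(object, "rehab_pipeline"))
  m <- stream_matrix(stream, strict = strict)
  offset <- 0L
  if (is.null(reference)) {
    reference <- initialize_reference(m, n_init)
    offset <- as.integer(n_init)
  }
  cfg <- object$config
  ws <- cfg$window_size
  n <- ncol(m)
  events <- data.frame(sample_index = integer(0), label = integer(0),
                       v1 = integer(0), v2 = integer(0), v3 = integer(0),
                       v4 = integer(0))
  if (n - offset < ws) return(structure(events, class = c("detection_events", "data.frame")))
  u <- m[, (offset + 1L):n, drop = FALSE] / as.numeric(reference)
  refract <- 0L
  for (end in ws:ncol(u)) {
    if (refract > 0L) { refract <- refract - 1L; next }
    w <- u[, (end - ws + 1L):end, drop = FALSE]
    if (is_action(w, cfg)) {
      v <- vote(object$ensemble,
                encode(object$autoencoder, flatten_sample(w)))
      events <- rbind(events, data.frame(
        sample_index = offset + end, label = v$winner,
        v1 = v$tallies[1], v2 = v$tallies[2], v3 = v$tallies[3],
        v4 = v$tallies[4]))
      refract <- cfg$refractory
    }
  }
  structure(events, class = c("detection_events", "data.frame"))
}

#' Serialize a fitted pipeline to JSON
#'
#' The bundle records the autoencoder weights, the six SVM hyperplanes, the
#' detection configuration, an optional resting reference and calibration,
#' and the training seed, so that a microcontroller-style forward pass can be
#' re-implemented from the file. [load_bundle()] restores a pipeline whose
#' predictions are bitwise identical to the original.
#'
#' @param object A `rehab_pipeline`.
#' @param path Output JSON path.
#' @param reference Optional length-3 resting reference to embed.
#' @param calibration Optional `hysteresis_calibration` to embed.
#' @export
save_bundle <- function(object, path, reference = NULL, calibration = NULL) {
  stopifnot(inherits(object, "rehab_pipeline"))
  l <- list(format = "rehabband_bundle", version = 1L,
            seed = object$seed,
            detection = unclass(object$config),
            autoencoder = ae_to_list(object$autoencoder),
            ensemble = ensemble_to_list(object$ensemble),
            training = object$training)
  if (!is.null(reference)) l$reference <- as.numeric(reference)
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "hysteresis_calibration"))
    l$calibration <- list(n_segments = calibration$n_segments,
                          seed = calibration$seed,
                          up = pwl_to_list(calibration$up),
                          down = pwl_to_list(calibration$down))
  }
  # 17 significant digits round-trip IEEE doubles exactly, so a saved
  # bundle reproduces the in-memory model bit for bit
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a fitted pipeline from JSON
#'
#' @param path JSON path written by [save_bundle()].
#' @return A `rehab_pipeline`; the embedded reference/calibration, when
#'   present, are attached as attributes `"reference"` and `"calibration"`.
#' @export
load_bundle <- function(path) {
  l <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE),
                error = function(e)
                  stop_input("cannot parse bundle file: ", conditionMessage(e)))
  if (is.null(l$format) || l$format != "rehabband_bundle")
    stop_input("not a rehabband bundle file")
  if (is.null(l$version) || l$version != 1L)
    stop_input("unsupported bundle version: ", l$version)
  ae <- ae_from_list(l$autoencoder)
  ens <- ensemble_from_list(l$ensemble)
  if (ae$config$code_dim != ens$code_dim)
    stop_input("inconsistent bundle: autoencoder code_dim ",
               ae$config$code_dim, " != ensemble code_dim ", ens$code_dim)
  d <- l$detection
  cfg <- detection_config(t1 = d$t1, t2 = d$t2, window_size = d$window_size,
                          step = d$step, prefix_len = d$prefix_len,
                          refractory = d$refractory)
  out <- structure(list(autoencoder = ae, ensemble = ens, config = cfg,
                        training = l$training, seed = l$seed),
                   class = "rehab_pipeline")
  if (!is.null(l$reference)) attr(out, "reference") <- as.numeric(l$reference)
  if (!is.null(l$calibration))
    attr(out, "calibration") <- structure(
      list(up = pwl_from_list(l$calibration$up),
           down = pwl_from_list(l$calibration$down),
           n_segments = as.integer(l$calibration$n_segments),
           seed = l$calibration$seed),
      class = "hysteresis_calibration")
  out
}
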