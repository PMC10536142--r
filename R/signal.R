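#' Validate a raw three-channel action sample
#'
#' A raw sample is a 3 x n matrix of AD counts: rows are the palmar, radial
#' and dorsal channels; columns are the 30 consecutive readings of a 2 s
#' action window at 15 Hz.
#'
#' @param ch Numeric 3 x `n_samples` matrix.
#' @param n_samples Expected number of readings per channel (default 30).
#' @return The validated matrix, invisibly classed as `raw_sample`.
#' @export
raw_sample <- function(ch, n_samples = 30L) {
  ch <- as.matrix(ch)
  if (nrow(ch) != 3L || ncol(ch) != n_samples)
    stop_input("raw sample must be a 3 x ", n_samples, " matrix, got ",
               nrow(ch), " x ", ncol(ch))
  if (any(!is.finite(ch))) stop_input("raw sample contains non-finite values")
  structure(ch, class = c("raw_sample", class(ch)))
}

#' Compute the per-channel resting reference
#'
#' The resting reference Ref_i is the arithmetic mean of the readings of
#' channel i over a relaxed-hand recording; every subsequent window of the
#' session is expressed as a ratio to it, which removes the dependence on how
#' tightly the wristband was strapped.
#'
#' @param resting A 3 x n matrix of AD counts recorded with the hand relaxed.
#' @return Numeric vector of 3 positive baselines, class `resting_reference`.
#' @export
compute_reference <- function(resting) {
  resting <- as.matrix(resting)
  if (nrow(resting) != 3L) stop_input("resting sample must have 3 channels")
  ref <- rowMeans(resting)
  if (any(!is.finite(ref)) || any(ref <= 0))
    stop_input("degenerate resting reference: channel means must be positive")
  structure(as.numeric(ref), class = "resting_reference")
}

#' Normalize a raw sample by its resting reference
#'
#' Every entry of the raw sample is divided by its channel's resting
#' reference: u_i(j) = ch_i(j) / Ref_i. The result is dimensionless and close
#' to 1 at rest.
#'
#' @param raw 3 x n matrix of AD counts.
#' @param ref Length-3 positive reference (see [compute_reference()]).
#' @return A 3 x n matrix of ratios.
#' @export
normalize_sample <- function(raw, ref) {
  raw <- as.matrix(raw)
  if (nrow(raw) != 3L) stop_input("raw sample must have 3 channels")
  ref <- as.numeric(ref)
  if (length(ref) != 3L || any(ref <= 0))
    stop_input("reference must be 3 positive values")
  raw / ref
}

#' Flatten a normalized sample into the 90-value classifier input
#'
#' The 3 x 30 normalized matrix is arranged channel-interleaved and
#' time-major: x = (u_1(1), u_2(1), u_3(1), u_1(2), ..., u_3(30)), i.e.
#' x(k) = u_a(b) with a = ((k-1) mod 3) + 1 and b = ceiling(k/3).
#'
#' @param u 3 x 30 numeric matrix.
#' @return Numeric vector of length 90.
#' @seealso [unflatten_sample()]
#' @export
flatten_sample <- function(u) {
  u <- as.matrix(u)
  if (nrow(u) != 3L || ncol(u) != 30L)
    stop_input("normalized sample must be 3 x 30")
  as.vector(u)   # column-major == channel-interleaved, time-major
}

#' Restore a 3 x 30 normalized matrix from its flattened form
#'
#' Inverse of [flatten_sample()].
#'
#' @param x Numeric vector of length 90.
#' @return 3 x 30 numeric matrix.
#' @export
unflatten_sample <- function(x) {
  if (length(x) != 90L) stop_input("feature vector must have length 90")
  matrix(as.numeric(x), nrow = 3L, ncol = 30L)
}

#' Write a labeled sample dataset to CSV
#'
#' One row per sample with columns
#' `subject,round,label,ch1_1..ch1_30,ch2_1..ch2_30,ch3_1..ch3_30`; a
#' companion reference file has columns `subject,round,ref1,ref2,ref3`.
#'
#' @param dataset A dataset as returned by [generate_dataset()]: a list with
#'   `samples` (list of 3 x 30 matrices), `labels`, `subject`, `round`, and
#'   `references` (per subject/round rows).
#' @param path Samples CSV path.
#' @param refs_path References CSV path.
#' @export
write_dataset <- function(dataset, path, refs_path) {
  mats <- dataset$samples
  flat <- t(vapply(mats, function(m) as.vector(t(m)), numeric(90)))
  colnames(flat) <- c(paste0("ch1_", 1:30), paste0("ch2_", 1:30),
                      paste0("ch3_", 1:30))
  d <- data.frame(subject = dataset$subject, round = dataset$round,
                  label = dataset$labels, flat, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  utils::write.csv(dataset$references, refs_path, row.names = FALSE)
  invisible(path)
}

#' Read a labeled sample dataset from CSV
#'
#' @param path Samples CSV written by [write_dataset()].
#' @param refs_path Companion references CSV.
#' @return A dataset list (`samples`, `labels`, `subject`, `round`,
#'   `references`).
#' @export
read_dataset <- function(path, refs_path) {
  d <- utils::read.csv(path, check.names = FALSE)
  refs <- utils::read.csv(refs_path)
  chcols <- c(paste0("ch1_", 1:30), paste0("ch2_", 1:30), paste0("ch3_", 1:30))
  if (!all(chcols %in% names(d)))
    stop_input("dataset CSV is missing channel columns")
  samples <- lapply(seq_len(nrow(d)), function(i)
    matrix(as.numeric(d[i, chcols]), nrow = 3L, byrow = TRUE))
  list(samples = samples, labels = as.integer(d$label),
       subject = as.integer(d$subject), round = as.integer(d$round),
       references = refs)
}

# Look up the (subject, round) reference row; returns length-3 numeric.
lookup_reference <- function(references, subject, round) {
  row <- references[references$subject == subject & references$round == round, ]
  if (nrow(row) != 1L)
    stop_input("no unique reference for subject ", subject, ", round ", round)
  as.numeric(row[1, c("ref1", "ref2", "ref3")])
}

# Normalize and flatten every sample of a dataset into an n x 90 matrix.
dataset_features <- function(dataset) {
  n <- length(dataset$samples)
  X <- matrix(NA_real_, n, 90L)
  for (i in seq_len(n)) {
    ref <- lookup_reference(dataset$references, dataset$subject[i],
                            dataset$round[i])
    X[i, ] <- flatten_sample(normalize_sample(dataset$samples[[i]], ref))
  }
  X
}
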