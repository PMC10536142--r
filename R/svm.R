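#' Train the one-vs-one linear SVM voting ensemble
#'
#' Fits six soft-margin linear SVMs (no kernel, cost C = 1), one per pair of
#' the four rehabilitation actions: S12, S13, S14, S23, S24, S34. Each member
#' is trained only on the samples of its two classes. At prediction time every
#' member casts one vote and the action with the most votes wins (see
#' [vote()]).
#'
#' @param codes Numeric matrix of encoded samples, one row per sample.
#' @param labels Integer class labels in 1..`n_classes`.
#' @param cost Soft-margin cost C (default 1).
#' @param n_classes Number of classes (default 4).
#' @return An object of class `svm_vote_ensemble`. Each member stores its
#'   class pair and the hyperplane in oriented form: decision value
#'   `w . x + b > 0` votes for the lower-indexed class of the pair.
#' @export
train_pairwise <- function(codes, labels, cost = 1, n_classes = 4L) {
  codes <- as.matrix(codes)
  labels <- as.integer(labels)
  if (nrow(codes) != length(labels))
    stop_input("codes and labels must have the same length")
  missing <- setdiff(seq_len(n_classes), unique(labels))
  if (length(missing) > 0)
    stop_input("no samples for class(es) ", paste(missing, collapse = ", "))

  members <- lapply(class_pairs(n_classes), function(pr) {
    i <- pr[1]; j <- pr[2]
    sel <- labels %in% pr
    Xp <- codes[sel, , drop = FALSE]
    yp <- factor(labels[sel], levels = pr)
    fit <- e1071::svm(Xp, yp, kernel = "linear", cost = cost,
                      scale = FALSE, type = "C-classification")
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # libsvm orients the decision value toward the class it saw first; flip
    # so positive always means the lower-indexed class of the pair
    pred <- stats::predict(fit, Xp, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    agree <- sum(sign(dv) == ifelse(pred == as.character(i), 1, -1))
    orient <- if (agree >= sum(sign(dv) != 0) / 2) 1 else -1
    list(pair = pr, w = orient * w, b = orient * b)
  })
  structure(list(members = members, cost = cost, n_classes = n_classes,
                 code_dim = ncol(codes)),
            class = "svm_vote_ensemble")
}

#' Cast the six pairwise votes for one encoded sample
#'
#' Each member SVM votes for one of its two classes by the sign of its
#' decision value (an exact zero, a measure-zero event, counts for the
#' lower-indexed class). Tallies therefore always sum to 6 and no class can
#' exceed 3 votes. A class that wins all three of its pairwise contests wins
#' outright. Ties on the tally are broken by the largest sum of decision
#' values oriented toward the tied class over the members involving it, then
#' by the lowest class index.
#'
#' @param ens A trained [train_pairwise()] ensemble.
#' @param code Numeric code vector.
#' @return An object of class `vote_result`: `tallies` (length 4, summing to
#'   6), `winner` (the predicted action label), and per-member `decisions`.
#' @export
vote <- function(ens, code) {
  stopifnot(inherits(ens, "svm_vote_ensemble"))
  code <- as.numeric(code)
  if (length(code) != ens$code_dim)
    stop_input("code has length ", length(code), ", ensemble expects ",
               ens$code_dim)
  k <- ens$n_classes
  tallies <- integer(k)
  score <- numeric(k)   # oriented decision-value sums, for tie-breaking
  dec <- data.frame(i = integer(0), j = integer(0), decision = numeric(0),
                    votes_for = integer(0))
  for (m in ens$members) {
    d <- sum(m$w * code) + m$b
    voted <- if (d >= 0) m$pair[1] else m$pair[2]
    tallies[voted] <- tallies[voted] + 1L
    score[m$pair[1]] <- score[m$pair[1]] + d
    score[m$pair[2]] <- score[m$pair[2]] - d
    dec <- rbind(dec, data.frame(i = m$pair[1], j = m$pair[2], decision = d,
                                 votes_for = voted))
  }
  cand <- which(tallies == max(tallies))
  if (length(cand) > 1L) cand <- cand[score[cand] == max(score[cand])]
  winner <- min(cand)
  structure(list(tallies = tallies, winner = as.integer(winner),
                 decisions = dec), class = "vote_result")
}

#' @export
print.vote_result <- function(x, ...) {
  cat("Votes:", paste(x$tallies, collapse = " "),
      "-> winner: action", x$winner, "\n")
  invisible(x)
}

#' Predict action labels for a matrix of codes
#'
#' @param object A `svm_vote_ensemble`.
#' @param newdata Code vector or matrix of code rows.
#' @param ... Unused.
#' @return Integer label(s).
#' @export
predict.svm_vote_ensemble <- function(object, newdata, ...) {
  X <- as_row_matrix(newdata, object$code_dim, "code")
  vapply(seq_len(nrow(X)), function(i) vote(object, X[i, ])$winner, integer(1))
}

#' @export
print.svm_vote_ensemble <- function(x, ...) {
  cat(sprintf("One-vs-one linear SVM ensemble: %d members over %d classes, C=%g, code dim %d\n",
              length(x$members), x$n_classes, x$cost, x$code_dim))
  invisible(x)
}

ensemble_to_list <- function(e) {
  list(cost = e$cost, n_classes = e$n_classes, code_dim = e$code_dim,
       members = lapply(e$members, function(m)
         list(pair = m$pair, w = m$w, b = m$b)))
}

ensemble_from_list <- function(l) {
  structure(list(
    members = lapply(l$members, function(m)
      list(pair = as.integer(unlist(m$pair)), w = as.numeric(unlist(m$w)),
           b = as.numeric(m$b))),
    cost = as.numeric(l$cost), n_classes = as.integer(l$n_classes),
    code_dim = as.integer(l$code_dim)
  ), class = "svm_vote_ensemble")
}
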