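# Stratified, seeded fold assignment: returns an integer fold id per sample.
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop_input("class ", cl, " has ", length(idx),
                   " samples; cannot make ", k, " folds")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Hyperparameter grid search by k-fold cross-validation
#'
#' For every (hidden_dim, code_dim) grid point, computes (a) the mean k-fold
#' validation mean-squared reconstruction error of the autoencoder (trained
#' on k-1 folds, evaluated on the held-out fold) and (b) the classification
#' error rate of the full voting pipeline. By default the pipeline error
#' follows the deployed evaluation procedure: the autoencoder is trained once
#' on all data, all data are encoded, and the SVM ensemble is k-fold
#' cross-validated on the codes. `leakage_free = TRUE` instead re-trains the
#' autoencoder inside each fold so the held-out fold never influences the
#' encoder.
#'
#' @param x Feature matrix (n x 90).
#' @param labels Integer labels 1--4.
#' @param hidden_grid,code_grid Integer vectors of layer sizes to scan.
#' @param k Number of folds (default 10).
#' @param epochs,batch_size,lr Autoencoder training settings.
#' @param cost SVM cost (default 1).
#' @param leakage_free Re-train the autoencoder per fold (default FALSE).
#' @param seed Integer seed (folds, initializations, batch order).
#' @return A data.frame of class `grid_result` with columns
#'   `hidden_dim,code_dim,cv_mse,error_rate`; attributes `k` and `seed`.
#' @export
grid_search <- function(x, labels, hidden_grid = seq(10L, 60L, 10L),
                        code_grid = seq(5L, 40L, 5L), k = 10L,
                        epochs = 200L, batch_size = 200L, lr = 1e-3,
                        cost = 1, leakage_free = FALSE, seed = 1L) {
  x <- as.matrix(x); labels <- as.integer(labels)
  if (length(hidden_grid) == 0L || length(code_grid) == 0L)
    stop_input("grids must be non-empty")
  fold <- stratified_folds(labels, k, seed)
  sub_seeds <- with_seed(seed, sample.int(2147483646L, 1L + k +
                                            length(hidden_grid) * length(code_grid) * (1L + k)))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; sub_seeds[si] }
  next_seed()  # reserve one draw so fold seeds differ from the fold assignment

  res <- NULL
  for (h in hidden_grid) for (cd in code_grid) {
    mses <- numeric(k)
    point_seed <- next_seed()
    ae_fold_seeds <- vapply(seq_len(k), function(i) next_seed(), integer(1))
    for (f in seq_len(k)) {
      tr <- x[fold != f, , drop = FALSE]
      va <- x[fold == f, , drop = FALSE]
      m <- suppressWarnings(
        train_autoencoder(tr, hidden_dim = h, code_dim = cd, epochs = epochs,
                          batch_size = batch_size, lr = lr,
                          seed = ae_fold_seeds[f]))
      mses[f] <- mean((reconstruct(m, va) - va)^2)
    }
    errs <- 0L
    if (!leakage_free) {
      ae_all <- suppressWarnings(
        train_autoencoder(x, hidden_dim = h, code_dim = cd, epochs = epochs,
                          batch_size = batch_size, lr = lr, seed = point_seed))
      codes <- encode(ae_all, x)
      for (f in seq_len(k)) {
        ens <- train_pairwise(codes[fold != f, , drop = FALSE],
                              labels[fold != f], cost = cost)
        pred <- predict(ens, codes[fold == f, , drop = FALSE])
        errs <- errs + sum(pred != labels[fold == f])
      }
    } else {
      for (f in seq_len(k)) {
        ae_f <- suppressWarnings(
          train_autoencoder(x[fold != f, , drop = FALSE], hidden_dim = h,
                            code_dim = cd, epochs = epochs,
                            batch_size = batch_size, lr = lr,
                            seed = ae_fold_seeds[f]))
        ens <- train_pairwise(encode(ae_f, x[fold != f, , drop = FALSE]),
                              labels[fold != f], cost = cost)
        pred <- predict(ens, encode(ae_f, x[fold == f, , drop = FALSE]))
        errs <- errs + sum(pred != labels[fold == f])
      }
    }
    res <- rbind(res, data.frame(hidden_dim = h, code_dim = cd,
                                 cv_mse = mean(mses),
                                 error_rate = errs / nrow(x)))
  }
  structure(res, k = k, seed = seed, leakage_free = leakage_free,
            class = c("grid_result", "data.frame"))
}

#' Generalized k-fold linear-separability test
#'
#' Quantifies how linearly separable two sets of encoded samples are. Each
#' set is shuffled (seeded) and split into k subsets; in fold i a linear SVM
#' (C = 1, no kernel) is trained on the small pair A_i and B_i only and
#' evaluated on all remaining samples. Low mean misclassification means the
#' two classes are far apart in code space, so a linear classifier trained on
#' few samples already generalizes.
#'
#' @param A,B Numeric matrices of code rows for the two classes.
#' @param k Number of folds (default 5).
#' @param cost SVM cost (default 1).
#' @param seed Integer seed for the shuffles.
#' @return An object of class `separability_result`: per-fold `rates` and
#'   their `mean`.
#' @export
generalized_kfold <- function(A, B, k = 5L, cost = 1, seed = 1L) {
  A <- as.matrix(A); B <- as.matrix(B)
  k <- as.integer(k)
  if (nrow(A) < k || nrow(B) < k)
    stop_input("each class needs at least k = ", k, " samples")
  with_seed(seed, {
    fa <- sample(rep_len(seq_len(k), nrow(A)))
    fb <- sample(rep_len(seq_len(k), nrow(B)))
    rates <- vapply(seq_len(k), function(i) {
      Xtr <- rbind(A[fa == i, , drop = FALSE], B[fb == i, , drop = FALSE])
      ytr <- factor(c(rep(1L, sum(fa == i)), rep(0L, sum(fb == i))),
                    levels = c(1L, 0L))
      Xte <- rbind(A[fa != i, , drop = FALSE], B[fb != i, , drop = FALSE])
      yte <- c(rep(1L, sum(fa != i)), rep(0L, sum(fb != i)))
      fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost,
                        scale = FALSE, type = "C-classification")
      pred <- as.integer(as.character(stats::predict(fit, Xte)))
      mean(pred != yte)
    }, numeric(1))
    structure(list(rates = rates, mean = mean(rates), k = k, seed = seed),
              class = "separability_result")
  })
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("Generalized %d-fold separability: mean misclassification %.4f\n",
              x$k, x$mean))
  cat("Per-fold rates:", paste(signif(x$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Separability of every class pair
#'
#' Runs [generalized_kfold()] for each of the six action pairs.
#'
#' @param codes Code matrix, one row per sample.
#' @param labels Integer labels 1--4.
#' @inheritParams generalized_kfold
#' @return Data.frame with columns `i,j,mean_rate` and one row per pair.
#' @export
separability_matrix <- function(codes, labels, k = 5L, cost = 1, seed = 1L) {
  codes <- as.matrix(codes); labels <- as.integer(labels)
  out <- NULL
  for (pr in class_pairs(4L)) {
    r <- generalized_kfold(codes[labels == pr[1], , drop = FALSE],
                           codes[labels == pr[2], , drop = FALSE],
                           k = k, cost = cost, seed = seed)
    out <- rbind(out, data.frame(i = pr[1], j = pr[2], mean_rate = r$mean))
  }
  out
}

#' Build a confusion matrix with a not-recognized column
#'
#' Predictions may be `NA`, meaning the window was not recognized as any
#' action (e.g. rejected by the pre-detection gate); these fall into an extra
#' `none` column so false negatives include unrecognized actions.
#'
#' @param truth Integer true labels 1--`n_classes`.
#' @param pred Integer predicted labels, `NA` for not recognized.
#' @param n_classes Number of classes (default 4).
#' @return Integer matrix `n_classes x (n_classes + 1)`, rows = truth,
#'   columns = predicted classes plus `none`.
#' @export
confusion_matrix <- function(truth, pred, n_classes = 4L) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  m <- matrix(0L, n_classes, n_classes + 1L,
              dimnames = list(truth = as.character(seq_len(n_classes)),
                              predicted = c(as.character(seq_len(n_classes)),
                                            "none")))
  for (i in seq_along(truth)) {
    col <- if (is.na(pred[i])) n_classes + 1L else pred[i]
    m[truth[i], col] <- m[truth[i], col] + 1L
  }
  m
}

#' Precision, recall and f1 from a confusion matrix
#'
#' For action X: TP is the count of X recognized as X; FP counts other
#' actions recognized as X; FN counts X recognized as another action or not
#' recognized at all (the `none` column). Per class,
#' P = TP/(TP+FP) x 100, R = TP/(TP+FN) x 100, f1 = 2PR/(P+R). Aggregate
#' precision and recall are unweighted (macro) means over the classes and
#' the aggregate f1 is the harmonic mean of the aggregate P and R.
#'
#' @param confusion Counts matrix: rows = truth, columns = predicted classes,
#'   optionally plus a final `none` column (see [confusion_matrix()]).
#' @return An object of class `rehab_metrics`: `per_class` data.frame
#'   (`class,TP,FP,FN,precision,recall,f1`, percentages; NA and a flag where
#'   TP+FP = 0), `macro` list (`precision,recall,f1`), `error_rate`
#'   (1 - accuracy over all counted samples) and the input matrix.
#' @export
compute_metrics <- function(confusion) {
  m <- as.matrix(confusion)
  if (any(m < 0)) stop_input("confusion counts must be non-negative")
  nc <- nrow(m)
  if (!ncol(m) %in% c(nc, nc + 1L))
    stop_input("confusion matrix must be square or have one extra 'none' column")
  tp <- diag(m[, seq_len(nc), drop = FALSE])
  fp <- colSums(m[, seq_len(nc), drop = FALSE]) - tp
  fn <- rowSums(m) - tp
  prec <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  rec <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(prec) & !is.na(rec) & prec + rec > 0,
               2 * prec * rec / (prec + rec), NA_real_)
  per_class <- data.frame(class = seq_len(nc), TP = tp, FP = fp, FN = fn,
                          precision = prec, recall = rec, f1 = f1,
                          undefined = is.na(prec) | is.na(rec))
  macro <- macro_summary(prec, rec)
  structure(list(per_class = per_class, macro = macro,
                 error_rate = 1 - sum(tp) / sum(m), confusion = m),
            class = "rehab_metrics")
}

#' Macro-average per-class precisions and recalls
#'
#' The aggregate precision and recall are the unweighted means of the
#' per-class values (in percent); the aggregate f1 is the harmonic mean
#' 2PR/(P+R) of those aggregates.
#'
#' @param precision,recall Numeric vectors of per-class percentages.
#' @return List with `precision`, `recall` and `f1` (percent).
#' @export
macro_summary <- function(precision, recall) {
  p <- mean(precision, na.rm = TRUE)
  r <- mean(recall, na.rm = TRUE)
  list(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

#' @export
print.rehab_metrics <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("Macro precision %.2f, recall %.2f, f1 %.2f; error rate %.4f\n",
              x$macro$precision, x$macro$recall, x$macro$f1, x$error_rate))
  invisible(x)
}
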