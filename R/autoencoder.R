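#' Train a single-hidden-layer autoencoder
#'
#' Reduces the 90-dimensional flattened action window to a low-dimensional
#' code. The encoder is input -> hidden (tanh) -> code (linear); the decoder
#' mirrors it, code -> hidden (tanh) -> input (linear), with untied weights.
#' Training minimizes the mean-squared reconstruction error with Adam on
#' mini-batches; the data are split at random into training and validation
#' sets and both errors are recorded per epoch. All randomness (split,
#' initialization, batch order) is governed by `seed`.
#'
#' @param x Numeric matrix, one sample per row (typically n x 90).
#' @param hidden_dim Hidden layer width (default 40).
#' @param code_dim Code (output-of-encoder) width (default 10). A code wider
#'   than the hidden layer is allowed but triggers a warning: such networks
#'   converge poorly.
#' @param epochs Training epochs (default 500).
#' @param batch_size Mini-batch size (default 200); datasets smaller than one
#'   batch are trained full-batch.
#' @param lr Adam step size (default 1e-3).
#' @param val_frac Fraction held out for validation (default 0.2, an 8:2
#'   split).
#' @param seed Integer seed.
#' @return An object of class `rehab_autoencoder`: weight matrices `W1..W4`,
#'   biases `b1..b4`, the training `history` (data.frame
#'   `epoch,train_mse,val_mse`), the held-out row indices, and the
#'   configuration.
#' @seealso [encode()], [reconstruct()]
#' @export
train_autoencoder <- function(x, hidden_dim = 40L, code_dim = 10L,
                              epochs = 500L, batch_size = 200L, lr = 1e-3,
                              val_frac = 0.2, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop_input("need at least 2 samples to train")
  if (any(!is.finite(x))) stop_input("training data contain non-finite values")
  d <- ncol(x)
  hidden_dim <- as.integer(hidden_dim); code_dim <- as.integer(code_dim)
  if (hidden_dim < 1L || code_dim < 1L) stop_input("layer sizes must be positive")
  if (code_dim >= hidden_dim)
    warning("code_dim >= hidden_dim: such autoencoders converge poorly")

  with_seed(seed, {
    n <- nrow(x)
    n_val <- max(1L, min(n - 1L, round(val_frac * n)))
    val_idx <- sample.int(n, n_val)
    xtr <- x[-val_idx, , drop = FALSE]
    xva <- x[val_idx, , drop = FALSE]

    uinit <- function(nin, nout) {
      lim <- 1 / sqrt(nin)
      matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
    }
    par <- list(W1 = uinit(d, hidden_dim), b1 = numeric(hidden_dim),
                W2 = uinit(hidden_dim, code_dim), b2 = numeric(code_dim),
                W3 = uinit(code_dim, hidden_dim), b3 = numeric(hidden_dim),
                W4 = uinit(hidden_dim, d), b4 = numeric(d))
    m <- lapply(par, function(p) p * 0)
    v <- lapply(par, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_step <- 0L

    fwd <- function(X) {
      h1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
      cd <- sweep(h1 %*% par$W2, 2, par$b2, "+")
      h2 <- tanh(sweep(cd %*% par$W3, 2, par$b3, "+"))
      xh <- sweep(h2 %*% par$W4, 2, par$b4, "+")
      list(h1 = h1, code = cd, h2 = h2, xhat = xh)
    }
    mse <- function(X) mean((fwd(X)$xhat - X)^2)

    bs <- min(as.integer(batch_size), nrow(xtr))
    history <- data.frame(epoch = seq_len(epochs),
                          train_mse = NA_real_, val_mse = NA_real_)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(xtr))
      for (start in seq(1L, nrow(xtr), by = bs)) {
        idx <- ord[start:min(start + bs - 1L, nrow(xtr))]
        X <- xtr[idx, , drop = FALSE]
        f <- fwd(X)
        nb <- nrow(X)
        g_xh <- 2 * (f$xhat - X) / (nb * d)
        gr <- list(
          W4 = crossprod(f$h2, g_xh), b4 = colSums(g_xh))
        d_h2 <- (g_xh %*% t(par$W4)) * (1 - f$h2^2)
        gr$W3 <- crossprod(f$code, d_h2); gr$b3 <- colSums(d_h2)
        d_cd <- d_h2 %*% t(par$W3)
        gr$W2 <- crossprod(f$h1, d_cd); gr$b2 <- colSums(d_cd)
        d_h1 <- (d_cd %*% t(par$W2)) * (1 - f$h1^2)
        gr$W1 <- crossprod(X, d_h1); gr$b1 <- colSums(d_h1)

        t_step <- t_step + 1L
        for (nm in names(par)) {
          g <- gr[[nm]]
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
          mhat <- m[[nm]] / (1 - beta1^t_step)
          vhat <- v[[nm]] / (1 - beta2^t_step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      history$train_mse[ep] <- mse(xtr)
      history$val_mse[ep] <- mse(xva)
    }

    structure(list(
      W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
      W3 = par$W3, b3 = par$b3, W4 = par$W4, b4 = par$b4,
      history = history, val_idx = sort(val_idx),
      config = list(input_dim = d, hidden_dim = hidden_dim,
                    code_dim = code_dim, epochs = epochs,
                    batch_size = batch_size, lr = lr, val_frac = val_frac,
                    seed = seed)
    ), class = "rehab_autoencoder")
  })
}

as_row_matrix <- function(x, d, what) {
  if (is.null(dim(x))) {
    if (length(x) != d) stop_input(what, " must have length ", d)
    x <- matrix(x, nrow = 1L)
  } else {
    x <- as.matrix(x)
    if (ncol(x) != d) stop_input(what, " must have ", d, " columns")
  }
  x
}

#' Encode samples to their low-dimensional codes
#'
#' @param model A trained [train_autoencoder()] model.
#' @param x A feature vector (length `input_dim`) or a matrix of rows.
#' @return A code vector, or a matrix of code rows.
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "rehab_autoencoder"))
  single <- is.null(dim(x))
  X <- as_row_matrix(x, model$config$input_dim, "input")
  h1 <- tanh(sweep(X %*% model$W1, 2, model$b1, "+"))
  cd <- sweep(h1 %*% model$W2, 2, model$b2, "+")
  if (single) drop(cd) else cd
}

#' Decode codes back to the input space
#'
#' @param model A trained [train_autoencoder()] model.
#' @param code A code vector (length `code_dim`) or a matrix of code rows.
#' @return Reconstructed feature vector(s).
#' @export
decode <- function(model, code) {
  stopifnot(inherits(model, "rehab_autoencoder"))
  single <- is.null(dim(code))
  C <- as_row_matrix(code, model$config$code_dim, "code")
  h2 <- tanh(sweep(C %*% model$W3, 2, model$b3, "+"))
  xh <- sweep(h2 %*% model$W4, 2, model$b4, "+")
  if (single) drop(xh) else xh
}

#' Encode-then-decode reconstruction
#'
#' @inheritParams encode
#' @return Reconstructed feature vector(s), same shape as `x`.
#' @export
reconstruct <- function(model, x) decode(model, encode(model, x))

#' @export
predict.rehab_autoencoder <- function(object, newdata,
                                      type = c("reconstruction", "code"), ...) {
  type <- match.arg(type)
  if (type == "code") encode(object, newdata) else reconstruct(object, newdata)
}

#' @export
print.rehab_autoencoder <- function(x, ...) {
  cfg <- x$config
  h <- x$history
  cat(sprintf("Autoencoder %d -> %d -> %d (tanh hidden, linear code), mirrored decoder\n",
              cfg$input_dim, cfg$hidden_dim, cfg$code_dim))
  cat(sprintf("Trained %d epochs (batch %d, Adam lr %g, seed %s); final train MSE %.4g, val MSE %.4g\n",
              cfg$epochs, cfg$batch_size, cfg$lr, cfg$seed,
              h$train_mse[nrow(h)], h$val_mse[nrow(h)]))
  invisible(x)
}

#' @export
plot.rehab_autoencoder <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_mse, h$val_mse), type = "l",
                    lty = 1, col = c("steelblue", "red3"),
                    xlab = "Epoch", ylab = "MSE", main = "Autoencoder training", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "red3"), bty = "n")
  invisible(x)
}

#' Export the training history as CSV
#'
#' @param model A trained autoencoder.
#' @param path Output CSV path (`epoch,train_mse,val_mse`).
#' @export
write_history <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

ae_to_list <- function(m) {
  list(config = m$config,
       W1 = m$W1, b1 = m$b1, W2 = m$W2, b2 = m$b2,
       W3 = m$W3, b3 = m$b3, W4 = m$W4, b4 = m$b4)
}

ae_from_list <- function(l) {
  cfg <- l$config
  as_mat <- function(w) matrix(unlist(w), nrow = length(w), byrow = TRUE)
  fix <- function(w, nr, nc) {
    w <- if (is.matrix(w)) w else as_mat(w)
    if (!all(dim(w) == c(nr, nc))) stop_input("autoencoder weight shape mismatch")
    w
  }
  d <- cfg$input_dim; h <- cfg$hidden_dim; k <- cfg$code_dim
  structure(list(
    W1 = fix(l$W1, d, h), b1 = as.numeric(l$b1),
    W2 = fix(l$W2, h, k), b2 = as.numeric(l$b2),
    W3 = fix(l$W3, k, h), b3 = as.numeric(l$b3),
    W4 = fix(l$W4, h, d), b4 = as.numeric(l$b4),
    history = NULL, val_idx = NULL, config = cfg
  ), class = "rehab_autoencoder")
}
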