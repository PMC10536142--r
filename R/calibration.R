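#' Calibration sweep of a thin-film pressure sensor
#'
#' A sweep pairs raw analog-to-digital (AD) counts with reference forces in
#' gram-force (gf), recorded while the applied pressure was either gradually
#' increased (loading) or gradually decreased (unloading). Thin-film
#' force-sensitive resistors are hysteretic, so the two directions trace
#' different curves and are calibrated separately.
#'
#' @param ad Numeric vector of AD counts.
#' @param force Numeric vector of reference forces (gf), non-negative, same
#'   length as `ad`.
#' @param direction `"loading"` or `"unloading"`.
#' @return An object of class `calibration_sweep`.
#' @export
calibration_sweep <- function(ad, force, direction = c("loading", "unloading")) {
  direction <- match.arg(direction)
  ad <- as.numeric(ad); force <- as.numeric(force)
  if (length(ad) != length(force))
    stop_input("ad and force must have the same length")
  if (any(!is.finite(ad)) || any(!is.finite(force)))
    stop_input("ad and force must be finite")
  if (any(force < 0))
    stop_input("forces must be non-negative")
  structure(list(ad = ad, force = force, direction = direction),
            class = "calibration_sweep")
}

#' @export
print.calibration_sweep <- function(x, ...) {
  cat(sprintf("Calibration sweep (%s): %d points, AD [%g, %g], force [%g, %g] gf\n",
              x$direction, length(x$ad), min(x$ad), max(x$ad),
              min(x$force), max(x$force)))
  invisible(x)
}

# Hinge basis for a continuous piecewise-linear function with interior
# breakpoints psi: columns 1, x, (x - psi_k)_+.
hinge_design <- function(x, psi) {
  X <- cbind(1, x)
  for (p in psi) X <- cbind(X, pmax(x - p, 0))
  X
}

pwl_rss <- function(x, y, psi) {
  X <- hinge_design(x, psi)
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

# One Muggeo-style breakpoint refinement pass: augment the hinge design with
# the indicator columns -(x > psi_k); the fitted ratio gamma_k / c_k is the
# first-order correction to psi_k. Damped until the RSS does not increase.
refine_breakpoints <- function(x, y, psi, max_iter = 60L, tol = 1e-10) {
  lo <- min(x); hi <- max(x)
  sep <- (hi - lo) * 1e-6
  clamp <- function(p) {
    p <- sort(p)
    p <- pmin(pmax(p, lo + sep), hi - sep)
    for (k in seq_along(p)[-1])
      if (p[k] - p[k - 1] < sep) p[k] <- p[k - 1] + sep
    pmin(p, hi - sep)
  }
  psi <- clamp(psi)
  rss <- pwl_rss(x, y, psi)
  for (it in seq_len(max_iter)) {
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
    V <- vapply(psi, function(p) -as.numeric(x > p), numeric(length(x)))
    X <- cbind(1, x, U, V)
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients
    k <- length(psi)
    ck <- cf[2 + seq_len(k)]
    gk <- cf[2 + k + seq_len(k)]
    ck[is.na(ck)] <- 0; gk[is.na(gk)] <- 0
    step <- ifelse(abs(ck) > 1e-12, gk / ck, 0)
    if (all(abs(step) < tol * (hi - lo) + 1e-14)) break
    h <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- clamp(psi + h * step)
      rss_new <- pwl_rss(x, y, cand)
      if (rss_new <= rss + 1e-14) {
        psi <- cand; improved <- rss_new < rss - tol * max(rss, 1); rss <- rss_new
        break
      }
      h <- h / 2
    }
    if (!improved && rss < 1e-20) break
    if (!improved && h < 1e-8) break
  }
  list(psi = psi, rss = rss)
}

#' Fit a continuous piecewise-linear calibration curve
#'
#' Fits force (gf) as a continuous piecewise-linear least-squares function of
#' the AD count with a fixed number of segments. Interior breakpoint positions
#' are chosen by numerical minimization of the residual sum of squares
#' (iterative breakpoint refinement from several seeded random starts).
#'
#' @param sweep A [calibration_sweep()].
#' @param n_segments Number of linear segments (default 9).
#' @param n_starts Number of random restarts for breakpoint optimization, in
#'   addition to the quantile-based start.
#' @param seed Integer seed controlling the random restarts.
#' @return An object of class `pwl_fit` with components `breakpoints` (the
#'   n_segments+1 segment boundaries, ends at the data range), `slopes`,
#'   `intercepts`, the hinge-basis coefficients, fitted values and residuals.
#' @seealso [fit_hysteresis_pair()], [predict.pwl_fit()]
#' @export
fit_piecewise <- function(sweep, n_segments = 9L, n_starts = 8L, seed = 1L) {
  stopifnot(inherits(sweep, "calibration_sweep"))
  n_segments <- as.integer(n_segments)
  if (n_segments < 1L) stop_input("n_segments must be >= 1")
  x <- sweep$ad; y <- sweep$force
  if (length(x) < 2L * (n_segments + 1L))
    stop_input("need at least ", 2L * (n_segments + 1L),
               " points to fit ", n_segments, " segments")
  if (diff(range(x)) <= 0)
    stop_input("AD values span a zero range; cannot fit a curve")

  k <- n_segments - 1L
  best <- NULL
  if (k == 0L) {
    best <- list(psi = numeric(0), rss = pwl_rss(x, y, numeric(0)))
  } else {
    starts <- list(stats::quantile(x, probs = seq_len(k) / n_segments,
                                   names = FALSE))
    with_seed(seed, {
      for (s in seq_len(n_starts)) {
        starts[[length(starts) + 1L]] <-
          sort(stats::runif(k, min(x), max(x)))
      }
    })
    for (ps in starts) {
      res <- refine_breakpoints(x, y, ps)
      if (is.null(best) || res$rss < best$rss) best <- res
      if (best$rss < 1e-18) break
    }
  }
  psi <- best$psi
  X <- hinge_design(x, psi)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  # per-segment slope/intercept from cumulative hinge coefficients
  bounds <- c(min(x), psi, max(x))
  slopes <- cf[2] + c(0, cumsum(cf[-(1:2)]))
  intercepts <- numeric(n_segments)
  intercepts[1] <- cf[1]
  if (n_segments > 1L) {
    for (s in 2:n_segments) {
      # continuity at the left boundary of segment s
      b <- bounds[s]
      intercepts[s] <- intercepts[s - 1] + (slopes[s - 1] - slopes[s]) * b
    }
  }
  structure(list(
    breakpoints = bounds,
    slopes = unname(slopes),
    intercepts = unname(intercepts),
    coefficients = unname(cf),
    psi = psi,
    n_segments = n_segments,
    direction = sweep$direction,
    rss = best$rss,
    sigma = sqrt(best$rss / max(1, length(x) - length(cf))),
    fitted.values = unname(X %*% cf)[, 1],
    residuals = y - unname(X %*% cf)[, 1],
    data = list(ad = x, force = y),
    seed = seed
  ), class = "pwl_fit")
}

#' Predict force from AD counts with a piecewise-linear fit
#'
#' AD values outside the calibrated range are linearly extrapolated from the
#' terminal segments (with a warning).
#'
#' @param object A `pwl_fit`.
#' @param ad Numeric vector of AD counts.
#' @param warn Warn when extrapolating outside the fitted AD range.
#' @param ... Unused.
#' @return Predicted forces (gf).
#' @export
predict.pwl_fit <- function(object, ad, warn = TRUE, ...) {
  ad <- as.numeric(ad)
  rng <- range(object$breakpoints)
  if (warn && any(ad < rng[1] | ad > rng[2]))
    warning("AD values outside the calibrated range [", rng[1], ", ", rng[2],
            "]; extrapolating terminal segments")
  drop(hinge_design(ad, object$psi) %*% object$coefficients)
}

#' @export
coef.pwl_fit <- function(object, ...) {
  data.frame(segment = seq_len(object$n_segments),
             from_ad = object$breakpoints[-length(object$breakpoints)],
             to_ad = object$breakpoints[-1],
             slope = object$slopes,
             intercept = object$intercepts)
}

#' @export
residuals.pwl_fit <- function(object, ...) object$residuals

#' @export
print.pwl_fit <- function(x, ...) {
  cat(sprintf("Piecewise-linear calibration fit (%s): %d segments, RSS %.4g gf^2, sigma %.3g gf\n",
              x$direction, x$n_segments, x$rss, x$sigma))
  cat("Breakpoints (AD): ", paste(signif(x$breakpoints, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.pwl_fit <- function(x, ...) {
  graphics::plot(x$data$ad, x$data$force, pch = 16, cex = 0.4, col = "grey40",
                 xlab = "AD count", ylab = "Force (gf)",
                 main = sprintf("Piecewise-linear fit (%s)", x$direction), ...)
  ord <- order(x$data$ad)
  graphics::lines(x$data$ad[ord], x$fitted.values[ord], col = "red3", lwd = 2)
  graphics::abline(v = x$psi, lty = 3, col = "grey60")
  invisible(x)
}

#' Fit a hysteresis-aware calibration from loading and unloading sweeps
#'
#' Loading and unloading sweeps of a hysteretic pressure sensor are fitted
#' independently; [predict.hysteresis_calibration()] averages the two curves,
#' which is the deployed pressure-prediction rule.
#'
#' @param up Loading [calibration_sweep()].
#' @param down Unloading [calibration_sweep()].
#' @inheritParams fit_piecewise
#' @return An object of class `hysteresis_calibration` with members `up` and
#'   `down`, both `pwl_fit`.
#' @export
fit_hysteresis_pair <- function(up, down, n_segments = 9L, n_starts = 8L,
                                seed = 1L) {
  stopifnot(inherits(up, "calibration_sweep"), inherits(down, "calibration_sweep"))
  if (up$direction != "loading")
    stop_input("`up` must be a loading sweep, got ", up$direction)
  if (down$direction != "unloading")
    stop_input("`down` must be an unloading sweep, got ", down$direction)
  structure(list(
    up = fit_piecewise(up, n_segments, n_starts, seed),
    down = fit_piecewise(down, n_segments, n_starts, seed),
    n_segments = as.integer(n_segments),
    seed = seed
  ), class = "hysteresis_calibration")
}

#' Predict pressure as the average of the loading and unloading fits
#'
#' @param object A `hysteresis_calibration`.
#' @param ad Numeric vector of AD counts.
#' @param warn Warn when extrapolating outside the fitted AD range.
#' @param ... Unused.
#' @return Predicted forces (gf).
#' @export
predict.hysteresis_calibration <- function(object, ad, warn = TRUE, ...) {
  (predict(object$up, ad, warn = warn) + predict(object$down, ad, warn = warn)) / 2
}

#' @export
print.hysteresis_calibration <- function(x, ...) {
  cat("Hysteresis calibration (prediction = mean of loading and unloading fits)\n")
  print(x$up); print(x$down)
  invisible(x)
}

#' Pressure-prediction error report
#'
#' The calibration error is the signed difference between predicted and true
#' force, `f_error = f_predict - f_true`; the relative error divides by the
#' true force and is undefined (NA, flagged) when the true force is zero.
#'
#' @param pred Predicted forces (gf).
#' @param true True forces (gf), non-negative.
#' @return A data.frame of class `calibration_report` with columns
#'   `f_predict`, `f_true`, `f_error`, `percent_error` (in percent; NA where
#'   `f_true == 0`) and `undefined` flagging those rows.
#' @export
calibration_error <- function(pred, true) {
  pred <- as.numeric(pred); true <- as.numeric(true)
  if (length(pred) != length(true))
    stop_input("pred and true must have the same length")
  if (any(true < 0)) stop_input("true forces must be non-negative")
  err <- pred - true
  pct <- ifelse(true > 0, 100 * err / true, NA_real_)
  structure(data.frame(f_predict = pred, f_true = true, f_error = err,
                       percent_error = pct, undefined = true == 0),
            class = c("calibration_report", "data.frame"))
}

#' Read calibration sweeps from CSV
#'
#' Expects columns `ad,force_gf,direction` and returns one
#' [calibration_sweep()] per direction present.
#'
#' @param path CSV file path.
#' @return Named list with elements `loading` and/or `unloading`.
#' @export
read_sweeps <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ad", "force_gf", "direction")
  if (!all(need %in% names(d)))
    stop_input("sweep CSV must have columns ", paste(need, collapse = ","))
  out <- list()
  for (dir in unique(d$direction)) {
    sub <- d[d$direction == dir, ]
    out[[dir]] <- calibration_sweep(sub$ad, sub$force_gf, dir)
  }
  out
}

#' Write calibration sweeps to CSV
#'
#' @param sweeps A list of [calibration_sweep()] objects.
#' @param path Output CSV path.
#' @export
write_sweeps <- function(sweeps, path) {
  rows <- lapply(sweeps, function(s)
    data.frame(ad = s$ad, force_gf = s$force, direction = s$direction))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

pwl_to_list <- function(f) {
  list(n_segments = f$n_segments, direction = f$direction,
       breakpoints = f$breakpoints, slopes = f$slopes,
       intercepts = f$intercepts, coefficients = f$coefficients,
       psi = f$psi, rss = f$rss, seed = f$seed)
}

pwl_from_list <- function(l) {
  structure(list(
    breakpoints = as.numeric(l$breakpoints), slopes = as.numeric(l$slopes),
    intercepts = as.numeric(l$intercepts),
    coefficients = as.numeric(l$coefficients), psi = as.numeric(l$psi),
    n_segments = as.integer(l$n_segments), direction = l$direction,
    rss = as.numeric(l$rss), sigma = NA_real_, fitted.values = NULL,
    residuals = NULL, data = NULL, seed = l$seed
  ), class = "pwl_fit")
}

#' Serialize a hysteresis calibration to JSON
#'
#' @param object A `hysteresis_calibration`.
#' @param path Output JSON path.
#' @export
write_calibration <- function(object, path) {
  stopifnot(inherits(object, "hysteresis_calibration"))
  jsonlite::write_json(list(type = "hysteresis_calibration",
                            n_segments = object$n_segments, seed = object$seed,
                            up = pwl_to_list(object$up),
                            down = pwl_to_list(object$down)),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a hysteresis calibration from JSON
#'
#' @param path JSON path written by [write_calibration()].
#' @return A `hysteresis_calibration`.
#' @export
read_calibration <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(l$type) || l$type != "hysteresis_calibration")
    stop_input("not a hysteresis_calibration JSON file")
  structure(list(up = pwl_from_list(l$up), down = pwl_from_list(l$down),
                 n_segments = as.integer(l$n_segments), seed = l$seed),
            class = "hysteresis_calibration")
}
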