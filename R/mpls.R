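#' Modified partial least squares regression
#'
#' Fits a PLS1 model by sequential NIPALS factor extraction on centred data.
#' With `standardize_residuals = TRUE` (the default) the fit follows the
#' Shenk-Westerhaus "modified" PLS: after each factor is extracted and
#' deflated, the X-residual columns and the y-residuals are divided by their
#' current standard deviations before the next factor is sought, and the
#' scalings are recorded so prediction replays the identical chain. With the
#' flag off the fit reduces exactly to plain NIPALS PLS1, which serves as a
#' cross-check mode.
#'
#' @param X predictors, samples x wavelengths (pre-treated absorbance).
#' @param y numeric response vector (reference values).
#' @param max_factors number of factors to extract.
#' @param standardize_residuals re-standardise residuals between factors
#'   (the MPLS modification).
#' @return An object of class `mpls_model` with per-factor weights, loadings,
#'   regression scalars and scaling vectors, centring means, and the training
#'   prediction path (fitted values at every factor count).
#' @examples
#' X <- matrix(rnorm(200), 20)
#' m <- mpls_fit(X, rnorm(20), max_factors = 3)
#' mpls_predict(m, X)
#' @export
mpls_fit <- function(X, y, max_factors, standardize_residuals = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); W <- ncol(X)
  if (length(y) != n) abort("`y` must have one value per row of `X`.")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("`X` and `y` must be finite.")
  }
  if (max_factors < 1) abort("`max_factors` must be at least 1.")
  if (max_factors >= n - 1) abort("`max_factors` must be below n - 1.")
  if (sd(y) < 1e-12) abort("`y` has zero variance.")

  mx <- colMeans(X)
  my <- mean(y)
  E <- sweep(X, 2, mx)
  f <- y - my

  wts <- vector("list", max_factors)   # weight vectors
  lds <- vector("list", max_factors)   # X loadings
  qs <- numeric(max_factors)           # y loadings
  sxs <- vector("list", max_factors)   # X residual scalings
  sys <- numeric(max_factors)          # y residual scalings
  scores <- matrix(NA_real_, n, max_factors)
  fitted_path <- matrix(NA_real_, n, max_factors)

  yhat <- rep(0, n)
  yscale <- 1     # cumulative product of y scalings applied so far
  p_eff <- 0
  for (k in seq_len(max_factors)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break      # residual information exhausted
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-24) break
    p <- drop(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - t * q
    yhat <- yhat + yscale * q * t
    sx <- rep(1, W); sy <- 1
    if (standardize_residuals && k < max_factors) {
      csd <- sqrt(colSums(E^2) / (n - 1))
      sx <- ifelse(csd < 1e-12, 1, csd)
      fsd <- sqrt(sum(f^2) / (n - 1))
      sy <- if (fsd < 1e-12) 1 else fsd
      E <- sweep(E, 2, sx, "/")
      f <- f / sy
    }
    wts[[k]] <- w; lds[[k]] <- p; qs[k] <- q
    sxs[[k]] <- sx; sys[k] <- sy
    scores[, k] <- t
    fitted_path[, k] <- my + yhat
    yscale <- yscale * sy
    p_eff <- k
  }
  if (p_eff == 0) abort("no usable factor could be extracted.")
  structure(
    list(n_factors = p_eff, weights = wts[seq_len(p_eff)],
         loadings = lds[seq_len(p_eff)], q = qs[seq_len(p_eff)],
         x_scalings = sxs[seq_len(p_eff)], y_scalings = sys[seq_len(p_eff)],
         x_center = mx, y_center = my,
         standardize_residuals = standardize_residuals,
         scores = scores[, seq_len(p_eff), drop = FALSE],
         fitted_path = fitted_path[, seq_len(p_eff), drop = FALSE],
         n = n, y = y),
    class = "mpls_model"
  )
}

# replay the centring/deflation/scaling chain on new rows; returns the
# score matrix and the prediction path (n x p)
mpls_chain <- function(m, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(m$x_center)) {
    abort("grid mismatch: X columns do not match the model's wavelengths.")
  }
  n <- nrow(X)
  E <- sweep(X, 2, m$x_center)
  p <- m$n_factors
  scores <- matrix(NA_real_, n, p)
  path <- matrix(NA_real_, n, p)
  yhat <- rep(0, n)
  yscale <- 1
  for (k in seq_len(p)) {
    t <- drop(E %*% m$weights[[k]])
    scores[, k] <- t
    yhat <- yhat + yscale * m$q[k] * t
    path[, k] <- m$y_center + yhat
    E <- E - tcrossprod(t, m$loadings[[k]])
    E <- sweep(E, 2, m$x_scalings[[k]], "/")
    yscale <- yscale * m$y_scalings[k]
  }
  list(scores = scores, path = path)
}

#' Predict from an MPLS model
#'
#' @param m an `mpls_model`.
#' @param X matrix on the model's retained wavelength grid.
#' @param n_factors number of factors to use (default: all fitted).
#' @param all_factors return the full prediction path (matrix with one
#'   column per factor count) instead of a vector.
#' @return Numeric vector of predictions, or a matrix when
#'   `all_factors = TRUE`.
#' @export
mpls_predict <- function(m, X, n_factors = m$n_factors, all_factors = FALSE) {
  if (n_factors < 1 || n_factors > m$n_factors) {
    abort("`n_factors` outside the fitted range.")
  }
  path <- mpls_chain(m, X)$path
  if (all_factors) path else path[, n_factors]
}

# scores of new samples in the model's factor space
mpls_scores <- function(m, X) mpls_chain(m, X)$scores

#' Equivalent regression coefficients of an MPLS model
#'
#' The fitted chain is affine in the input spectrum, so it collapses to
#' `yhat = intercept + x . beta`; this extracts that form.
#'
#' @param m an `mpls_model`.
#' @param n_factors factor count at which to evaluate.
#' @return list with `intercept` and coefficient vector `beta` (length =
#'   number of retained wavelengths).
#' @export
mpls_coef <- function(m, n_factors = m$n_factors) {
  W <- length(m$x_center)
  probe <- rbind(m$x_center, sweep(diag(W), 2, m$x_center, "+"))
  pred <- mpls_predict(m, probe, n_factors)
  beta <- pred[-1] - pred[1]
  list(intercept = pred[1] - sum(beta * m$x_center), beta = beta)
}

#' @export
print.mpls_model <- function(x, ...) {
  cat(sprintf("<mpls_model: %d factor(s), %d wavelengths, %s>\n",
              x$n_factors, length(x$x_center),
              if (x$standardize_residuals) "residuals standardized (MPLS)"
              else "plain PLS1"))
  invisible(x)
}

#' @method tidy mpls_model
#' @export
tidy.mpls_model <- function(x, ...) {
  cf <- mpls_coef(x)
  tibble::tibble(term = c("(Intercept)", names(x$x_center) %||%
                            paste0("x", seq_along(cf$beta))),
                 estimate = c(cf$intercept, cf$beta))
}

#' @method glance mpls_model
#' @export
glance.mpls_model <- function(x, ...) {
  res <- x$y - x$fitted_path[, x$n_factors]
  tibble::tibble(
    n = x$n,
    n_factors = x$n_factors,
    sec = sec(res, x$n_factors),
    rsq_cal = rsq(x$y, x$fitted_path[, x$n_factors], mode = "calibration")
  )
}
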