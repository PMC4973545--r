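SCATTER_METHODS <- c("None", "SNVD", "SNV", "Detrend", "SMSC", "WMSC", "IMSC")

MATH_CODES <- c("0,0,1,1", "1,4,4,1", "2,4,4,1", "1,8,8,1", "2,8,8,1",
                "1,10,10,1", "2,10,10,1", "1,12,12,1", "2,12,12,1",
                "1,16,16,1", "2,16,16,1")

#' Parse a derivative treatment code
#'
#' Math treatments are written `"d,g,s1,s2"`: derivative order (0 = raw
#' spectra, 1 or 2), gap between the differenced points, first-smoothing
#' segment length and second-smoothing segment length, all in data points.
#' `"0,0,1,1"` denotes the untreated spectra.
#'
#' @param code string such as `"2,4,4,1"`.
#' @return A named list with integer fields `d`, `g`, `s1`, `s2`.
#' @examples
#' parse_treatment_code("2,4,4,1")
#' @export
parse_treatment_code <- function(code) {
  parts <- strsplit(trimws(code), ",", fixed = TRUE)[[1]]
  nums <- suppressWarnings(as.integer(parts))
  if (length(nums) != 4 || anyNA(nums) || any(nums < 0)) {
    abort("treatment code must be four comma-separated non-negative integers.")
  }
  d <- nums[1]; g <- nums[2]; s1 <- nums[3]; s2 <- nums[4]
  if (d > 2) abort("derivative order must be 0, 1 or 2.")
  if (d >= 1 && g < 1) abort("a derivative needs a gap of at least 1 point.")
  if (s1 < 1 || s2 < 1) abort("segment lengths must be at least 1 point.")
  list(d = d, g = g, s1 = s1, s2 = s2)
}

#' Define a spectral pre-treatment
#'
#' A pre-treatment couples one scatter-correction method with one gap-segment
#' derivative code. Scatter correction is applied first (common chemometric
#' practice, configurable via `scatter_first`), then the derivative. The MSC
#' family needs a reference learned from a calibration set with
#' [fit_pretreatment()] before it can be applied.
#'
#' @param code derivative code string, see [parse_treatment_code()].
#' @param scatter one of `"None"`, `"SNVD"`, `"SNV"`, `"Detrend"`, `"SMSC"`,
#'   `"WMSC"`, `"IMSC"`.
#' @param scatter_first apply scatter correction before the derivative
#'   (default) or after.
#' @return An object of class `pretreatment_spec`.
#' @examples
#' pretreatment("2,4,4,1", "SNVD")
#' @export
pretreatment <- function(code = "0,0,1,1", scatter = "None",
                         scatter_first = TRUE) {
  scatter <- match.arg(scatter, SCATTER_METHODS)
  structure(
    list(code = code, deriv = parse_treatment_code(code), scatter = scatter,
         scatter_first = scatter_first, reference = NULL),
    class = "pretreatment_spec"
  )
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  fitted <- if (is.null(x$reference)) "" else " (fitted)"
  cat(sprintf("<pretreatment %s + %s%s>\n", x$code, x$scatter, fitted))
  invisible(x)
}

#' The full pre-treatment grid
#'
#' The standard search grid couples each of the 7 scatter-correction methods
#' (None, SNVD, SNV, Detrend, SMSC, WMSC, IMSC) with each of the 11 math
#' treatments (0,0,1,1 up to 2,16,16,1), giving 77 candidate pre-treatments.
#'
#' @param scatter_methods,codes character vectors defining a reduced grid.
#' @return A tibble with columns `code`, `scatter` and a list-column `spec`
#'   of `pretreatment_spec` objects.
#' @examples
#' nrow(build_grid())  # 77
#' @export
build_grid <- function(scatter_methods = SCATTER_METHODS, codes = MATH_CODES) {
  grid <- tidyr::expand_grid(scatter = scatter_methods, code = codes)
  grid$spec <- purrr::map2(grid$code, grid$scatter, pretreatment)
  grid[, c("code", "scatter", "spec")]
}

# ---- scatter correction ----------------------------------------------------

snv_rows <- function(X) {
  mu <- rowMeans(X)
  s <- apply(X, 1, sd)
  bad <- s < 1e-12
  if (any(bad)) {
    abort(sprintf("SNV undefined for constant row(s): %s",
                  paste(which(bad)[1:min(3, sum(bad))], collapse = ", ")))
  }
  (X - mu) / s
}

detrend_rows <- function(X, wl) {
  # remove the least-squares quadratic baseline in wavelength from each row
  w <- (wl - mean(wl)) / stats::sd(wl)
  B <- cbind(1, w, w^2)
  X - t(B %*% qr.coef(qr(B), t(X)))
}

msc_reference <- function(X) {
  list(mean = colMeans(X), weights = NULL)
}

wmsc_reference <- function(X) {
  v <- apply(X, 2, var)
  list(mean = colMeans(X), weights = 1 / pmax(v, 1e-12))
}

msc_rows <- function(X, ref, weights = NULL, inverse = FALSE) {
  m <- ref
  out <- X
  for (i in seq_len(nrow(X))) {
    x <- X[i, ]
    if (inverse) {
      # regress reference on the spectrum: m = a' + b' x
      fit <- if (is.null(weights)) lm.fit(cbind(1, x), m) else
        stats::lm.wfit(cbind(1, x), m, weights)
      out[i, ] <- fit$coefficients[1] + fit$coefficients[2] * x
    } else {
      # regress the spectrum on the reference: x = a + b m
      fit <- if (is.null(weights)) lm.fit(cbind(1, m), x) else
        stats::lm.wfit(cbind(1, m), x, weights)
      b <- fit$coefficients[2]
      if (!is.finite(b) || abs(b) < 1e-12) {
        abort(sprintf("degenerate scatter slope for row %d", i))
      }
      out[i, ] <- (x - fit$coefficients[1]) / b
    }
  }
  out
}

#' Scatter-correct an absorbance matrix
#'
#' Implements the scatter-correction family: `SNV` z-scores each row (mean 0,
#' sample SD 1); `Detrend` subtracts each row's least-squares quadratic in
#' wavelength; `SNVD` applies SNV then Detrend; the multiplicative methods
#' regress each spectrum against a reference mean spectrum learned on the
#' calibration set -- `SMSC` returns `(x - intercept)/slope`, `WMSC` does the
#' same with per-wavelength weights proportional to the inverse calibration
#' variance, and `IMSC` regresses the reference on the spectrum and returns
#' the fitted values. `None` is the identity.
#'
#' @param X scans x wavelengths matrix of log(1/R).
#' @param method scatter method name.
#' @param wl wavelength vector (needed by Detrend).
#' @param reference fitted reference (list with `mean`, `weights`) for the
#'   MSC family; when `NULL` and `fit = TRUE` it is learned from `X`.
#' @param fit learn the reference from `X` (calibration mode).
#' @return list with the corrected `X` and the `reference` used (NULL for
#'   reference-free methods).
#' @export
scatter_correct <- function(X, method, wl = NULL, reference = NULL,
                            fit = FALSE) {
  method <- match.arg(method, SCATTER_METHODS)
  needs_ref <- method %in% c("SMSC", "WMSC", "IMSC")
  if (needs_ref && is.null(reference)) {
    if (!fit) abort(sprintf("%s needs a fitted reference in apply mode.", method))
    reference <- if (method == "WMSC") wmsc_reference(X) else msc_reference(X)
  }
  Xc <- switch(method,
    None = X,
    SNV = snv_rows(X),
    Detrend = detrend_rows(X, wl),
    SNVD = detrend_rows(snv_rows(X), wl),
    SMSC = msc_rows(X, reference$mean),
    WMSC = msc_rows(X, reference$mean, weights = reference$weights),
    IMSC = msc_rows(X, reference$mean, inverse = TRUE)
  )
  list(X = Xc, reference = if (needs_ref) reference else NULL)
}

# ---- gap-segment derivative ------------------------------------------------

# centred moving average of `s` points over matrix columns; returns the
# smoothed matrix on the sub-grid where the full window fits
moving_average <- function(X, s, idx) {
  if (s <= 1) return(list(X = X, idx = idx))
  left <- (s - 1) %/% 2
  right <- s - 1 - left
  W <- ncol(X)
  if (W < s) abort("spectrum too short for the smoothing window.")
  CS <- cbind(0, t(apply(X, 1, cumsum)))
  centre <- (1 + left):(W - right)
  sm <- (CS[, centre + right + 1, drop = FALSE] -
           CS[, centre - left, drop = FALSE]) / s
  list(X = sm, idx = idx[centre])
}

#' Gap-segment derivative of spectra
#'
#' WinISI-style derivatives: each spectrum is smoothed with a centred moving
#' average of `s1` points, differenced across a gap of `g` points (first
#' derivative: `x(i+g) - x(i-g)`; second: `x(i-g) - 2 x(i) + x(i+g)`;
#' unnormalised differences, as only relative scale matters after centering),
#' then smoothed again with `s2` points. The output is truncated to the
#' wavelengths where every window fits, and the retained grid is returned.
#'
#' @param X scans x wavelengths matrix (a single spectrum may be passed as a
#'   vector).
#' @param d,g,s1,s2 derivative order, gap and segment lengths in data points.
#' @param wl wavelength vector; defaults to column index.
#' @return list with the derivative matrix `X` and retained `wavelengths`.
#' @examples
#' gap_segment_derivative(rbind((1:40)^2), d = 2, g = 4, s1 = 1, s2 = 1)$X[1]
#' @export
gap_segment_derivative <- function(X, d, g, s1 = 1, s2 = 1, wl = NULL) {
  if (is.null(dim(X))) X <- rbind(X)
  W <- ncol(X)
  wl <- wl %||% seq_len(W)
  if (d >= 1 && W <= 2 * g + s1) abort("spectrum too short for gap and segment.")
  sm <- moving_average(X, s1, seq_len(W))
  Xs <- sm$X; idx <- sm$idx
  if (d >= 1) {
    Wm <- ncol(Xs)
    if (Wm <= 2 * g) abort("spectrum too short for the gap difference.")
    centre <- (1 + g):(Wm - g)
    lo <- Xs[, centre - g, drop = FALSE]
    hi <- Xs[, centre + g, drop = FALSE]
    Xs <- if (d == 1) hi - lo else lo - 2 * Xs[, centre, drop = FALSE] + hi
    idx <- idx[centre]
  }
  sm2 <- moving_average(Xs, s2, idx)
  list(X = sm2$X, wavelengths = wl[sm2$idx])
}

# ---- composition -----------------------------------------------------------

pretreat_matrix <- function(X, wl, spec, fit = FALSE) {
  dv <- spec$deriv
  run_scatter <- function(M, w) {
    sc <- scatter_correct(M, spec$scatter, wl = w,
                          reference = spec$reference, fit = fit)
    if (fit) spec$reference <<- sc$reference
    sc$X
  }
  if (isTRUE(spec$scatter_first)) {
    X <- run_scatter(X, wl)
    der <- gap_segment_derivative(X, dv$d, dv$g, dv$s1, dv$s2, wl)
    X <- der$X; wl <- der$wavelengths
  } else {
    der <- gap_segment_derivative(X, dv$d, dv$g, dv$s1, dv$s2, wl)
    X <- run_scatter(der$X, der$wavelengths)
    wl <- der$wavelengths
  }
  list(X = X, wavelengths = wl, spec = spec)
}

#' Fit and apply a pre-treatment to spectra
#'
#' `fit_pretreatment()` learns any data-dependent parts of a pre-treatment
#' (the MSC reference spectrum and WMSC weights) from a calibration set and
#' returns the fitted spec. `apply_pretreatment()` transforms spectra with a
#' (fitted) spec: scatter correction, then the gap-segment derivative, with
#' the retained wavelength grid carried in the result.
#'
#' @param spectra a spectra tibble.
#' @param spec a `pretreatment_spec`, see [pretreatment()].
#' @return `fit_pretreatment()`: the fitted spec. `apply_pretreatment()`: a
#'   spectra tibble on the retained grid.
#' @examples
#' sp <- as_spectra(matrix(rnorm(300), 3), seq(400, 598, 2), c("a", "b", "c"))
#' apply_pretreatment(sp, pretreatment("2,4,4,1", "SNV"))
#' @export
fit_pretreatment <- function(spectra, spec) {
  X <- spectra_matrix(spectra)
  pretreat_matrix(X, spectra_wavelengths(spectra), spec, fit = TRUE)$spec
}

#' @rdname fit_pretreatment
#' @export
apply_pretreatment <- function(spectra, spec) {
  needs_ref <- spec$scatter %in% c("SMSC", "WMSC", "IMSC")
  if (needs_ref && is.null(spec$reference)) {
    abort("spec must be fitted with fit_pretreatment() first.")
  }
  out <- pretreat_matrix(spectra_matrix(spectra),
                         spectra_wavelengths(spectra), spec)
  as_spectra(out$X, out$wavelengths, spectra$sample_id,
             spectra[["subsample_id"]])
}
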