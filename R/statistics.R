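#' Summary statistics for a reference constituent
#'
#' Reports the range, mean, standard deviation (denominator n - 1) and
#' coefficient of variation (CV = SD/mean x 100) of a value vector, the
#' columns of a composition summary table.
#'
#' @param v numeric vector, length at least 2.
#' @return A one-row tibble: `n`, `min`, `max`, `mean`, `sd`, `cv`.
#' @examples
#' summary_stats(c(1, 2, 3))
#' @export
summary_stats <- function(v) {
  if (length(v) < 2 || anyNA(v)) abort("need at least 2 finite values.")
  m <- mean(v)
  s <- sd(v)
  if (abs(m) < 1e-300) abort("CV undefined for zero mean.")
  tibble::tibble(n = length(v), min = min(v), max = max(v),
                 mean = m, sd = s, cv = s / m * 100)
}

#' Standard error of calibration
#'
#' `SEC = sqrt(sum(e^2) / (n - p - 1))` for training residuals `e` of a model
#' with `p` factors; the denominator charges one degree of freedom per factor
#' plus one for the intercept.
#'
#' @param residuals training residuals (observed - fitted).
#' @param p number of model factors.
#' @return SEC, a non-negative scalar.
#' @export
sec <- function(residuals, p) {
  n <- length(residuals)
  if (n <= p + 1) abort("SEC needs n > p + 1.")
  sqrt(sum(residuals^2) / (n - p - 1))
}

#' Standard error of cross-validation or prediction
#'
#' The uncorrected root-mean-square of held-out residuals,
#' `sqrt(sum(e^2)/n)`; used both for SECV (pooled cross-validation
#' residuals) and SEP (validation-set residuals).
#'
#' @param residuals held-out residuals.
#' @return The RMS error, a non-negative scalar.
#' @export
secv_sep <- function(residuals) {
  if (length(residuals) < 1) abort("no residuals supplied.")
  sqrt(mean(residuals^2))
}

#' Coefficients of determination
#'
#' `mode = "calibration"` gives `1 - SSE/SST` (the in-fit RSQ);
#' `mode = "correlation"` gives the squared Pearson correlation between
#' observed and predicted, the convention used for cross-validation and
#' validation R-squared.
#'
#' @param y observed values.
#' @param y_hat predicted values.
#' @param mode `"calibration"` or `"correlation"`.
#' @return R-squared scalar.
#' @export
rsq <- function(y, y_hat, mode = c("calibration", "correlation")) {
  mode <- match.arg(mode)
  if (length(y) < 3) abort("R-squared needs at least 3 samples.")
  if (sd(y) < 1e-12) abort("R-squared undefined for zero-variance y.")
  if (mode == "calibration") {
    1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)
  } else {
    if (sd(y_hat) < 1e-12) return(0)
    cor(y, y_hat)^2
  }
}

#' Ratio of performance to deviation
#'
#' `RPD = SD / SE`, with SD the reference-value standard deviation and SE
#' either the SECV (cross-validation, RPD_cv) or the SEP (validation, RPD_v).
#' Calibrations with RPD above 2.5 are conventionally deemed fit for routine
#' quantitative use.
#'
#' @param sd standard deviation of the reference values.
#' @param se SECV or SEP.
#' @return The ratio.
#' @examples
#' rpd(0.759, 0.266)
#' @export
rpd <- function(sd, se) {
  if (se <= 0) abort("RPD undefined for non-positive standard error.")
  sd / se
}

#' Standard error of laboratory from duplicate determinations
#'
#' `SEL = sqrt(sum((a - b)^2) / (2 m))` over `m` duplicate pairs, and
#' `RSEL = SEL / mean x 100` expresses it relative to the constituent mean.
#'
#' @param a,b paired duplicate laboratory values.
#' @return A one-row tibble: `n_pairs`, `sel`, `mean`, `rsel`.
#' @export
sel <- function(a, b) {
  if (length(a) < 1 || length(a) != length(b)) {
    abort("need at least one duplicate pair, with equal lengths.")
  }
  s <- sqrt(sum((a - b)^2) / (2 * length(a)))
  m <- mean(c(a, b))
  tibble::tibble(n_pairs = length(a), sel = s, mean = m, rsel = s / m * 100)
}
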