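default_max_factors <- function(n) max(1L, min(15L, n %/% 6L))

# partition n samples into n_groups of near-equal size, seeded
cv_groups <- function(n, n_groups, seed = NULL) {
  if (n_groups < 2 || n_groups > n) {
    abort("`n_groups` must lie between 2 and the number of samples.")
  }
  with_seed(seed, sample(rep_len(seq_len(n_groups), n)))
}

# matrix-level cross-validation; pre-treatment (MSC references) is refitted
# inside each training fold so no information leaks to the held-out group
cross_validate_matrix <- function(X, wl, y, spec, max_factors, groups) {
  n <- nrow(X)
  preds <- matrix(NA_real_, n, max_factors)
  p_common <- max_factors
  for (gidx in sort(unique(groups))) {
    test <- groups == gidx
    sp <- spec
    sp$reference <- NULL
    tr <- pretreat_matrix(X[!test, , drop = FALSE], wl, sp, fit = TRUE)
    te <- pretreat_matrix(X[test, , drop = FALSE], wl, tr$spec)
    p_fold <- min(max_factors, sum(!test) - 2L)
    m <- mpls_fit(tr$X, y[!test], p_fold,
                  standardize_residuals = spec$standardize %||% TRUE)
    path <- mpls_predict(m, te$X, all_factors = TRUE)
    preds[test, seq_len(m$n_factors)] <- path
    p_common <- min(p_common, m$n_factors)
  }
  curve <- tibble::tibble(
    factors = seq_len(p_common),
    secv = vapply(seq_len(p_common),
                  function(p) secv_sep(y - preds[, p]), numeric(1)),
    r2_cv = vapply(seq_len(p_common),
                   function(p) rsq(y, preds[, p], "correlation"), numeric(1))
  )
  list(curve = curve, optimal_factors = which.min(curve$secv),
       predictions = preds[, seq_len(p_common), drop = FALSE])
}

#' Cross-validated factor selection
#'
#' Splits the calibration samples into `n_groups` seeded random groups of
#' near-equal size, and for every factor count pools the held-out residuals
#' over groups into `SECV(p) = sqrt(sum(e^2)/n)`. The optimal factor count is
#' the SECV minimum (ties resolved toward fewer factors). Data-dependent
#' pre-treatment parts (MSC references) are refitted inside every training
#' fold.
#'
#' @param spectra spectra tibble of the calibration set (one row per sample).
#' @param y reference values aligned with `spectra` rows.
#' @param spec a `pretreatment_spec`.
#' @param max_factors largest factor count scanned; default
#'   `min(15, n %/% 6)`.
#' @param n_groups number of cross-validation groups (default 6).
#' @param seed seed for the group partition.
#' @return list with `curve` (tibble: `factors`, `secv`, `r2_cv`),
#'   `optimal_factors`, and the pooled cross-validation `predictions`.
#' @export
cross_validate <- function(spectra, y, spec = pretreatment(),
                           max_factors = NULL, n_groups = 6, seed = NULL) {
  X <- spectra_matrix(spectra)
  max_factors <- max_factors %||% default_max_factors(nrow(X))
  groups <- cv_groups(nrow(X), n_groups, seed)
  cross_validate_matrix(X, spectra_wavelengths(spectra), y, spec,
                        max_factors, groups)
}

#' Global H spectral-outlier scores
#'
#' The global H statistic of sample *i* is its squared Mahalanobis distance
#' in the model's p-dimensional score space (mean and covariance taken from
#' the calibration scores), divided by p, so the calibration-set average is
#' close to 1. Samples with GH at or above 10 are conventionally treated as
#' spectral outliers.
#'
#' @param m fitted `mpls_model`.
#' @param X pre-treated matrix on the model grid; defaults to the training
#'   scores.
#' @return Numeric vector of GH scores.
#' @export
global_h <- function(m, X = NULL) {
  S <- m$scores
  centre <- colMeans(S)
  V <- cov(S)
  if (rcond_safe(V) < 1e-12) {
    warn("near-singular score covariance; ridge-stabilized.")
    V <- V + diag(1e-8 * mean(diag(V)) + 1e-300, ncol(V))
  }
  scores <- if (is.null(X)) S else mpls_scores(m, X)
  mahalanobis(scores, centre, V) / m$n_factors
}

rcond_safe <- function(V) {
  if (nrow(V) == 1) return(if (V[1, 1] > 0) 1 else 0)
  tryCatch(rcond(V), error = function(e) 0)
}

#' T residual-outlier flags
#'
#' `T_i = |y_i - yhat_i| / SEC`; samples with `T` strictly above the
#' threshold (default 2.5) do not fit the calibration and are flagged.
#'
#' @param m fitted `mpls_model`.
#' @param X pre-treated matrix the model was fitted on.
#' @param y reference values.
#' @param threshold flagging threshold (strict inequality).
#' @return Logical vector of flags.
#' @export
t_outliers <- function(m, X, y, threshold = 2.5) {
  res <- y - mpls_predict(m, X)
  s <- sec(res, m$n_factors)
  if (s == 0) return(rep(FALSE, length(y)))
  abs(res) / s > threshold
}

fit_pass <- function(X, wl, y, spec, max_factors, n_groups, seed) {
  sp <- spec
  sp$reference <- NULL
  fitted <- pretreat_matrix(X, wl, sp, fit = TRUE)
  groups <- cv_groups(nrow(X), n_groups, seed)
  cv <- cross_validate_matrix(X, wl, y, spec, max_factors, groups)
  model <- mpls_fit(fitted$X, y, cv$optimal_factors,
                    standardize_residuals = spec$standardize %||% TRUE)
  list(spec = fitted$spec, Xp = fitted$X, wl = fitted$wavelengths,
       cv = cv, model = model)
}

#' Calibrate one constituent with outlier elimination
#'
#' Runs the full single-treatment calibration loop on a calibration set:
#' pre-treat, select the factor count by cross-validation, fit the MPLS
#' model, flag global-H (GH >= `gh_threshold`) and T (> `t_threshold`)
#' outliers, and - for at most `max_passes` elimination passes - remove the
#' flagged samples jointly and repeat. Evaluation statistics are computed on
#' the surviving samples.
#'
#' @param spectra spectra tibble, one (averaged) row per calibration sample.
#' @param reference data frame with `sample_id` and constituent columns.
#' @param constituent name of the reference column to calibrate (e.g.
#'   `"de_d"`).
#' @param spec a `pretreatment_spec`.
#' @param max_factors,n_groups,seed as in [cross_validate()].
#' @param gh_threshold,t_threshold,max_passes outlier rules: GH cut
#'   (inclusive), T cut (strict), and the maximum number of elimination
#'   passes.
#' @return An object of class `nirs_calibration`: fitted spec and model,
#'   SECV curve, outlier log, and a one-row `stats` tibble (n, mean, sd,
#'   sec, rsq_cal, secv, r2_cv, rpd_cv).
#' @export
calibrate <- function(spectra, reference, constituent = "de_d",
                      spec = pretreatment(), max_factors = NULL,
                      n_groups = 6, gh_threshold = 10, t_threshold = 2.5,
                      max_passes = 2, seed = NULL) {
  if (!constituent %in% names(reference)) {
    abort(sprintf("constituent `%s` not found in the reference table.",
                  constituent))
  }
  idx <- match(spectra$sample_id, reference$sample_id)
  if (anyNA(idx)) abort("some spectra have no matching reference row.")
  y_all <- reference[[constituent]][idx]
  X0 <- spectra_matrix(spectra)
  wl <- spectra_wavelengths(spectra)
  n0 <- nrow(X0)
  if (n0 < 20) abort("calibration needs at least 20 samples.")
  max_factors <- max_factors %||% default_max_factors(n0)

  keep <- seq_len(n0)
  removed <- tibble::tibble(sample_id = character(), pass = integer(),
                            reason = character(), gh = numeric(),
                            t = numeric())
  passes <- 0L
  repeat {
    fit <- fit_pass(X0[keep, , drop = FALSE], wl, y_all[keep], spec,
                    min(max_factors, length(keep) - 2L), n_groups, seed)
    gh <- global_h(fit$model)
    tres <- y_all[keep] - mpls_predict(fit$model, fit$Xp)
    s <- sec(tres, fit$model$n_factors)
    tstat <- if (s == 0) rep(0, length(keep)) else abs(tres) / s
    flag_h <- gh >= gh_threshold
    flag_t <- tstat > t_threshold
    flags <- flag_h | flag_t
    if (!any(flags) || passes >= max_passes) break
    passes <- passes + 1L
    removed <- dplyr::bind_rows(removed, tibble::tibble(
      sample_id = spectra$sample_id[keep][flags],
      pass = passes,
      reason = ifelse(flag_h[flags] & flag_t[flags], "H+T",
                      ifelse(flag_h[flags], "H", "T")),
      gh = gh[flags], t = tstat[flags]
    ))
    keep <- keep[!flags]
    if (length(keep) < n0 / 2) {
      abort("more than half the calibration samples flagged as outliers.")
    }
  }

  y <- y_all[keep]
  fitted_vals <- mpls_predict(fit$model, fit$Xp)
  p <- fit$model$n_factors
  secv_val <- fit$cv$curve$secv[fit$cv$optimal_factors]
  stats <- tibble::tibble(
    n = length(keep), mean = mean(y), sd = sd(y),
    sec = sec(y - fitted_vals, p),
    rsq_cal = rsq(y, fitted_vals, "calibration"),
    secv = secv_val,
    r2_cv = fit$cv$curve$r2_cv[fit$cv$optimal_factors],
    rpd_cv = rpd(sd(y), secv_val)
  )
  structure(
    list(spec = fit$spec, model = fit$model, constituent = constituent,
         n_used = length(keep), sample_ids = spectra$sample_id[keep],
         removed = removed, passes = passes,
         secv_curve = fit$cv$curve, optimal_factors = fit$cv$optimal_factors,
         stats = stats, seed = seed),
    class = "nirs_calibration"
  )
}

#' @export
print.nirs_calibration <- function(x, ...) {
  cat(sprintf("<nirs_calibration: %s | %s + %s | %d factors | n = %d (%d removed)>\n",
              x$constituent, x$spec$code, x$spec$scatter,
              x$optimal_factors, x$n_used, nrow(x$removed)))
  print(x$stats)
  invisible(x)
}

#' @method tidy nirs_calibration
#' @export
tidy.nirs_calibration <- function(x, ...) x$secv_curve

#' @method glance nirs_calibration
#' @export
glance.nirs_calibration <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(constituent = x$constituent, code = x$spec$code,
                   scatter = x$spec$scatter, factors = x$optimal_factors),
    x$stats
  )
}

#' Grid search over pre-treatments
#'
#' Runs [calibrate()] for every pre-treatment in the grid (the same seed,
#' hence the same cross-validation partition, is used throughout) and ranks
#' the results by SECV ascending, breaking ties by higher cross-validation
#' R-squared and then fewer factors.
#'
#' @inheritParams calibrate
#' @param grid tibble from [build_grid()] (or a reduced grid).
#' @param ... passed on to [calibrate()].
#' @return An object of class `nirs_grid_search` with the ranked
#'   `leaderboard` tibble and the winning `nirs_calibration` as `best`.
#' @export
grid_search <- function(spectra, reference, constituent = "de_d",
                        grid = build_grid(), seed = NULL, ...) {
  if (nrow(grid) == 0) abort("empty pre-treatment grid.")
  if (!constituent %in% names(reference)) {
    abort(sprintf("constituent `%s` not found in the reference table.",
                  constituent))
  }
  fits <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      calibrate(spectra, reference, constituent, spec = grid$spec[[i]],
                seed = seed, ...),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[i]] <- tibble::tibble(code = grid$code[i],
                                  scatter = grid$scatter[i],
                                  error = conditionMessage(fit))
    } else {
      fits[[i]] <- fit
      rows[[i]] <- dplyr::bind_cols(
        tibble::tibble(code = grid$code[i], scatter = grid$scatter[i],
                       factors = fit$optimal_factors),
        fit$stats, tibble::tibble(error = NA_character_)
      )
    }
  }
  board <- dplyr::bind_rows(rows)
  ok <- is.na(board$error)
  if (!any(ok)) abort("every pre-treatment in the grid failed to calibrate.")
  ranking <- order(board$secv, -board$r2_cv, board$factors,
                   na.last = TRUE)
  board <- board[ranking, ]
  board$rank <- ifelse(is.na(board$error), seq_len(nrow(board)), NA_integer_)
  best_i <- ranking[1]
  structure(
    list(leaderboard = board, best = fits[[best_i]],
         constituent = constituent, seed = seed),
    class = "nirs_grid_search"
  )
}

#' @export
print.nirs_grid_search <- function(x, ...) {
  cat(sprintf("<nirs_grid_search: %s, %d pre-treatments>\n",
              x$constituent, nrow(x$leaderboard)))
  print(head(x$leaderboard, 5))
  invisible(x)
}

#' @method tidy nirs_grid_search
#' @export
tidy.nirs_grid_search <- function(x, ...) x$leaderboard

#' Validate a calibration on held-out samples
#'
#' Applies the stored pre-treatment (no refitting) and model to a validation
#' set and reports the standard validation statistics.
#'
#' @param result a `nirs_calibration` (or the `best` of a grid search).
#' @param spectra spectra tibble of the validation samples (averaged).
#' @param reference reference data frame with `sample_id` and the calibrated
#'   constituent.
#' @return One-row tibble: `n`, `mean`, `sd`, `sep`, `rsq_v`, `rpd_v`,
#'   `bias`.
#' @export
validate <- function(result, spectra, reference) {
  if (inherits(result, "nirs_grid_search")) result <- result$best
  if (nrow(spectra) == 0) abort("empty validation set.")
  idx <- match(spectra$sample_id, reference$sample_id)
  if (anyNA(idx)) abort("some validation spectra have no reference row.")
  y <- reference[[result$constituent]][idx]
  pre <- pretreat_matrix(spectra_matrix(spectra),
                         spectra_wavelengths(spectra), result$spec)
  pred <- mpls_predict(result$model, pre$X)
  sep <- secv_sep(y - pred)
  tibble::tibble(
    n = length(y), mean = mean(y), sd = sd(y), sep = sep,
    rsq_v = rsq(y, pred, "correlation"),
    rpd_v = rpd(sd(y), sep),
    bias = mean(pred - y)
  )
}

#' Predict a constituent for new spectra
#'
#' @param object a `nirs_calibration`.
#' @param spectra spectra tibble on the calibration's raw grid.
#' @param ... unused.
#' @return Tibble with `sample_id` and `prediction`.
#' @export
predict.nirs_calibration <- function(object, spectra, ...) {
  pre <- pretreat_matrix(spectra_matrix(spectra),
                         spectra_wavelengths(spectra), object$spec)
  tibble::tibble(sample_id = spectra$sample_id,
                 prediction = mpls_predict(object$model, pre$X))
}
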