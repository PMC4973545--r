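# a small synthetic calibration problem with known latent rank
latent_problem <- function(n = 60, W = 90, rank = 3, noise_frac = 0.01,
                           seed = 1) {
  set.seed(seed)
  scores <- matrix(rnorm(n * rank), n)
  load <- matrix(rnorm(rank * W), rank)
  X <- scores %*% load + matrix(rnorm(n * W, 0, 1e-4), n)
  y <- drop(scores %*% seq_len(rank))
  y <- y + rnorm(n, 0, noise_frac * sd(y))
  sp <- as_spectra(X, seq(400, by = 2, length.out = W),
                   sprintf("s%03d", seq_len(n)))
  list(spectra = sp, X = X, y = y)
}

test_that("cross-validation recovers the latent factor count", {
  hits <- 0
  for (s in 1:10) {
    prob <- latent_problem(seed = s)
    cv <- cross_validate(prob$spectra, prob$y, pretreatment(),
                         max_factors = 8, seed = s)
    hits <- hits + (cv$optimal_factors == 3)
  }
  expect_gte(hits, 6)
})

test_that("n_groups = n reproduces a brute-force leave-one-out oracle", {
  prob <- latent_problem(n = 15, W = 25, noise_frac = 0.2, seed = 2)
  spec <- pretreatment("1,2,2,1", "SNV")
  cv <- cross_validate(prob$spectra, prob$y, spec, max_factors = 5,
                       n_groups = 15, seed = 3)
  # oracle: explicit loop, refitting pre-treatment and model per left-out row
  X <- spectra_matrix(prob$spectra)
  wl <- spectra_wavelengths(prob$spectra)
  for (p in 1:5) {
    preds <- vapply(1:15, function(i) {
      tr <- pretreat_matrix(X[-i, , drop = FALSE], wl, spec, fit = TRUE)
      te <- pretreat_matrix(X[i, , drop = FALSE], wl, tr$spec)
      m <- mpls_fit(tr$X, prob$y[-i], p)
      mpls_predict(m, te$X)
    }, numeric(1))
    expect_equal(cv$curve$secv[p], sqrt(mean((prob$y - preds)^2)),
                 tolerance = 1e-10)
  }
})

test_that("the cross-validation partition is seed-stable", {
  prob <- latent_problem(seed = 4)
  cv1 <- cross_validate(prob$spectra, prob$y, pretreatment(), seed = 11)
  cv2 <- cross_validate(prob$spectra, prob$y, pretreatment(), seed = 11)
  expect_identical(cv1$curve, cv2$curve)
  expect_error(cross_validate(prob$spectra, prob$y, pretreatment(),
                              n_groups = 100), "between")
})

test_that("global H is a scaled Mahalanobis distance in score space", {
  prob <- latent_problem(seed = 6)
  X <- spectra_matrix(prob$spectra)
  m <- mpls_fit(X, prob$y, 3)
  gh <- global_h(m)
  # the calibration average sits near 1 (exactly (n-1)/n for the empirical
  # covariance), and the score centroid scores zero
  n <- nrow(X)
  expect_equal(mean(gh), (n - 1) / n, tolerance = 1e-8)
  expect_gt(mean(gh), 0.9)
  expect_lt(mean(gh), 1.1)
  centroid <- rbind(m$x_center)
  expect_lt(global_h(m, centroid), 1e-10)
  # a wildly amplified spectrum is an H outlier
  big <- rbind(100 * X[1, ])
  expect_gte(global_h(m, big), 10)
})

test_that("T outliers use the strict 2.5 rule on SEC-standardised residuals", {
  set.seed(1)
  t <- rnorm(12)
  X <- outer(t, rnorm(30))
  y0 <- drop(X %*% rnorm(30))
  m <- mpls_fit(X, y0, 1)
  pred <- mpls_predict(m, X)
  # residuals exactly {5,3,2,1,1,0...}: SEC = 2, so T = 2.5 at the boundary
  e <- c(5, 3, 2, 1, 1, rep(0, 7))
  flags <- t_outliers(m, X, pred + e)
  expect_false(any(flags))            # 5/2 = 2.5 is not > 2.5
  flags2 <- t_outliers(m, X, pred + c(6, e[-1]))
  expect_identical(which(flags2), 1L) # 6/SEC now crosses the threshold
  expect_false(any(t_outliers(m, X, pred)))  # zero residuals, no flags
})

test_that("a flag-free calibration finishes in one fit with no removals", {
  prob <- implant_problem(seed = 101)
  res <- calibrate(prob$avg, prob$ref, "de_ref",
                   pretreatment("2,8,8,1", "SNVD"), seed = 1)
  expect_equal(res$n_used, 88)
  expect_equal(nrow(res$removed), 0)
  expect_equal(res$passes, 0)
})

test_that("implanted gross outliers are eliminated within two passes", {
  recovered <- 0
  for (s in 1:10) {
    prob <- implant_problem(seed = 100 + s)
    imp <- implant_outliers(prob$avg, prob$ref)
    res <- calibrate(imp$avg, imp$ref, "de_ref",
                     pretreatment("2,8,8,1", "SNVD"), seed = s)
    expect_lte(res$passes, 2)
    if (res$n_used == 86 &&
        all(imp$avg$sample_id[c(5, 20)] %in% res$removed$sample_id)) {
      recovered <- recovered + 1
    }
  }
  expect_gte(recovered, 8)
})

test_that("calibration aborts when outliers would decimate the set", {
  prob <- latent_problem(n = 30, seed = 8)
  y_bad <- prob$y + c(rep(0, 10), rnorm(20, 0, 50))
  expect_error(
    calibrate(prob$spectra, tibble::tibble(sample_id = prob$spectra$sample_id,
                                           de_d = y_bad),
              "de_d", pretreatment(), t_threshold = 0.5, seed = 1),
    "half")
})

test_that("grid search ranks by SECV and is deterministic", {
  cfg <- sim_config(n_samples = 45, seed = 21)
  ds <- make_dataset(cfg)
  avg <- average_duplicates(ds$spectra)
  grid <- build_grid(c("None", "SNV"), c("0,0,1,1", "1,4,4,1"))
  gs1 <- grid_search(avg, ds$reference, "de_c", grid = grid, seed = 5)
  gs2 <- grid_search(avg, ds$reference, "de_c", grid = grid, seed = 5)
  expect_equal(nrow(gs1$leaderboard), 4)
  expect_identical(gs1$leaderboard, gs2$leaderboard)
  ok <- gs1$leaderboard[is.na(gs1$leaderboard$error), ]
  expect_true(!is.unsorted(ok$secv))
  expect_equal(gs1$best$stats$secv, min(ok$secv))
})

test_that("scatter-corrected treatments beat raw treatment on scattered data", {
  wins <- 0
  for (s in 1:5) {
    cfg <- sim_config(n_samples = 40, seed = 300 + s)
    ds <- make_dataset(cfg)
    avg <- average_duplicates(ds$spectra)
    secv_of <- function(scatter) {
      calibrate(avg, ds$reference, "de_c",
                pretreatment("1,4,4,1", scatter), seed = s)$stats$secv
    }
    best_corr <- min(secv_of("SNV"), secv_of("SMSC"))
    wins <- wins + (best_corr < secv_of("None"))
  }
  expect_gte(wins, 3)
})

test_that("validation applies the stored treatment without refitting", {
  cfg <- sim_config(n_samples = 60, seed = 31)
  ds <- make_dataset(cfg)
  avg <- average_duplicates(ds$spectra)
  s <- split_cal_val(avg$sample_id, 15, seed = 2)
  cal <- avg[avg$sample_id %in% s$cal, ]
  val <- avg[avg$sample_id %in% s$val, ]
  res <- calibrate(cal, ds$reference, "de_d",
                   pretreatment("2,8,8,1", "SMSC"), seed = 2)
  v <- validate(res, val, ds$reference)
  expect_equal(v$n, 15)
  expect_gt(v$rpd_v, 0)
  # validating on the calibration survivors reproduces the fitted residuals
  surv <- cal[cal$sample_id %in% res$sample_ids, ]
  v_self <- validate(res, surv, ds$reference)
  idx <- match(surv$sample_id, ds$reference$sample_id)
  pred <- predict(res, surv)$prediction
  expect_equal(v_self$sep,
               sqrt(mean((ds$reference$de_d[idx] - pred)^2)),
               tolerance = 1e-12)
  p <- res$model$n_factors
  expect_equal(res$stats$sec,
               v_self$sep * sqrt(v_self$n / (v_self$n - p - 1)),
               tolerance = 1e-8)
  expect_error(validate(res, val[0, ], ds$reference), "empty")
})
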