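test_that("treatment codes parse and invalid codes are rejected", {
  expect_equal(parse_treatment_code("2,4,4,1"),
               list(d = 2L, g = 4L, s1 = 4L, s2 = 1L))
  raw <- parse_treatment_code("0,0,1,1")
  expect_equal(raw$d, 0L)
  expect_error(parse_treatment_code("3,2,2,1"), "order")
  expect_error(parse_treatment_code("1,0,4,1"), "gap")
  expect_error(parse_treatment_code("1,4,0,1"), "segment")
  expect_error(parse_treatment_code("1,4,4"), "four")
})

test_that("SNV z-scores each spectrum", {
  wl <- c(400, 402, 404)
  out <- scatter_correct(rbind(c(0, 1, 2)), "SNV", wl)$X
  expect_equal(drop(out), c(-1, 0, 1))
  X <- matrix(rnorm(20 * 50, mean = 3), 20)
  snv <- scatter_correct(X, "SNV", seq(400, 498, 2))$X
  expect_lt(max(abs(rowMeans(snv))), 1e-10)
  expect_lt(max(abs(apply(snv, 1, sd) - 1)), 1e-10)
  expect_error(scatter_correct(rbind(rep(1, 5)), "SNV", 1:5), "constant")
})

test_that("detrend annihilates quadratic baselines", {
  wl <- seq(400, 598, 2)
  quad <- outer(c(1, -2, 0.5), wl^2) + outer(c(3, 1, -1), wl) + c(5, 0, 2)
  expect_lt(max(abs(scatter_correct(quad, "Detrend", wl)$X)), 1e-6)
  # adding any quadratic leaves the detrended signal unchanged
  X <- matrix(rnorm(3 * length(wl)), 3)
  expect_equal(scatter_correct(X + quad, "Detrend", wl)$X,
               scatter_correct(X, "Detrend", wl)$X, tolerance = 1e-6)
})

test_that("multiplicative scatter corrections invert affine scatter", {
  wl <- seq(1100, 1298, 2)
  ref <- sin(wl / 40) + wl / 1000
  cal <- rbind(ref, 1.3 * ref + 0.2, 0.7 * ref - 0.1, 1.1 * ref + 0.05)
  rownames(cal) <- NULL
  sc <- scatter_correct(cal, "SMSC", wl, fit = TRUE)
  # a row that is a + b * reference comes back as the reference
  row <- rbind(0.4 + 1.9 * sc$reference$mean)
  fixed <- scatter_correct(row, "SMSC", wl, reference = sc$reference)$X
  expect_equal(drop(fixed), sc$reference$mean, tolerance = 1e-8)
  # IMSC returns fitted values of the reference-on-spectrum regression
  inv <- scatter_correct(row, "IMSC", wl, reference = sc$reference)$X
  expect_equal(drop(inv), sc$reference$mean, tolerance = 1e-8)
  # WMSC equals SMSC when calibration variances are equal across wavelengths
  expect_error(scatter_correct(row, "SMSC", wl), "apply mode")
})

test_that("scatter-only perturbations collapse after SMSC and SNV", {
  wl <- seq(1100, 1498, 2)
  base <- exp(-((wl - 1300)^2) / 5000) + wl / 2000
  for (noise in c(1e-3, 1e-5)) {
    set.seed(42)
    X <- t(vapply(1:8, function(i) {
      runif(1, 0.7, 1.3) * base + runif(1, -0.2, 0.2) +
        rnorm(length(wl), 0, noise)
    }, numeric(length(wl))))
    sm <- scatter_correct(X, "SMSC", wl, fit = TRUE)$X
    out <- scatter_correct(sm, "SNV", wl)$X
    spread <- max(dist(out)) / sqrt(length(wl))
    expect_lt(spread, 60 * noise)
  }
})

test_that("gap-segment derivatives match their closed forms", {
  i <- 1:60
  # second difference of an affine function vanishes
  lin <- gap_segment_derivative(rbind(3 * i + 7), d = 2, g = 4)
  expect_lt(max(abs(lin$X)), 1e-10)
  # (i-g)^2 - 2 i^2 + (i+g)^2 = 2 g^2
  sq <- gap_segment_derivative(rbind(i^2), d = 2, g = 4, s1 = 1, s2 = 1)
  expect_equal(unname(drop(sq$X)), rep(32, ncol(sq$X)))
  # first difference across gap g of the identity ramp is 2 g
  ramp <- gap_segment_derivative(rbind(i), d = 1, g = 3, s1 = 1, s2 = 1)
  expect_equal(unname(drop(ramp$X)), rep(6, ncol(ramp$X)))
  expect_error(gap_segment_derivative(rbind(1:10), d = 2, g = 4, s1 = 4),
               "too short")
})

test_that("the derivative operator is linear and tracks the retained grid", {
  set.seed(7)
  x <- rnorm(80); y <- rnorm(80)
  wl <- seq(400, 558, 2)
  tr <- function(v) gap_segment_derivative(rbind(v), 2, 4, 4, 3, wl)
  expect_equal(tr(2 * x - 5 * y)$X, 2 * tr(x)$X - 5 * tr(y)$X,
               tolerance = 1e-10)
  out <- tr(x)
  expect_true(all(out$wavelengths %in% wl))
  expect_equal(ncol(out$X), length(out$wavelengths))
  expect_lt(length(out$wavelengths), length(wl))
})

test_that("pre-treatment application composes scatter and derivative", {
  sp <- toy_spectra(n = 4, W = 80, seed = 2)
  raw <- apply_pretreatment(sp, pretreatment("0,0,1,1", "None"))
  expect_equal(spectra_matrix(raw), spectra_matrix(sp))
  spec <- fit_pretreatment(sp, pretreatment("2,4,4,1", "SMSC"))
  once <- apply_pretreatment(sp, spec)
  expect_identical(spectra_matrix(once),
                   spectra_matrix(apply_pretreatment(sp, spec)))
  expect_error(apply_pretreatment(sp, pretreatment("1,4,4,1", "WMSC")),
               "fitted")
})

test_that("SNVD after a derivative shrinks scatter-driven spread", {
  # multiplicative-scatter copies of one spectrum: the derivative alone keeps
  # the multiplicative spread, SNVD removes it
  wl <- seq(1100, 1898, 2)
  base <- exp(-((wl - 1450)^2) / 8000) + 0.5 * exp(-((wl - 1700)^2) / 3000)
  set.seed(9)
  X <- t(vapply(1:10, function(i) {
    exp(rnorm(1, 0, 0.1)) * base + rnorm(1, 0, 0.05)
  }, numeric(length(wl))))
  sp <- as_spectra(X, wl, sprintf("s%d", 1:10))
  d_only <- spectra_matrix(apply_pretreatment(sp, pretreatment("2,4,4,1")))
  d_snvd <- spectra_matrix(
    apply_pretreatment(sp, pretreatment("2,4,4,1", "SNVD")))
  spread <- function(M) mean(apply(M / sd(M), 2, sd))
  expect_lt(spread(d_snvd), spread(d_only))
})

test_that("the pre-treatment grid holds the 77 unique combinations", {
  grid <- build_grid()
  expect_equal(nrow(grid), 77)
  expect_equal(dplyr::n_distinct(grid$code, grid$scatter), 77)
  expect_equal(dplyr::n_distinct(grid$scatter), 7)
  expect_equal(dplyr::n_distinct(grid$code), 11)
  expect_true(any(grid$code == "2,12,12,1" & grid$scatter == "SNVD"))
  expect_true(any(grid$code == "0,0,1,1" & grid$scatter == "None"))
})
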