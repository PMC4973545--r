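#' Configuration for the synthetic corn dataset generator
#'
#' The generator emulates a feed-NIRS calibration study: a set of ground corn
#' samples with correlated proximate composition, reference energies derived
#' from that composition, and diffuse-reflectance log(1/R) spectra on the
#' 400-2498 nm / 2 nm grid, each sample scanned in duplicate subsamples.
#' Composition ranges, means and SDs default to the entire-set summary of a
#' 117-sample Chinese corn collection (% DM): moisture 10.90-14.00, CP
#' 7.80-11.00, EE 2.09-4.97, ash 0.83-1.82, ADF 1.73-3.69, NDF 6.40-19.37.
#' Calculated energies (`de_c`, `me_c`) follow the Noblet-Perez equations
#' exactly; determined energies (`de_d`, `me_d`) add seeded Gaussian lab
#' noise whose SD (default 0.19 MJ/kg) puts the signal-SD-to-noise ratio in
#' the 2.5-2.9 regime typical of digestion-trial references.
#'
#' Spectra are built from an invented but NIR-plausible band library (2-4
#' Gaussian absorption bands per constituent in the 1100-2400 nm overtone
#' region) on a fixed smooth corn background, then per-scan degraded with a
#' multiplicative scatter factor, a baseline tilt and offset, and white
#' noise -- the broad peaks, baseline shifts and parallel scatter shifts seen
#' in raw feed spectra.
#'
#' @param n_samples number of corn samples (default 117).
#' @param seed integer seed governing all randomness.
#' @param n_scans duplicate subsample scans per sample (default 2).
#' @param wl_min,wl_max,wl_step wavelength grid in nm.
#' @param scatter_sd SD of the log multiplicative scatter factor per scan.
#' @param scatter_tilt_sd,scatter_curve_sd SDs of the wavelength-linear and
#'   quadratic terms of the log multiplicative factor, making the scatter
#'   wavelength-dependent as particle-size effects are.
#' @param additive_sd SD of the per-scan additive offset (absorbance).
#' @param baseline_slope_sd SD of the per-scan additive linear baseline tilt
#'   (absorbance over the full range).
#' @param noise_sd white-noise SD per wavelength point (absorbance; the
#'   default matches a scanning monochromator averaging 32 scans).
#' @param lab_noise_sd SD of determined-energy lab noise (MJ/kg DM).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 117, seed = 1, n_scans = 2,
                       wl_min = 400, wl_max = 2498, wl_step = 2,
                       scatter_sd = 0.05, scatter_tilt_sd = 0.02,
                       scatter_curve_sd = 0.01, additive_sd = 0.02,
                       baseline_slope_sd = 0.01, noise_sd = 5e-5,
                       lab_noise_sd = 0.22) {
  # sd is the target sample SD of the truncated draw; sd_inflation is the
  # pre-truncation scale factor that makes the post-truncation SD land on it
  # (the ranges sit at only 1.5-2.5 sigma, so clipping shrinks the spread)
  composition <- tibble::tibble(
    constituent = c("moisture", "cp", "ee", "ash", "adf", "ndf"),
    min = c(10.90, 7.80, 2.09, 0.83, 1.73, 6.40),
    max = c(14.00, 11.00, 4.97, 1.82, 3.69, 19.37),
    mean = c(12.63, 9.41, 3.87, 1.41, 2.33, 12.02),
    sd = c(0.892, 0.718, 0.580, 0.257, 0.443, 3.083),
    sd_inflation = c(1.80, 1.25, 1.26, 1.71, 1.55, 1.69)
  )
  # fibre-linked correlation structure: the cell-wall fractions travel
  # together and against oil/protein, as in bran-rich versus starchy kernels;
  # this also reproduces the calculated-energy spread of real corn sets
  corr <- diag(6)
  dimnames(corr) <- list(composition$constituent, composition$constituent)
  set_r <- function(a, b, r) corr[a, b] <<- corr[b, a] <<- r
  set_r("adf", "ndf", 0.75); set_r("ash", "ndf", 0.75)
  set_r("ash", "adf", 0.55); set_r("ee", "ndf", -0.65)
  set_r("cp", "ndf", -0.5); set_r("ee", "ash", -0.4)
  set_r("cp", "ash", -0.3); set_r("cp", "ee", 0.3)
  set_r("ee", "adf", -0.45); set_r("cp", "adf", -0.3)
  # invented band library: centres in the NIR overtone/combination region,
  # amplitudes in absorbance per g/kg of constituent
  bands <- tibble::tibble(
    constituent = c("moisture", "moisture",
                    "cp", "cp", "cp",
                    "ee", "ee", "ee",
                    "ash",
                    "adf", "adf",
                    "ndf", "ndf", "ndf"),
    center = c(1450, 1940,
               1510, 2055, 2180,
               1210, 1725, 2310,
               2100,
               1680, 2270,
               1490, 2100, 2335),
    width = c(45, 55,
              40, 50, 45,
              35, 40, 45,
              120,
              50, 45,
              60, 55, 50),
    amplitude = c(10e-4, 12e-4,
                  7.5e-4, 9e-4, 8e-4,
                  10e-4, 12e-4, 11e-4,
                  2.5e-4,
                  7.5e-4, 8e-4,
                  6e-4, 5e-4, 6.5e-4)
  )
  structure(
    list(n_samples = n_samples, seed = seed, n_scans = n_scans,
         wavelengths = seq(wl_min, wl_max, by = wl_step),
         composition = composition, corr = corr, bands = bands,
         scatter_sd = scatter_sd, scatter_tilt_sd = scatter_tilt_sd,
         scatter_curve_sd = scatter_curve_sd, additive_sd = additive_sd,
         baseline_slope_sd = baseline_slope_sd, noise_sd = noise_sd,
         lab_noise_sd = lab_noise_sd),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %d samples x %d scans, %d wavelengths, seed %s>\n",
              x$n_samples, x$n_scans, length(x$wavelengths),
              format(x$seed)))
  invisible(x)
}

#' Draw correlated corn compositions
#'
#' Samples compositions (% DM) from a truncated multivariate normal with the
#' configured means, SDs, correlations and ranges; rows falling outside any
#' range are redrawn until all lie inside.
#'
#' @param cfg a [sim_config()].
#' @return Tibble with `sample_id` and one column per constituent (% DM).
#' @export
sample_compositions <- function(cfg) {
  comp <- cfg$composition
  s <- comp$sd * (comp$sd_inflation %||% rep(1, nrow(comp)))
  Sigma <- diag(s) %*% cfg$corr %*% diag(s)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("infeasible composition correlation matrix.")
  draw <- function(k) MASS::mvrnorm(k, comp$mean, Sigma)
  with_seed(cfg$seed, {
    out <- matrix(NA_real_, cfg$n_samples, nrow(comp))
    need <- seq_len(cfg$n_samples)
    guard <- 0
    while (length(need) > 0) {
      cand <- draw(length(need))
      if (is.null(dim(cand))) cand <- rbind(cand)
      ok <- apply(cand, 1, function(r) all(r >= comp$min & r <= comp$max))
      out[need[ok], ] <- cand[ok, , drop = FALSE]
      need <- need[!ok]
      guard <- guard + 1
      if (guard > 10000) abort("range truncation rejected too many draws.")
    }
    colnames(out) <- comp$constituent
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("corn%03d", seq_len(cfg$n_samples))),
      tibble::as_tibble(out)
    )
  })
}

#' Attach reference energies to simulated compositions
#'
#' `de_c`/`me_c` are the exact Noblet-Perez equation outputs for each
#' composition (so the energy module and the generator agree by
#' construction); `de_d`/`me_d` add independent Gaussian lab noise of SD
#' `cfg$lab_noise_sd`, emulating digestion-trial determination error, with
#' `me_d` clamped to at most `de_d` to respect the energy balance.
#'
#' @param compositions tibble from [sample_compositions()].
#' @param cfg a [sim_config()].
#' @return The reference tibble: compositions plus `de_c`, `me_c`, `de_d`,
#'   `me_d` (MJ/kg DM).
#' @export
generate_energies <- function(compositions, cfg) {
  ref <- add_calculated_energy(compositions, units = "percent_dm")
  with_seed(cfg$seed + 1L, {
    n <- nrow(ref)
    ref$de_d <- ref$de_c + rnorm(n, 0, cfg$lab_noise_sd)
    ref$me_d <- pmin(ref$me_c + rnorm(n, 0, cfg$lab_noise_sd), ref$de_d)
  })
  ref
}

# fixed smooth corn background: rising baseline plus broad water/starch bumps
background_spectrum <- function(wl) {
  0.35 + 3.5e-4 * (wl - 400) +
    0.25 * exp(-((wl - 1450)^2) / (2 * 90^2)) +
    0.40 * exp(-((wl - 1940)^2) / (2 * 110^2)) +
    0.35 * exp(-((wl - 2100)^2) / (2 * 140^2))
}

#' Simulate NIR spectra for a set of compositions
#'
#' Each sample's noiseless spectrum is the fixed background plus the sum of
#' its constituents' Gaussian bands scaled by concentration (g/kg DM). Each
#' scan then receives an independent multiplicative scatter factor, linear
#' baseline tilt, additive offset and white noise; duplicate scans of a
#' sample share the composition and differ only in these scan effects.
#'
#' @param compositions tibble with `sample_id` and constituent columns
#'   (% DM).
#' @param cfg a [sim_config()].
#' @return A spectra tibble with `cfg$n_scans` rows per sample and
#'   `subsample_id` marking the scans.
#' @export
generate_spectra <- function(compositions, cfg) {
  wl <- cfg$wavelengths
  W <- length(wl)
  base <- background_spectrum(wl)
  profiles <- lapply(split(cfg$bands, cfg$bands$constituent), function(b) {
    Reduce(`+`, lapply(seq_len(nrow(b)), function(i) {
      b$amplitude[i] * exp(-((wl - b$center[i])^2) / (2 * b$width[i]^2))
    }))
  })
  n <- nrow(compositions)
  signal <- matrix(rep(base, each = n), n, W)
  for (const in names(profiles)) {
    conc <- compositions[[const]] * 10   # % DM -> g/kg DM
    signal <- signal + outer(conc, profiles[[const]])
  }
  with_seed(cfg$seed + 2L, {
    scans <- n * cfg$n_scans
    row_of <- rep(seq_len(n), each = cfg$n_scans)
    ramp <- (wl - wl[1]) / (wl[W] - wl[1]) - 0.5
    # wavelength-dependent multiplicative scatter in log space
    log_mult <- outer(rnorm(scans, 0, cfg$scatter_sd), rep(1, W)) +
      outer(rnorm(scans, 0, cfg$scatter_tilt_sd), ramp) +
      outer(rnorm(scans, 0, cfg$scatter_curve_sd), ramp^2 - 1 / 12)
    tilt <- rnorm(scans, 0, cfg$baseline_slope_sd)
    offs <- rnorm(scans, 0, cfg$additive_sd)
    X <- exp(log_mult) * signal[row_of, , drop = FALSE] +
      outer(tilt, ramp) + offs +
      matrix(rnorm(scans * W, 0, cfg$noise_sd), scans, W)
    as_spectra(X, wl,
               compositions$sample_id[row_of],
               rep(sprintf("sub%d", seq_len(cfg$n_scans)), n))
  })
}

#' Generate a complete synthetic dataset
#'
#' Composes [sample_compositions()], [generate_energies()] and
#' [generate_spectra()]; optionally writes the spectra/reference CSV pair.
#'
#' @param cfg a [sim_config()].
#' @param dir optional directory to write `spectra.csv` and
#'   `reference.csv` into.
#' @return list with the `spectra` tibble (n_samples x n_scans rows) and the
#'   `reference` tibble (one row per sample).
#' @examples
#' ds <- make_dataset(sim_config(n_samples = 25, wl_max = 898))
#' @export
make_dataset <- function(cfg = sim_config(), dir = NULL) {
  comp <- sample_compositions(cfg)
  reference <- generate_energies(comp, cfg)
  spectra <- generate_spectra(comp, cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_spectra(spectra, file.path(dir, "spectra.csv"))
    readr::write_csv(reference, file.path(dir, "reference.csv"),
                     progress = FALSE)
  }
  list(spectra = spectra, reference = reference)
}
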