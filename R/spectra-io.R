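#' Spectra tibbles
#'
#' Spectra travel through the package as ordinary tibbles with one row per
#' scan: a `sample_id` column, an optional `subsample_id` column marking
#' replicate scans of the same sample, and one numeric column per wavelength,
#' named by its position in nanometres (`"400"`, `"402"`, ...). Absorbance is
#' log(1/R). The default grid is 400-2498 nm in 2 nm steps (1050 points), the
#' standard scanning-monochromator layout for feed NIRS; any strictly
#' increasing constant-step grid is accepted so tests can use toy grids.
#'
#' @param absorbance numeric matrix, scans x wavelengths, of log(1/R) values.
#' @param wavelengths numeric vector of wavelengths in nm, one per column.
#' @param sample_ids character vector of sample identifiers, one per row.
#' @param subsample_ids optional character vector marking replicate scans.
#' @return A tibble with `sample_id`, optionally `subsample_id`, and one
#'   column per wavelength.
#' @examples
#' as_spectra(matrix(rnorm(6), 2), c(400, 402, 404), c("a", "b"))
#' @export
as_spectra <- function(absorbance, wavelengths, sample_ids,
                       subsample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  validate_grid(wavelengths)
  if (ncol(absorbance) != length(wavelengths)) {
    abort("`absorbance` must have one column per wavelength.")
  }
  if (nrow(absorbance) != length(sample_ids)) {
    abort("`sample_ids` must have one entry per scan row.")
  }
  if (!all(is.finite(absorbance))) {
    abort("absorbance values must all be finite.")
  }
  out <- tibble::as_tibble(absorbance, .name_repair = "minimal")
  names(out) <- format_wl(wavelengths)
  ids <- tibble::tibble(sample_id = as.character(sample_ids))
  if (!is.null(subsample_ids)) {
    ids$subsample_id <- as.character(subsample_ids)
  }
  dplyr::bind_cols(ids, out)
}

format_wl <- function(wl) {
  # keep names stable under read/write round trips
  sub("\\.?0+$", "", sprintf("%.6f", wl))
}

validate_grid <- function(wl) {
  if (length(wl) < 2 || anyNA(wl)) {
    abort("wavelength grid must hold at least two finite values.")
  }
  steps <- diff(wl)
  if (any(steps <= 0)) {
    abort("wavelength grid must be strictly increasing.")
  }
  if (max(steps) - min(steps) > 1e-8 * max(abs(wl))) {
    abort("wavelength grid must have a constant step (gapped header).")
  }
  invisible(wl)
}

#' Extract the wavelength grid or absorbance matrix from a spectra tibble
#'
#' @param spectra a spectra tibble (see [as_spectra()]).
#' @return `spectra_wavelengths()`: numeric vector of nm.
#'   `spectra_matrix()`: numeric matrix, scans x wavelengths, with sample ids
#'   as row names.
#' @export
spectra_wavelengths <- function(spectra) {
  wl <- suppressWarnings(as.numeric(names(spectra)))
  wl[!is.na(wl)]
}

#' @rdname spectra_wavelengths
#' @export
spectra_matrix <- function(spectra) {
  keep <- !is.na(suppressWarnings(as.numeric(names(spectra))))
  m <- as.matrix(spectra[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- spectra$sample_id
  colnames(m) <- names(spectra)[keep]
  m
}

id_cols <- function(spectra) {
  intersect(c("sample_id", "subsample_id"), names(spectra))
}

#' Read and write spectra files
#'
#' The on-disk dialect is plain CSV: columns `sample_id`, optionally
#' `subsample_id`, then one column per wavelength with the wavelength in nm as
#' the header. The header grid is validated (strictly increasing, constant
#' step) before any values are accepted.
#'
#' @param path file path.
#' @param spectra a spectra tibble.
#' @return `read_spectra()` returns a spectra tibble with rows in file order;
#'   `write_spectra()` returns `path` invisibly.
#' @export
read_spectra <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"sample_id" %in% names(raw)) {
    abort("spectra file must carry a `sample_id` column.")
  }
  wl_names <- setdiff(names(raw), c("sample_id", "subsample_id"))
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) {
    abort(paste0("non-numeric wavelength header: ",
                 paste(wl_names[is.na(wl)][1:3], collapse = ", ")))
  }
  validate_grid(wl)
  m <- matrix(NA_real_, nrow(raw), length(wl))
  for (j in seq_along(wl_names)) {
    v <- suppressWarnings(as.numeric(raw[[wl_names[j]]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("non-numeric absorbance at row %d, wavelength %s",
                    i, wl_names[j]))
    }
    m[, j] <- v
  }
  as_spectra(m, wl, raw$sample_id,
             if ("subsample_id" %in% names(raw)) raw$subsample_id)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(spectra, path) {
  readr::write_csv(spectra, path, progress = FALSE)
  invisible(path)
}

#' Average replicate subsample scans
#'
#' Each sample is scanned in independent subsamples and the mean spectrum is
#' used for chemometric analysis. Rows sharing a `sample_id` are replaced by
#' their arithmetic mean, in order of first occurrence; averaging is done on
#' the raw log(1/R) values, before any pre-treatment.
#'
#' @param spectra a spectra tibble, possibly with several scans per sample.
#' @return A spectra tibble with one row per unique `sample_id` and no
#'   `subsample_id` column.
#' @export
average_duplicates <- function(spectra) {
  m <- spectra_matrix(spectra)
  ids <- spectra$sample_id
  uniq <- unique(ids)
  f <- factor(ids, levels = uniq)
  counts <- tabulate(f)
  if (any(counts == 0)) abort("sample with zero scans.")
  avg <- rowsum(m, f) / counts
  as_spectra(avg, spectra_wavelengths(spectra), uniq)
}

#' Split sample ids into calibration and validation sets
#'
#' A seeded uniform random draw without stratification: `n_val` ids are drawn
#' for the validation set and the remainder form the calibration set. The two
#' sets are disjoint and together exhaust the input.
#'
#' @param ids character vector of unique sample ids.
#' @param n_val number of validation samples (0 < n_val < length(ids)).
#' @param seed integer seed making the split reproducible.
#' @return A list with character vectors `cal` and `val`.
#' @examples
#' split_cal_val(sprintf("s%03d", 1:117), 29, seed = 1)
#' @export
split_cal_val <- function(ids, n_val, seed = NULL) {
  n <- length(ids)
  if (anyDuplicated(ids)) abort("`ids` must be unique.")
  if (n_val <= 0 || n_val >= n) {
    abort("`n_val` must be strictly between 0 and the number of samples.")
  }
  val <- with_seed(seed, sort(sample.int(n, n_val)))
  list(cal = ids[-val], val = ids[val])
}
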