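#' Run the full calibration pipeline
#'
#' End-to-end orchestration for one constituent: average duplicate scans,
#' split samples into calibration and validation sets (or use a supplied
#' split), grid-search the pre-treatments on the calibration set, and
#' validate the winner on the held-out samples.
#'
#' @param spectra spectra tibble (raw scans; duplicates are averaged here).
#' @param reference reference data frame keyed by `sample_id`.
#' @param constituent reference column to calibrate.
#' @param grid pre-treatment grid, see [build_grid()].
#' @param n_val validation-set size used when `split` is NULL (default 29,
#'   a 88/29 split at n = 117).
#' @param split optional list with `cal` and `val` id vectors.
#' @param seed seed for the split and the cross-validation partitions.
#' @param ... passed to [calibrate()] via [grid_search()].
#' @return An object of class `nirs_run`: the grid-search object, the
#'   validation stats, the split, and the constituent.
#' @export
run_calibration <- function(spectra, reference, constituent = "de_d",
                            grid = build_grid(), n_val = 29, split = NULL,
                            seed = NULL, ...) {
  averaged <- average_duplicates(spectra)
  split <- split %||% split_cal_val(averaged$sample_id, n_val, seed = seed)
  cal <- averaged[averaged$sample_id %in% split$cal, ]
  val <- averaged[averaged$sample_id %in% split$val, ]
  gs <- grid_search(cal, reference, constituent, grid = grid, seed = seed,
                    ...)
  structure(
    list(grid_search = gs, best = gs$best,
         validation = validate(gs$best, val, reference),
         split = split, constituent = constituent, seed = seed),
    class = "nirs_run"
  )
}

#' @export
print.nirs_run <- function(x, ...) {
  b <- x$best
  cat(sprintf("<nirs_run: %s | winner %s + %s | %d factors, n = %d>\n",
              x$constituent, b$spec$code, b$spec$scatter,
              b$optimal_factors, b$n_used))
  cat("calibration / cross-validation:\n"); print(b$stats)
  cat("validation:\n"); print(x$validation)
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Emits the leaderboard, the winner's summary row, the validation
#' statistics and the outlier log as TSV files plus a plain-text log with
#' the seed and split.
#'
#' @param run a `nirs_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(run$grid_search$leaderboard,
                   file.path(dir, "leaderboard.tsv"), progress = FALSE)
  readr::write_tsv(glance(run$best), file.path(dir, "calibration.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$validation, file.path(dir, "validation.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$best$removed, file.path(dir, "outliers.tsv"),
                   progress = FALSE)
  writeLines(c(
    sprintf("constituent: %s", run$constituent),
    sprintf("seed: %s", format(run$seed)),
    sprintf("calibration ids: %s", paste(run$split$cal, collapse = ",")),
    sprintf("validation ids: %s", paste(run$split$val, collapse = ","))
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Summary report tables
#'
#' Builds the three standard report tables from one or more completed runs:
#' a per-set composition/energy summary (min, max, mean, SD, CV), a
#' calibration/cross-validation table (one row per constituent) and a
#' validation table.
#'
#' @param runs a `nirs_run` or list of them.
#' @param reference the reference table the runs used.
#' @param columns reference columns to summarise; defaults to every numeric
#'   column.
#' @return list of tibbles `summary`, `calibration`, `validation`.
#' @export
run_report <- function(runs, reference, columns = NULL) {
  if (inherits(runs, "nirs_run")) runs <- list(runs)
  columns <- columns %||%
    names(reference)[vapply(reference, is.numeric, logical(1))]
  summary <- purrr::map_dfr(columns, function(cl) {
    dplyr::bind_cols(tibble::tibble(item = cl),
                     summary_stats(reference[[cl]]))
  })
  calibration <- purrr::map_dfr(runs, function(r) glance(r$best))
  validation <- purrr::map_dfr(runs, function(r) {
    dplyr::bind_cols(tibble::tibble(constituent = r$constituent),
                     r$validation)
  })
  list(summary = summary, calibration = calibration,
       validation = validation)
}
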