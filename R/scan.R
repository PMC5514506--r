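#' Specification of a methane-yield parameter scan
#'
#' Defines the grid searched over bulk glucose ("SBulk") and the initial
#' count of one species ("init area number"), with the other species
#' held fixed, replicated over seeds.
#'
#' @param glucose_values bulk glucose levels, g/L.
#' @param varied_species "methanogen" or "acidogen".
#' @param varied_counts initial counts of the varied species (>= 1
#'   allowed down to 1).
#' @param fixed_count initial count of the other species.
#' @param seeds integer seeds; one simulation per (glucose, count,
#'   seed).
#' @param duration simulated hours per run.
#' @return object of class `scan_spec`.
#' @export
scan_spec <- function(glucose_values, varied_species = c("methanogen",
                                                         "acidogen"),
                      varied_counts, fixed_count = 100,
                      seeds = 1:3, duration = 650) {
  varied_species <- match.arg(varied_species)
  stopifnot(length(glucose_values) >= 1, length(varied_counts) >= 1,
            all(glucose_values > 0), all(varied_counts >= 1),
            fixed_count >= 0, length(seeds) >= 1, duration > 0)
  structure(list(glucose_values = as.numeric(glucose_values),
                 varied_species = varied_species,
                 varied_counts = as.integer(varied_counts),
                 fixed_count = as.integer(fixed_count),
                 seeds = as.integer(seeds),
                 duration = as.numeric(duration)),
            class = "scan_spec")
}

#' Run a methane-yield parameter scan
#'
#' Runs one granule simulation per (glucose, count, seed) tuple of the
#' spec, scores each with [specific_methanogenic_activity()], and
#' aggregates the mean and standard deviation of the yield per grid
#' cell. Cells are independent: results do not depend on execution
#' order. A failed run is recorded as a missing cell with its
#' diagnostic and the scan continues.
#'
#' @param spec a [scan_spec].
#' @param base_protocol protocol the scan perturbs (default
#'   [default_protocol()]).
#' @return object of class `scan_result`: list with `runs` (tidy
#'   tibble: glucose, count, seed, yield_ml_per_g, diameter_mm, error)
#'   and `grid` (per-cell mean and sd of the yield).
#' @export
run_scan <- function(spec, base_protocol = default_protocol()) {
  stopifnot(inherits(spec, "scan_spec"))
  cells <- tidyr::expand_grid(glucose = spec$glucose_values,
                              count = spec$varied_counts,
                              seed = spec$seeds)
  fixed_species <- if (spec$varied_species == "methanogen") "acidogen"
                   else "methanogen"
  runs <- purrr::pmap_dfr(cells, function(glucose, count, seed) {
    proto <- base_protocol
    proto$solutes$bulk_value[proto$solutes$name == "glucose"] <- glucose
    counts <- setNames(c(count, spec$fixed_count),
                       c(spec$varied_species, fixed_species))
    proto$config$init_counts <- counts
    proto$config$duration <- spec$duration
    proto$config$seed <- as.integer(seed)
    res <- tryCatch({
      run <- run_simulation(proto)
      sma <- specific_methanogenic_activity(run)
      gm <- granule_metrics(run)
      tibble::tibble(yield_ml_per_g = sma$activity_ml_per_g,
                     diameter_mm = gm$diameter_mm, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(yield_ml_per_g = NA_real_, diameter_mm = NA_real_,
                     error = conditionMessage(e))
    })
    dplyr::bind_cols(tibble::tibble(glucose = glucose, count = count,
                                    seed = seed), res)
  })
  grid <- runs |>
    dplyr::group_by(.data$glucose, .data$count) |>
    dplyr::summarise(
      mean_yield = mean(.data$yield_ml_per_g, na.rm = TRUE),
      sd_yield = sd(.data$yield_ml_per_g, na.rm = TRUE),
      n_ok = sum(!is.na(.data$yield_ml_per_g)), .groups = "drop")
  structure(list(spec = spec, runs = runs, grid = grid),
            class = "scan_result")
}

#' @exportS3Method print scan_result
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d x %d grid (%s varied), %d runs\n",
              length(x$spec$glucose_values), length(x$spec$varied_counts),
              x$spec$varied_species, nrow(x$runs)))
  print(x$grid)
  invisible(x)
}

#' Best cell of a scan
#'
#' The grid cell with the highest mean yield; ties are broken toward
#' lower glucose, then lower count (least feed, smallest inoculum).
#'
#' @param result a `scan_result`.
#' @return tibble with one row: `glucose`, `count`, `mean_yield`.
#' @export
best_cell <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  ok <- result$grid[result$grid$n_ok > 0 & is.finite(result$grid$mean_yield), ]
  if (nrow(ok) == 0) {
    rlang::abort("all scan cells failed", class = "granusim_scan_error")
  }
  ok <- ok[order(-ok$mean_yield, ok$glucose, ok$count), ]
  ok[1, c("glucose", "count", "mean_yield")]
}
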