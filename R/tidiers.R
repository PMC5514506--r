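#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a granulation run
#'
#' Returns the per-step summary series: per-type cell counts and
#' biomass, standing solute masses, and the cumulative methane ledger.
#'
#' @param x a `granulation_run`.
#' @param ... unused.
#' @return a tibble with one row per timestep.
#' @export
tidy.granulation_run <- function(x, ...) x$summary

#' One-row summary of a granulation run
#'
#' Final counts, granule diameter, dead-core radius and specific
#' methanogenic activity.
#'
#' @param x a `granulation_run`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.granulation_run <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  gm <- granule_metrics(x)
  sma <- specific_methanogenic_activity(x)
  tibble::tibble(
    time = fin$time,
    acidogens = fin$acidogens, methanogens = fin$methanogens,
    dead = fin$dead,
    diameter_mm = gm$diameter_mm,
    dead_core_radius_um = gm$dead_core_radius_um,
    ch4_ml = sma$ch4_ml,
    activity_ml_per_g = sma$activity_ml_per_g)
}

#' @rdname tidy.granulation_run
#' @export
tidy.radial_profile <- function(x, ...) x$counts

#' Tidy a scan result
#'
#' @param x a `scan_result`.
#' @param ... unused.
#' @return tibble with one row per (glucose, count, seed) run.
#' @export
tidy.scan_result <- function(x, ...) x$runs

#' Best cell of a scan as a one-row summary
#'
#' @param x a `scan_result`.
#' @param ... unused.
#' @return a one-row tibble (see [best_cell()]).
#' @export
glance.scan_result <- function(x, ...) best_cell(x)
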