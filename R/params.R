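# Reference tables used across the analysis: the closed accident taxonomy,
# monsoon-climate monthly normals, PET comfort bands, and the published
# per-type PET distribution parameters used by the Monte Carlo stage.

#' The 18-label construction accident taxonomy
#'
#' @return Character vector of the 18 accident type labels.
#' @export
accident_types <- function() {
  c("electric shock", "slip", "fall", "traffic accident", "be hit",
    "collision", "get jammed", "leak or contact of chemicals", "fire",
    "bumped", "drowned", "explosion", "hypoxia", "violence",
    "contact of abnormal temperature", "cut", "animal injury",
    "fall beneath")
}

#' Monthly climate normals for a Korean monsoon climate
#'
#' Ten-year monthly means of air temperature, wind speed and relative
#' humidity for South Korea, together with the corresponding monthly PET.
#' These are the calibration targets of the synthetic climate generator.
#'
#' @return A tibble with columns `month`, `ta`, `v`, `rh`, `pet`.
#' @export
monthly_climate_normals <- function() {
  tibble::tibble(
    month = 1:12,
    ta = c(-0.9, 1.6, 6.3, 12.2, 17.8, 21.6, 25.1, 25.4, 20.9, 15, 8.2, 1.3),
    v = c(2.3, 2.4, 2.5, 2.5, 2.2, 2.0, 2.0, 1.9, 1.7, 1.9, 2.1, 2.3),
    rh = c(60.8, 60.0, 59.2, 61.2, 63.7, 72.9, 81.0, 79.4, 76.5, 71.3,
           67.5, 63.3),
    pet = c(-12.0, -8.9, -2.8, 4.9, 12.2, 16.9, 21.2, 21.6, 16.5, 9.3,
            0.5, -9.1)
  )
}

#' Monthly accident frequency shape
#'
#' Ten-year monthly mean counts of fatal accidents and injuries in the
#' Korean construction industry. The synthetic registry uses the
#' severity-specific shape (normalized to mean 1) as its seasonal intensity
#' modulation.
#'
#' @return A tibble with columns `month`, `fatal_mean`, `injury_mean`.
#' @export
monthly_accident_shape <- function() {
  tibble::tibble(
    month = 1:12,
    fatal_mean = c(37.80, 31.80, 41.70, 43.60, 45.50, 43.90, 50.00, 48.90,
                   45.80, 51.00, 47.40, 44.30),
    injury_mean = c(1168.30, 1049.60, 1602.40, 1757.70, 1925.80, 1990.00,
                    1900.00, 2001.70, 1778.60, 2116.50, 1909.70, 1579.50)
  )
}

#' Ten-year accident totals by type and severity
#'
#' Published ten-year totals of fatal incidents and injuries for each of the
#' 18 accident types; the synthetic registry's default base rates are these
#' totals divided by ten years.
#'
#' @return A tibble with columns `accident_type`, `fatal_total`,
#'   `injury_total`.
#' @export
accident_type_totals <- function() {
  readr::read_csv(
    system.file("extdata", "accident_type_totals.csv",
                package = "comfortrisk"),
    show_col_types = FALSE
  )
}

#' Published PET distribution parameters by accident type
#'
#' Mean and standard deviation of event-level PET for each accident type and
#' severity, together with the published Monte Carlo percentages for the
#' cold (< 18 degC), hot (>= 23 degC) and outside-comfort ranges. The
#' parameter rows can be fed directly to [mcs_probabilities()] without any
#' registry.
#'
#' @param severity Optional filter, `"fatal"` or `"injury"`.
#' @return A tibble with columns `accident_type`, `severity`, `mean`, `sd`,
#'   `published_cold_pct`, `published_hot_pct`, `published_outside_pct`.
#' @export
pet_distribution_params <- function(severity = NULL) {
  out <- readr::read_csv(
    system.file("extdata", "pet_distribution_params.csv",
                package = "comfortrisk"),
    show_col_types = FALSE
  )
  if (!is.null(severity)) {
    sv <- match.arg(severity, c("fatal", "injury"))
    out <- out[out$severity == sv, ]
  }
  out
}

#' District-level linkage example records
#'
#' Six published example accident rows with their matched hourly weather and
#' the PET values produced by the thermophysiological simulation tool used
#' to build the original exposure database. Used as a soft cross-check of
#' the in-package PET approximation.
#'
#' @return A tibble with city, district, timestamp parts, weather fields,
#'   `pet_reference` and `accident_type`.
#' @export
linkage_examples <- function() {
  readr::read_csv(
    system.file("extdata", "linkage_examples.csv", package = "comfortrisk"),
    show_col_types = FALSE
  )
}
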