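# Season and PET comfort-band classification, and the cross-tabulations
# (month x type x severity, band x type x severity) used by the summary
# tables.

#' PET comfort bands
#'
#' The nine thermal-perception bands as half-open intervals
#' `[lower, upper)`. The published band edges repeat their endpoints
#' ("4~8", "8~13"); the half-open convention makes the bands an exact
#' partition of the real line. The comfort zone is exactly `[18, 23)`;
#' everything below is the cold zone, everything at or above 23 degC the
#' hot zone.
#'
#' @return A tibble with `label`, `lower`, `upper`, `zone`.
#' @export
comfort_bands <- function() {
  tibble::tibble(
    label = c("Very cold", "Cold", "Cool", "Slightly cool", "Neutral",
              "Slightly warm", "Warm", "Hot", "Very hot"),
    lower = c(-Inf, 4, 8, 13, 18, 23, 29, 35, 41),
    upper = c(4, 8, 13, 18, 23, 29, 35, 41, Inf),
    zone = c("cold", "cold", "cold", "cold", "comfort",
             "hot", "hot", "hot", "hot")
  )
}

#' Classify PET into a comfort band
#'
#' @param pet PET values in degC (finite).
#' @param allow_na Tolerate `NA` inputs (returned as `NA` band).
#' @return Factor of band labels, ordered cold to hot.
#' @export
classify_pet <- function(pet, allow_na = FALSE) {
  if (!allow_na && any(!is.finite(pet))) {
    stop("`pet` must be finite", call. = FALSE)
  }
  bands <- comfort_bands()
  cut(pet, breaks = c(bands$lower, Inf)[!duplicated(c(bands$lower, Inf))],
      labels = bands$label, right = FALSE)
}

#' Comfort zone of a PET value
#'
#' @inheritParams classify_pet
#' @return Factor with levels `cold`, `comfort`, `hot`.
#' @export
comfort_zone <- function(pet, allow_na = FALSE) {
  if (!allow_na && any(!is.finite(pet))) {
    stop("`pet` must be finite", call. = FALSE)
  }
  factor(ifelse(pet < 18, "cold", ifelse(pet < 23, "comfort", "hot")),
         levels = c("cold", "comfort", "hot"))
}

#' Season of a calendar month
#'
#' March-May is spring, June-August summer, September-November autumn and
#' December-February winter.
#'
#' @param month Integer month, 1-12.
#' @return Factor with levels `spring`, `summer`, `autumn`, `winter`.
#' @export
season_of <- function(month) {
  if (any(is.na(month)) || any(month %% 1 != 0) ||
      any(month < 1 | month > 12)) {
    stop("`month` must be an integer in 1..12", call. = FALSE)
  }
  s <- c("winter", "winter", "spring", "spring", "spring", "summer",
         "summer", "summer", "autumn", "autumn", "autumn", "winter")
  factor(s[month], levels = c("spring", "summer", "autumn", "winter"))
}

#' Cross-tabulate classified events
#'
#' Integer counts of events over the requested axes, with every cell
#' present (zero-filled). The grand total always equals the number of
#' events.
#'
#' @param events Linked events with at least `accident_type` and
#'   `severity`; `month` axes need `timestamp`, band axes need
#'   `comfort_band`/`zone`.
#' @param axes Character vector of grouping axes, from `month`, `season`,
#'   `comfort_band`, `zone`, `accident_type`, `severity`.
#' @return A tibble of the axis columns plus integer `n`.
#' @export
crosstab <- function(events, axes = c("month", "accident_type", "severity")) {
  allowed <- c("month", "season", "comfort_band", "zone",
               "accident_type", "severity")
  bad_axes <- setdiff(axes, allowed)
  if (length(bad_axes)) {
    stop("unknown axes: ", paste(bad_axes, collapse = ", "), call. = FALSE)
  }
  if ("accident_type" %in% names(events)) {
    bad <- setdiff(unique(events$accident_type), accident_types())
    if (length(bad)) {
      stop("unknown accident type label(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df <- events
  if ("month" %in% axes) {
    df$month <- factor(as.POSIXlt(df$timestamp)$mon + 1L, levels = 1:12)
  }
  if ("accident_type" %in% axes) {
    df$accident_type <- factor(df$accident_type, levels = accident_types())
  }
  if ("severity" %in% axes) {
    df$severity <- factor(df$severity, levels = c("fatal", "injury"))
  }
  if ("comfort_band" %in% axes) {
    df$comfort_band <- factor(df$comfort_band, levels = comfort_bands()$label)
  }
  if ("zone" %in% axes) {
    df$zone <- factor(df$zone, levels = c("cold", "comfort", "hot"))
  }
  out <- dplyr::count(df, dplyr::across(dplyr::all_of(axes)), .drop = FALSE)
  out$n <- as.integer(out$n)
  out
}
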