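# Deterministic join of accident records to the climate record of their
# city, district and hour. District-level exposure semantics: every
# district of a city carries the city's weather, so two accidents in
# different districts of the same city at the same hour receive identical
# weather; different hours or different cities receive independent rows.

#' Link accident records to hourly climate records
#'
#' Joins on the key (city, district, hour), with accident timestamps
#' truncated (not rounded) to the hour. Under the `"nearest-hour"` policy,
#' events without an exact climate row fall back to the record one hour
#' earlier or later (the earlier hour wins ties); under `"strict"` they are
#' dropped and counted. PET, comfort band and season are computed for every
#' matched event.
#'
#' @param accidents Tibble with `city`, `district`, `timestamp`,
#'   `accident_type`, `severity`.
#' @param climate Tibble with `city`, `district`, `timestamp`, `ta`,
#'   `tmrt`, `v`, `rh`; one row per district-hour.
#' @param policy `"strict"` or `"nearest-hour"`.
#' @param compute_pet Compute `pet`, `comfort_band`, `zone`, `season` for
#'   matched events (default TRUE).
#' @param person,control Personal factors and PET solver control.
#' @return A tibble of linked events with the accident fields, matched
#'   weather fields and `match_quality` (`"exact"`, `"nearest-hour"` or
#'   `"unmatched"`). Under `"strict"`, unmatched events are excluded and
#'   their count is attached as attribute `n_unmatched` (also reported via
#'   `message()`); under `"nearest-hour"`, residually unmatched events are
#'   kept with `NA` weather and no PET.
#' @export
link_accidents <- function(accidents, climate,
                           policy = c("strict", "nearest-hour"),
                           compute_pet = TRUE,
                           person = person_state(),
                           control = pet_control()) {
  policy <- match.arg(policy)
  for (col in c("city", "district", "timestamp")) {
    if (!col %in% names(accidents) || !col %in% names(climate)) {
      stop("both inputs need a `", col, "` column", call. = FALSE)
    }
  }
  climate <- dplyr::mutate(climate, .hour = .truncate_hour(.data$timestamp))
  dup <- dplyr::count(climate, .data$city, .data$district, .data$.hour)
  if (any(dup$n > 1)) {
    stop(sprintf("climate feed has %d duplicated (city, district, hour) keys",
                 sum(dup$n > 1)), call. = FALSE)
  }
  weather <- dplyr::select(climate, "city", "district", ".hour",
                           "ta", "tmrt", "v", "rh")

  acc <- dplyr::mutate(accidents, .row = dplyr::row_number(),
                       .hour = .truncate_hour(.data$timestamp))
  out <- dplyr::left_join(acc, weather,
                          by = c("city", "district", ".hour"))
  out$match_quality <- ifelse(is.na(out$ta), "unmatched", "exact")

  if (policy == "nearest-hour" && any(out$match_quality == "unmatched")) {
    for (shift in c(-3600, 3600)) {
      miss <- out$match_quality == "unmatched"
      if (!any(miss)) break
      cand <- dplyr::mutate(out[miss, names(acc)],
                            .hour = .data$.hour + shift)
      repl <- dplyr::left_join(cand, weather,
                               by = c("city", "district", ".hour"))
      hit <- !is.na(repl$ta)
      for (col in c("ta", "tmrt", "v", "rh")) {
        out[[col]][miss][hit] <- repl[[col]][hit]
      }
      out$match_quality[miss][hit] <- "nearest-hour"
    }
  }

  n_unmatched <- sum(out$match_quality == "unmatched")
  if (policy == "strict") {
    if (n_unmatched > 0) {
      message(sprintf("dropping %d unmatched accident record(s)", n_unmatched))
    }
    out <- out[out$match_quality != "unmatched", ]
  }

  if (compute_pet && nrow(out) > 0) {
    matched <- out$match_quality != "unmatched"
    out$pet <- NA_real_
    if (any(matched)) {
      env <- env_state(ta = out$ta[matched], tmrt = out$tmrt[matched],
                       v = out$v[matched], rh = out$rh[matched])
      out$pet[matched] <- pet(env, person, control)$pet
    }
    out$comfort_band <- classify_pet(out$pet, allow_na = TRUE)
    out$zone <- comfort_zone(out$pet, allow_na = TRUE)
    out$season <- season_of(as.POSIXlt(out$timestamp)$mon + 1L)
  }

  out <- dplyr::arrange(out, .data$.row)
  out$.row <- NULL
  out$.hour <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  out
}

.truncate_hour <- function(timestamp) {
  as.POSIXct(trunc(as.POSIXlt(timestamp, tz = "UTC"), units = "hours"))
}
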