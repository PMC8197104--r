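# Synthetic climate feed and accident registry generator. Emulates the
# statistical structure the analysis assumes: district-level station
# structure where every district of a city shares the city's weather,
# monsoon-climate monthly normals with diurnal and autoregressive hourly
# variation, and inhomogeneous-Poisson accident streams over the 18-type
# taxonomy with seasonal and comfort-dependent intensity.

#' Configuration for the synthetic registry
#'
#' Defaults reproduce the conditions of the source exposure database: ten
#' calendar years, a three-city/six-district administrative layout, monthly
#' climate normals from [monthly_climate_normals()], per-type base rates
#' equal to the published ten-year totals divided by ten, and seasonal
#' modulation from the published monthly accident shape.
#'
#' @param years Number of simulated calendar years.
#' @param start_year First calendar year.
#' @param layout Named list mapping city names to character vectors of
#'   district names.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param normals Monthly climate normals (tibble with `month`, `ta`, `v`,
#'   `rh`).
#' @param diurnal_amplitude Amplitude of the diurnal temperature sinusoid,
#'   degC (peak at 14:00).
#' @param ar1_coef,ar1_sd AR(1) coefficient and stationary standard
#'   deviation of the hourly temperature noise.
#' @param radiant_noon_offset Radiant temperature elevation over air
#'   temperature at solar noon, degC (zero at night, sinusoidal between
#'   06:00 and 18:00).
#' @param wind_sdlog Log-scale standard deviation of the lognormal hourly
#'   wind speed.
#' @param rh_concentration Concentration parameter of the beta-distributed
#'   hourly relative humidity.
#' @param base_rates Tibble `accident_type`, `severity`, `events_per_year`.
#' @param seasonal_shape Tibble `month`, `fatal_mean`, `injury_mean` used
#'   (normalized to mean 1 per severity) as monthly intensity modulation.
#' @param comfort_multiplier Intensity multiplier applied to hours whose
#'   PET lies outside the 18-23 degC comfort range; a scalar or a named
#'   vector by accident type. 1 disables the planted effect.
#' @param working_hours Inclusive start/end clock hours of the working day.
#' @param person,pet_ctrl Personal factors and PET solver control used when
#'   accident intensities depend on PET.
#' @return A list of class `registry_config`.
#' @export
registry_config <- function(years = 10,
                            start_year = 2007,
                            layout = list(
                              Seoul = c("Gangbuk-gu", "Jung-gu", "Gangseo-gu"),
                              Incheon = "Nam-gu",
                              Cheongju = c("Sangdang-gu", "Seowon-gu")),
                            seed = 1L,
                            normals = monthly_climate_normals(),
                            diurnal_amplitude = 4,
                            ar1_coef = 0.8,
                            ar1_sd = 1.5,
                            radiant_noon_offset = 10,
                            wind_sdlog = 0.4,
                            rh_concentration = 25,
                            base_rates = NULL,
                            seasonal_shape = monthly_accident_shape(),
                            comfort_multiplier = 1,
                            working_hours = c(7, 17),
                            person = person_state(),
                            pet_ctrl = pet_control()) {
  if (length(layout) == 0 || any(lengths(layout) == 0)) {
    stop("`layout` must name at least one city with at least one district",
         call. = FALSE)
  }
  if (years < 1) stop("`years` must be >= 1", call. = FALSE)
  if (is.null(base_rates)) {
    tot <- accident_type_totals()
    base_rates <- tibble::tibble(
      accident_type = rep(tot$accident_type, 2),
      severity = rep(c("fatal", "injury"), each = nrow(tot)),
      events_per_year = c(tot$fatal_total, tot$injury_total) / 10
    )
  }
  if (any(base_rates$events_per_year < 0)) {
    stop("base rates must be >= 0", call. = FALSE)
  }
  structure(
    list(years = years, start_year = start_year, layout = layout,
         seed = as.integer(seed), normals = normals,
         diurnal_amplitude = diurnal_amplitude, ar1_coef = ar1_coef,
         ar1_sd = ar1_sd, radiant_noon_offset = radiant_noon_offset,
         wind_sdlog = wind_sdlog, rh_concentration = rh_concentration,
         base_rates = base_rates, seasonal_shape = seasonal_shape,
         comfort_multiplier = comfort_multiplier,
         working_hours = working_hours, person = person,
         pet_ctrl = pet_ctrl),
    class = "registry_config"
  )
}

# Mid-month day-of-year anchors whose piecewise-linear interpolation, when
# averaged back over each month, reproduces the monthly targets. Solved by
# fixed-point correction (the interpolation smooths local extrema, so the
# anchors must over-shoot them slightly).
.mean_preserving_anchors <- function(targets) {
  doy <- 1:365
  month_of <- rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  mid <- as.numeric(tapply(doy, month_of, function(x) mean(range(x))))
  anchors <- targets
  for (i in 1:50) {
    xs <- c(mid[12] - 365, mid, mid[1] + 365)
    ys <- c(anchors[12], anchors, anchors[1])
    daily <- stats::approx(xs, ys, xout = doy)$y
    implied <- as.numeric(tapply(daily, month_of, mean))
    err <- targets - implied
    if (max(abs(err)) < 1e-10) break
    anchors <- anchors + err
  }
  list(mid = mid, anchors = anchors)
}

.hourly_grid <- function(start_year, years) {
  start <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year), tz = "UTC")
  end <- as.POSIXct(sprintf("%d-01-01 00:00:00", start_year + years), tz = "UTC")
  seq(start, end - 3600, by = "hour")
}

#' Generate a synthetic hourly climate feed
#'
#' One hourly weather series per city, copied to every district of the
#' city. Air temperature is a mean-preserving interpolation of the monthly
#' normals plus a diurnal sinusoid and AR(1) noise; wind is lognormal and
#' relative humidity beta-distributed around their monthly normals; radiant
#' temperature is air temperature plus a deterministic daytime offset.
#'
#' @param config A [registry_config()].
#' @return A tibble of `ClimateRecord`s: `city`, `district`, `timestamp`,
#'   `ta`, `tmrt`, `v`, `rh`, one row per district-hour.
#' @export
generate_climate <- function(config = registry_config()) {
  stopifnot(inherits(config, "registry_config"))
  nm <- config$normals
  anch <- .mean_preserving_anchors(nm$ta)
  ts <- .hourly_grid(config$start_year, config$years)
  lt <- as.POSIXlt(ts)
  hour <- lt$hour
  month <- lt$mon + 1L
  # day-of-year on the 365-day anchor scale (leap day maps onto Feb 28)
  doy <- pmin(lt$yday + 1L, 365L)
  xs <- c(anch$mid[12] - 365, anch$mid, anch$mid[1] + 365)
  ys <- c(anch$anchors[12], anch$anchors, anch$anchors[1])
  base_ta <- stats::approx(xs, ys, xout = doy)$y
  diurnal <- config$diurnal_amplitude * cos(2 * pi * (hour - 14) / 24)
  daylight <- ifelse(hour >= 6 & hour <= 18,
                     sin(pi * (hour - 6) / 12), 0)
  n <- length(ts)
  v_mu <- log(nm$v[month]) - config$wind_sdlog^2 / 2
  rh_mu <- nm$rh[month] / 100

  per_city <- withr::with_seed(config$seed, {
    lapply(names(config$layout), function(city) {
      innov <- stats::rnorm(n, 0, config$ar1_sd * sqrt(1 - config$ar1_coef^2))
      noise <- as.numeric(stats::filter(innov, config$ar1_coef,
                                        method = "recursive"))
      ta <- base_ta + diurnal + noise
      v <- stats::rlnorm(n, v_mu, config$wind_sdlog)
      rh <- 100 * stats::rbeta(n, config$rh_concentration * rh_mu,
                               config$rh_concentration * (1 - rh_mu))
      rh <- pmin(pmax(rh, 0), 100)
      tibble::tibble(
        city = city, timestamp = ts, ta = ta,
        tmrt = ta + config$radiant_noon_offset * daylight,
        v = v, rh = rh)
    })
  })
  city_tbl <- dplyr::bind_rows(per_city)
  districts <- tibble::tibble(
    city = rep(names(config$layout), lengths(config$layout)),
    district = unlist(config$layout, use.names = FALSE)
  )
  out <- dplyr::inner_join(districts, city_tbl, by = "city",
                           relationship = "many-to-many")
  dplyr::arrange(out, .data$city, .data$district, .data$timestamp)
}

# TRUE for Monday-Friday hours within the working day.
.is_working_hour <- function(timestamp, working_hours) {
  lt <- as.POSIXlt(timestamp)
  lt$wday %in% 1:5 & lt$hour >= working_hours[1] & lt$hour <= working_hours[2]
}

# Per-city-hour PET for the hours where accident intensity is evaluated.
.city_hour_pet <- function(climate, config) {
  first_district <- dplyr::distinct(climate, .data$city, .data$district)
  first_district <- dplyr::slice_head(
    dplyr::group_by(first_district, .data$city), n = 1)
  ch <- dplyr::semi_join(climate, first_district, by = c("city", "district"))
  keep <- .is_working_hour(ch$timestamp, config$working_hours)
  ch <- ch[keep, c("city", "timestamp", "ta", "tmrt", "v", "rh")]
  env <- env_state(ta = ch$ta, tmrt = ch$tmrt, v = ch$v, rh = ch$rh)
  ch$pet <- pet(env, config$person, config$pet_ctrl)$pet
  ch
}

#' Seasonal intensity multipliers
#'
#' Monthly accident-frequency modulation, normalized to mean 1 within each
#' severity.
#'
#' @param config A [registry_config()].
#' @return A tibble `month`, `severity`, `multiplier`.
#' @export
seasonal_multipliers <- function(config = registry_config()) {
  sh <- config$seasonal_shape
  tibble::tibble(
    month = rep(sh$month, 2),
    severity = rep(c("fatal", "injury"), each = nrow(sh)),
    multiplier = c(sh$fatal_mean / mean(sh$fatal_mean),
                   sh$injury_mean / mean(sh$injury_mean))
  )
}

#' Solve the comfort multiplier for a planted outside-comfort probability
#'
#' Given seasonal intensity weights and an outside-comfort indicator per
#' working hour, returns the multiplier `k` such that the expected fraction
#' of events in outside-comfort hours equals `target`:
#' `k W_out / (k W_out + W_in) = target`.
#'
#' @param weights Non-negative intensity weights per hour (seasonal
#'   multiplier values).
#' @param outside Logical vector, TRUE where PET is outside 18-23 degC.
#' @param target Planted outside-comfort event probability in (0, 1).
#' @return The scalar multiplier.
#' @export
calibrate_comfort_multiplier <- function(weights, outside, target) {
  stopifnot(length(weights) == length(outside), target > 0, target < 1)
  w_out <- sum(weights[outside])
  w_in <- sum(weights[!outside])
  if (w_out == 0) stop("no outside-comfort hours in the series", call. = FALSE)
  (target / (1 - target)) * (w_in / w_out)
}

#' Generate a synthetic accident registry
#'
#' Inhomogeneous Poisson sampling per accident type and severity over the
#' working station-hours (Monday-Friday, within `working_hours`) of the
#' climate feed. The hourly intensity is the base rate times the monthly
#' seasonal multiplier times the comfort multiplier for hours whose PET
#' falls outside 18-23 degC; seasonal multipliers are normalized so that the
#' expected annual count (at comfort multiplier 1) equals the configured
#' base rate. Events are distributed uniformly over the districts of each
#' city.
#'
#' @param climate A climate feed from [generate_climate()]. A precomputed
#'   `pet` column is used if present.
#' @param config The [registry_config()] used to generate the climate.
#' @return A tibble of `AccidentRecord`s: `city`, `district`, `timestamp`,
#'   `accident_type`, `severity`.
#' @export
generate_accidents <- function(climate, config = registry_config()) {
  stopifnot(inherits(config, "registry_config"))
  if (any(config$base_rates$events_per_year < 0)) {
    stop("base rates must be >= 0", call. = FALSE)
  }
  need_pet <- !identical(config$comfort_multiplier, 1) ||
    length(config$comfort_multiplier) > 1
  if ("pet" %in% names(climate)) {
    ch <- dplyr::distinct(climate, .data$city, .data$timestamp,
                          .keep_all = TRUE)
    ch <- ch[.is_working_hour(ch$timestamp, config$working_hours), ]
  } else if (need_pet) {
    ch <- .city_hour_pet(climate, config)
  } else {
    ch <- dplyr::distinct(climate, .data$city, .data$timestamp,
                          .keep_all = TRUE)
    ch <- ch[.is_working_hour(ch$timestamp, config$working_hours), ]
    ch$pet <- NA_real_
  }
  if (nrow(ch) == 0) stop("climate feed has no working hours", call. = FALSE)
  month <- as.POSIXlt(ch$timestamp)$mon + 1L
  outside <- !is.na(ch$pet) & (ch$pet < 18 | ch$pet >= 23)
  seas <- seasonal_multipliers(config)
  n_cities <- length(config$layout)
  hours_per_year <- nrow(ch) / n_cities / config$years

  rate_tbl <- config$base_rates
  km <- config$comfort_multiplier
  k_of <- function(type) {
    if (length(km) == 1 && is.null(names(km))) km
    else if (!is.null(names(km)) && type %in% names(km)) unname(km[type])
    else 1
  }

  events <- withr::with_seed(config$seed + 1L, {
    out <- vector("list", nrow(rate_tbl))
    for (i in seq_len(nrow(rate_tbl))) {
      row <- rate_tbl[i, ]
      s <- seas$multiplier[seas$severity == row$severity][month]
      k <- ifelse(outside, k_of(row$accident_type), 1)
      lambda <- row$events_per_year / (hours_per_year * n_cities) * s * k
      n_ev <- stats::rpois(length(lambda), lambda)
      idx <- rep.int(seq_along(n_ev), n_ev)
      if (length(idx) == 0) { out[[i]] <- NULL; next }
      city <- ch$city[idx]
      n_d <- lengths(config$layout)
      offset <- c(0, cumsum(n_d))[seq_along(n_d)]
      names(offset) <- names(n_d)
      all_d <- unlist(config$layout, use.names = FALSE)
      j <- floor(stats::runif(length(city)) * n_d[city]) + 1
      district <- all_d[offset[city] + j]
      out[[i]] <- tibble::tibble(
        city = city, district = unname(district),
        timestamp = ch$timestamp[idx],
        accident_type = row$accident_type, severity = row$severity)
    }
    dplyr::bind_rows(out)
  })
  if (nrow(events) == 0) {
    return(tibble::tibble(
      city = character(), district = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      accident_type = character(), severity = character()))
  }
  dplyr::arrange(events, .data$timestamp, .data$city, .data$district,
                 .data$accident_type)
}

#' Write a synthetic registry to CSV
#'
#' Generates the climate feed and accident registry and writes
#' `climate.csv` and `accidents.csv` into `dir`.
#'
#' @param config A [registry_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with both tibbles.
#' @export
simulate_registry_csv <- function(config = registry_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  climate <- generate_climate(config)
  accidents <- generate_accidents(climate, config)
  readr::write_csv(climate, file.path(dir, "climate.csv"))
  readr::write_csv(accidents, file.path(dir, "accidents.csv"))
  invisible(list(climate = climate, accidents = accidents))
}
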