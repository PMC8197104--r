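# Steady-state human heat-balance model (Fanger PMV) and the physiological
# equivalent temperature (PET) derived from it by load equivalence against a
# standardized indoor reference environment.

#' Saturation water vapor pressure (Magnus form)
#'
#' Saturation vapor pressure over water, `611.2 * exp(17.62 * ta / (243.12 +
#' ta))` Pa. The single continuous Magnus form is used at all temperatures,
#' including below 0 degC, to avoid a discontinuity at the freezing point.
#'
#' @param ta Air temperature in degC.
#' @return Saturation vapor pressure in Pa.
#' @export
saturation_vapor_pressure <- function(ta) {
  611.2 * exp(17.62 * ta / (243.12 + ta))
}

#' Water vapor partial pressure from relative humidity
#'
#' @param ta Air temperature in degC.
#' @param rh Relative humidity in percent, in `[0, 100]`.
#' @return Partial pressure of water vapor in Pa.
#' @export
vapor_pressure <- function(ta, rh) {
  if (any(!is.finite(rh)) || any(rh < 0 | rh > 100)) {
    stop("`rh` must be within [0, 100] percent", call. = FALSE)
  }
  rh / 100 * saturation_vapor_pressure(ta)
}

#' Clothing surface area factor
#'
#' Ratio of the clothed body surface area to the nude body surface area as a
#' function of clothing insulation. Two linear branches meet at
#' 0.078 m2K/W; the boundary value belongs to the lower branch.
#'
#' @param icl Clothing thermal resistance in m2K/W (`>= 0`).
#' @return Dimensionless area factor, `>= 1`.
#' @export
clothing_area_factor <- function(icl) {
  if (any(!is.finite(icl)) || any(icl < 0)) {
    stop("`icl` must be finite and >= 0", call. = FALSE)
  }
  ifelse(icl <= 0.078, 1.00 + 1.290 * icl, 1.05 + 0.645 * icl)
}

#' Convective heat transfer coefficient
#'
#' Larger of the natural-convection term `2.38 * |tcl - ta|^0.25` and the
#' forced-convection term `12.1 * sqrt(var)`.
#'
#' @param tcl Clothing surface temperature in degC.
#' @param ta Air temperature in degC.
#' @param var Relative air velocity in m/s (`>= 0`).
#' @return Coefficient in W/m2K.
#' @export
convective_coeff <- function(tcl, ta, var) {
  if (any(!is.finite(var)) || any(var < 0)) {
    stop("`var` must be finite and >= 0", call. = FALSE)
  }
  pmax(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(var))
}

#' Environmental state for the heat-balance model
#'
#' Builds a validated table of environmental inputs. Vapor pressure may be
#' given directly via `pa` (as in the PET reference environment, which fixes
#' `pa` regardless of air temperature) or derived from relative humidity.
#'
#' @param ta Air temperature, degC.
#' @param tmrt Mean radiant temperature, degC. Defaults to `ta`.
#' @param v Air velocity at body level, m/s.
#' @param rh Relative humidity, percent. Ignored when `pa` is supplied.
#' @param pa Water vapor partial pressure, Pa (optional).
#' @return A tibble with columns `ta`, `tmrt`, `v`, `rh`, `pa`.
#' @export
env_state <- function(ta, tmrt = ta, v, rh = NULL, pa = NULL) {
  if (is.null(pa) && is.null(rh)) {
    stop("supply either `rh` or `pa`", call. = FALSE)
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("`v` must be finite and >= 0", call. = FALSE)
  }
  if (is.null(pa)) {
    pa <- vapor_pressure(ta, rh)
  } else {
    if (any(pa < 0)) stop("`pa` must be >= 0", call. = FALSE)
    if (is.null(rh)) rh <- NA_real_
  }
  tibble::tibble(ta = ta, tmrt = tmrt, v = v, rh = rh, pa = pa)
}

#' Personal factors for the heat-balance model
#'
#' The default subject matches the fixed personal factors of the accident
#' analysis: 80 W total metabolic rate and 0.9 clo clothing. The total
#' wattage is converted to a flux with the subject's DuBois body surface
#' area (default 1.80 m2).
#'
#' @param met_watts Total metabolic rate in W.
#' @param body_surface_area_m2 DuBois body surface area in m2.
#' @param clo Clothing insulation in clo (1 clo = 0.155 m2K/W).
#' @param work Effective mechanical power in W/m2 (default 0).
#' @return A list with `met` and `work` (W/m2), `icl` (m2K/W) and `clo`.
#' @export
person_state <- function(met_watts = 80, body_surface_area_m2 = 1.80,
                         clo = 0.9, work = 0) {
  if (met_watts <= 0) stop("`met_watts` must be > 0", call. = FALSE)
  if (work < 0) stop("`work` must be >= 0", call. = FALSE)
  if (clo < 0) stop("`clo` must be >= 0", call. = FALSE)
  list(
    met = met_watts / body_surface_area_m2,
    work = work,
    icl = clo * 0.155,
    clo = clo
  )
}

# Vectorized clothing-temperature residual: rhs(tcl) - tcl, where rhs is the
# skin-side balance. Strictly decreasing in tcl, so it brackets a single root.
.tcl_residual <- function(tcl, ta, tmrt, v, tsk, icl, fcl) {
  hc <- pmax(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(v))
  tsk - icl * (3.96e-8 * fcl * ((tcl + 273)^4 - (tmrt + 273)^4) +
                 fcl * hc * (tcl - ta)) - tcl
}

#' Solve the clothing surface temperature
#'
#' The clothing surface temperature appears on both sides of its defining
#' balance (conduction through clothing = radiative + convective loss from
#' the clothed surface), with the convective coefficient recomputed from the
#' current iterate. A damped fixed-point iteration (damping 0.5) is tried
#' first; elements that fail to converge -- typical at outdoor wind speeds,
#' where the iteration oscillates -- fall back to bisection on the residual,
#' which is monotone in `tcl` and therefore always terminates.
#'
#' @param env An [env_state()] table (or data frame with its columns).
#' @param person A [person_state()] list.
#' @param tol Convergence tolerance on `tcl`, degC.
#' @param max_iter Maximum fixed-point iterations before the fallback.
#' @return A tibble with `tcl` (degC), `hc` (W/m2K), `fcl`, `iterations`
#'   and `converged`.
#' @export
solve_clothing_temperature <- function(env, person = person_state(),
                                       tol = 1e-4, max_iter = 500) {
  ta <- env$ta; tmrt <- env$tmrt; v <- env$v
  n <- length(ta)
  icl <- person$icl
  fcl <- clothing_area_factor(icl)
  tsk <- 35.7 - 0.028 * (person$met - person$work)

  tcl <- (tsk + ta) / 2
  done <- rep(FALSE, n)
  iters <- rep(0L, n)
  for (i in seq_len(max_iter)) {
    res <- .tcl_residual(tcl, ta, tmrt, v, tsk, icl, fcl)
    new <- tcl + 0.5 * res
    step_ok <- is.finite(new)
    just_done <- !done & step_ok & abs(new - tcl) < tol
    iters[!done] <- i
    tcl[!done & step_ok] <- new[!done & step_ok]
    done <- done | just_done
    # abandon elements whose iterates blew up; bisection handles them
    blown <- !done & !step_ok
    if (any(blown)) tcl[blown] <- NA_real_
    if (all(done | blown)) break
    if (i >= 30 && any(!done)) break  # oscillating: hand over to bisection
  }

  todo <- !done
  if (any(todo)) {
    lo <- pmin(ta[todo], tmrt[todo]) - 30
    hi <- rep(tsk + 30, sum(todo))
    for (k in 1:28) {
      mid <- (lo + hi) / 2
      pos <- .tcl_residual(mid, ta[todo], tmrt[todo], v[todo], tsk, icl, fcl) > 0
      lo <- ifelse(pos, mid, lo)
      hi <- ifelse(pos, hi, mid)
    }
    tcl[todo] <- (lo + hi) / 2
    iters[todo] <- iters[todo] + 28L
  }

  res <- .tcl_residual(tcl, ta, tmrt, v, tsk, icl, fcl)
  if (any(!is.finite(tcl)) || any(abs(res) > 1)) {
    stop("clothing temperature solver failed to converge", call. = FALSE)
  }
  tibble::tibble(
    tcl = tcl,
    hc = pmax(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(v)),
    fcl = fcl,
    iterations = iters,
    converged = TRUE
  )
}

# Thermal load on the body: metabolic heat production minus all heat losses
# (skin diffusion, sweat evaporation above the activity threshold, latent and
# sensible respiration, radiation, convection), in W/m2. Zero load means the
# environment is thermally neutral for the subject.
.body_load <- function(ta, tmrt, v, pa, person, tcl_fit = NULL) {
  if (is.null(tcl_fit)) {
    tcl_fit <- solve_clothing_temperature(
      tibble::tibble(ta = ta, tmrt = tmrt, v = v), person)
  }
  m <- person$met
  mw <- m - person$work
  sweat <- pmax(0.42 * (mw - 58.15), 0)
  mw -
    3.05e-3 * (5733 - 6.99 * mw - pa) -
    sweat -
    1.7e-5 * m * (5867 - pa) -
    0.0014 * m * (34 - ta) -
    3.96e-8 * tcl_fit$fcl * ((tcl_fit$tcl + 273)^4 - (tmrt + 273)^4) -
    tcl_fit$fcl * tcl_fit$hc * (tcl_fit$tcl - ta)
}

#' Predicted mean vote (PMV)
#'
#' Fanger's steady-state comfort index: the thermal load on the body scaled
#' by a metabolic sensitivity factor, `PMV = (0.303 exp(-0.036 M) + 0.028) *
#' L`. The load sums metabolic heat production against evaporative skin
#' loss, sweat evaporation, latent and sensible respiration, and radiative
#' and convective loss from the clothed surface.
#'
#' @inheritParams solve_clothing_temperature
#' @return A tibble with `pmv`, `load` (W/m2), `tcl`, `hc`, `fcl` and
#'   `iterations`.
#' @export
pmv <- function(env, person = person_state()) {
  fit <- solve_clothing_temperature(env, person)
  load <- .body_load(env$ta, env$tmrt, env$v, env$pa, person, fit)
  tibble::tibble(
    pmv = (0.303 * exp(-0.036 * person$met) + 0.028) * load,
    load = load,
    tcl = fit$tcl,
    hc = fit$hc,
    fcl = fit$fcl,
    iterations = fit$iterations
  )
}

#' Control parameters for the PET solver
#'
#' @param reference_v Air velocity of the reference environment, m/s.
#' @param reference_pa Vapor pressure of the reference environment, Pa.
#' @param bracket Search interval for the reference air temperature, degC.
#' @param tol Bisection tolerance on PET, degC.
#' @return A list of solver settings.
#' @export
pet_control <- function(reference_v = 0.1, reference_pa = 1200,
                        bracket = c(-60, 70), tol = 0.005) {
  list(reference_v = reference_v, reference_pa = reference_pa,
       bracket = bracket, tol = tol)
}

#' Physiological equivalent temperature (PET)
#'
#' Air temperature of a standardized indoor reference environment (mean
#' radiant temperature equal to air temperature, air velocity 0.1 m/s, vapor
#' pressure 1200 Pa) at which the model subject (0.9 clo, 80 W) carries the
#' same thermal load as in the actual environment. The reference temperature
#' is found by bisection; the load is strictly increasing in the reference
#' air temperature, so the root is unique.
#'
#' This is a single-node approximation: the skin temperature is the fixed
#' metabolic linear form of the PMV model rather than a regulated two-node
#' state, so strong wind combined with elevated radiant temperature is
#' weighted more heavily than in full thermophysiological simulators.
#'
#' @inheritParams solve_clothing_temperature
#' @param control A [pet_control()] list.
#' @return A tibble with `pet` (degC), `converged` and `reference_load`
#'   (W/m2).
#' @export
pet <- function(env, person = person_state(), control = pet_control()) {
  load_actual <- .body_load(env$ta, env$tmrt, env$v, env$pa, person)
  n <- length(load_actual)
  lo <- rep(control$bracket[1], n)
  hi <- rep(control$bracket[2], n)
  ref_load_at <- function(t) {
    .body_load(t, t, rep(control$reference_v, length(t)),
               rep(control$reference_pa, length(t)), person)
  }
  l_lo <- ref_load_at(lo); l_hi <- ref_load_at(hi)
  bad <- l_lo > load_actual | l_hi < load_actual
  if (any(bad)) {
    stop(sprintf("PET bracket [%g, %g] does not contain the matching load for %d input(s)",
                 control$bracket[1], control$bracket[2], sum(bad)), call. = FALSE)
  }
  steps <- ceiling(log2(diff(control$bracket) / control$tol))
  for (i in seq_len(steps)) {
    mid <- (lo + hi) / 2
    below <- ref_load_at(mid) < load_actual
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  out <- (lo + hi) / 2
  ref_load <- ref_load_at(out)
  tibble::tibble(
    pet = out,
    converged = abs(ref_load - load_actual) <= 1,
    reference_load = ref_load
  )
}

#' Add thermal-comfort columns to a weather table
#'
#' Convenience wrapper for batch work: takes a data frame with columns
#' `ta`, `tmrt`, `v`, `rh` and appends `pa`, `pmv`, `tcl` and `pet`.
#'
#' @param df Data frame of hourly weather with the four input columns.
#' @param person A [person_state()] list.
#' @param control A [pet_control()] list.
#' @return The input with the four computed columns appended.
#' @export
augment_thermal_comfort <- function(df, person = person_state(),
                                    control = pet_control()) {
  needed <- c("ta", "tmrt", "v", "rh")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  env <- env_state(ta = df$ta, tmrt = df$tmrt, v = df$v, rh = df$rh)
  p <- pmv(env, person)
  df$pa <- env$pa
  df$pmv <- p$pmv
  df$tcl <- p$tcl
  df$pet <- pet(env, person, control)$pet
  df
}

#' Batch CSV thermal-comfort computation
#'
#' Reads a UTF-8 CSV with header columns `ta,tmrt,v,rh`, appends
#' `pa,pmv,tcl,pet` and writes the result.
#'
#' @param input,output Paths to the input and output CSV files.
#' @inheritParams augment_thermal_comfort
#' @return Invisibly, the augmented tibble.
#' @export
thermal_comfort_csv <- function(input, output, person = person_state(),
                                control = pet_control()) {
  df <- readr::read_csv(input, show_col_types = FALSE)
  out <- augment_thermal_comfort(df, person, control)
  readr::write_csv(out, output)
  invisible(out)
}
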