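# Monte Carlo estimation of the probability that an accident type's PET
# falls in the cold (< 18 degC), hot (>= 23 degC) and outside-comfort
# ranges. Each probability is the mean of indicator values over draws from
# the type's fitted PET distribution.

#' Fit a per-type PET distribution from linked events
#'
#' Sample mean and sample standard deviation (denominator n - 1) of the
#' event-level PET values for one accident type and severity.
#'
#' @param linked Linked events with `pet`, `accident_type`, `severity`.
#' @param type Accident type label (optional filter).
#' @param severity `"fatal"` or `"injury"` (optional filter).
#' @return A one-row tibble `accident_type`, `severity`, `mean`, `sd`,
#'   `n_events`.
#' @export
fit_pet_distribution <- function(linked, type = NULL, severity = NULL) {
  df <- linked
  if (!is.null(type)) df <- df[df$accident_type == type, ]
  if (!is.null(severity)) df <- df[df$severity == severity, ]
  x <- df$pet[!is.na(df$pet)]
  if (length(x) < 2) {
    stop("need at least 2 events with PET to fit a distribution",
         call. = FALSE)
  }
  tibble::tibble(
    accident_type = if (is.null(type)) NA_character_ else type,
    severity = if (is.null(severity)) NA_character_ else severity,
    mean = mean(x),
    sd = stats::sd(x),
    n_events = length(x)
  )
}

#' Fit PET distributions for every (type, severity) group
#'
#' @param linked Linked events with `pet`, `accident_type`, `severity`.
#' @param min_events Groups with fewer events are skipped.
#' @return A tibble with one row per retained group.
#' @export
fit_pet_distributions <- function(linked, min_events = 2) {
  df <- linked[!is.na(linked$pet), ]
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$accident_type, .data$severity),
    mean = mean(.data$pet), sd = stats::sd(.data$pet),
    n_events = dplyr::n(), .groups = "drop")
  out[out$n_events >= min_events, ]
}

#' Monte Carlo comfort-range probabilities
#'
#' Draws `n_draws` PET values from `Normal(mean, sd)` and reports the
#' fractions below 18 degC (cold), at or above 23 degC (hot) and their sum
#' (outside the comfort range), with binomial standard errors and
#' normal-approximation 95% confidence intervals. A zero standard
#' deviation is handled as a point mass.
#'
#' @param dist A tibble of PET distributions (columns `mean`, `sd`; extra
#'   columns such as `accident_type`/`severity` are carried through), or a
#'   single named list.
#' @param n_draws Number of Monte Carlo draws per row (>= 1000).
#' @param seed Integer seed (required for reproducibility).
#' @return A tibble with, per input row: `p_cold`, `p_hot`, `p_outside`,
#'   `p_neutral`, standard errors, 95% CI bounds, `n_draws`, `seed`.
#' @export
mcs_probabilities <- function(dist, n_draws = 1e6, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (n_draws < 1000) stop("`n_draws` must be >= 1000", call. = FALSE)
  dist <- tibble::as_tibble(dist[c(intersect(
    c("accident_type", "severity", "mean", "sd"), names(dist)))])
  if (any(!is.finite(dist$mean)) || any(!is.finite(dist$sd))) {
    stop("`mean` and `sd` must be finite", call. = FALSE)
  }
  if (any(dist$sd < 0)) stop("`sd` must be >= 0", call. = FALSE)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(nrow(dist)), function(i) {
      x <- stats::rnorm(n_draws, dist$mean[i], dist$sd[i])
      p_cold <- mean(x < 18)
      p_hot <- mean(x >= 23)
      p_out <- p_cold + p_hot
      se <- function(p) sqrt(p * (1 - p) / n_draws)
      tibble::tibble(
        p_cold = p_cold, p_hot = p_hot, p_outside = p_out,
        p_neutral = 1 - p_out,
        se_cold = se(p_cold), se_hot = se(p_hot), se_outside = se(p_out),
        ci_cold_lo = p_cold - 1.96 * se(p_cold),
        ci_cold_hi = p_cold + 1.96 * se(p_cold),
        ci_hot_lo = p_hot - 1.96 * se(p_hot),
        ci_hot_hi = p_hot + 1.96 * se(p_hot),
        ci_outside_lo = p_out - 1.96 * se(p_out),
        ci_outside_hi = p_out + 1.96 * se(p_out))
    })
  })
  out <- dplyr::bind_cols(dist, dplyr::bind_rows(rows))
  out$n_draws <- n_draws
  out$seed <- as.integer(seed)
  out
}
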