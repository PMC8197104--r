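# Shared in-code fixtures for the network and dataset tests.

ts0 <- as.POSIXct("2013-05-06 00:00", tz = "UTC")  # a Monday

toy_station_hours <- function(n_days = 2) {
  hours <- ts0 + 3600 * (0:(24 * n_days - 1))
  tibble::tibble(city = "Seoul", district = "Jung-gu", timestamp = hours,
                 ta = 15, tmrt = 20, v = 1, rh = 50)
}

# Feature table whose two outcomes depend (through a logistic link) on a
# single planted input variable, with small additive noise.
make_planted_table <- function(n = 400, seed = 1, signal = "ta") {
  withr::with_seed(seed, {
    tbl <- tibble::tibble(
      city = "S", district = "d",
      timestamp = ts0 + 3600 * seq_len(n),
      ta = runif(n, -10, 35), tmrt = runif(n, -10, 45),
      v = runif(n, 0, 8), rh = runif(n, 10, 95))
    z <- (tbl[[signal]] - mean(tbl[[signal]])) / sd(tbl[[signal]])
    tbl$fatal <- plogis(3 * z) + rnorm(n, 0, 0.02)
    tbl$injury <- plogis(3 * z) + rnorm(n, 0, 0.02)
    tbl
  })
}
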