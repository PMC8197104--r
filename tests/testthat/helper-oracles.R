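# Independent oracles, deliberately written as plain scalar transcriptions
# so they share no code with the package's vectorized solvers.

oracle_sat_vp <- function(ta) 611.2 * exp(17.62 * ta / (243.12 + ta))

# Clothing temperature by scalar bisection of the surface balance, with the
# convective coefficient recomputed at every candidate. Resolution 1e-5 degC.
oracle_tcl <- function(ta, tmrt, v, met, work, icl) {
  fcl <- if (icl <= 0.078) 1.00 + 1.290 * icl else 1.05 + 0.645 * icl
  tsk <- 35.7 - 0.028 * (met - work)
  g <- function(tcl) {
    hc <- max(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(v))
    tsk - icl * (3.96e-8 * fcl * ((tcl + 273)^4 - (tmrt + 273)^4) +
                   fcl * hc * (tcl - ta)) - tcl
  }
  lo <- min(ta, tmrt) - 30
  hi <- tsk + 30
  while (hi - lo > 1e-5) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Straight-line transcription of the seven-term PMV load, evaluated at the
# oracle clothing temperature.
oracle_pmv <- function(ta, tmrt, v, rh, met, work, icl) {
  pa <- rh / 100 * oracle_sat_vp(ta)
  tcl <- oracle_tcl(ta, tmrt, v, met, work, icl)
  fcl <- if (icl <= 0.078) 1.00 + 1.290 * icl else 1.05 + 0.645 * icl
  hc <- max(2.38 * abs(tcl - ta)^0.25, 12.1 * sqrt(v))
  mw <- met - work
  load <- mw -
    3.05e-3 * (5733 - 6.99 * mw - pa) -
    max(0.42 * (mw - 58.15), 0) -
    1.7e-5 * met * (5867 - pa) -
    0.0014 * met * (34 - ta) -
    3.96e-8 * fcl * ((tcl + 273)^4 - (tmrt + 273)^4) -
    fcl * hc * (tcl - ta)
  (0.303 * exp(-0.036 * met) + 0.028) * load
}

# Exhaustive path enumeration of the connection-weight decomposition:
# triple loop over (input, hidden, output) paths.
oracle_garson <- function(w_input, w_output) {
  n_in <- nrow(w_input); n_h <- ncol(w_input); n_out <- ncol(w_output)
  q <- numeric(n_in)
  for (i in seq_len(n_in)) {
    for (h in seq_len(n_h)) {
      denom <- 0
      for (k in seq_len(n_in)) denom <- denom + abs(w_input[k, h])
      if (denom == 0) next
      for (o in seq_len(n_out)) {
        q[i] <- q[i] + abs(w_input[i, h]) / denom * abs(w_output[h, o])
      }
    }
  }
  q / sum(q)
}

# Exhaustive nested-loop join of accidents to climate on (city, district,
# hour), ignoring row order.
oracle_join <- function(accidents, climate) {
  hr <- function(t) as.POSIXct(trunc(as.POSIXlt(t, tz = "UTC"), "hours"))
  ah <- hr(accidents$timestamp)
  ch <- hr(climate$timestamp)
  out <- vector("list", nrow(accidents))
  for (i in seq_len(nrow(accidents))) {
    hit <- 0L
    for (j in seq_len(nrow(climate))) {
      if (accidents$city[i] == climate$city[j] &&
          accidents$district[i] == climate$district[j] &&
          ah[i] == ch[j]) { hit <- j; break }
    }
    out[[i]] <- if (hit > 0) {
      data.frame(i = i, ta = climate$ta[hit], tmrt = climate$tmrt[hit],
                 v = climate$v[hit], rh = climate$rh[hit])
    } else {
      data.frame(i = i, ta = NA_real_, tmrt = NA_real_, v = NA_real_,
                 rh = NA_real_)
    }
  }
  do.call(rbind, out)
}

# Small registry configuration shared by generator-dependent tests.
small_registry <- function(seed = 101L, years = 1, k_out = 1) {
  registry_config(
    years = years, start_year = 2010,
    layout = list(Seoul = c("Gangbuk-gu", "Jung-gu"), Incheon = "Nam-gu"),
    seed = seed, comfort_multiplier = k_out)
}
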