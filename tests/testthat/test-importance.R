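test_that("build_dataset emits one row per working station-hour with hand-tallied targets", {
  cl <- toy_station_hours(2)
  linked <- tibble::tibble(
    city = "Seoul", district = "Jung-gu",
    timestamp = c(ts0 + 3600 * 9 + 120,   # 09:02, fatal
                  ts0 + 3600 * 9 + 1800,  # 09:30, injury (same hour)
                  ts0 + 3600 * 30),       # Tuesday 06:00, outside working hours
    accident_type = "fall",
    severity = c("fatal", "injury", "injury"))
  out <- build_dataset(linked, cl)
  expect_equal(nrow(out), 2 * 11)  # two working days x 11 working hours
  hit <- out$timestamp == ts0 + 3600 * 9
  expect_equal(out$fatal[hit], 1L)
  expect_equal(out$injury[hit], 1L)
  expect_equal(sum(out$fatal), 1L)
  expect_equal(sum(out$injury), 1L)  # the 06:00 event has no feature row

  binary <- build_dataset(linked, cl, encoding = "binary")
  expect_true(all(binary$fatal %in% 0:1))

  # zero accidents: all-zero targets, feature rows still emitted
  empty <- build_dataset(linked[0, ], cl)
  expect_equal(nrow(empty), 22)
  expect_true(all(empty$fatal == 0 & empty$injury == 0))
  expect_error(build_dataset(linked, cl[0, ]), "no working station-hours")
})

test_that("a planted single-variable signal is recovered with high R^2", {
  tbl <- make_planted_table(seed = 42)
  model <- train_network(tbl, network_spec(seed = 5L))
  expect_gte(model$r2, 0.9)
  imp <- garson_importance(model)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_equal(imp$variable[which.max(imp$importance)], "ta")
})

test_that("training is deterministic given the seed and warns when unconverged", {
  tbl <- make_planted_table(seed = 2)
  m1 <- train_network(tbl, network_spec(seed = 9L))
  m2 <- train_network(tbl, network_spec(seed = 9L))
  expect_identical(m1$fit$wts, m2$fit$wts)
  expect_identical(m1$r2, m2$r2)
  expect_warning(train_network(tbl, network_spec(seed = 9L, maxit = 2)),
                 "maxit")
})

test_that("identically zero targets give the R^2 = 0 convention", {
  tbl <- make_planted_table(seed = 3)
  tbl$fatal <- 0
  tbl$injury <- 0
  model <- train_network(tbl, network_spec(seed = 1L))
  expect_equal(model$r2, 0)
})

test_that("fewer than 100 rows is an error", {
  tbl <- make_planted_table(n = 50)
  expect_error(train_network(tbl), "100")
})

test_that("connection-weight importance matches hand-checkable cases", {
  # all inputs with equal absolute weight: symmetric importance
  w_in <- matrix(c(1, -1, 1, -1), nrow = 4, ncol = 9)
  rownames(w_in) <- c("ta", "tmrt", "v", "rh")
  w_out <- matrix(rnorm(18), nrow = 9, ncol = 2)
  imp <- garson_importance(list(w_input = w_in, w_output = w_out))
  expect_equal(imp$importance, rep(0.25, 4))

  # single live input takes all the importance
  w_in2 <- matrix(0, 4, 9, dimnames = list(c("ta", "tmrt", "v", "rh"), NULL))
  w_in2["ta", ] <- rnorm(9)
  imp2 <- garson_importance(list(w_input = w_in2, w_output = w_out))
  expect_equal(imp2$importance[imp2$variable == "ta"], 1)

  expect_error(
    garson_importance(list(w_input = w_in2 * 0, w_output = w_out)),
    "zero")
})

test_that("importance equals the exhaustive path-enumeration oracle", {
  set.seed(77)
  for (i in 1:10) {
    w_in <- matrix(rnorm(36), 4, 9,
                   dimnames = list(c("ta", "tmrt", "v", "rh"), NULL))
    w_out <- matrix(rnorm(18), 9, 2)
    got <- garson_importance(list(w_input = w_in, w_output = w_out))
    expect_equal(got$importance, oracle_garson(w_in, w_out),
                 tolerance = 1e-12)
    # invariance to permuting hidden units
    perm <- sample(9)
    got_p <- garson_importance(list(w_input = w_in[, perm],
                                    w_output = w_out[perm, ]))
    expect_equal(got_p$importance, got$importance)
  }
})

test_that("signed importance spread shrinks when the outcome is independent of all inputs", {
  # measured on the signed (magnitude-preserving) variant: as n grows the
  # fitted function flattens and all connection weights shrink, so the
  # signed importances contract toward zero together. The normalized
  # shares cannot show this -- they are a ratio of vanishing weights and
  # stay ill-conditioned under input-independence.
  mean_spread <- function(n) {
    mean(vapply(1:3, function(s) {
      tbl <- withr::with_seed(1000 * s, {
        t <- make_planted_table(n = n, seed = 1000 * s)
        t$fatal <- 0.5 + rnorm(n, 0, 0.01)
        t$injury <- 0.5 + rnorm(n, 0, 0.01)
        t
      })
      model <- suppressWarnings(train_network(tbl, network_spec(seed = s)))
      diff(range(garson_importance(model, method = "olden")$importance))
    }, numeric(1)))
  }
  expect_lt(mean_spread(3200), mean_spread(200))
})
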