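ts <- function(s) as.POSIXct(s, tz = "UTC")

toy_climate <- function() {
  tibble::tibble(
    city = c("Seoul", "Seoul", "Seoul", "Incheon"),
    district = c("Gangbuk-gu", "Jung-gu", "Gangbuk-gu", "Nam-gu"),
    timestamp = ts(c("2009-01-02 09:00", "2009-01-02 09:00",
                     "2009-01-02 10:00", "2009-01-02 09:00")),
    ta = c(-6.2, -6.2, -5.0, -4.5),
    tmrt = c(5.3, 5.3, 6.0, 12.4),
    v = c(1.9, 1.9, 2.0, 7.6),
    rh = c(64, 64, 60, 57))
}

test_that("same city and hour share weather; hours and cities differ", {
  acc <- tibble::tibble(
    city = c("Seoul", "Seoul", "Seoul", "Incheon"),
    district = c("Gangbuk-gu", "Jung-gu", "Gangbuk-gu", "Nam-gu"),
    timestamp = ts(c("2009-01-02 09:12", "2009-01-02 09:40",
                     "2009-01-02 10:05", "2009-01-02 09:59")),
    accident_type = c("fall", "traffic accident", "fall", "fall beneath"),
    severity = "fatal")
  out <- link_accidents(acc, toy_climate())
  expect_equal(nrow(out), 4)
  expect_true(all(out$match_quality == "exact"))
  # rows 1-2: same city, different districts, same hour -> same weather
  expect_equal(out$ta[1], out$ta[2])
  expect_equal(out$pet[1], out$pet[2])
  # same district, different hour -> different weather
  expect_false(out$ta[1] == out$ta[3])
  # different city, same hour -> independent weather
  expect_false(out$ta[1] == out$ta[4])
  expect_equal(out$ta[1], -6.2)
})

test_that("an empty climate feed leaves everything unmatched", {
  acc <- tibble::tibble(city = "Seoul", district = "Gangbuk-gu",
                        timestamp = ts("2009-01-02 09:00"),
                        accident_type = "fall", severity = "fatal")
  expect_message(
    out <- link_accidents(acc, toy_climate()[0, ], policy = "strict"),
    "1 unmatched")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_unmatched"), 1)
})

test_that("linked plus unmatched counts conserve the input", {
  cl <- toy_climate()
  acc <- tibble::tibble(
    city = c("Seoul", "Busan"), district = c("Gangbuk-gu", "Haeundae-gu"),
    timestamp = ts(c("2009-01-02 09:00", "2009-01-02 09:00")),
    accident_type = "fall", severity = "injury")
  out <- link_accidents(acc, cl, policy = "nearest-hour")
  expect_equal(nrow(out), nrow(acc))
  expect_equal(sum(out$match_quality != "unmatched") +
                 attr(out, "n_unmatched"), nrow(acc))
  suppressMessages(strict <- link_accidents(acc, cl, policy = "strict"))
  expect_equal(nrow(strict) + attr(strict, "n_unmatched"), nrow(acc))
})

test_that("nearest-hour fallback uses +/- 1 hour, preferring the earlier hour", {
  cl <- toy_climate()
  acc <- tibble::tibble(
    city = "Seoul", district = "Gangbuk-gu",
    # 11:xx has no climate row; 10:00 exists (earlier), 12:00 does not
    timestamp = ts("2009-01-02 11:30"),
    accident_type = "fall", severity = "fatal")
  out <- link_accidents(acc, cl, policy = "nearest-hour")
  expect_equal(out$match_quality, "nearest-hour")
  expect_equal(out$ta, -5.0)
  # two hours away is out of the fallback window
  acc2 <- dplyr::mutate(acc, timestamp = ts("2009-01-02 12:30"))
  out2 <- link_accidents(acc2, cl, policy = "nearest-hour")
  expect_equal(out2$match_quality, "unmatched")
  expect_true(is.na(out2$pet))
})

test_that("duplicate climate keys are an integrity error", {
  cl <- dplyr::bind_rows(toy_climate(), toy_climate()[1, ])
  acc <- tibble::tibble(city = "Seoul", district = "Gangbuk-gu",
                        timestamp = ts("2009-01-02 09:00"),
                        accident_type = "fall", severity = "fatal")
  expect_error(link_accidents(acc, cl), "duplicated")
})

test_that("linkage equals the exhaustive nested-loop join on a random fixture", {
  set.seed(88)
  cities <- c("A", "B", "C")
  districts <- c("d1", "d2")
  hours <- ts("2010-06-01 00:00") + 3600 * (0:199)
  cl <- expand.grid(city = cities, district = districts,
                    timestamp = hours, stringsAsFactors = FALSE)
  # city-hour weather copied across districts
  key <- interaction(cl$city, format(cl$timestamp))
  ta_city_hour <- runif(length(levels(key)), -10, 35)
  cl$ta <- ta_city_hour[as.integer(key)]
  cl$tmrt <- cl$ta + 5; cl$v <- 1; cl$rh <- 50
  cl <- tibble::as_tibble(cl)

  acc <- tibble::tibble(
    city = sample(c(cities, "Z"), 1000, replace = TRUE),
    district = sample(districts, 1000, replace = TRUE),
    timestamp = sample(hours, 1000, replace = TRUE) +
      round(runif(1000, 0, 3599)),
    accident_type = sample(accident_types(), 1000, replace = TRUE),
    severity = sample(c("fatal", "injury"), 1000, replace = TRUE))

  got <- link_accidents(acc, cl, policy = "nearest-hour",
                        compute_pet = FALSE)
  want <- oracle_join(acc, cl)
  # oracle has no fallback; exact matches must agree, and the fallback can
  # only fire where the oracle found nothing
  exact <- got$match_quality == "exact"
  expect_equal(got$ta[exact], want$ta[exact])
  expect_true(all(is.na(want$ta[!exact])))
  # permutation invariance: shuffling the input never changes a linked row
  perm <- sample(nrow(acc))
  got2 <- link_accidents(acc[perm, ], cl, policy = "nearest-hour",
                         compute_pet = FALSE)
  expect_equal(got2$ta, got$ta[perm])
  expect_equal(got2$match_quality, got$match_quality[perm])
})
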