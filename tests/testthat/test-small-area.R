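# Census post-stratification, suppression, aggregation, map truncation.

make_props <- function(n_by, wood_by) {
  # n_by / wood_by: named lists lsoa|type -> counts
  rows <- lapply(names(n_by), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    n <- n_by[[k]]; w <- wood_by[[k]]
    data.frame(lsoa = parts[1], property_type = parts[2],
               wood_fuel = c(rep(TRUE, w), rep(FALSE, n - w)))
  })
  do.call(rbind, rows)
}

test_that("stratum rates and the 20-certificate suppression boundary", {
  props <- make_props(list(`A|detached` = 20, `A|terrace` = 19),
                      list(`A|detached` = 5, `A|terrace` = 19))
  got <- stratum_rates(props)
  det <- got[got$property_type == "detached", ]
  ter <- got[got$property_type == "terrace", ]
  expect_equal(det$p_hat, 0.25)
  expect_false(det$suppressed)   # exactly at the threshold is kept
  expect_true(ter$suppressed)    # one below is suppressed
  expect_equal(ter$p_hat, 1)
})

test_that("suppression count is monotone in the threshold", {
  set.seed(5)
  props <- data.frame(
    lsoa = sample(sprintf("L%02d", 1:8), 600, TRUE),
    property_type = sample(c("detached", "terrace", "flat"), 600, TRUE),
    wood_fuel = runif(600) < 0.1)
  n_sup <- vapply(c(5, 10, 20, 40, 80),
                  function(m) sum(stratum_rates(props, min_epc = m)$suppressed),
                  numeric(1))
  expect_true(all(diff(n_sup) >= 0))
})

test_that("corrected count is rate times Census stock", {
  props <- make_props(list(`A|detached` = 40), list(`A|detached` = 10))
  rates <- stratum_rates(props)
  stock <- data.frame(lsoa = "A", property_type = "detached", n_census = 200)
  got <- corrected_counts(rates, stock)
  expect_equal(got$est_count, 0.25 * 200)
})

test_that("correction identity: stock equal to EPC counts reproduces counts", {
  props <- make_props(list(`A|detached` = 50, `A|terrace` = 30,
                           `B|detached` = 25),
                      list(`A|detached` = 7, `A|terrace` = 3,
                           `B|detached` = 0))
  rates <- stratum_rates(props)
  stock <- rates[c("lsoa", "property_type")]
  stock$n_census <- rates$n_epc
  got <- corrected_counts(rates, stock)
  expect_equal(got$est_count, rates$n_fuel[match(
    paste(got$lsoa, got$property_type),
    paste(rates$lsoa, rates$property_type))])
})

test_that("missing stock warns and suppresses; borrow pools the LAD rate", {
  props <- make_props(list(`A|detached` = 100, `B|detached` = 10),
                      list(`A|detached` = 20, `B|detached` = 1))
  rates <- stratum_rates(props)
  stock <- data.frame(lsoa = c("A", "B"), property_type = "detached",
                      n_census = c(150, 60))
  # missing stock for an unsuppressed stratum warns
  expect_warning(corrected_counts(rates, stock[2, ]), "missing from Census")
  # excluded by default: suppressed B gets NA
  got <- corrected_counts(rates, stock)
  expect_true(is.na(got$est_count[got$lsoa == "B"]))
  # borrowing fills B from the pooled LAD rate 21/110
  hier <- data.frame(lsoa = c("A", "B"), lad = "D1")
  got_b <- corrected_counts(rates, stock, "borrow", hier)
  expect_equal(got_b$est_count[got_b$lsoa == "B"], 21 / 110 * 60)
})

test_that("prevalence uses houses only; concentration uses all types", {
  ec <- data.frame(
    lsoa = "A",
    property_type = c("detached", "terrace", "flat"),
    n_census = c(100, 100, 300),
    n_epc = c(50, 50, 50), n_fuel = c(10, 5, 3),
    p_hat = c(0.2, 0.1, 0.06), suppressed = FALSE,
    est_count = c(20, 10, 18))
  expect_equal(area_prevalence(ec), 100 * 30 / 200)  # flats excluded
  expect_equal(area_concentration(ec, 2), 48 / 2)    # flats included
  expect_error(area_concentration(ec, 0), "positive")
  # all house strata suppressed -> NA with a reason
  ec$suppressed <- c(TRUE, TRUE, FALSE)
  p <- area_prevalence(ec)
  expect_true(is.na(p))
  expect_match(attr(p, "reason"), "suppressed")
})

test_that("area_estimates and hierarchy aggregation conserve counts", {
  props <- make_props(
    list(`A|detached` = 40, `A|flat` = 30, `B|detached` = 25,
         `B|terrace` = 30, `C|detached` = 50),
    list(`A|detached` = 8, `A|flat` = 1, `B|detached` = 5,
         `B|terrace` = 3, `C|detached` = 10))
  rates <- stratum_rates(props)
  stock <- rates[c("lsoa", "property_type")]
  stock$n_census <- c(80, 60, 50, 60, 100)
  cc <- corrected_counts(rates, stock)
  areas <- data.frame(lsoa = c("A", "B", "C"), area_km2 = c(1, 2, 4))
  est <- area_estimates(cc, areas)
  expect_equal(est$geography, c("A", "B", "C"))
  expect_equal(est$est_count[1], 0.2 * 80 + (1 / 30) * 60)
  expect_equal(est$prevalence_pct[2], 100 * (0.2 * 50 + 0.1 * 60) / 110)
  expect_equal(est$prevalence_uncorrected_pct[3], 100 * 10 / 50)
  expect_equal(est$concentration_per_km2, est$est_count / c(1, 2, 4))

  hier <- data.frame(lsoa = c("A", "B", "C"), ward = c("W1", "W1", "W2"),
                     lad = "D1", region = "R1")
  for (lv in c("ward", "lad", "region")) {
    agg <- aggregate_estimates(est, hier, lv)
    expect_equal(sum(agg$est_count), sum(est$est_count))
    expect_equal(sum(agg$house_est), sum(est$house_est))
    expect_equal(sum(agg$area_km2), sum(est$area_km2))
  }
  wd <- aggregate_estimates(est, hier, "ward")
  expect_equal(wd$prevalence_pct[wd$geography == "W1"],
               100 * sum(est$house_est[1:2]) / sum(est$house_census[1:2]))
  # an LSOA missing from the hierarchy is an error
  expect_error(aggregate_estimates(est, hier[-2, ], "ward"), "missing")
})

test_that("map truncation clips to the 5th and 95th percentiles", {
  x <- c(0:100, NA)
  got <- truncate_for_mapping(x)
  q <- quantile(0:100, c(0.05, 0.95), names = FALSE, type = 7)
  expect_equal(min(got, na.rm = TRUE), q[1])
  expect_equal(max(got, na.rm = TRUE), q[2])
  expect_true(is.na(got[102]))
  # interior values are untouched
  expect_equal(got[51], 50)
  expect_error(truncate_for_mapping(c(1, NA)), "two finite")
})
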