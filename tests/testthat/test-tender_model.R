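test_that("constructors enforce domain invariants", {
  expect_error(endpoint_spec("x", disutility = 1.2, duration_months = 1,
                             cost_per_event = 0),
               "disutility")
  expect_error(endpoint_spec("x", disutility = 0.5, duration_months = 0,
                             cost_per_event = 0),
               "duration_months")
  expect_error(endpoint_spec("x", disutility = 0.5, duration_months = 1,
                             cost_per_event = -1),
               "cost_per_event")
  expect_error(make_lot(baseline_utility = 0), "baseline_utility")
  expect_error(make_lot(baseline_utility = 1.1), "baseline_utility")
  expect_error(make_lot(wtp_per_qaly = -5), "wtp_per_qaly")
  # a disutility outlasting the horizon cannot enter the lot
  expect_error(
    make_lot(horizon_months = 6, endpoints = list(
      endpoint_spec("a", disutility = 0.2, duration_months = 12,
                    cost_per_event = 10))),
    "duration_months exceeds")
  expect_error(
    device_offer("d", price = 100,
                 event_rates = c(a = 0.1, a = 0.2)),
    "unique")
})

test_that("duplicate endpoint ids are rejected at construction, never merged", {
  eps <- list(
    endpoint_spec("stroke", disutility = 0.2, duration_months = 3,
                  cost_per_event = 10),
    endpoint_spec("stroke", disutility = 0.4, duration_months = 6,
                  cost_per_event = 20))
  expect_error(make_lot(endpoints = eps), "duplicate endpoint_id.*stroke")
})

test_that("endpoint count is bounded at 1-10", {
  eps <- lapply(1:11, function(i)
    endpoint_spec(paste0("e", i), disutility = 0.1, duration_months = 1,
                  cost_per_event = 1))
  expect_error(make_lot(endpoints = eps), "between 1 and 10")
  expect_s3_class(make_lot(endpoints = eps[1:10]), "lot_parameters")
  expect_s3_class(make_lot(endpoints = eps[1]), "lot_parameters")
})

test_that("percent rates are converted to fractions at construction", {
  o <- device_offer("d", price = 100,
                    event_rates = c(minor_stroke = 2.35,
                                    major_stroke = 0.16, death = 0.07),
                    rate_unit = "percent")
  expect_equal(unname(o$event_rates),
               c(0.0235, 0.0016, 0.0007))
  o2 <- device_offer("d", price = 100,
                     event_rates = c(a = 0.5), rate_unit = "fraction")
  expect_equal(unname(o2$event_rates), 0.5)
})

test_that("offers above the starting price are excluded, at-cap admitted", {
  lot <- make_lot(starting_price = 600)
  expect_true(validate_offer(make_offer(lot, price = 530), lot)$admitted)
  expect_true(validate_offer(make_offer(lot, price = 600), lot)$admitted)
  v <- validate_offer(make_offer(lot, price = 600.01), lot)
  expect_false(v$admitted)
  expect_match(v$reason, "starting price")
})

test_that("out-of-range rates are excluded with the endpoint named", {
  lot <- make_lot()
  o <- make_offer(lot, rates = c(0.01, 1.02, 0))
  v <- validate_offer(o, lot)
  expect_false(v$admitted)
  expect_match(v$reason, "major_stroke")
  expect_no_match(v$reason, "minor_stroke")
})

test_that("endpoint mismatch is a structural defect, distinct from price", {
  lot <- make_lot()
  o <- device_offer("d", price = 100,
                    event_rates = c(minor_stroke = 0.1, major_stroke = 0.1,
                                    sepsis = 0.1))
  v <- validate_offer(o, lot)
  expect_false(v$admitted)
  expect_match(v$reason, "^structural: endpoint mismatch")
  expect_match(v$reason, "sepsis")
  expect_match(v$reason, "death")
  expect_no_match(v$reason, "price")
})

test_that("validation is deterministic and independent of other offers", {
  lot <- make_lot()
  offers <- lapply(c(300, 700, 500), function(p)
    make_offer(lot, device_id = paste0("p", p), price = p))
  one_by_one <- lapply(offers, validate_offer, lot = lot)
  reversed <- lapply(rev(offers), validate_offer, lot = lot)
  expect_identical(one_by_one, rev(reversed))
  expect_identical(validate_offer(offers[[2]], lot),
                   validate_offer(offers[[2]], lot))
})
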