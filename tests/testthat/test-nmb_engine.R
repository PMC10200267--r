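test_that("disutility time-normalization follows d * t / H", {
  expect_identical(adjust_disutility(0.30, 1, 12), 0.30 * 1 / 12)
  expect_equal(adjust_disutility(0.30, 1, 12), 0.025)
  # duration equal to the horizon is the identity
  expect_equal(adjust_disutility(0.7, 12, 12), 0.7)
  # a deeper short loss equals a shallower long one
  expect_identical(adjust_disutility(0.50, 1, 12),
                   adjust_disutility(0.25, 2, 12))
  expect_equal(adjust_disutility(0.50, 1, 12), 0.5 / 12)
  expect_error(adjust_disutility(0.3, 13, 12), "exceeds the horizon")
  expect_error(adjust_disutility(1.3, 1, 12), "real_disutility")
})

test_that("baseline QALDs are utility times horizon days", {
  expect_equal(baseline_qalds(make_lot(baseline_utility = 0.93)), 339.45)
  expect_equal(baseline_qalds(make_lot(baseline_utility = 1)), 365)
  lot50 <- make_lot(baseline_utility = 0.5, horizon_months = 100 / 365 * 12,
                    endpoints = list(
                      endpoint_spec("a", disutility = 0.1,
                                    duration_months = 1,
                                    cost_per_event = 1)))
  expect_equal(lot50$horizon_days, 100)
  expect_equal(baseline_qalds(lot50), 50)
})

test_that("disutility QALDs sum rate-weighted adjusted disutilities", {
  lot <- make_lot()
  expect_equal(disutility_qalds(lot, make_offer(lot, rates = 0)), 0)
  # single endpoint, certain event, full disutility for the whole horizon
  lot1 <- make_lot(baseline_utility = 1, endpoints = list(
    endpoint_spec("death", disutility = 1, duration_months = 12,
                  cost_per_event = 0)))
  expect_equal(disutility_qalds(lot1, make_offer(lot1, rates = 1)), 365)
  # hand-computed three-endpoint case
  o <- make_offer(lot, rates = c(0.1, 0.02, 0.01))
  expected <- (0.1 * 0.15 * 3 / 12 + 0.02 * 0.55 + 0.01 * 0.93) * 365
  expect_equal(disutility_qalds(lot, o), expected)
})

test_that("net QALDs subtract exactly and clamp negatives with a warning", {
  expect_identical(net_qalds(339.45, 26.2625), 339.45 - 26.2625)
  expect_equal(net_qalds(339.45, 26.2625), 313.1875)
  expect_identical(net_qalds(123.4, 0), 123.4)
  expect_warning(out <- net_qalds(100, 150), "clamped")
  expect_identical(out, 0)
})

test_that("QALD/QALY conversion divides by days per year", {
  expect_equal(qalds_to_qalys(313.1875, 365), 313.1875 / 365)
  expect_equal(round(qalds_to_qalys(313.1875, 365), 4), 0.858)
  expect_identical(qalds_to_qalys(365, 365), 1)
  expect_identical(qalds_to_qalys(0, 365), 0)
  expect_error(qalds_to_qalys(313, 0), "days_per_year")
  expect_error(qalds_to_qalys(-1, 365), "qalds")
})

test_that("monetization applies the WTP threshold linearly", {
  lot <- make_lot(wtp_per_qaly = 60000)
  expect_equal(monetize_benefit(313.1875, lot), 313.1875 / 365 * 60000)
  expect_equal(round(monetize_benefit(313.1875, lot), 2), 51482.88)
  expect_identical(monetize_benefit(0, lot), 0)
  lot2 <- make_lot(wtp_per_qaly = 120000)
  expect_equal(monetize_benefit(313.1875, lot2),
               2 * monetize_benefit(313.1875, lot))
})

test_that("total cost sums expected event costs plus the price when included", {
  lot <- make_lot()
  o <- make_offer(lot, price = 530, rates = 0)
  expect_equal(total_cost(lot, o), 530)
  expect_equal(total_cost(lot, o, include_price = FALSE), 0)
  o2 <- make_offer(lot, price = 530, rates = c(0.1, 0.02, 0.01))
  expect_equal(total_cost(lot, o2, include_price = FALSE),
               0.1 * 6000 + 0.02 * 70000 + 0.01 * 150000)
})

test_that("compute_nmb produces a complete, conserving eight-step trace", {
  lot <- make_lot()
  o <- make_offer(lot, price = 530, rates = c(0.1, 0.02, 0.01))
  res <- compute_nmb(lot, o)
  expect_s3_class(res, "device_result")
  expect_equal(nrow(res$step_trace), 8)
  # conservation at full precision
  expect_identical(res$qalds_net, res$qalds_baseline - res$qalds_disutility)
  expect_identical(res$nmb, res$benefit_money - res$cost_total)
  expect_identical(res$step_trace$value[4],
                   res$step_trace$value[2] - res$step_trace$value[3])
  expect_identical(res$step_trace$value[7],
                   res$step_trace$value[5] - res$step_trace$value[6])
  expect_identical(res$step_trace$value[8], res$nmb)
  expect_equal(res$qalys, res$qalds_net / 365)
})

test_that("compute_nmb honours given step inputs for trace replay", {
  lot <- make_lot()
  o <- make_offer(lot, price = 530, rates = c(0.0235, 0.0016, 0.0007))
  res <- compute_nmb(lot, o,
                     given = list(disutility_qalds = 26.2625,
                                  cost_total = 891.5365))
  expect_equal(res$qalds_net, 313.1875)
  expect_equal(res$benefit_money, 313.1875 / 365 * 60000)
  expect_equal(res$cost_total, 891.5365)
  expect_equal(res$nmb, 313.1875 / 365 * 60000 - 891.5365)
  expect_error(compute_nmb(lot, o, given = list(qalys = 1)),
               "unknown given")
})

test_that("compute_nmb refuses inadmissible offers", {
  lot <- make_lot(starting_price = 600)
  expect_error(compute_nmb(lot, make_offer(lot, price = 700)),
               "not admissible")
})

test_that("zero-event price-excluded NMB matches the closed form exactly", {
  lot <- make_lot(baseline_utility = 0.81, wtp_per_qaly = 47000)
  res <- compute_nmb(lot, make_offer(lot, price = 250, rates = 0),
                     include_price = FALSE)
  expect_equal(res$nmb, 0.81 * 365 / 365 * 47000, tolerance = 1e-12)
})

test_that("NMB strictly decreases when any single event rate increases", {
  lot <- make_lot()
  base_rates <- c(0.02, 0.01, 0.005)
  nmb0 <- compute_nmb(lot, make_offer(lot, rates = base_rates))$nmb
  for (i in seq_along(base_rates)) {
    bumped <- base_rates
    bumped[i] <- bumped[i] + 0.01
    expect_lt(compute_nmb(lot, make_offer(lot, rates = bumped))$nmb, nmb0)
  }
})
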