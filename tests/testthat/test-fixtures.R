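test_that("the carotid-stent fixture matches its published inputs", {
  fx <- carotid_stent_fixture()
  expect_length(fx$offers, 3)
  expect_length(fx$lot$endpoints, 3)
  expect_equal(fx$lot$wtp_per_qaly, 60000)
  expect_equal(fx$lot$horizon_months, 12)
  expect_equal(fx$lot$baseline_utility, 0.93)
  expect_equal(fx$offers[["ABBOTT"]]$price, 530)
  expect_equal(unname(fx$offers[["ABBOTT"]]$event_rates),
               c(0.0235, 0.0016, 0.0007))
  expect_equal(unname(fx$offers[["CARDINAL_HEALTH"]]$event_rates),
               c(0.0169, 0.0104, 0.0093))
  expect_equal(unname(fx$offers[["MEDTRONIC"]]$event_rates),
               c(0.0089, 0.0312, 0.0178))
  # every offer passes lot validation
  for (o in fx$offers) expect_true(validate_offer(o, fx$lot)$admitted)
  # the calibrated costs reproduce the published Abbott step-6 total
  expect_equal(total_cost(fx$lot, fx$offers[["ABBOTT"]]), 891.5365,
               tolerance = 1e-9)
  expect_true(file.exists(fx$notes_path))
})

test_that("the published Abbott disutility total is a given, not derivable", {
  fx <- carotid_stent_fixture()
  # with every disutility at its ceiling the rates cannot reach 26.2625
  max_possible <- sum(fx$offers[["ABBOTT"]]$event_rates) * 365
  expect_lt(max_possible, 26.2625)
  expect_equal(fx$given[["ABBOTT"]]$disutility_qalds, 26.2625)
  expect_equal(fx$given[["ABBOTT"]]$cost_total, 891.5365)
})

test_that("the same seed reproduces the same tender; seeds differ", {
  spec <- synthetic_tender_spec(n_devices = 4, seed = 99)
  expect_identical(generate_tender(spec), generate_tender(spec))
  expect_false(identical(
    generate_tender(spec),
    generate_tender(synthetic_tender_spec(n_devices = 4, seed = 100))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_tender(synthetic_tender_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("a single-device spec yields a valid one-offer tender", {
  tender <- generate_tender(synthetic_tender_spec(
    n_devices = 1, price_exceed_frac = 0, seed = 3))
  expect_length(tender$offers, 1)
  expect_true(validate_offer(tender$offers[[1]], tender$lot)$admitted)
})

test_that("generated tenders satisfy every domain invariant", {
  n_offers <- 0L
  n_overpriced <- 0L
  for (seed in 1:200) {
    tender <- generate_tender(synthetic_tender_spec(
      n_devices = 5, n_endpoints = 1 + seed %% 10,
      price_exceed_frac = 0.05, seed = seed))
    # constructors re-validate on the way in; re-assert the key bounds
    expect_true(tender$lot$baseline_utility > 0 &&
                  tender$lot$baseline_utility <= 1)
    for (ep in tender$lot$endpoints) {
      expect_true(ep$disutility >= 0 && ep$disutility <= 1)
      expect_true(ep$duration_months > 0 &&
                    ep$duration_months <= tender$lot$horizon_months)
      expect_gte(ep$cost_per_event, 0)
    }
    for (offer in tender$offers) {
      n_offers <- n_offers + 1L
      expect_true(all(offer$event_rates >= 0 & offer$event_rates <= 1))
      v <- validate_offer(offer, tender$lot)
      if (!v$admitted) {
        expect_match(v$reason, "starting price")
        n_overpriced <- n_overpriced + 1L
      } else {
        # generated rates keep net QALDs strictly positive: no clamping
        expect_gt(compute_nmb(tender$lot, offer)$qalds_net, 0)
      }
    }
  }
  expect_gte(n_offers, 1000L)
  # the exclusion path is exercised at roughly the configured 5% frequency
  expect_gt(n_overpriced, 0L)
  expect_lt(n_overpriced / n_offers, 0.15)
})

test_that("infeasible generator ranges fail before generation", {
  expect_error(synthetic_tender_spec(disutility_range = c(0.5, 1.2)),
               "disutility_range")
  expect_error(synthetic_tender_spec(duration_range = c(1, 24),
                                     horizon_months = 12),
               "duration_range")
  expect_error(synthetic_tender_spec(rate_range = c(-0.1, 0.5)),
               "rate_range")
  expect_error(synthetic_tender_spec(n_endpoints = 11), "n_endpoints")
})
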