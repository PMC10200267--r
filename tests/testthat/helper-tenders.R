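# Shared builders and the independent brute-force oracle.

# Minimal single/multi-endpoint lot for unit tests.
make_lot <- function(horizon_months = 12, baseline_utility = 0.93,
                     wtp_per_qaly = 60000, starting_price = 600,
                     endpoints = NULL, days_per_year = 365) {
  if (is.null(endpoints)) {
    endpoints <- list(
      endpoint_spec("minor_stroke", "minor stroke", disutility = 0.15,
                    duration_months = 3, cost_per_event = 6000),
      endpoint_spec("major_stroke", "major stroke", disutility = 0.55,
                    duration_months = horizon_months,
                    cost_per_event = 70000),
      endpoint_spec("death", disutility = max(0, min(1, baseline_utility)),
                    duration_months = horizon_months,
                    cost_per_event = 150000))
  }
  lot_parameters(lot_id = "test-lot", horizon_months = horizon_months,
                 baseline_utility = baseline_utility,
                 wtp_per_qaly = wtp_per_qaly,
                 starting_price = starting_price, endpoints = endpoints,
                 days_per_year = days_per_year)
}

make_offer <- function(lot, device_id = "dev", price = 500, rates = 0) {
  rates <- rep_len(rates, length(lot$endpoints))
  device_offer(device_id, manufacturer = device_id, price = price,
               event_rates = stats::setNames(rates, names(lot$endpoints)))
}

# Brute-force NMB, written directly from the model definition and kept
# independent of the pipeline: one expression summing over endpoints.
nmb_oracle <- function(lot, offer, include_price = TRUE) {
  d <- vapply(lot$endpoints, `[[`, numeric(1), "disutility")
  t <- vapply(lot$endpoints, `[[`, numeric(1), "duration_months")
  c_ <- vapply(lot$endpoints, `[[`, numeric(1), "cost_per_event")
  r <- offer$event_rates[names(lot$endpoints)]
  (lot$baseline_utility - sum(r * d * t / lot$horizon_months)) *
    lot$horizon_days / lot$days_per_year * lot$wtp_per_qaly -
    sum(r * c_) - if (include_price) offer$price else 0
}
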