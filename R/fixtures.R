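# Packaged worked example and a seeded synthetic-tender generator.
#
# The generator draws whole tenders (a lot plus offers) that satisfy every
# domain invariant, for property testing: monotonicity, oracle
# equivalence, time-normalization invariance, two-scale bounds.

#' The carotid-stent worked example
#'
#' Loads the packaged reconstruction of a 2021 carotid-stent tender:
#' three endpoints (minor stroke, major stroke, death), a 12-month
#' horizon, baseline utility 0.93, WTP 60,000 euro/QALY, and three offers
#' (Abbott 530; Cardinal Health 518; Medtronic 408) with their published
#' 12-month event rates.
#'
#' The per-endpoint disutilities and costs of the original tender were
#' never published; the packaged values are calibrated/reconstructed and
#' labelled non-authoritative (see the sidecar
#' `carotid_stent_NOTES.md` in the package's `extdata` directory, returned
#' as `notes_path`). The published Abbott intermediate totals (26.2625
#' disutility QALDs, 891.5365 total cost) are shipped as *given* step
#' inputs in the `given` element, suitable for trace replay via
#' [compute_nmb()]'s `given` argument.
#'
#' @return A list: `lot` ([lot_parameters()]), `offers` (named list of
#'   [device_offer()]), `given` (named list of per-device trace
#'   overrides), `notes_path` (path to the provenance notes).
#' @export
#' @examples
#' fx <- carotid_stent_fixture()
#' fx$offers[["ABBOTT"]]$event_rates  # fractions: 0.0235, 0.0016, 0.0007
carotid_stent_fixture <- function() {
  lot <- read_lot(system.file("extdata", "carotid_stent_lot.json",
                              package = "nmbtender", mustWork = TRUE))
  offers <- read_devices(
    system.file("extdata", "carotid_stent_devices.csv",
                package = "nmbtender", mustWork = TRUE),
    rate_unit = "percent")
  given <- jsonlite::fromJSON(
    system.file("extdata", "carotid_stent_given.json",
                package = "nmbtender", mustWork = TRUE),
    simplifyVector = FALSE)
  given$comment <- NULL
  list(lot = lot, offers = offers, given = given,
       notes_path = system.file("extdata", "carotid_stent_NOTES.md",
                                package = "nmbtender", mustWork = TRUE))
}

#' Specification for a synthetic tender
#'
#' Bundles the ranges from which [generate_tender()] draws a random lot
#' and its offers. All ranges must lie inside the domain invariants of the
#' tender types; infeasible ranges error here, before any generation.
#'
#' Disutilities and per-event costs are drawn strictly positive so that
#' the NMB is strictly monotone in every rate, and rates are bounded (and
#' rescaled if necessary) so that expected disutility never exhausts the
#' baseline quality-adjusted survival: generated tenders stay away from
#' the degenerate clamp-to-zero regime.
#'
#' @param n_devices Number of offers to draw (default 5).
#' @param n_endpoints Number of endpoints (default 3, the documented
#'   profile; 1-10 allowed).
#' @param horizon_months Lot horizon (default 12).
#' @param utility_range Range for the baseline utility, within `(0, 1]`.
#' @param wtp_range Range for the WTP threshold, positive.
#' @param rate_range Range for event rates (fractions), within `[0, 1]`.
#' @param disutility_range Range for endpoint disutilities, within
#'   `(0, 1]`.
#' @param duration_range Range for disutility durations in months; upper
#'   end capped at `horizon_months` (default `c(0.5, horizon_months)`).
#' @param cost_range Range for per-event costs, positive.
#' @param price_range Range for offered prices, positive; the lot starting
#'   price is the upper end.
#' @param price_exceed_frac Fraction of offers deliberately priced above
#'   the starting price, to exercise the exclusion path (default 0.05).
#' @param seed Integer seed making the tender reproducible.
#'
#' @return An object of class `synthetic_tender_spec`.
#' @export
synthetic_tender_spec <- function(n_devices = 5, n_endpoints = 3,
                                  horizon_months = 12,
                                  utility_range = c(0.7, 1),
                                  wtp_range = c(2e4, 1e5),
                                  rate_range = c(0.001, 0.15),
                                  disutility_range = c(0.05, 1),
                                  duration_range = c(0.5, horizon_months),
                                  cost_range = c(100, 5e4),
                                  price_range = c(100, 1000),
                                  price_exceed_frac = 0.05,
                                  seed = 1L) {
  chk_range <- function(r, name, lower, upper, lower_open = FALSE) {
    if (!is.numeric(r) || length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      return(sprintf("%s: must be a non-decreasing numeric pair", name))
    }
    c(check_scalar(r[1], paste0(name, "[1]"), lower = lower, upper = upper,
                   lower_open = lower_open),
      check_scalar(r[2], paste0(name, "[2]"), lower = lower, upper = upper,
                   lower_open = lower_open))
  }
  problems <- c(
    check_scalar(n_devices, "n_devices", lower = 1),
    check_scalar(n_endpoints, "n_endpoints", lower = 1, upper = 10),
    check_scalar(horizon_months, "horizon_months", lower = 0,
                 lower_open = TRUE),
    chk_range(utility_range, "utility_range", 0, 1, lower_open = TRUE),
    chk_range(wtp_range, "wtp_range", 0, Inf, lower_open = TRUE),
    chk_range(rate_range, "rate_range", 0, 1),
    chk_range(disutility_range, "disutility_range", 0, 1,
              lower_open = TRUE),
    chk_range(duration_range, "duration_range", 0, horizon_months,
              lower_open = TRUE),
    chk_range(cost_range, "cost_range", 0, Inf, lower_open = TRUE),
    chk_range(price_range, "price_range", 0, Inf, lower_open = TRUE),
    check_scalar(price_exceed_frac, "price_exceed_frac", lower = 0,
                 upper = 1),
    check_scalar(seed, "seed"))
  raise_problems(problems, "invalid synthetic_tender_spec")
  structure(
    list(n_devices = as.integer(n_devices),
         n_endpoints = as.integer(n_endpoints),
         horizon_months = horizon_months,
         utility_range = utility_range, wtp_range = wtp_range,
         rate_range = rate_range, disutility_range = disutility_range,
         duration_range = duration_range, cost_range = cost_range,
         price_range = price_range,
         price_exceed_frac = price_exceed_frac,
         seed = as.integer(seed)),
    class = "synthetic_tender_spec")
}

#' Generate a random tender from a specification
#'
#' Draws a lot and `n_devices` offers from the ranges in `spec`,
#' reproducibly for a fixed `spec$seed` (the caller's RNG state is left
#' untouched). The starting price is the upper end of `price_range`; a
#' `price_exceed_frac` share of offers is priced 1-50% above it so that
#' the price-exclusion path is exercised. Rates are rescaled, if needed,
#' so the expected disutility stays below 90% of the baseline utility.
#'
#' @param spec A [synthetic_tender_spec()].
#' @return A list: `lot` ([lot_parameters()]) and `offers` (named list of
#'   [device_offer()]).
#' @export
#' @examples
#' tender <- generate_tender(synthetic_tender_spec(seed = 42))
#' length(tender$offers)
generate_tender <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tender_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  runif2 <- function(n, r) stats::runif(n, r[1], r[2])
  endpoints <- lapply(seq_len(spec$n_endpoints), function(i) {
    endpoint_spec(
      endpoint_id = sprintf("ep%02d", i),
      label = sprintf("endpoint %d", i),
      disutility = runif2(1, spec$disutility_range),
      duration_months = runif2(1, spec$duration_range),
      cost_per_event = runif2(1, spec$cost_range))
  })
  lot <- lot_parameters(
    lot_id = sprintf("synthetic-%d", spec$seed),
    horizon_months = spec$horizon_months,
    baseline_utility = runif2(1, spec$utility_range),
    wtp_per_qaly = runif2(1, spec$wtp_range),
    starting_price = spec$price_range[2],
    endpoints = endpoints)

  adj <- vapply(endpoints, function(ep) {
    adjust_disutility(ep$disutility, ep$duration_months,
                      spec$horizon_months)
  }, numeric(1))
  offers <- lapply(seq_len(spec$n_devices), function(j) {
    rates <- runif2(spec$n_endpoints, spec$rate_range)
    load <- sum(rates * adj)
    cap <- 0.9 * lot$baseline_utility
    if (load > cap) rates <- rates * cap / load
    price <- if (stats::runif(1) < spec$price_exceed_frac) {
      spec$price_range[2] * stats::runif(1, 1.01, 1.5)
    } else {
      runif2(1, spec$price_range)
    }
    device_offer(
      device_id = sprintf("dev%02d", j),
      manufacturer = sprintf("maker %d", j),
      price = price,
      event_rates = stats::setNames(rates, names(lot$endpoints)))
  })
  names(offers) <- vapply(offers, `[[`, character(1), "device_id")
  list(lot = lot, offers = offers)
}
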