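# Domain types for tender lots, clinical endpoints, and device offers.
#
# A lot fixes the parameters shared by every competing device (the "fixed
# parameters" of the tender): analysis horizon, baseline utility, WTP
# threshold, starting price, and the clinical endpoints with their
# disutilities, durations, and per-event costs. An offer carries the
# device-specific ("variable") parameters: the price bid and the probability
# of each endpoint event within the horizon.

#' Define a clinical endpoint of a tender lot
#'
#' An endpoint bundles the lot-level constants attached to one adverse
#' clinical event: the utility decrement it causes, how long that decrement
#' persists, and the expected cost of managing one event.
#'
#' @param endpoint_id Short identifier, unique within the lot (e.g.
#'   `"minor_stroke"`). Used as the suffix of the `rate_<endpoint_id>`
#'   columns in device CSV files.
#' @param label Free-text label for reports (defaults to `endpoint_id`).
#' @param disutility Utility decrement caused by the event while it lasts,
#'   dimensionless, in `[0, 1]`.
#' @param duration_months How long the decrement persists, in months. Must be
#'   positive and cannot exceed the lot horizon.
#' @param cost_per_event Expected cost of managing one event, in the lot
#'   currency, non-negative.
#'
#' @return An object of class `endpoint_spec`.
#' @seealso [lot_parameters()], [adjust_disutility()]
#' @export
#' @examples
#' endpoint_spec("minor_stroke", "minor stroke",
#'               disutility = 0.15, duration_months = 3, cost_per_event = 6000)
endpoint_spec <- function(endpoint_id, label = endpoint_id, disutility,
                          duration_months, cost_per_event) {
  problems <- character()
  if (!is.character(endpoint_id) || length(endpoint_id) != 1L ||
      is.na(endpoint_id) || !nzchar(endpoint_id)) {
    problems <- c(problems, "endpoint_id: must be a non-empty string")
  }
  problems <- c(problems,
                check_scalar(disutility, "disutility", lower = 0, upper = 1),
                check_scalar(duration_months, "duration_months",
                             lower = 0, lower_open = TRUE),
                check_scalar(cost_per_event, "cost_per_event", lower = 0))
  raise_problems(problems, "invalid endpoint_spec")
  structure(
    list(endpoint_id = endpoint_id, label = as.character(label)[1L],
         disutility = as.numeric(disutility),
         duration_months = as.numeric(duration_months),
         cost_per_event = as.numeric(cost_per_event)),
    class = "endpoint_spec")
}

#' Define the fixed parameters of a tender lot
#'
#' The lot constants are identical for every device competing in the lot:
#' the analysis time horizon, the utility patients experience in the absence
#' of events, the willingness-to-pay (WTP) threshold used to monetize
#' quality-adjusted survival, the maximum admissible bid (starting price),
#' and the list of clinical endpoints.
#'
#' The horizon is entered in months; the internal day count is
#' `horizon_days = round(days_per_year * horizon_months / 12)`, so a 12-month
#' horizon with the default 365 days/year gives 365 days.
#'
#' @param lot_id Identifier of the lot.
#' @param horizon_months Analysis time horizon in months, positive.
#' @param baseline_utility Utility in the absence of events, in `(0, 1]`.
#' @param wtp_per_qaly Willingness-to-pay threshold, currency per QALY
#'   gained, positive.
#' @param starting_price Maximum admissible offer price, positive. Offers
#'   priced above it are excluded; offers exactly at it are admitted.
#' @param endpoints List of [endpoint_spec()] objects, 1 to 10, with unique
#'   `endpoint_id`s. Each endpoint's `duration_months` must not exceed
#'   `horizon_months`.
#' @param days_per_year Days per year used for QALD/QALY conversion
#'   (default 365).
#' @param currency_label Free-text currency name for reports
#'   (default `"euro"`).
#'
#' @return An object of class `lot_parameters` with the derived field
#'   `horizon_days`.
#' @export
#' @examples
#' lot_parameters(
#'   lot_id = "demo", horizon_months = 12, baseline_utility = 0.93,
#'   wtp_per_qaly = 60000, starting_price = 600,
#'   endpoints = list(
#'     endpoint_spec("death", disutility = 0.93, duration_months = 12,
#'                   cost_per_event = 150000)))
lot_parameters <- function(lot_id, horizon_months, baseline_utility,
                           wtp_per_qaly, starting_price, endpoints,
                           days_per_year = 365, currency_label = "euro") {
  problems <- c(
    check_scalar(horizon_months, "horizon_months", lower = 0, lower_open = TRUE),
    check_scalar(baseline_utility, "baseline_utility",
                 lower = 0, lower_open = TRUE, upper = 1),
    check_scalar(wtp_per_qaly, "wtp_per_qaly", lower = 0, lower_open = TRUE),
    check_scalar(starting_price, "starting_price", lower = 0, lower_open = TRUE),
    check_scalar(days_per_year, "days_per_year", lower = 0, lower_open = TRUE))
  if (!is.list(endpoints) ||
      !all(vapply(endpoints, inherits, logical(1), "endpoint_spec"))) {
    problems <- c(problems,
                  "endpoints: must be a list of endpoint_spec objects")
  } else {
    if (length(endpoints) < 1L || length(endpoints) > 10L) {
      problems <- c(problems, sprintf(
        "endpoints: count must be between 1 and 10, got %d",
        length(endpoints)))
    }
    ids <- vapply(endpoints, `[[`, character(1), "endpoint_id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      problems <- c(problems, sprintf(
        "endpoints: duplicate endpoint_id(s): %s",
        paste(dup, collapse = ", ")))
    }
    if (is.numeric(horizon_months) && length(horizon_months) == 1L &&
        is.finite(horizon_months)) {
      over <- ids[vapply(endpoints, `[[`, numeric(1),
                         "duration_months") > horizon_months]
      if (length(over)) {
        problems <- c(problems, sprintf(
          "endpoints: duration_months exceeds the %s-month horizon for: %s",
          format(horizon_months), paste(over, collapse = ", ")))
      }
    }
  }
  raise_problems(problems, "invalid lot_parameters")
  names(endpoints) <- vapply(endpoints, `[[`, character(1), "endpoint_id")
  structure(
    list(lot_id = as.character(lot_id)[1L],
         horizon_months = as.numeric(horizon_months),
         horizon_days = round(days_per_year * horizon_months / 12),
         baseline_utility = as.numeric(baseline_utility),
         wtp_per_qaly = as.numeric(wtp_per_qaly),
         starting_price = as.numeric(starting_price),
         days_per_year = as.numeric(days_per_year),
         endpoints = endpoints,
         currency_label = as.character(currency_label)[1L]),
    class = "lot_parameters")
}

#' Define one device offer (bid)
#'
#' @param device_id Identifier of the device/bid.
#' @param manufacturer Free-text manufacturer name.
#' @param price Offered price in the lot currency, non-negative.
#' @param event_rates Named numeric vector or list mapping `endpoint_id` to
#'   the probability of that event within the lot horizon. Percentages as
#'   printed in clinical reports ("2.35%") are selected with
#'   `rate_unit = "percent"`; internally rates are always stored as
#'   fractions.
#' @param rate_unit Either `"fraction"` (default) or `"percent"`.
#'
#' @return An object of class `device_offer` with rates stored as fractions.
#' @export
#' @examples
#' device_offer("ABBOTT", "Abbott", price = 530,
#'              event_rates = c(minor_stroke = 2.35, major_stroke = 0.16,
#'                              death = 0.07),
#'              rate_unit = "percent")
device_offer <- function(device_id, manufacturer = "", price, event_rates,
                         rate_unit = c("fraction", "percent")) {
  rate_unit <- match.arg(rate_unit)
  problems <- character()
  if (!is.character(device_id) || length(device_id) != 1L ||
      is.na(device_id) || !nzchar(device_id)) {
    problems <- c(problems, "device_id: must be a non-empty string")
  }
  problems <- c(problems, check_scalar(price, "price", lower = 0))
  rates <- unlist(event_rates)
  if (!is.numeric(rates) || is.null(names(rates)) ||
      any(!nzchar(names(rates))) || anyDuplicated(names(rates))) {
    problems <- c(problems,
      "event_rates: must be numeric with unique, non-empty endpoint names")
    rates <- numeric()
  } else if (anyNA(rates)) {
    problems <- c(problems, "event_rates: missing values not allowed")
  }
  raise_problems(problems, "invalid device_offer")
  if (rate_unit == "percent") rates <- rates / 100
  structure(
    list(device_id = device_id, manufacturer = as.character(manufacturer)[1L],
         price = as.numeric(price), event_rates = rates),
    class = "device_offer")
}

#' Validate a device offer against the lot rules
#'
#' An offer is admitted unless it violates an admission rule:
#' * a price above the lot starting price (at-cap offers are admitted);
#' * any event rate outside `[0, 1]` once expressed as a fraction;
#' * an endpoint mismatch — the offer's rate names must match the lot's
#'   endpoint ids exactly (a structural defect of the bid, reported
#'   distinctly from a price exclusion).
#'
#' Validation is deterministic and depends only on the offer and the lot,
#' never on the other offers.
#'
#' @param offer A [device_offer()].
#' @param lot A [lot_parameters()].
#'
#' @return A list with elements `admitted` (logical) and `reason`
#'   (`NA_character_` when admitted, otherwise a string naming the violated
#'   rule; structural endpoint mismatches are prefixed `"structural:"`).
#' @export
#' @examples
#' fx <- carotid_stent_fixture()
#' validate_offer(fx$offers[["ABBOTT"]], fx$lot)
validate_offer <- function(offer, lot) {
  stopifnot(inherits(offer, "device_offer"), inherits(lot, "lot_parameters"))
  lot_ids <- names(lot$endpoints)
  offer_ids <- names(offer$event_rates)
  missing_ids <- setdiff(lot_ids, offer_ids)
  extra_ids <- setdiff(offer_ids, lot_ids)
  if (length(missing_ids) || length(extra_ids)) {
    parts <- c(
      if (length(missing_ids))
        sprintf("missing rate(s) for endpoint(s) %s",
                paste(missing_ids, collapse = ", ")),
      if (length(extra_ids))
        sprintf("rate(s) for unknown endpoint(s) %s",
                paste(extra_ids, collapse = ", ")))
    return(list(admitted = FALSE, reason = paste0(
      "structural: endpoint mismatch: ", paste(parts, collapse = "; "))))
  }
  bad <- offer_ids[offer$event_rates < 0 | offer$event_rates > 1]
  if (length(bad)) {
    return(list(admitted = FALSE, reason = sprintf(
      "event rate outside [0, 1] for endpoint(s): %s",
      paste(bad, collapse = ", "))))
  }
  if (offer$price > lot$starting_price) {
    return(list(admitted = FALSE, reason = sprintf(
      "price %s exceeds the starting price %s",
      format(offer$price), format(lot$starting_price))))
  }
  list(admitted = TRUE, reason = NA_character_)
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat(sprintf(
    "<endpoint_spec> %s (%s): disutility %.4g for %.4g months, cost/event %.6g\n",
    x$endpoint_id, x$label, x$disutility, x$duration_months,
    x$cost_per_event))
  invisible(x)
}

#' @export
print.lot_parameters <- function(x, ...) {
  cat(sprintf("<lot_parameters> %s\n", x$lot_id))
  cat(sprintf("  horizon: %.4g months (%g days), baseline utility %.4g\n",
              x$horizon_months, x$horizon_days, x$baseline_utility))
  cat(sprintf("  WTP: %s %s/QALY, starting price %s %s\n",
              format_amount(x$wtp_per_qaly, 0), x$currency_label,
              format_amount(x$starting_price, 2), x$currency_label))
  cat(sprintf("  endpoints (%d):\n", length(x$endpoints)))
  for (ep in x$endpoints) {
    cat("   -"); print(ep)
  }
  invisible(x)
}

#' @export
print.device_offer <- function(x, ...) {
  cat(sprintf("<device_offer> %s (%s): price %s; rates %s\n",
              x$device_id, x$manufacturer, format_amount(x$price, 2),
              paste(sprintf("%s=%.4g", names(x$event_rates), x$event_rates),
                    collapse = ", ")))
  invisible(x)
}

# -- internal validation helpers ---------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    return(sprintf("%s: must be a single finite number", name))
  }
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    return(sprintf("%s: %s outside %s%s, %s%s", name, format(x),
                   if (lower_open) "(" else "[", format(lower),
                   format(upper), if (upper_open) ")" else "]"))
  }
  character()
}

raise_problems <- function(problems, header) {
  if (length(problems)) {
    stop(paste0(header, ":\n", paste0("  - ", problems, collapse = "\n")),
         call. = FALSE)
  }
  invisible(NULL)
}
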