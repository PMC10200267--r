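# The eight-step NMB computation for one device:
#   1. time horizon
#   2. baseline QALDs            u_base * horizon_days
#   3. disutility QALDs          sum_i r_i * d_i * t_i / H * horizon_days
#   4. net QALDs (and QALYs)     step2 - step3
#   5. monetized benefit         net QALDs / days_per_year * WTP
#   6. total cost                sum_i r_i * c_i (+ price)
#   7. benefit minus cost
#   8. NMB                       the step-7 value
# All arithmetic is at full floating precision; rounding happens only when
# a report is rendered.

#' Time-normalize a disutility to the analysis horizon
#'
#' An event disutility that persists for only part of the horizon is spread
#' over the whole horizon:
#' `adjusted = real_disutility * real_duration / horizon`. A utility loss of
#' 0.50 for one month therefore has the same effect on quality-adjusted
#' survival as a loss of 0.25 for two months.
#'
#' @param real_disutility Utility decrement while the event lasts, in
#'   `[0, 1]`.
#' @param real_duration Duration of the decrement, months, in
#'   `(0, horizon]`. A duration longer than the horizon is an error: the
#'   analysis cannot account for disutility beyond its own horizon.
#' @param horizon Analysis time horizon, months, positive.
#'
#' @return The adjusted disutility, dimensionless, in
#'   `[0, real_disutility]`.
#' @export
#' @examples
#' adjust_disutility(0.30, 1, 12)  # 0.025
adjust_disutility <- function(real_disutility, real_duration, horizon) {
  raise_problems(c(
    check_scalar(real_disutility, "real_disutility", lower = 0, upper = 1),
    check_scalar(real_duration, "real_duration", lower = 0, lower_open = TRUE),
    check_scalar(horizon, "horizon", lower = 0, lower_open = TRUE)),
    "invalid disutility adjustment")
  if (real_duration > horizon) {
    stop(sprintf(
      "real_duration (%s months) exceeds the horizon (%s months)",
      format(real_duration), format(horizon)), call. = FALSE)
  }
  real_disutility * real_duration / horizon
}

#' Baseline quality-adjusted life days over the horizon
#'
#' QALDs accrued at the baseline utility in the absence of any event:
#' `baseline_utility * horizon_days`.
#'
#' @param lot A [lot_parameters()].
#' @return Baseline QALDs (numeric scalar).
#' @export
baseline_qalds <- function(lot) {
  stopifnot(inherits(lot, "lot_parameters"))
  lot$baseline_utility * lot$horizon_days
}

#' Expected QALDs lost to endpoint events
#'
#' For each endpoint, the event probability within the horizon multiplies
#' the horizon-adjusted disutility; the sum is scaled to days:
#' `sum_i rate_i * adjust_disutility(d_i, t_i, H) * horizon_days`.
#'
#' @param lot A [lot_parameters()].
#' @param offer An admitted [device_offer()].
#' @return Expected disutility in QALDs, `>= 0`; 0 when all rates are 0.
#' @export
disutility_qalds <- function(lot, offer) {
  stopifnot(inherits(lot, "lot_parameters"), inherits(offer, "device_offer"))
  adj <- vapply(lot$endpoints, function(ep) {
    adjust_disutility(ep$disutility, ep$duration_months, lot$horizon_months)
  }, numeric(1))
  sum(offer$event_rates[names(lot$endpoints)] * adj) * lot$horizon_days
}

#' Net QALDs after subtracting event disutility
#'
#' `baseline - disutility`. A negative result (possible only with extreme
#' inputs: the expected loss exceeding the whole baseline survival) is
#' clamped to 0 with a warning rather than propagated, since net
#' quality-adjusted survival below zero has no interpretation in this model.
#'
#' @param baseline Baseline QALDs, from [baseline_qalds()].
#' @param disutility Disutility QALDs, from [disutility_qalds()].
#' @return Net QALDs, `>= 0`.
#' @export
net_qalds <- function(baseline, disutility) {
  out <- baseline - disutility
  if (out < 0) {
    warning(sprintf(
      "net QALDs negative (%.4f); clamped to 0 - check disutility inputs",
      out), call. = FALSE)
    out <- 0
  }
  out
}

#' Convert QALDs to QALYs
#'
#' @param qalds Quality-adjusted life days, `>= 0`.
#' @param days_per_year Days per year, positive (default 365).
#' @return QALYs: `qalds / days_per_year`.
#' @export
qalds_to_qalys <- function(qalds, days_per_year = 365) {
  raise_problems(c(
    check_scalar(qalds, "qalds", lower = 0),
    check_scalar(days_per_year, "days_per_year", lower = 0,
                 lower_open = TRUE)),
    "invalid QALD/QALY conversion")
  qalds / days_per_year
}

#' Monetize quality-adjusted survival at the WTP threshold
#'
#' Converts net QALDs to currency:
#' `qalds / days_per_year * wtp_per_qaly`.
#'
#' @param qalds Net QALDs, `>= 0`.
#' @param lot A [lot_parameters()] supplying `days_per_year` and
#'   `wtp_per_qaly`.
#' @return Monetized benefit in the lot currency.
#' @export
monetize_benefit <- function(qalds, lot) {
  stopifnot(inherits(lot, "lot_parameters"))
  qalds_to_qalys(qalds, lot$days_per_year) * lot$wtp_per_qaly
}

#' Expected total cost of an offer
#'
#' Expected endpoint-management costs, `sum_i rate_i * cost_per_event_i`,
#' plus the offered device price when `include_price` is `TRUE` (the
#' default: the tender score must respond to the price bid, otherwise the
#' cheapest and the dearest offer with equal outcomes would tie).
#'
#' @param lot A [lot_parameters()].
#' @param offer An admitted [device_offer()].
#' @param include_price Add the offer price to the event costs
#'   (default `TRUE`).
#' @return Expected cost in the lot currency.
#' @export
total_cost <- function(lot, offer, include_price = TRUE) {
  stopifnot(inherits(lot, "lot_parameters"), inherits(offer, "device_offer"))
  costs <- vapply(lot$endpoints, `[[`, numeric(1), "cost_per_event")
  sum(offer$event_rates[names(lot$endpoints)] * costs) +
    if (isTRUE(include_price)) offer$price else 0
}

#' Compute the net monetary benefit of a device offer
#'
#' Runs the full eight-step pipeline for one admitted offer and returns the
#' complete step trace together with the final NMB:
#' `NMB = monetized benefit of net QALDs - total cost`.
#'
#' When the per-endpoint fixed parameters of a published trace are not
#' available but its intermediate totals are, `given` can replay them:
#' `given$disutility_qalds` replaces the step-3 computation and
#' `given$cost_total` replaces step 6 (in which case `include_price` is
#' moot, the given value being the complete cost). Results computed with
#' `given` values carry them in the `given` field and should be labelled as
#' trace replays, not model outputs, in any report.
#'
#' @param lot A [lot_parameters()].
#' @param offer A [device_offer()]; must be admitted by
#'   [validate_offer()].
#' @param include_price Add the offer price to the event costs in step 6
#'   (default `TRUE`).
#' @param given Optional list with elements `disutility_qalds` and/or
#'   `cost_total` overriding steps 3 and 6 with externally supplied totals.
#'
#' @return An object of class `device_result`: fields `device_id`,
#'   `manufacturer`, `price`, `qalds_baseline`, `qalds_disutility`,
#'   `qalds_net`, `qalys`, `benefit_money`, `cost_events`, `cost_total`,
#'   `nmb`, `include_price`, `given`, and `step_trace` (a data frame with
#'   columns `step`, `description`, `value` mirroring the report layout).
#' @export
#' @examples
#' fx <- carotid_stent_fixture()
#' res <- compute_nmb(fx$lot, fx$offers[["ABBOTT"]],
#'                    given = fx$given[["ABBOTT"]])
#' res$nmb
compute_nmb <- function(lot, offer, include_price = TRUE, given = NULL) {
  stopifnot(inherits(lot, "lot_parameters"), inherits(offer, "device_offer"))
  v <- validate_offer(offer, lot)
  if (!v$admitted) {
    stop(sprintf("offer %s is not admissible: %s", offer$device_id,
                 v$reason), call. = FALSE)
  }
  if (!is.null(given)) {
    unknown <- setdiff(names(given), c("disutility_qalds", "cost_total"))
    if (length(unknown)) {
      stop(sprintf("unknown given value(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }

  base <- baseline_qalds(lot)
  dis <- if (!is.null(given$disutility_qalds)) {
    as.numeric(given$disutility_qalds)
  } else {
    disutility_qalds(lot, offer)
  }
  net <- net_qalds(base, dis)
  qalys <- qalds_to_qalys(net, lot$days_per_year)
  benefit <- monetize_benefit(net, lot)
  cost_events <- total_cost(lot, offer, include_price = FALSE)
  cost <- if (!is.null(given$cost_total)) {
    as.numeric(given$cost_total)
  } else {
    cost_events + if (isTRUE(include_price)) offer$price else 0
  }
  nmb <- benefit - cost

  trace <- data.frame(
    step = 1:8,
    description = c(
      "Selecting the time horizon",
      "Estimating QALDs over time horizon (at baseline utility in the absence of events)",
      "Estimating disutility in QALDs related to the endpoints",
      "Subtracting QALDs of disutility related to the endpoints",
      "QALDs converted into currency according to the WTP threshold",
      "Estimating costs related to the endpoints",
      "Subtracting costs related to the endpoints",
      "NMB"),
    value = c(lot$horizon_months, base, dis, net, benefit, cost, nmb, nmb),
    unit = c("months", "QALDs", "QALDs", "QALDs", lot$currency_label,
             lot$currency_label, lot$currency_label, lot$currency_label),
    stringsAsFactors = FALSE)

  structure(
    list(device_id = offer$device_id, manufacturer = offer$manufacturer,
         price = offer$price,
         qalds_baseline = base, qalds_disutility = dis, qalds_net = net,
         qalys = qalys, benefit_money = benefit,
         cost_events = cost_events, cost_total = cost, nmb = nmb,
         include_price = isTRUE(include_price),
         given = given, step_trace = trace),
    class = "device_result")
}

#' @export
print.device_result <- function(x, decimals = 4, ...) {
  cat(sprintf("<device_result> %s (%s), price %s\n", x$device_id,
              x$manufacturer, format_amount(x$price, 2)))
  if (!is.null(x$given)) {
    cat(sprintf("  [trace replay: %s supplied externally]\n",
                paste(names(x$given), collapse = ", ")))
  }
  tr <- x$step_trace
  for (i in seq_len(nrow(tr))) {
    cat(sprintf("  %d. %s: %s %s\n", tr$step[i], tr$description[i],
                format_amount(tr$value[i], decimals), tr$unit[i]))
  }
  cat(sprintf("  QALYs: %s\n", format_amount(x$qalys, decimals)))
  invisible(x)
}
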