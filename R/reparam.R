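# Two-scale presentation: many public tenders require the final score to be
# split into a 0-30 price scale and a 0-70 quality scale rather than the
# single open-ended monetary scale of the NMB.

#' Two-scale (0-30 price / 0-70 quality) scores
#'
#' Maps device results onto the administrative two-scale convention:
#'
#' * **price score** (0-30): with the default `"proportional"` rule,
#'   `30 * lowest_price / device_price` — the cheapest offer gets exactly
#'   30. The `"interpolated"` alternative maps the lot starting price to 0
#'   and the lowest offered price to 30 linearly.
#' * **quality score** (0-70): `70 * q / max(q)` where
#'   `q = benefit_money - cost_events` is the price-exclusive monetized
#'   benefit net of expected event costs — the best-quality device gets
#'   exactly 70.
#'
#' Both scores are capped to their scales; the total is their sum. These
#' rules are a documented, configurable default: unlike the raw NMB, a
#' fixed 30/70 weighting is not guaranteed to preserve the NMB ranking, so
#' disagreement between the two orderings is surfaced by
#' [two_scale_agreement()] rather than hidden.
#'
#' @param results List of `device_result` objects (all with positive
#'   prices).
#' @param lot The [lot_parameters()] of the tender (supplies the starting
#'   price for the interpolated rule).
#' @param price_rule `"proportional"` (default) or `"interpolated"`.
#'
#' @return A data frame with columns `device_id`, `price_score`,
#'   `quality_score`, `total_score`.
#' @export
#' @examples
#' fx <- carotid_stent_fixture()
#' res <- lapply(fx$offers, function(o) compute_nmb(fx$lot, o))
#' two_scale_scores(res, fx$lot)
two_scale_scores <- function(results, lot,
                             price_rule = c("proportional", "interpolated")) {
  price_rule <- match.arg(price_rule)
  if (length(results) == 0L) {
    stop("no admissible offers: nothing to score", call. = FALSE)
  }
  stopifnot(inherits(lot, "lot_parameters"),
            all(vapply(results, inherits, logical(1), "device_result")))
  price <- vapply(results, `[[`, numeric(1), "price")
  if (any(price <= 0)) {
    stop("two-scale scoring requires every price to be positive",
         call. = FALSE)
  }
  quality <- vapply(results, function(r) r$benefit_money - r$cost_events,
                    numeric(1))
  if (max(quality) <= 0) {
    stop(paste("maximum price-exclusive net benefit is not positive;",
               "two-scale quality scores are undefined - check the WTP",
               "threshold and event costs"), call. = FALSE)
  }

  price_score <- switch(price_rule,
    proportional = 30 * min(price) / price,
    interpolated = {
      if (min(price) == lot$starting_price) {
        rep(30, length(price))  # all at the cap: no spread to interpolate
      } else {
        30 * (lot$starting_price - price) /
          (lot$starting_price - min(price))
      }
    })
  quality_score <- 70 * quality / max(quality)

  price_score <- pmin(pmax(price_score, 0), 30)
  quality_score <- pmin(pmax(quality_score, 0), 70)
  data.frame(
    device_id = vapply(results, `[[`, character(1), "device_id"),
    price_score = unname(price_score),
    quality_score = unname(quality_score),
    total_score = unname(price_score + quality_score),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Do the two-scale scores agree with the raw NMB ranking?
#'
#' Diagnostic comparing the ordering by two-scale total score with the
#' ordering by raw NMB for one tender. A fixed 30/70 price/quality
#' weighting re-weights price against quality, so the two orderings can
#' genuinely differ; this function makes such disagreements visible.
#'
#' @param results List of `device_result` objects.
#' @param lot The [lot_parameters()] of the tender.
#' @param price_rule Passed to [two_scale_scores()].
#' @return A list: `agree` (logical), `nmb_ranking` and
#'   `two_scale_ranking` (character vectors of device ids).
#' @export
two_scale_agreement <- function(results, lot,
                                price_rule = c("proportional",
                                               "interpolated")) {
  scores <- two_scale_scores(results, lot, price_rule = price_rule)
  price <- vapply(results, `[[`, numeric(1), "price")[scores$device_id]
  ts_ranking <- scores$device_id[order(-scores$total_score, price,
                                       scores$device_id, method = "radix")]
  nmb_ranking <- rank_devices(results)
  list(agree = identical(ts_ranking, nmb_ranking),
       nmb_ranking = nmb_ranking, two_scale_ranking = ts_ranking)
}
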