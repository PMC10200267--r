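# Final classification of a tender lot: NMBs in decreasing order, the
# device with the highest NMB wins.

#' Rank device results by decreasing NMB
#'
#' Deterministic tie-breaking: equal NMBs are ordered by lower price first,
#' then lexicographically by `device_id`. A procurement ranking must never
#' depend on the order in which bids were opened.
#'
#' @param results A list of `device_result` objects (see [compute_nmb()]).
#' @return Character vector of `device_id`s in winning order (decreasing
#'   NMB).
#' @export
#' @examples
#' fx <- carotid_stent_fixture()
#' res <- lapply(fx$offers, function(o) compute_nmb(fx$lot, o))
#' rank_devices(res)
rank_devices <- function(results) {
  if (length(results) == 0L) {
    stop("no admissible offers: nothing to rank", call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "device_result")))
  ids <- unname(vapply(results, `[[`, character(1), "device_id"))
  nmb <- vapply(results, `[[`, numeric(1), "nmb")
  price <- vapply(results, `[[`, numeric(1), "price")
  ids[order(-nmb, price, ids, method = "radix")]
}

#' Evaluate a complete tender lot
#'
#' Validates every offer against the lot, computes the NMB of each admitted
#' offer, ranks the admitted devices by decreasing NMB, and optionally
#' appends the two-scale (0-30 price / 0-70 quality) presentation.
#'
#' @param lot A [lot_parameters()].
#' @param offers A list of [device_offer()] objects.
#' @param include_price Include the offered price in each device's cost
#'   (default `TRUE`).
#' @param given Optional named list (by `device_id`) of `given` overrides
#'   forwarded to [compute_nmb()] for trace replays.
#' @param two_scale Also compute [two_scale_scores()] (default `FALSE`).
#' @param price_rule Price-score rule for the two-scale presentation, see
#'   [two_scale_scores()].
#'
#' @return An object of class `tender_result`: `lot_id`, `results` (named
#'   list of `device_result` for admitted offers), `excluded` (data frame
#'   `device_id`, `reason`), `ranking` (device ids, winners first), and
#'   `two_scale` (data frame or `NULL`).
#' @export
#' @examples
#' fx <- carotid_stent_fixture()
#' evaluate_tender(fx$lot, fx$offers)$ranking
evaluate_tender <- function(lot, offers, include_price = TRUE, given = NULL,
                            two_scale = FALSE,
                            price_rule = c("proportional", "interpolated")) {
  stopifnot(inherits(lot, "lot_parameters"))
  price_rule <- match.arg(price_rule)
  stopifnot(is.list(offers),
            all(vapply(offers, inherits, logical(1), "device_offer")))
  ids <- vapply(offers, `[[`, character(1), "device_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate device_id(s) among offers: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }

  results <- list()
  excluded <- data.frame(device_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (offer in offers) {
    v <- validate_offer(offer, lot)
    if (v$admitted) {
      results[[offer$device_id]] <- compute_nmb(
        lot, offer, include_price = include_price,
        given = given[[offer$device_id]])
    } else {
      excluded <- rbind(excluded, data.frame(
        device_id = offer$device_id, reason = v$reason,
        stringsAsFactors = FALSE))
    }
  }
  if (length(results) == 0L) {
    stop("no admissible offers in this lot", call. = FALSE)
  }

  structure(
    list(lot_id = lot$lot_id,
         results = results,
         excluded = excluded,
         ranking = rank_devices(results),
         two_scale = if (isTRUE(two_scale)) {
           two_scale_scores(results, lot, price_rule = price_rule)
         }),
    class = "tender_result")
}

#' Summarize a tender result as a ranking table
#'
#' @param object A `tender_result`.
#' @param ... Unused.
#' @return A data frame with one row per admitted device in winning order:
#'   `rank`, `device_id`, `manufacturer`, `price`, `nmb`, plus the
#'   two-scale columns when present.
#' @export
summary.tender_result <- function(object, ...) {
  res <- object$results[object$ranking]
  out <- data.frame(
    rank = seq_along(res),
    device_id = vapply(res, `[[`, character(1), "device_id"),
    manufacturer = vapply(res, `[[`, character(1), "manufacturer"),
    price = vapply(res, `[[`, numeric(1), "price"),
    nmb = vapply(res, `[[`, numeric(1), "nmb"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(object$two_scale)) {
    out <- merge(out, object$two_scale, by = "device_id", sort = FALSE)
    out <- out[order(out$rank), ]
    rownames(out) <- NULL
  }
  out
}

#' @export
print.tender_result <- function(x, ...) {
  cat(sprintf("<tender_result> lot %s: %d admitted, %d excluded\n",
              x$lot_id, length(x$results), nrow(x$excluded)))
  print(summary(x))
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    for (i in seq_len(nrow(x$excluded))) {
      cat(sprintf("  %s: %s\n", x$excluded$device_id[i], x$excluded$reason[i]))
    }
  }
  invisible(x)
}
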