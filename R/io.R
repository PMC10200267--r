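# Readers and writers for the two input formats the tool consumes -- a lot
# configuration (JSON) and a device-offer table (CSV) -- and for the report
# bundle it emits. Input files accept plain decimals only; thousands
# separators appear only in rendered reports.

#' Read a lot configuration from JSON
#'
#' The file must contain an object with fields `lot_id`, `horizon_months`,
#' `baseline_utility`, `wtp_per_qaly`, `starting_price`, and `endpoints`
#' (an array of objects with `endpoint_id`, `disutility`,
#' `duration_months`, `cost_per_event`, and optional `label`); optional
#' top-level fields `days_per_year` and `currency_label`. Every schema
#' violation is reported at once, with its field path.
#'
#' @param path Path to the JSON lot configuration.
#' @return A validated [lot_parameters()].
#' @export
#' @examples
#' lot_file <- system.file("extdata", "carotid_stent_lot.json",
#'                         package = "nmbtender")
#' read_lot(lot_file)
read_lot <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("lot config not found: %s", path), call. = FALSE)
  }
  cfg <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("failed to parse lot config %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  if (!is.list(cfg) || is.null(names(cfg))) {
    stop(sprintf("lot config %s: top level must be a JSON object", path),
         call. = FALSE)
  }

  problems <- character()
  need_num <- function(obj, field, where) {
    val <- obj[[field]]
    if (is.null(val)) {
      problems <<- c(problems, sprintf("%s%s: missing", where, field))
      NA_real_
    } else if (!is.numeric(val) || length(val) != 1L) {
      problems <<- c(problems,
                     sprintf("%s%s: must be a single number", where, field))
      NA_real_
    } else {
      val
    }
  }
  need_chr <- function(obj, field, where) {
    val <- obj[[field]]
    if (is.null(val)) {
      problems <<- c(problems, sprintf("%s%s: missing", where, field))
      NA_character_
    } else {
      as.character(val)[1L]
    }
  }

  lot_id <- need_chr(cfg, "lot_id", "")
  horizon <- need_num(cfg, "horizon_months", "")
  utility <- need_num(cfg, "baseline_utility", "")
  wtp <- need_num(cfg, "wtp_per_qaly", "")
  start <- need_num(cfg, "starting_price", "")
  dpy <- if (is.null(cfg$days_per_year)) 365 else
    need_num(cfg, "days_per_year", "")
  currency <- if (is.null(cfg$currency_label)) "euro" else
    as.character(cfg$currency_label)[1L]

  eps <- list()
  if (is.null(cfg$endpoints) || !is.list(cfg$endpoints) ||
      length(cfg$endpoints) == 0L) {
    problems <- c(problems, "endpoints: missing or empty array")
  } else {
    for (i in seq_along(cfg$endpoints)) {
      ep <- cfg$endpoints[[i]]
      where <- sprintf("endpoints[%d].", i)
      eid <- need_chr(ep, "endpoint_id", where)
      dis <- need_num(ep, "disutility", where)
      dur <- need_num(ep, "duration_months", where)
      cst <- need_num(ep, "cost_per_event", where)
      if (!anyNA(c(dis, dur, cst)) && !is.na(eid)) {
        eps[[length(eps) + 1L]] <- tryCatch(
          endpoint_spec(eid,
                        label = if (is.null(ep$label)) eid else ep$label,
                        disutility = dis, duration_months = dur,
                        cost_per_event = cst),
          error = function(e) {
            problems <<- c(problems,
                           sprintf("%s%s", where, conditionMessage(e)))
            NULL
          })
      }
    }
    eps <- Filter(Negate(is.null), eps)
  }
  raise_problems(problems, sprintf("invalid lot config %s", path))

  lot_parameters(lot_id = lot_id, horizon_months = horizon,
                 baseline_utility = utility, wtp_per_qaly = wtp,
                 starting_price = start, endpoints = eps,
                 days_per_year = dpy, currency_label = currency)
}

#' Write a lot configuration to JSON
#'
#' Inverse of [read_lot()]: `read_lot(write_lot(lot, path))` reproduces the
#' in-memory lot exactly.
#'
#' @param lot A [lot_parameters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lot <- function(lot, path) {
  stopifnot(inherits(lot, "lot_parameters"))
  cfg <- list(
    lot_id = lot$lot_id,
    horizon_months = lot$horizon_months,
    baseline_utility = lot$baseline_utility,
    wtp_per_qaly = lot$wtp_per_qaly,
    starting_price = lot$starting_price,
    days_per_year = lot$days_per_year,
    currency_label = lot$currency_label,
    endpoints = lapply(unname(lot$endpoints), function(ep) {
      list(endpoint_id = ep$endpoint_id, label = ep$label,
           disutility = ep$disutility,
           duration_months = ep$duration_months,
           cost_per_event = ep$cost_per_event)
    }))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read device offers from CSV
#'
#' The CSV must have the header
#' `device_id,manufacturer,price,rate_<endpoint_id>,...`, one row per
#' offer. Rates are read as fractions by default; `rate_unit = "percent"`
#' divides them by 100 (for tables transcribed from clinical reports that
#' print "2.35"). Errors are addressed by row and column.
#'
#' @param path Path to the CSV file.
#' @param rate_unit `"fraction"` (default) or `"percent"`.
#' @return A named list of [device_offer()] objects.
#' @export
#' @examples
#' dev_file <- system.file("extdata", "carotid_stent_devices.csv",
#'                         package = "nmbtender")
#' read_devices(dev_file, rate_unit = "percent")
read_devices <- function(path, rate_unit = c("fraction", "percent")) {
  rate_unit <- match.arg(rate_unit)
  if (!file.exists(path)) {
    stop(sprintf("device file not found: %s", path), call. = FALSE)
  }
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE),
    error = function(e) {
      stop(sprintf("failed to parse device CSV %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  required <- c("device_id", "manufacturer", "price")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("device CSV %s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rate_cols <- grep("^rate_", names(tab), value = TRUE)
  unknown <- setdiff(names(tab), c(required, rate_cols))
  if (length(unknown)) {
    stop(sprintf(
      "device CSV %s: unknown column(s): %s (rate columns must be named rate_<endpoint_id>)",
      path, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(rate_cols) == 0L) {
    stop(sprintf("device CSV %s: no rate_<endpoint_id> columns", path),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) {
    stop(sprintf("device CSV %s: no offers (empty body)", path),
         call. = FALSE)
  }

  problems <- character()
  parse_num <- function(x, row, col) {
    val <- suppressWarnings(as.numeric(x))
    if (is.na(val)) {
      problems <<- c(problems, sprintf(
        "row %d, column %s: non-numeric value %s", row, col,
        deparse(as.character(x))))
    }
    val
  }
  offers <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    price <- parse_num(tab$price[i], i, "price")
    rates <- vapply(rate_cols, function(col) parse_num(tab[[col]][i], i, col),
                    numeric(1))
    names(rates) <- sub("^rate_", "", rate_cols)
    if (!anyNA(c(price, rates))) {
      offers[[i]] <- tryCatch(
        device_offer(tab$device_id[i], tab$manufacturer[i], price, rates,
                     rate_unit = rate_unit),
        error = function(e) {
          problems <<- c(problems,
                         sprintf("row %d: %s", i, conditionMessage(e)))
          NULL
        })
    }
  }
  raise_problems(problems, sprintf("invalid device CSV %s", path))
  offers <- Filter(Negate(is.null), offers)
  names(offers) <- vapply(offers, `[[`, character(1), "device_id")
  offers
}

#' Write device offers to CSV
#'
#' Inverse of [read_devices()]; the rate columns are emitted in the unit
#' requested so that a percent-convention file round-trips as percent.
#'
#' @param offers List of [device_offer()] objects with identical endpoint
#'   sets.
#' @param path Output path.
#' @param rate_unit `"fraction"` (default) or `"percent"`.
#' @return `path`, invisibly.
#' @export
write_devices <- function(offers, path,
                          rate_unit = c("fraction", "percent")) {
  rate_unit <- match.arg(rate_unit)
  stopifnot(is.list(offers), length(offers) > 0L,
            all(vapply(offers, inherits, logical(1), "device_offer")))
  ep_ids <- names(offers[[1L]]$event_rates)
  rows <- lapply(offers, function(o) {
    stopifnot(setequal(names(o$event_rates), ep_ids))
    rates <- o$event_rates[ep_ids]
    if (rate_unit == "percent") rates <- rates * 100
    c(device_id = o$device_id, manufacturer = o$manufacturer,
      price = format(o$price, digits = 15),
      stats::setNames(vapply(rates, format, character(1), digits = 15),
                      paste0("rate_", ep_ids)))
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the tender report bundle
#'
#' Emits, in `out_dir`:
#' * `report.txt` — per-device step traces in the eight-step layout, the
#'   ranking table, and the exclusions;
#' * `traces.csv` — every step of every admitted device, machine-readable;
#' * `ranking.csv` — rank, device, manufacturer, price, NMB (plus the
#'   two-scale columns when present);
#' * `exclusions.csv` — excluded devices and the rule each violated;
#' * `run_summary.json` — lot id, package version, rendering options, and
#'   counts, for audit.
#'
#' Output is byte-stable: the same `tender_result` and options always
#' produce identical files. QALD/QALY values render at `qald_decimals`,
#' currency at `currency_decimals`; passing `decimals` sets both.
#'
#' @param result A `tender_result` from [evaluate_tender()].
#' @param out_dir Output directory; must exist and be writable.
#' @param decimals Optional single value (0-6) overriding both decimal
#'   settings.
#' @param qald_decimals Decimals for QALD/QALY rendering (default 4).
#' @param currency_decimals Decimals for currency rendering (default 2).
#' @return Invisibly, the named character vector of files written.
#' @export
write_report <- function(result, out_dir, decimals = NULL,
                         qald_decimals = 4, currency_decimals = 2) {
  stopifnot(inherits(result, "tender_result"))
  if (!is.null(decimals)) {
    raise_problems(check_scalar(decimals, "decimals", lower = 0, upper = 6),
                   "invalid report options")
    qald_decimals <- currency_decimals <- as.integer(decimals)
  }
  if (!dir.exists(out_dir)) {
    stop(sprintf("output directory does not exist: %s", out_dir),
         call. = FALSE)
  }
  if (file.access(out_dir, mode = 2) != 0L) {
    stop(sprintf("output directory is not writable: %s", out_dir),
         call. = FALSE)
  }

  render_step <- function(value, unit) {
    if (unit == "months") format(value)
    else if (unit == "QALDs") format_amount(value, qald_decimals)
    else format_amount(value, currency_decimals)
  }

  lines <- c(sprintf("Tender report - lot %s", result$lot_id), "")
  trace_rows <- list()
  for (res in result$results[result$ranking]) {
    lines <- c(lines, sprintf("Device %s (%s), offered price %s",
                              res$device_id, res$manufacturer,
                              format_amount(res$price, currency_decimals)))
    if (!is.null(res$given)) {
      lines <- c(lines, sprintf(
        "  note: trace replay - %s supplied externally, not recomputed",
        paste(names(res$given), collapse = ", ")))
    }
    tr <- res$step_trace
    for (i in seq_len(nrow(tr))) {
      lines <- c(lines, sprintf("  %d. %s: %s %s", tr$step[i],
                                tr$description[i],
                                render_step(tr$value[i], tr$unit[i]),
                                tr$unit[i]))
    }
    lines <- c(lines, sprintf("  QALYs: %s",
                              format_amount(res$qalys, qald_decimals)), "")
    trace_rows[[res$device_id]] <- cbind(
      data.frame(device_id = res$device_id, stringsAsFactors = FALSE), tr)
  }

  ranking_tab <- summary(result)
  lines <- c(lines, "Ranking (decreasing NMB):")
  for (i in seq_len(nrow(ranking_tab))) {
    lines <- c(lines, sprintf(
      "  %d. %s (%s) - price %s, NMB %s", ranking_tab$rank[i],
      ranking_tab$device_id[i], ranking_tab$manufacturer[i],
      format_amount(ranking_tab$price[i], currency_decimals),
      format_amount(ranking_tab$nmb[i], currency_decimals)))
  }
  lines <- c(lines, "")
  if (nrow(result$excluded)) {
    lines <- c(lines, "Excluded offers:")
    for (i in seq_len(nrow(result$excluded))) {
      lines <- c(lines, sprintf("  %s: %s", result$excluded$device_id[i],
                                result$excluded$reason[i]))
    }
  } else {
    lines <- c(lines, "Excluded offers: none")
  }

  files <- c(report = file.path(out_dir, "report.txt"),
             traces = file.path(out_dir, "traces.csv"),
             ranking = file.path(out_dir, "ranking.csv"),
             exclusions = file.path(out_dir, "exclusions.csv"),
             summary = file.path(out_dir, "run_summary.json"))
  writeLines(lines, files[["report"]])
  utils::write.csv(do.call(rbind, c(trace_rows, make.row.names = FALSE)),
                   files[["traces"]], row.names = FALSE)
  utils::write.csv(ranking_tab, files[["ranking"]], row.names = FALSE)
  utils::write.csv(result$excluded, files[["exclusions"]],
                   row.names = FALSE)
  jsonlite::write_json(
    list(lot_id = result$lot_id,
         package = "nmbtender",
         package_version = as.character(utils::packageVersion("nmbtender")),
         n_admitted = length(result$results),
         n_excluded = nrow(result$excluded),
         ranking = result$ranking,
         two_scale = !is.null(result$two_scale),
         qald_decimals = qald_decimals,
         currency_decimals = currency_decimals),
    files[["summary"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
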