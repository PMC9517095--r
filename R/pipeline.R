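#' Configuration for a pipeline run
#'
#' Bundles the paths and settings a daily run needs. Scheduling itself is
#' left to the host (a cron entry invoking the one-shot daily run at
#' 00:00); the package exposes one-shot functions only, which keeps runs
#' reproducible and testable.
#'
#' @param feed_dir Directory of fixture crawl payloads to poll.
#' @param store A [wq_store()] (or a path to a saved one).
#' @param stations Station metadata data frame.
#' @param scheme A [grading_scheme()]; default the shipped scheme.
#' @param target_class Warning target class; default \code{"III"}.
#' @param horizon_hours,step_hours Forecast product resolution; defaults
#'   24 and 1.
#' @param outbox Directory for warning reports.
#' @param seed Root seed; all randomness in the run derives from it.
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(feed_dir = NULL, store = wq_store(),
                       stations = NULL, scheme = default_grading_scheme(),
                       target_class = "III", horizon_hours = 24,
                       step_hours = 1, outbox = NULL, seed = 1) {
  if (horizon_hours <= 0) stop("`horizon_hours` must be > 0",
                               call. = FALSE)
  if (is.character(store)) store <- wq_store(store)
  structure(list(feed_dir = feed_dir, store = store, stations = stations,
                 scheme = scheme, target_class = target_class,
                 horizon_hours = horizon_hours, step_hours = step_hours,
                 outbox = outbox, seed = seed),
            class = "run_config")
}

# predictions for one (station, indicator) given a trained fit
.station_prediction <- function(fit, store, sid, indicator, config) {
  rec <- store_records(config$store, sid)
  if (!nrow(rec) || !indicator %in% names(rec)) return(NULL)
  v <- rec[[indicator]][order(rec$time)]
  v <- v[!is.na(v)]
  if (length(v) < fit$lookback) return(NULL)
  t0 <- max(rec$time)
  p <- predict_day(fit, history = v, horizon_hours = config$horizon_hours,
                   step_hours = config$step_hours, start_time = t0,
                   indicator = indicator, scheme = config$scheme)
  cbind(data.frame(station_id = sid, indicator = indicator,
                   stringsAsFactors = FALSE),
        p)
}

#' Automatic daily prediction and early warning
#'
#' The automatic operating mode: for every water-quality station with
#' sufficient history, predict every registered indicator over the next
#' day (hourly by default), grade the predictions, raise warnings against
#' the target class, and aggregate predicted grades to sub-watershed and
#' watershed level. Stations or indicators whose registry key has no
#' trained model are skipped with a notice. The run is deterministic for
#' a fixed store snapshot and seed.
#'
#' @param config A [run_config()].
#' @param fits Named list of trained forecasters keyed like
#'   [build_registry()] keys (\code{watershed/position/indicator}).
#' @param stations Station metadata; defaults to \code{config$stations}.
#' @return A list of class \code{"run_summary"}: \code{predictions} (all
#'   graded hourly predictions), \code{warnings} (warning events),
#'   \code{by_subwatershed} and \code{by_watershed} (worst predicted
#'   class per unit), \code{attempted}, \code{skipped} (untrained or
#'   data-poor keys).
#' @export
run_auto <- function(config, fits, stations = NULL) {
  if (is.null(stations)) stations <- config$stations
  if (is.null(stations)) stop("no station metadata", call. = FALSE)
  wq_st <- stations[stations$kind == "water_quality", , drop = FALSE]
  inds <- unique(vapply(strsplit(names(fits), "/"), function(p) p[3L], ""))
  preds <- list(); skipped <- character(); attempted <- 0L
  for (i in seq_len(nrow(wq_st))) {
    st <- wq_st[i, ]
    for (ind in inds) {
      attempted <- attempted + 1L
      key <- paste(st$watershed, st$position, ind, sep = "/")
      if (is.null(fits[[key]])) {
        skipped <- c(skipped, paste0(st$station_id, ":", key))
        next
      }
      p <- .station_prediction(fits[[key]], config$store, st$station_id,
                               ind, config)
      if (is.null(p)) {
        skipped <- c(skipped, paste0(st$station_id, ":", key,
                                     " (insufficient history)"))
        next
      }
      preds[[length(preds) + 1L]] <- p
    }
  }
  if (length(skipped))
    message("run_auto: skipped ", length(skipped),
            " station-indicator pair(s) without a trained model or history")
  predictions <- if (length(preds)) do.call(rbind, preds) else NULL
  warns <- if (!is.null(predictions))
    raise_warnings(predictions, config$scheme, config$target_class,
                   config$outbox)
  else raise_warnings(data.frame(station_id = character(),
                                 time = as.POSIXct(character()),
                                 indicator = character(),
                                 value = numeric()),
                      config$scheme, config$target_class)
  agg <- function(unit) {
    if (is.null(predictions)) return(NULL)
    u <- stations[match(predictions$station_id, stations$station_id),
                  unit]
    grp <- if (unit == "position")
      paste(stations$watershed[match(predictions$station_id,
                                     stations$station_id)], u, sep = "/")
    else u
    worst <- tapply(as.integer(predictions$class), grp, function(ix)
      if (all(is.na(ix))) NA_integer_ else max(ix, na.rm = TRUE))
    data.frame(unit = names(worst),
               worst_class = wq_classes()[as.integer(worst)],
               stringsAsFactors = FALSE)
  }
  structure(list(predictions = predictions, warnings = warns,
                 by_subwatershed = agg("position"),
                 by_watershed = agg("watershed"),
                 attempted = attempted, skipped = skipped),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("Daily prediction run\n")
  cat(sprintf("  station-indicator pairs attempted: %d (skipped %d)\n",
              x$attempted, length(x$skipped)))
  np <- if (is.null(x$predictions)) 0L else nrow(x$predictions)
  cat(sprintf("  hourly predictions: %d\n", np))
  cat(sprintf("  warnings raised: %d\n", nrow(x$warnings)))
  rep_path <- attr(x$warnings, "report")
  if (!is.null(rep_path)) cat("  warning report:", rep_path, "\n")
  invisible(x)
}

#' Manual (user-defined) prediction and early warning
#'
#' The user-driven operating mode: predictions and warnings restricted to
#' the requested stations and indicators. For identical store snapshot,
#' models and seed, the result equals the corresponding slice of
#' [run_auto()].
#'
#' @param config A [run_config()].
#' @param fits Trained forecasters, as in [run_auto()].
#' @param stations Station metadata.
#' @param station_ids Requested station ids.
#' @param indicators Requested indicator keys.
#' @param horizon_hours Optional override of the configured horizon.
#' @return A \code{"run_summary"} restricted to the request.
#' @export
run_manual <- function(config, fits, station_ids, indicators,
                       stations = NULL, horizon_hours = NULL) {
  if (is.null(stations)) stations <- config$stations
  bad <- setdiff(station_ids, stations$station_id)
  if (length(bad))
    stop("unknown station(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(stations$station_id, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(indicators, wq_indicators()$indicator)
  if (length(bad))
    stop("unknown indicator(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(wq_indicators()$indicator, collapse = ", "),
         call. = FALSE)
  if (!is.null(horizon_hours)) config$horizon_hours <- horizon_hours
  sub <- stations[stations$station_id %in% station_ids, , drop = FALSE]
  keys <- unique(paste(sub$watershed[rep(seq_len(nrow(sub)),
                                         each = length(indicators))],
                       sub$position[rep(seq_len(nrow(sub)),
                                        each = length(indicators))],
                       rep(indicators, nrow(sub)), sep = "/"))
  run_auto(config, fits[intersect(names(fits), keys)], stations = sub)
}
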