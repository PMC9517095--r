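#' Generate a synthetic monitoring-station network
#'
#' Lays out a national-style monitoring network: each watershed is divided
#' into upstream, middle and downstream sub-watersheds, and every
#' sub-watershed receives \code{stations_per_subwatershed} stations. Station
#' coordinates are random (the network makes no claim to geographic realism).
#'
#' @param n_watersheds Number of watersheds (default 10).
#' @param stations_per_subwatershed Stations in each of the three
#'   sub-watershed positions of every watershed.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @param watershed_names Optional character vector of watershed names; by
#'   default \code{"WS01"}, \code{"WS02"}, ...
#' @param kind Station kind, \code{"water_quality"} or \code{"hydrology"}.
#' @return A data frame of station metadata with columns
#'   \code{station_id}, \code{name}, \code{lon}, \code{lat},
#'   \code{watershed}, \code{position}, \code{kind}.
#' @examples
#' net <- generate_network(10, 1, seed = 7)
#' nrow(net)  # 30 stations: 10 watersheds x 3 positions
#' @export
generate_network <- function(n_watersheds = 10, stations_per_subwatershed = 1,
                             seed = 1, watershed_names = NULL,
                             kind = c("water_quality", "hydrology")) {
  kind <- match.arg(kind)
  if (n_watersheds < 1 || stations_per_subwatershed < 1)
    stop("`n_watersheds` and `stations_per_subwatershed` must be >= 1",
         call. = FALSE)
  if (is.null(watershed_names))
    watershed_names <- sprintf("WS%02d", seq_len(n_watersheds))
  if (length(watershed_names) != n_watersheds)
    stop("`watershed_names` must have length `n_watersheds`", call. = FALSE)
  positions <- c("upstream", "middle", "downstream")
  grid <- expand.grid(slot = seq_len(stations_per_subwatershed),
                      position = positions, watershed = watershed_names,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  with_seed(seed, {
    data.frame(
      station_id = sprintf("S%04d", seq_len(n)),
      name = paste0(grid$watershed, "-", substr(grid$position, 1, 2),
                    "-", grid$slot),
      lon = round(runif(n, 74, 134), 4),
      lat = round(runif(n, 19, 53), 4),
      watershed = grid$watershed,
      position = grid$position,
      kind = kind,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification of one synthetic indicator series
#'
#' Describes the statistical structure of a generated monitoring series:
#' a baseline level, an annual sinusoidal cycle, an AR(1) deviation driven
#' by Gaussian innovations, and injection rates for missing values and
#' exact-duplicate records.
#'
#' @param indicator Indicator key (see [wq_indicators()]).
#' @param baseline Long-run mean level, in the indicator's units.
#' @param seasonal_amplitude Amplitude of the sinusoidal seasonal term.
#' @param seasonal_period Seasonal period in hours (default 8760, one year).
#' @param ar_coefficient AR(1) coefficient in (-1, 1); the lag-1
#'   autocorrelation of the deviation process.
#' @param noise_sd Standard deviation of the AR(1) Gaussian innovations
#'   (>= 0).
#' @param sampling_interval Hours between records; default 4, the cadence
#'   of the national water-quality feed. Hydrology series use 12.
#' @param missing_rate,duplicate_rate Probabilities in \[0, 1\] that a
#'   value is dropped (set missing) or a record is emitted twice.
#' @return An object of class \code{"series_spec"}.
#' @examples
#' series_spec("COD_Mn", baseline = 4, seasonal_amplitude = 1,
#'             ar_coefficient = 0.8, noise_sd = 0.3)
#' @export
series_spec <- function(indicator, baseline, seasonal_amplitude = 0,
                        seasonal_period = 8760, ar_coefficient = 0,
                        noise_sd = 0, sampling_interval = 4,
                        missing_rate = 0, duplicate_rate = 0) {
  if (!.is_known_indicator(indicator))
    stop(sprintf("unknown indicator '%s'; known: %s", indicator,
                 paste(wq_indicators()$indicator, collapse = ", ")),
         call. = FALSE)
  stopifnot_scalar_number(baseline, "baseline")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (abs(ar_coefficient) >= 1)
    stop("`ar_coefficient` must lie in (-1, 1)", call. = FALSE)
  if (missing_rate < 0 || missing_rate > 1 ||
      duplicate_rate < 0 || duplicate_rate > 1)
    stop("`missing_rate` and `duplicate_rate` must lie in [0, 1]",
         call. = FALSE)
  if (sampling_interval <= 0)
    stop("`sampling_interval` must be > 0", call. = FALSE)
  structure(list(indicator = indicator, baseline = baseline,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_period = seasonal_period,
                 ar_coefficient = ar_coefficient, noise_sd = noise_sd,
                 sampling_interval = sampling_interval,
                 missing_rate = missing_rate,
                 duplicate_rate = duplicate_rate),
            class = "series_spec")
}

# one AR(1)+seasonal path on a regular time grid; innovations ~ N(0, sd)
.simulate_path <- function(spec, n) {
  hours <- (seq_len(n) - 1L) * spec$sampling_interval
  seas <- if (spec$seasonal_amplitude == 0) 0 else
    spec$seasonal_amplitude * sin(2 * pi * hours / spec$seasonal_period)
  dev <- numeric(n)
  if (spec$noise_sd > 0) {
    eps <- rnorm(n, 0, spec$noise_sd)
    # start the deviation at its stationary distribution
    dev[1L] <- eps[1L] / sqrt(1 - spec$ar_coefficient^2)
    if (n > 1L) for (t in 2:n)
      dev[t] <- spec$ar_coefficient * dev[t - 1L] + eps[t]
  }
  spec$baseline + seas + dev
}

#' Generate a synthetic monitoring series for one station
#'
#' Produces timestamped records at the specification's sampling interval:
#' value = baseline + seasonal sinusoid + AR(1) deviation. Missing values
#' and exact-duplicate records are then injected at the specified rates.
#' Deterministic for a fixed seed. Timestamps are whole-hour, timezone-naive
#' (stored as UTC), matching the feed's publication convention.
#'
#' @param station One row of a [generate_network()] data frame (or any list
#'   with a \code{station_id}).
#' @param spec A [series_spec()], or a list of them (one indicator each) to
#'   generate a multi-indicator record set on a shared time grid; all specs
#'   must then agree on \code{sampling_interval}, and the first spec's
#'   \code{duplicate_rate} governs record-level duplication.
#' @param start,end POSIXct (or parseable strings); records cover
#'   \code{[start, end)}, i.e. \code{floor((end - start) / interval)} rows
#'   before duplicate injection.
#' @param seed Integer seed.
#' @return A data frame with columns \code{station_id}, \code{time} and one
#'   column per indicator.
#' @examples
#' st <- generate_network(1, 1, seed = 1)[1, ]
#' sp <- series_spec("DO", baseline = 8, noise_sd = 0.2, ar_coefficient = 0.6)
#' x <- generate_series(st, sp, "2021-03-01 00:00", "2021-03-02 00:00", seed = 3)
#' nrow(x)  # 6 four-hourly records in one day
#' @export
generate_series <- function(station, spec, start, end, seed = 1) {
  if (inherits(spec, "series_spec")) spec <- list(spec)
  if (!length(spec) || !all(vapply(spec, inherits, TRUE, "series_spec")))
    stop("`spec` must be a series_spec or a list of them", call. = FALSE)
  if (is.character(start)) start <- parse_wq_time(start)
  if (is.character(end)) end <- parse_wq_time(end)
  if (!(start < end)) stop("`end` must be after `start`", call. = FALSE)
  ivals <- vapply(spec, `[[`, 0, "sampling_interval")
  if (length(unique(ivals)) > 1L)
    stop("all specs must share one sampling_interval", call. = FALSE)
  interval <- ivals[1L]
  n <- floor(as.numeric(difftime(end, start, units = "hours")) / interval)
  if (n < 1L) stop("time range shorter than one sampling interval",
                   call. = FALSE)
  times <- start + (seq_len(n) - 1L) * interval * 3600

  out <- data.frame(station_id = rep(station$station_id, n), time = times,
                    stringsAsFactors = FALSE)
  sid <- station$station_id
  with_seed(child_seed(seed, sid, "values"), {
    for (sp in spec) {
      v <- .simulate_path(sp, n)
      if (sp$missing_rate > 0)
        v[runif(n) < sp$missing_rate] <- NA_real_
      out[[sp$indicator]] <- v
    }
  })
  dup_rate <- spec[[1L]]$duplicate_rate
  if (dup_rate > 0) {
    dup <- with_seed(child_seed(seed, sid, "dups"),
                     which(runif(n) < dup_rate))
    if (length(dup)) {
      out <- out[sort(c(seq_len(n), dup)), , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  out
}

#' Describe a pollution spike
#'
#' A sudden pollution event at one station: an additive offset applied to
#' one indicator over a time window. By default the offset is oriented in
#' the "worse water quality" direction — negative for dissolved oxygen
#' (pollution depletes DO), positive for every other indicator. Pass
#' \code{direction = "raw"} to use \code{magnitude}'s sign as given.
#'
#' @param station_id Affected station.
#' @param indicator Indicator key.
#' @param start_time POSIXct or parseable string; window start.
#' @param duration Hours; the window is \code{[start, start + duration)}.
#' @param magnitude Offset size in indicator units.
#' @param direction \code{"worse"} (default) or \code{"raw"}.
#' @return An object of class \code{"spike_event"}.
#' @export
spike_event <- function(station_id, indicator, start_time, duration,
                        magnitude, direction = c("worse", "raw")) {
  direction <- match.arg(direction)
  if (!.is_known_indicator(indicator))
    stop(sprintf("unknown indicator '%s'", indicator), call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (is.character(start_time)) start_time <- parse_wq_time(start_time)
  offset <- if (direction == "worse")
    abs(magnitude) * (if (indicator == "DO") -1 else 1) else magnitude
  structure(list(station_id = station_id, indicator = indicator,
                 start_time = start_time, duration = duration,
                 magnitude = offset),
            class = "spike_event")
}

#' Inject a pollution spike into a record set
#'
#' Adds the event's offset to the named indicator for all records of the
#' event's station falling inside the event window; every other record and
#' every other column is returned unchanged.
#'
#' @param records A record data frame (as from [generate_series()]).
#' @param event A [spike_event()].
#' @return The modified records.
#' @export
inject_spike <- function(records, event) {
  stopifnot(inherits(event, "spike_event"))
  if (!event$indicator %in% names(records))
    stop(sprintf("records carry no '%s' column", event$indicator),
         call. = FALSE)
  endt <- event$start_time + event$duration * 3600
  hit <- records$station_id == event$station_id &
    records$time >= event$start_time & records$time < endt
  if (!any(hit))
    stop("spike window does not overlap the record range", call. = FALSE)
  records[[event$indicator]][hit] <-
    records[[event$indicator]][hit] + event$magnitude
  records
}

#' Write records as a fixture crawl payload
#'
#' Serializes one station's records into the JSON dialect the ingestion
#' module polls: \code{{"station_id", "station_name", "records": [{"time":
#' "YYYY-MM-DD HH:00", "<indicator>": number|null, ...}]}}. Missing values
#' are written as \code{null} and survive a round trip.
#'
#' @param records Non-empty record data frame for a single station.
#' @param path Output file path.
#' @param station_name Optional display name (defaults to the station id).
#' @return \code{path}, invisibly.
#' @export
write_crawl_payload <- function(records, path, station_name = NULL) {
  if (!nrow(records)) stop("`records` is empty", call. = FALSE)
  sid <- unique(records$station_id)
  if (length(sid) != 1L)
    stop("a payload holds exactly one station", call. = FALSE)
  inds <- setdiff(names(records), c("station_id", "time"))
  recs <- lapply(seq_len(nrow(records)), function(i) {
    r <- list(time = format_wq_time(records$time[i]))
    for (ind in inds) {
      v <- records[[ind]][i]
      r[[ind]] <- if (is.na(v)) NULL else v
      if (is.na(v)) r[ind] <- list(NULL)
    }
    r
  })
  payload <- list(station_id = sid,
                  station_name = if (is.null(station_name)) sid
                                 else station_name,
                  records = recs)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Parse a fixture crawl payload
#'
#' @param path Path to a JSON payload written by [write_crawl_payload()]
#'   (or produced externally in the same dialect).
#' @return A record data frame with attribute \code{"station_name"}.
#' @export
read_crawl_payload <- function(path) {
  p <- jsonlite::read_json(path)
  if (is.null(p$station_id) || is.null(p$records))
    stop("malformed payload: missing station_id or records", call. = FALSE)
  inds <- unique(unlist(lapply(p$records, function(r)
    setdiff(names(r), "time"))))
  n <- length(p$records)
  out <- data.frame(station_id = rep(p$station_id, n),
                    time = parse_wq_time(vapply(p$records, `[[`, "", "time")),
                    stringsAsFactors = FALSE)
  for (ind in inds)
    out[[ind]] <- vapply(p$records, function(r)
      if (is.null(r[[ind]])) NA_real_ else as.numeric(r[[ind]]), 0)
  attr(out, "station_name") <- p$station_name
  out
}

#' Read or write station metadata CSV
#'
#' Station metadata travels as CSV with header
#' \code{station_id,name,lon,lat,watershed,position,kind}.
#'
#' @param stations Station data frame (see [generate_network()]).
#' @param path File path.
#' @return \code{write_station_metadata}: \code{path} invisibly;
#'   \code{read_station_metadata}: the station data frame.
#' @export
write_station_metadata <- function(stations, path) {
  utils::write.csv(stations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_station_metadata
#' @export
read_station_metadata <- function(path) {
  st <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "name", "lon", "lat", "watershed", "position",
            "kind")
  missing <- setdiff(need, names(st))
  if (length(missing))
    stop("station metadata lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(st$position), c("upstream", "middle", "downstream"))
  if (length(bad))
    stop("invalid position values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  st
}
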