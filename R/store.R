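#' Monitoring-data store
#'
#' An in-memory store mirroring the surveillance database layout: a station
#' information table, per-kind station registries, and hydrology and
#' water-quality data tables keyed by (station_id, time). The backing
#' database of a deployment is an implementation detail; this store keeps
#' the five logical tables behind a small contract and can round-trip to a
#' directory of CSV files for persistence.
#'
#' @param path Optional directory; when given and existing, the store is
#'   loaded from it ([load_store()]).
#' @return An object of class \code{"wq_store"} (an environment).
#' @examples
#' store <- wq_store()
#' store_counts(store)
#' @export
wq_store <- function(path = NULL) {
  if (!is.null(path) && dir.exists(path)) return(load_store(path))
  e <- new.env(parent = emptyenv())
  e$stations <- data.frame(station_id = character(), name = character(),
                           lon = numeric(), lat = numeric(),
                           watershed = character(), position = character(),
                           kind = character(), stringsAsFactors = FALSE)
  e$hydrology_stations <- data.frame(station_id = character(),
                                     stringsAsFactors = FALSE)
  e$water_quality_stations <- data.frame(station_id = character(),
                                         stringsAsFactors = FALSE)
  e$hydrology_data <- NULL      # data frames created lazily on first insert
  e$water_quality_data <- NULL
  class(e) <- "wq_store"
  e
}

#' @export
print.wq_store <- function(x, ...) {
  n <- store_counts(x)
  cat("<wq_store>\n")
  cat(sprintf("  stations: %d (%d hydrology, %d water quality)\n",
              n["stations"], n["hydrology_stations"],
              n["water_quality_stations"]))
  cat(sprintf("  records : %d hydrology, %d water quality\n",
              n["hydrology_data"], n["water_quality_data"]))
  invisible(x)
}

#' Row counts of the five store tables
#' @param store A [wq_store()].
#' @return Named integer vector.
#' @export
store_counts <- function(store) {
  cnt <- function(x) if (is.null(x)) 0L else nrow(x)
  c(stations = nrow(store$stations),
    hydrology_stations = nrow(store$hydrology_stations),
    water_quality_stations = nrow(store$water_quality_stations),
    hydrology_data = cnt(store$hydrology_data),
    water_quality_data = cnt(store$water_quality_data))
}

.data_table_for <- function(kind) {
  if (kind == "hydrology") "hydrology_data" else "water_quality_data"
}

.station_table_for <- function(kind) {
  if (kind == "hydrology") "hydrology_stations"
  else "water_quality_stations"
}

# kind of a station as registered, else inferred from indicator columns
.station_kind <- function(store, station_id, record_cols = character()) {
  i <- match(station_id, store$stations$station_id)
  if (!is.na(i) && nzchar(store$stations$kind[i]))
    return(store$stations$kind[i])
  hyd <- wq_indicators()$indicator[wq_indicators()$category == "hydrology"]
  if (length(intersect(record_cols, hyd)) &&
      !length(setdiff(intersect(record_cols, .numeric_indicators()), hyd)))
    "hydrology" else "water_quality"
}

#' Retrieve stored records
#'
#' @param store A [wq_store()].
#' @param station_id Optional filter.
#' @param kind \code{"water_quality"} (default) or \code{"hydrology"}.
#' @return Record data frame sorted by station then time (zero rows if
#'   nothing stored).
#' @export
store_records <- function(store, station_id = NULL,
                          kind = c("water_quality", "hydrology")) {
  kind <- match.arg(kind)
  d <- store[[.data_table_for(kind)]]
  if (is.null(d))
    return(data.frame(station_id = character(),
                      time = as.POSIXct(character(), tz = "UTC"),
                      stringsAsFactors = FALSE))
  if (!is.null(station_id)) d <- d[d$station_id %in% station_id, ,
                                   drop = FALSE]
  d <- d[order(d$station_id, d$time), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Persist a store to (or load it from) a directory of CSV files
#'
#' One CSV per logical table; data-table timestamps are written in
#' \code{YYYY-MM-DD HH:MM} form.
#'
#' @param store A [wq_store()].
#' @param path Directory (created if needed).
#' @return \code{save_store}: \code{path} invisibly; \code{load_store}: a
#'   \code{wq_store}.
#' @export
save_store <- function(store, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("stations", "hydrology_stations", "water_quality_stations",
               "hydrology_data", "water_quality_data")) {
    d <- store[[tb]]
    if (is.null(d)) next
    if ("time" %in% names(d)) d$time <- format_wq_time(d$time)
    utils::write.csv(d, file.path(path, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  store <- wq_store()
  for (tb in c("stations", "hydrology_stations", "water_quality_stations",
               "hydrology_data", "water_quality_data")) {
    f <- file.path(path, paste0(tb, ".csv"))
    if (!file.exists(f)) next
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if ("time" %in% names(d)) d$time <- parse_wq_time(d$time)
    store[[tb]] <- d
  }
  store
}
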