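#' Build the forecast-model registry
#'
#' One forecast model is maintained per (watershed, sub-watershed
#' position, indicator) combination; all stations sharing a key pool
#' their data for that model's training. With the national default — 10
#' watersheds, three sub-watershed positions, seven modeled indicators —
#' the registry holds 210 keys. Keys whose sub-watershed has no station
#' are created but flagged untrainable.
#'
#' @param stations Station metadata (see [generate_network()]); duplicate
#'   rows are ignored.
#' @param indicators Indicator keys to model; default
#'   [modeled_indicators()].
#' @param watersheds Watershed names; defaults to those present in
#'   \code{stations}.
#' @return A data frame with one row per key: \code{watershed},
#'   \code{position}, \code{indicator}, \code{key}, \code{n_stations},
#'   \code{trainable}.
#' @examples
#' net <- generate_network(10, 1, seed = 7)
#' nrow(build_registry(net))  # 210
#' @export
build_registry <- function(stations, indicators = modeled_indicators(),
                           watersheds = NULL) {
  stations <- unique(stations)
  if (is.null(watersheds)) watersheds <- unique(stations$watershed)
  keys <- expand.grid(indicator = indicators,
                      position = c("upstream", "middle", "downstream"),
                      watershed = watersheds,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keys <- keys[, c("watershed", "position", "indicator")]
  keys$key <- paste(keys$watershed, keys$position, keys$indicator,
                    sep = "/")
  keys$n_stations <- vapply(seq_len(nrow(keys)), function(i)
    sum(stations$watershed == keys$watershed[i] &
          stations$position == keys$position[i]), 0L)
  keys$trainable <- keys$n_stations > 0L
  rownames(keys) <- NULL
  keys
}

#' Train forecasters for registry keys
#'
#' Fits one [wq_lstm()] per trainable registry key, pooling the stored
#' series of every station that shares the key. Keys without data (or
#' with too little) are skipped with a notice.
#'
#' @param store A [wq_store()] holding cleaned records.
#' @param registry Output of [build_registry()].
#' @param stations Station metadata mapping stations to keys.
#' @param keys Optional subset of \code{registry$key} to train.
#' @param min_length Minimum pooled series length required; default 120.
#' @param seed Root seed; each key trains under a derived child seed.
#' @param ... Passed to [wq_lstm()] (e.g. \code{units}, \code{epochs}).
#' @return Named list of \code{wq_lstm} fits, one per trained key.
#' @export
train_registry <- function(store, registry, stations, keys = NULL,
                           min_length = 120, seed = 1, ...) {
  if (is.null(keys)) keys <- registry$key[registry$trainable]
  fits <- list()
  for (k in keys) {
    row <- registry[registry$key == k, ]
    if (!nrow(row)) { message("unknown key skipped: ", k); next }
    sids <- stations$station_id[stations$watershed == row$watershed &
                                  stations$position == row$position]
    series <- list()
    for (sid in sids) {
      rec <- store_records(store, sid)
      if (nrow(rec) && row$indicator %in% names(rec)) {
        v <- rec[[row$indicator]][order(rec$time)]
        if (sum(!is.na(v)) >= min_length) series <- c(series, list(v))
      }
    }
    if (!length(series)) {
      message("no usable data for key ", k, "; skipped")
      next
    }
    fits[[k]] <- wq_lstm(series, seed = child_seed(seed, k), ...)
  }
  fits
}
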