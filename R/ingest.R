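#' Decide whether a payload carries new data
#'
#' The update judgment mirrors the crawl loop's measurement-time test: a
#' payload is new if its latest record timestamp for the station is strictly
#' newer than the latest already stored, or if the station is unknown (the
#' new-station path).
#'
#' @param payload Record data frame for one station (see
#'   [read_crawl_payload()]).
#' @param store A [wq_store()].
#' @return \code{TRUE} if cleaning and storing should proceed.
#' @export
detect_update <- function(payload, store) {
  sid <- unique(payload$station_id)
  kind <- .station_kind(store, sid, names(payload))
  stored <- store_records(store, sid, kind)
  if (!nrow(stored)) return(TRUE)
  max(payload$time) > max(stored$time)
}

#' Clean a batch of monitoring records
#'
#' Applies the feed-hygiene rules before storage: exact duplicates collapse
#' to one; records whose indicator values are all missing are dropped;
#' negative concentrations (for indicators measured in mg/L, NTU or
#' cells/L) are treated as missing for that indicator rather than
#' discarding the co-measured values; records sharing a (station, time) key
#' but disagreeing in values are resolved in favour of the later-parsed one
#' (a message notes the conflict). Output is sorted by station and time.
#' The operation is idempotent.
#'
#' @param records Record data frame.
#' @return Cleaned record data frame.
#' @export
clean_records <- function(records) {
  if (!nrow(records)) return(records)
  inds <- intersect(names(records), .numeric_indicators())
  for (ind in intersect(inds, .nonnegative_indicators())) {
    bad <- !is.na(records[[ind]]) & records[[ind]] < 0
    if (any(bad)) records[[ind]][bad] <- NA_real_
  }
  # exact duplicates -> one copy
  records <- records[!duplicated(records), , drop = FALSE]
  # same (station, time) key, different values: later-parsed wins
  key <- paste(records$station_id, format_wq_time(records$time))
  if (anyDuplicated(key)) {
    message(sprintf("clean_records: %d conflicting record(s) for a stored key; keeping the later-parsed value",
                    sum(duplicated(key))))
    records <- records[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  # null records: every indicator value missing
  if (length(inds)) {
    allna <- rowSums(!is.na(records[, inds, drop = FALSE])) == 0L
    records <- records[!allna, , drop = FALSE]
  }
  records <- records[order(records$station_id, records$time), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Insert cleaned records into the store
#'
#' Records with an unseen (station, time) key are inserted; keys already
#' present are skipped. Unknown stations are registered in the station
#' table (and the per-kind station registry) on first sight.
#'
#' @param records Cleaned record data frame (run [clean_records()] first;
#'   duplicate keys within the batch are an error).
#' @param store A [wq_store()]; modified in place.
#' @param station_meta Optional station metadata rows used when registering
#'   new stations.
#' @return Named integer vector \code{c(inserted, skipped)}.
#' @export
upsert_records <- function(records, store, station_meta = NULL) {
  if (!nrow(records)) return(c(inserted = 0L, skipped = 0L))
  key <- paste(records$station_id, format_wq_time(records$time))
  if (anyDuplicated(key))
    stop("batch contains duplicate (station, time) keys; clean it first",
         call. = FALSE)
  inserted <- 0L; skipped <- 0L
  for (sid in unique(records$station_id)) {
    rows <- records[records$station_id == sid, , drop = FALSE]
    kind <- .station_kind(store, sid, names(rows))
    if (!sid %in% store$stations$station_id) {
      meta <- if (!is.null(station_meta) &&
                  sid %in% station_meta$station_id)
        station_meta[station_meta$station_id == sid, , drop = FALSE]
      else data.frame(station_id = sid, name = sid, lon = NA_real_,
                      lat = NA_real_, watershed = NA_character_,
                      position = NA_character_, kind = kind,
                      stringsAsFactors = FALSE)
      store$stations <- rbind(store$stations, meta[, names(store$stations)])
      reg <- .station_table_for(kind)
      store[[reg]] <- rbind(store[[reg]],
                            data.frame(station_id = sid,
                                       stringsAsFactors = FALSE))
    }
    tbl <- .data_table_for(kind)
    old <- store[[tbl]]
    if (is.null(old)) {
      store[[tbl]] <- rows
      inserted <- inserted + nrow(rows)
      next
    }
    oldkey <- paste(old$station_id, format_wq_time(old$time))
    newkey <- paste(rows$station_id, format_wq_time(rows$time))
    fresh <- !(newkey %in% oldkey)
    skipped <- skipped + sum(!fresh)
    if (any(fresh)) {
      add <- rows[fresh, , drop = FALSE]
      allcols <- union(names(old), names(add))
      for (cc in setdiff(allcols, names(old))) old[[cc]] <- NA_real_
      for (cc in setdiff(allcols, names(add))) add[[cc]] <- NA_real_
      store[[tbl]] <- rbind(old[, allcols], add[, allcols])
      inserted <- inserted + nrow(add)
    }
  }
  c(inserted = inserted, skipped = skipped)
}

#' Poll a feed directory and ingest fresh payloads
#'
#' Stands in for the crawl trigger loop: every \code{*.json} payload in the
#' directory is parsed in lexicographic filename order; the update judgment
#' ([detect_update()]) gates cleaning and storing. Malformed payloads are
#' logged and skipped, never fatal.
#'
#' @param feed_dir Directory of payload files.
#' @param store A [wq_store()]; modified in place.
#' @param station_meta Optional station metadata for new-station
#'   registration.
#' @return A data frame with one row per payload file: \code{file},
#'   \code{status} (\code{"ingested"}, \code{"unchanged"}, \code{"error"}),
#'   \code{inserted}, \code{skipped}.
#' @export
poll_feed <- function(feed_dir, store, station_meta = NULL) {
  if (!dir.exists(feed_dir))
    stop(sprintf("feed directory '%s' does not exist", feed_dir),
         call. = FALSE)
  files <- sort(list.files(feed_dir, pattern = "\\.json$",
                           full.names = TRUE))
  out <- lapply(files, function(f) {
    res <- tryCatch({
      payload <- read_crawl_payload(f)
      if (!detect_update(payload, store))
        return(data.frame(file = basename(f), status = "unchanged",
                          inserted = 0L, skipped = 0L,
                          stringsAsFactors = FALSE))
      sm <- upsert_records(clean_records(payload), store, station_meta)
      data.frame(file = basename(f), status = "ingested",
                 inserted = sm[["inserted"]], skipped = sm[["skipped"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message(sprintf("poll_feed: skipping '%s': %s", basename(f),
                      conditionMessage(e)))
      data.frame(file = basename(f), status = "error", inserted = 0L,
                 skipped = 0L, stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
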