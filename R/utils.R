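# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream-specific child seed from a root seed; stays below 2^31.
child_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

#' @importFrom stats rnorm runif sd approx
NULL

.time_format <- "%Y-%m-%d %H:%M"

#' Format or parse feed timestamps
#'
#' Monitoring timestamps travel as timezone-naive whole-hour strings,
#' \code{"YYYY-MM-DD HH:MM"}; internally they are POSIXct in UTC.
#'
#' @param t POSIXct vector.
#' @param s Character vector of timestamps.
#' @return \code{format_wq_time}: character; \code{parse_wq_time}:
#'   POSIXct.
#' @export
format_wq_time <- function(t) format(t, .time_format, tz = "UTC")

#' @rdname format_wq_time
#' @export
parse_wq_time <- function(s) as.POSIXct(s, format = .time_format, tz = "UTC")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
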