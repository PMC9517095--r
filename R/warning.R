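#' Raise pollution early warnings from graded predictions
#'
#' Scans a table of predicted indicator values: every (station, time,
#' indicator) whose predicted class is strictly worse than the target
#' class becomes a warning event carrying a rendered message. When any
#' event exists and an outbox directory is given, a Markdown warning
#' report is written there (the stand-in for mailing the administrator).
#'
#' @param predictions Data frame with columns \code{station_id},
#'   \code{time}, \code{indicator}, \code{value}.
#' @param scheme A [grading_scheme()].
#' @param target_class Attainment target; default \code{"III"}.
#' @param outbox Optional directory for the warning report.
#' @return Data frame of warning events (zero rows when water quality is
#'   within target everywhere): \code{station_id}, \code{time},
#'   \code{indicator}, \code{value}, \code{predicted_class},
#'   \code{target_class}, \code{message}. The report path, if written, is
#'   attached as attribute \code{"report"}.
#' @export
raise_warnings <- function(predictions, scheme, target_class = "III",
                           outbox = NULL) {
  need <- c("station_id", "time", "indicator", "value")
  missing <- setdiff(need, names(predictions))
  if (length(missing))
    stop("predictions lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  target <- .class_factor(target_class)
  if (is.na(target)) stop("unknown target class", call. = FALSE)
  cls <- rep(.class_factor(NA), nrow(predictions))
  for (ind in unique(predictions$indicator)) {
    k <- predictions$indicator == ind
    cls[k] <- grade_value(ind, predictions$value[k], scheme)
  }
  hit <- !is.na(cls) & cls > target
  ev <- predictions[hit, need, drop = FALSE]
  ev$predicted_class <- as.character(cls[hit])
  ev$target_class <- rep(as.character(target), nrow(ev))
  ev$message <- sprintf(
    "station %s: predicted %s = %.3g at %s grades class %s, worse than target %s",
    ev$station_id, ev$indicator, ev$value, format_wq_time(ev$time),
    ev$predicted_class, ev$target_class)
  ev <- ev[order(ev$station_id, ev$time, ev$indicator), , drop = FALSE]
  rownames(ev) <- NULL
  if (nrow(ev) && !is.null(outbox)) {
    dir.create(outbox, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outbox, sprintf("warning-report-%s.md",
                                      format(min(ev$time), "%Y%m%d")))
    lines <- c("# Water pollution warning report", "",
               sprintf("Target class: %s. %d exceedance(s) predicted.",
                       target, nrow(ev)), "",
               paste0("- ", ev$message))
    writeLines(lines, path)
    attr(ev, "report") <- path
  }
  ev
}

#' Build a water-quality assessment report
#'
#' Runs the three assessment analyses — attainment against the target
#' class, class category proportions, and the link relative ratio of
#' period means per indicator — over a span of stored records, in annual,
#' monthly or custom period resolution.
#'
#' @param records Record data frame (must carry \code{time} and at least
#'   one gradable indicator column).
#' @param scheme A [grading_scheme()].
#' @param mode \code{"monthly"} (default), \code{"annual"} or
#'   \code{"custom"}.
#' @param target_class Attainment target; default \code{"III"}.
#' @param indicators Indicators to tabulate; default: every gradable
#'   column present.
#' @param period_format For \code{mode = "custom"}: a \code{format()}
#'   template grouping timestamps into periods (e.g. \code{"\%Y-W\%U"}).
#' @return An object of class \code{"wq_report"}: a list with
#'   \code{scope}, \code{grades}, \code{attainment},
#'   \code{category_proportions} and \code{link_relative_ratio} (one table
#'   per indicator).
#' @export
build_report <- function(records, scheme,
                         mode = c("monthly", "annual", "custom"),
                         target_class = "III", indicators = NULL,
                         period_format = "%Y-%m") {
  mode <- match.arg(mode)
  if (!nrow(records)) stop("empty record range", call. = FALSE)
  fmt <- switch(mode, monthly = "%Y-%m", annual = "%Y",
                custom = period_format)
  gradable <- names(Filter(function(e) e$direction != "none",
                           scheme$indicators))
  if (is.null(indicators))
    indicators <- intersect(names(records), gradable)
  if (!length(indicators))
    stop("no gradable indicator selected", call. = FALSE)
  sub <- records[, c("station_id", "time", indicators), drop = FALSE]
  grades <- grade_record(sub, scheme)
  periods <- format(records$time, fmt, tz = "UTC")
  lrr <- lapply(stats::setNames(indicators, indicators), function(ind) {
    v <- records[[ind]]
    if (length(unique(periods[!is.na(v)])) < 2L) return(NULL)
    link_relative_ratio(v, periods)
  })
  structure(list(
    scope = list(mode = mode, target_class = target_class,
                 indicators = indicators,
                 from = min(records$time), to = max(records$time),
                 stations = unique(records$station_id),
                 n_records = nrow(records)),
    grades = grades,
    attainment = attainment(grades, target_class),
    category_proportions = category_proportions(grades),
    link_relative_ratio = Filter(Negate(is.null), lrr)),
    class = "wq_report")
}

#' @export
print.wq_report <- function(x, ...) {
  s <- x$scope
  cat(sprintf("Water-quality report (%s), %s to %s\n", s$mode,
              format_wq_time(s$from), format_wq_time(s$to)))
  cat(sprintf("  %d records, %d station(s), indicators: %s\n",
              s$n_records, length(s$stations),
              paste(s$indicators, collapse = ", ")))
  cat(sprintf("  attainment (target %s): %.1f%%\n", s$target_class,
              100 * x$attainment))
  cat("  category proportions:\n")
  print(round(x$category_proportions, 3))
  for (ind in names(x$link_relative_ratio)) {
    cat(sprintf("  link relative ratio, %s:\n", ind))
    print(x$link_relative_ratio[[ind]], row.names = FALSE)
  }
  invisible(x)
}

#' Write a report as Markdown with CSV side tables
#'
#' @param report A [build_report()] object.
#' @param path Output Markdown file; CSV tables are written alongside it.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  s <- report$scope
  stem <- sub("\\.md$", "", path)
  props <- report$category_proportions
  lines <- c(
    sprintf("# Water-quality report (%s)", s$mode), "",
    sprintf("Span: %s to %s; %d records over %d station(s).",
            format_wq_time(s$from), format_wq_time(s$to), s$n_records,
            length(s$stations)),
    sprintf("Indicators: %s.", paste(s$indicators, collapse = ", ")), "",
    sprintf("## Attainment (target class %s)", s$target_class), "",
    sprintf("%.1f%% of records meet the target.", 100 * report$attainment),
    "", "## Category proportions", "",
    "| class | proportion |", "|---|---|",
    sprintf("| %s | %.3f |", names(props), props), "")
  for (ind in names(report$link_relative_ratio)) {
    tb <- report$link_relative_ratio[[ind]]
    f <- paste0(stem, "-lrr-", ind, ".csv")
    utils::write.csv(tb, f, row.names = FALSE)
    lines <- c(lines, sprintf("## Link relative ratio: %s", ind), "",
               "| period | mean | change (%) |", "|---|---|---|",
               sprintf("| %s | %.4g | %s |", tb$period, tb$mean,
                       ifelse(is.na(tb$change_pct), "-",
                              sprintf("%+.1f", tb$change_pct))), "")
  }
  writeLines(lines, path)
  invisible(path)
}
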