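#' Water-quality class labels
#'
#' The six surface-water classes in order of worsening quality: I-V plus
#' inferior-V ("worse than class V", sometimes displayed as level VI).
#'
#' @return Character vector of the six labels, best first.
#' @export
wq_classes <- function() c("I", "II", "III", "IV", "V", "inferior-V")

.class_factor <- function(x) {
  factor(x, levels = wq_classes(), ordered = TRUE)
}

#' Construct a grading scheme
#'
#' A grading scheme maps indicator concentrations to the six
#' water-quality classes. Each indicator carries a direction and, for the
#' threshold directions, five class boundaries (upper limits of classes
#' I-V for \code{higher_is_worse}; lower limits for
#' \code{lower_is_worse}, e.g. dissolved oxygen). \code{range} indicators
#' (pH) have a two-sided acceptable interval: in range grades I,
#' out of range inferior-V. \code{none} marks an indicator that carries no
#' class limits (e.g. water temperature) and is skipped by grading.
#' Boundary values grade into the better class (inclusive bounds).
#'
#' @param ... Named per-indicator entries, each a list with
#'   \code{direction} and \code{boundaries}.
#' @return An object of class \code{"grading_scheme"}.
#' @examples
#' sch <- grading_scheme(
#'   COD_Mn = list(direction = "higher_is_worse",
#'                 boundaries = c(2, 4, 6, 10, 15)))
#' grade_value("COD_Mn", 5, sch)  # III
#' @export
grading_scheme <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) &&
      is.list(entries[[1L]][[1L]]))
    entries <- entries[[1L]]
  for (nm in names(entries)) {
    e <- entries[[nm]]
    dir <- e$direction
    if (!dir %in% c("higher_is_worse", "lower_is_worse", "range", "none"))
      stop(sprintf("'%s': unknown direction '%s'", nm, dir), call. = FALSE)
    b <- e$boundaries
    # ties are allowed: some standards give two classes the same limit
    # (e.g. BOD5 classes I and II), which makes the tied better class
    # absorb the boundary value
    if (dir == "higher_is_worse" &&
        (length(b) != 5L || any(diff(b) < 0)))
      stop(sprintf("'%s': need 5 non-decreasing boundaries", nm),
           call. = FALSE)
    if (dir == "lower_is_worse" &&
        (length(b) != 5L || any(diff(b) > 0)))
      stop(sprintf("'%s': need 5 non-increasing boundaries", nm),
           call. = FALSE)
    if (dir == "range" && (length(b) != 2L || b[1L] >= b[2L]))
      stop(sprintf("'%s': range needs boundaries c(lo, hi)", nm),
           call. = FALSE)
  }
  structure(list(indicators = entries), class = "grading_scheme")
}

#' @export
print.grading_scheme <- function(x, ...) {
  cat("Water-quality grading scheme\n")
  for (nm in names(x$indicators)) {
    e <- x$indicators[[nm]]
    cat(sprintf("  %-8s %-16s %s\n", nm, e$direction,
                paste(e$boundaries, collapse = " ")))
  }
  invisible(x)
}

#' Read or write a grading-scheme configuration file
#'
#' The configuration is a plain-text file, one indicator per line:
#' \code{indicator: direction b1 b2 ...}; blank lines and \code{#}
#' comments are ignored.
#'
#' @param path File path.
#' @param scheme A [grading_scheme()].
#' @return \code{read_grading_scheme}: a \code{grading_scheme};
#'   \code{write_grading_scheme}: \code{path} invisibly.
#' @export
read_grading_scheme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[:[:space:]]+")[[1L]]
    parts <- parts[nzchar(parts)]
    entries[[parts[1L]]] <- list(
      direction = parts[2L],
      boundaries = if (length(parts) > 2L)
        as.numeric(parts[-(1:2)]) else numeric())
  }
  grading_scheme(entries)
}

#' @rdname read_grading_scheme
#' @export
write_grading_scheme <- function(scheme, path) {
  lines <- vapply(names(scheme$indicators), function(nm) {
    e <- scheme$indicators[[nm]]
    paste(c(paste0(nm, ":"), e$direction, e$boundaries), collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Default grading scheme (GB 3838-2002 surface-water limits)
#'
#' Reads the configuration shipped with the package, populated with the
#' Chinese surface-water environmental-quality class limits (river values
#' for total phosphorus). Water temperature and turbidity carry no class
#' boundaries there and are marked \code{none}.
#'
#' @return A [grading_scheme()].
#' @export
default_grading_scheme <- function() {
  read_grading_scheme(system.file("extdata", "gb3838_scheme.cfg",
                                  package = "wqwatch", mustWork = TRUE))
}

#' Grade indicator values into water-quality classes
#'
#' Assigns each value the best (lowest-numbered) class whose limit it
#' meets; values beyond the class-V limit grade inferior-V. Boundary
#' values grade into the better class. Range-type indicators grade I in
#' range and inferior-V (non-attainment) outside. Missing values grade
#' \code{NA}.
#'
#' @param indicator Indicator key present in the scheme.
#' @param value Numeric vector.
#' @param scheme A [grading_scheme()].
#' @return Ordered factor over [wq_classes()] (all \code{NA} for a
#'   \code{none}-direction indicator).
#' @export
grade_value <- function(indicator, value, scheme) {
  e <- scheme$indicators[[indicator]]
  if (is.null(e))
    stop(sprintf("indicator '%s' not in grading scheme", indicator),
         call. = FALSE)
  cls <- rep(NA_character_, length(value))
  ok <- !is.na(value)
  if (e$direction == "higher_is_worse") {
    idx <- vapply(value[ok], function(v) sum(v > e$boundaries) + 1L, 0L)
    cls[ok] <- wq_classes()[idx]
  } else if (e$direction == "lower_is_worse") {
    idx <- vapply(value[ok], function(v) sum(v < e$boundaries) + 1L, 0L)
    cls[ok] <- wq_classes()[idx]
  } else if (e$direction == "range") {
    cls[ok] <- ifelse(value[ok] >= e$boundaries[1L] &
                        value[ok] <= e$boundaries[2L],
                      "I", "inferior-V")
  }
  .class_factor(cls)
}

#' Overall class of monitoring records
#'
#' Single-factor evaluation: a record's overall class is the worst class
#' over its gradable indicators.
#'
#' @param records Record data frame (indicator columns) or a single
#'   record row.
#' @param scheme A [grading_scheme()].
#' @return Ordered factor of overall classes, one per record row.
#' @export
grade_record <- function(records, scheme) {
  inds <- intersect(names(records), names(scheme$indicators))
  inds <- inds[vapply(inds, function(i)
    scheme$indicators[[i]]$direction != "none", TRUE)]
  if (!length(inds))
    stop("no gradable indicator column in records", call. = FALSE)
  per <- vapply(inds, function(i)
    as.integer(grade_value(i, records[[i]], scheme)),
    integer(nrow(records)))
  per <- matrix(per, nrow = nrow(records))
  worst <- apply(per, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else max(r, na.rm = TRUE))
  .class_factor(wq_classes()[worst])
}

#' Attainment rate against a target class
#'
#' Fraction of graded records whose class meets (is no worse than) the
#' target class.
#'
#' @param grades Ordered factor (or character) of classes, e.g. from
#'   [grade_record()]; \code{NA} grades are dropped.
#' @param target_class Target class label; default \code{"III"}.
#' @return Proportion in \[0, 1\].
#' @export
attainment <- function(grades, target_class = "III") {
  g <- .class_factor(as.character(grades))
  g <- g[!is.na(g)]
  if (!length(g)) stop("no graded records", call. = FALSE)
  target <- .class_factor(target_class)
  if (is.na(target)) stop("unknown target class", call. = FALSE)
  mean(g <= target)
}

#' Proportion of records in each water-quality class
#'
#' @param grades Ordered factor (or character) of classes; \code{NA}
#'   dropped.
#' @return Named numeric vector over the six classes, summing to 1.
#' @export
category_proportions <- function(grades) {
  g <- .class_factor(as.character(grades))
  g <- g[!is.na(g)]
  if (!length(g)) stop("no graded records", call. = FALSE)
  p <- as.vector(table(g)) / length(g)
  stats::setNames(p, wq_classes())
}

#' Link relative ratio of period means
#'
#' Percent change of each period's mean relative to the immediately
#' preceding period: \code{100 * (m_t - m_(t-1)) / m_(t-1)}. A zero
#' previous-period mean leaves that comparison undefined (\code{NA}, with
#' a warning).
#'
#' @param values Numeric vector.
#' @param periods Period labels aligned with \code{values} (e.g.
#'   \code{"2021-03"}); periods compare in sorted label order.
#' @return Data frame with \code{period}, \code{mean} and
#'   \code{change_pct} (\code{NA} for the first period).
#' @examples
#' link_relative_ratio(c(4, 4, 2, 2, 3, 3),
#'                     rep(c("P1", "P2", "P3"), each = 2))
#' @export
link_relative_ratio <- function(values, periods) {
  if (length(values) != length(periods))
    stop("`values` and `periods` differ in length", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]; periods <- as.character(periods)[keep]
  labs <- sort(unique(periods))
  if (length(labs) < 2L)
    stop("need at least 2 periods", call. = FALSE)
  means <- vapply(labs, function(p) mean(values[periods == p]), 0)
  prev <- c(NA, means[-length(means)])
  if (any(prev == 0, na.rm = TRUE))
    warning("zero previous-period mean: change undefined for that pair")
  chg <- ifelse(is.na(prev) | prev == 0, NA_real_,
                100 * (means - prev) / prev)
  data.frame(period = labs, mean = unname(means),
             change_pct = unname(chg), stringsAsFactors = FALSE)
}
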