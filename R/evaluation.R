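#' Nash-Sutcliffe efficiency
#'
#' NSE = 1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2). A perfect
#' simulation scores 1; predicting the observed mean everywhere scores 0;
#' values below 0 are worse than the mean predictor.
#'
#' @param observed,simulated Numeric vectors of equal length (>= 2).
#' @return A single numeric value, at most 1.
#' @examples
#' nse(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' @export
nse <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("`observed` and `simulated` differ in length", call. = FALSE)
  if (length(observed) < 2L)
    stop("need at least 2 paired observations", call. = FALSE)
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0)
    stop("NSE undefined for constant observations", call. = FALSE)
  1 - sum((observed - simulated)^2) / denom
}

#' Cross-correlation of predictions against observations
#'
#' The scalar skill score reported for every forecaster: by default the
#' lag-0 product-moment correlation ([cor_pearson()]); any of the
#' dependence metrics may be substituted.
#'
#' @param observed,simulated Numeric vectors of equal length.
#' @param metric One of \code{"pearson"}, \code{"cosine"}, \code{"dcor"},
#'   \code{"mic"}.
#' @return A single numeric value.
#' @export
cc <- function(observed, simulated,
               metric = c("pearson", "cosine", "dcor", "mic")) {
  metric <- match.arg(metric)
  f <- switch(metric, pearson = cor_pearson, cosine = cor_cosine,
              dcor = cor_dcor, mic = cor_mic)
  f(observed, simulated)
}

#' Acceptability verdict for a CC value
#'
#' A model is rated \code{"very_good"} when CC >= 0.75, \code{"acceptable"}
#' when CC >= 0.65, and \code{"unacceptable"} below that; both thresholds
#' are inclusive.
#'
#' @param cc_value Numeric in \[-1, 1\] (vectorized).
#' @return Character vector of verdicts.
#' @examples
#' cc_verdict(c(0.8, 0.7, 0.64))
#' @export
cc_verdict <- function(cc_value) {
  if (any(is.na(cc_value)) || any(cc_value < -1 | cc_value > 1))
    stop("`cc_value` must lie in [-1, 1]", call. = FALSE)
  ifelse(cc_value >= 0.75, "very_good",
         ifelse(cc_value >= 0.65, "acceptable", "unacceptable"))
}

#' Evaluation report for trained forecasters
#'
#' Collects per-split CC, NSE and verdicts of one or more fits into a
#' single table, the shape used for registry-wide skill summaries.
#'
#' @param fits A \code{wq_lstm} fit or a named list of them (as from
#'   [train_registry()]).
#' @return Data frame with columns \code{key}, \code{split}, \code{n},
#'   \code{CC}, \code{NSE}, \code{verdict}.
#' @export
evaluate_models <- function(fits) {
  if (inherits(fits, "wq_lstm")) fits <- list(model = fits)
  out <- lapply(names(fits), function(k) {
    m <- fits[[k]]$metrics
    cbind(data.frame(key = k, stringsAsFactors = FALSE), m)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Box plot of CC distributions per indicator
#'
#' Mirrors the registry-skill display: one box per indicator showing the
#' distribution of per-model CC values, with the acceptability threshold
#' (0.65) drawn as a dashed reference line.
#'
#' @param report An [evaluate_models()] table whose \code{key} ends in the
#'   indicator (\code{.../indicator}), or a data frame with
#'   \code{indicator} and \code{CC} columns.
#' @param split Which split to display; default \code{"test"}.
#' @param ... Passed to [graphics::boxplot()].
#' @return The report subset plotted, invisibly.
#' @export
plot_cc_distribution <- function(report, split = "test", ...) {
  if (!"indicator" %in% names(report))
    report$indicator <- vapply(strsplit(report$key, "/"),
                               function(p) p[length(p)], "")
  if ("split" %in% names(report))
    report <- report[report$split == split, , drop = FALSE]
  graphics::boxplot(CC ~ indicator, data = report, ylab = "CC",
                    xlab = "indicator", ...)
  graphics::abline(h = 0.65, lty = 2, col = "red")
  invisible(report)
}
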