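#' Dependence metrics for input-variable screening
#'
#' Four scalar dependence measures used by the lagged correlation scan:
#' the product-moment (Pearson) correlation, cosine similarity, Szekely's
#' distance correlation, and the maximal information coefficient (MIC).
#' Pearson and cosine are signed in \[-1, 1\]; distance correlation and MIC
#' lie in \[0, 1\].
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single numeric value.
#' @name dependence-metrics
NULL

#' @describeIn dependence-metrics Product-moment correlation; errors on
#'   constant input (the correlation is undefined there) and requires
#'   length >= 3.
#' @examples
#' cor_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' cor_cosine(c(3, 4), c(4, 3))               # 0.96
#' @export
cor_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations",
                           call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant series", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' @describeIn dependence-metrics Cosine similarity, the inner product over
#'   the product of Euclidean norms; errors on a zero vector.
#' @export
cor_cosine <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length",
                                   call. = FALSE)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  sum(x * y) / (nx * ny)
}

#' @describeIn dependence-metrics Distance correlation from double-centered
#'   pairwise-distance matrices; returns 0 when the product of distance
#'   variances is 0 (e.g. a constant series). Requires length >= 4.
#' @export
cor_dcor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations", call. = FALSE)
  A <- .dcenter(abs(outer(x, x, "-")))
  B <- .dcenter(abs(outer(y, y, "-")))
  dcov2_xy <- mean(A * B)
  dvar2_x <- mean(A * A)
  dvar2_y <- mean(B * B)
  denom <- dvar2_x * dvar2_y
  if (denom <= 0) return(0)
  v <- dcov2_xy / sqrt(denom)
  sqrt(max(v, 0))
}

# double-center a distance matrix: subtract row and column means, add the
# grand mean
.dcenter <- function(d) {
  rm_ <- rowMeans(d); cm_ <- colMeans(d); gm <- mean(d)
  d - outer(rm_, rep(1, ncol(d))) - outer(rep(1, nrow(d)), cm_) + gm
}

#' @describeIn dependence-metrics Maximal information coefficient: the
#'   maximum over grid partitions (nx, ny), with nx * ny < n^0.6 cells, of
#'   the empirical mutual information (log base 2) normalized by
#'   log2(min(nx, ny)). Partitions are equal-frequency in each variable.
#'   Requires length >= 8.
#' @export
cor_mic <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 8L) stop("need at least 8 paired observations", call. = FALSE)
  bound <- n^0.6
  best <- 0
  nx_max <- floor((bound - 1e-9) / 2)   # strict: nx * ny < n^0.6
  if (nx_max >= 2) {
    for (nx in 2:nx_max) {
      ny_max <- floor((bound - 1e-9) / nx)
      if (ny_max < 2) next
      for (ny in 2:ny_max) {
        mi <- .grid_mi(x, y, nx, ny)
        v <- mi / log2(min(nx, ny))
        if (v > best) best <- v
      }
    }
  }
  min(best, 1)
}

# equal-frequency binning of a vector into k bins (ties broken by order)
.equifreq_bins <- function(v, k) {
  r <- rank(v, ties.method = "first")
  as.integer(ceiling(r * k / length(v)))
}

# empirical mutual information (bits) of an nx-by-ny equifrequency grid
.grid_mi <- function(x, y, nx, ny) {
  bx <- .equifreq_bins(x, nx)
  by <- .equifreq_bins(y, ny)
  n <- length(x)
  joint <- table(bx, by) / n
  px <- rowSums(joint); py <- colSums(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(px) + h(py) - h(as.vector(joint))
}

#' Lagged dependence scan between two series
#'
#' Evaluates a dependence metric between a candidate series and a target
#' over lags k = 1..K: at lag k the pair is the candidate shifted back k
#' steps against the target, i.e. \code{metric(x[1:(n-k)], y[(k+1):n])},
#' truncating to the overlap (never padding). The lag with the largest
#' absolute value is reported as \code{best_lag}.
#'
#' @param x Candidate (possible input) series.
#' @param y Target series.
#' @param K Maximum lag in sampling steps; default 12.
#' @param metric One of \code{"pearson"}, \code{"cosine"}, \code{"dcor"},
#'   \code{"mic"}.
#' @return An object of class \code{"lag_scan"}: a list with \code{metric},
#'   \code{lags}, \code{values} (length K) and \code{best_lag}.
#' @examples
#' x <- sin(seq(0, 20, by = 0.25))
#' y <- c(rep(NA, 3), head(x, -3))      # y_t = x_{t-3}
#' s <- lag_scan(x[-(1:3)], y[-(1:3)], K = 6)
#' s$best_lag
#' @export
lag_scan <- function(x, y, K = 12,
                     metric = c("pearson", "cosine", "dcor", "mic")) {
  metric <- match.arg(metric)
  n <- length(x)
  if (length(y) != n) stop("`x` and `y` differ in length", call. = FALSE)
  min_len <- switch(metric, pearson = 3L, cosine = 2L, dcor = 4L, mic = 8L)
  if (K >= n - min_len + 1L)
    stop("series too short for K lags", call. = FALSE)
  f <- switch(metric, pearson = cor_pearson, cosine = cor_cosine,
              dcor = cor_dcor, mic = cor_mic)
  vals <- vapply(seq_len(K), function(k) {
    f(x[seq_len(n - k)], y[(k + 1L):n])
  }, 0)
  structure(list(metric = metric, lags = seq_len(K), values = vals,
                 best_lag = which.max(abs(vals))),
            class = "lag_scan")
}

#' @export
print.lag_scan <- function(x, ...) {
  cat(sprintf("Lag scan (%s), lags 1..%d\n", x$metric, length(x$lags)))
  print(round(stats::setNames(x$values, paste0("k=", x$lags)), 4))
  cat(sprintf("best lag: %d (|%s| = %.4f)\n", x$best_lag, x$metric,
              abs(x$values[x$best_lag])))
  invisible(x)
}

#' Select model input variables by lagged correlation
#'
#' Screens candidate indicators against a forecast target: each candidate
#' is lag-scanned and kept when its best absolute dependence value reaches
#' the threshold. Selected candidates are ordered by descending score, and
#' the target's own history is always the first input.
#'
#' @param data Data frame of aligned indicator series (one column per
#'   indicator).
#' @param target Name of the target column.
#' @param candidates Candidate column names; defaults to every other
#'   numeric column. May be empty, giving a history-only model.
#' @param threshold Minimum best absolute metric value; default 0.3.
#' @param K Maximum lag; default 12.
#' @param metric Dependence metric, as in [lag_scan()].
#' @return A data frame with one row per selected input: \code{input},
#'   \code{best_lag}, \code{score} (the target-history row carries
#'   \code{NA}).
#' @export
select_inputs <- function(data, target, candidates = NULL, threshold = 0.3,
                          K = 12, metric = "pearson") {
  if (!target %in% names(data))
    stop(sprintf("target '%s' not in data", target), call. = FALSE)
  if (is.null(candidates))
    candidates <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                          target)
  y <- data[[target]]
  rows <- lapply(candidates, function(cand) {
    s <- lag_scan(data[[cand]], y, K = K, metric = metric)
    data.frame(input = cand, best_lag = s$best_lag,
               score = abs(s$values[s$best_lag]),
               stringsAsFactors = FALSE)
  })
  scans <- do.call(rbind, rows)
  keep <- if (is.null(scans)) NULL else
    scans[scans$score >= threshold, , drop = FALSE]
  if (!is.null(keep) && nrow(keep))
    keep <- keep[order(-keep$score), , drop = FALSE]
  out <- rbind(data.frame(input = target, best_lag = NA_integer_,
                          score = NA_real_, stringsAsFactors = FALSE),
               keep)
  rownames(out) <- NULL
  out
}
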