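#' Standardization for model inputs
#'
#' Forecast models train on z-scored values; the scaler (mean and standard
#' deviation) is always fitted on the training split only and reused,
#' unchanged, on validation and test data.
#'
#' @param x Numeric vector.
#' @param name Label used in error messages (e.g. the indicator).
#' @param scaler A scaler returned by \code{fit_scaler}.
#' @return \code{fit_scaler}: a list with \code{mean}, \code{sd},
#'   \code{name}; \code{standardize} / \code{inverse_standardize}: the
#'   transformed vector.
#' @examples
#' sc <- fit_scaler(c(2, 4, 6), "DO")
#' inverse_standardize(standardize(c(2, 4, 6), sc), sc)
#' @export
fit_scaler <- function(x, name = "series") {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0)
    stop(sprintf("cannot standardize '%s': zero variance", name),
         call. = FALSE)
  list(mean = m, sd = s, name = name)
}

#' @rdname fit_scaler
#' @export
standardize <- function(x, scaler) (x - scaler$mean) / scaler$sd

#' @rdname fit_scaler
#' @export
inverse_standardize <- function(x, scaler) x * scaler$sd + scaler$mean

#' Sliding supervised windows from a series
#'
#' Maps a series (optionally with exogenous input columns) to supervised
#' pairs: L consecutive steps of inputs predicting the following H values
#' of the first column. The window count is \code{n - L - H + 1}. Windows
#' touching a missing value are dropped rather than imputed (gaps left by
#' cleaning are real).
#'
#' @param series Numeric vector, or matrix whose first column is the
#'   forecast target.
#' @param L Lookback length (steps).
#' @param H Forecast horizon (steps ahead); default 1.
#' @return A list: \code{X}, an (n_windows x L x D) array; \code{y}, a
#'   vector (H = 1) or matrix of targets; \code{target_index}, the series
#'   index of each window's first target.
#' @export
make_windows <- function(series, L, H = 1) {
  if (is.vector(series)) series <- matrix(series, ncol = 1)
  n <- nrow(series)
  if (n <= L + H - 1L)
    stop(sprintf("series length %d too short for lookback %d + horizon %d",
                 n, L, H), call. = FALSE)
  n_w <- n - L - H + 1L
  D <- ncol(series)
  X <- array(NA_real_, c(n_w, L, D))
  ymat <- matrix(NA_real_, n_w, H)
  for (w in seq_len(n_w)) {
    X[w, , ] <- series[w:(w + L - 1L), , drop = FALSE]
    ymat[w, ] <- series[(w + L):(w + L + H - 1L), 1L]
  }
  ok <- apply(X, 1, function(m) !anyNA(m)) & !apply(ymat, 1, anyNA)
  X <- X[ok, , , drop = FALSE]
  ymat <- ymat[ok, , drop = FALSE]
  list(X = X, y = if (H == 1L) drop(ymat) else ymat,
       target_index = (L + seq_len(n_w))[ok])
}

# chronological segment boundaries for one series of length n
.split_bounds <- function(n, split) {
  n_train <- floor(split[1] * n)
  n_val <- floor(split[2] * n)
  c(train_end = n_train, val_end = n_train + n_val)
}

#' Fit an LSTM forecaster
#'
#' The central fitting function of the package: a single-layer LSTM
#' regression on sliding windows of a (standardized) indicator series,
#' predicting one step ahead. The network's read-out is parameterized as
#' the one-step increment — the forecast is the last observed value plus
#' the predicted change — so an untrained network starts at the
#' persistence forecast and training models the correction. The series is
#' split chronologically into training, validation and test segments; the
#' scaler is fitted on the training segment only, and the weights kept are
#' those of the epoch with the lowest validation error (a checkpoint
#' against overfitting). When \code{units} or \code{lookback} have length
#' greater than one, every combination is fitted and the configuration
#' with the best validation cross-correlation is kept (the default grid is
#' units 16 and 32 by lookback 8 and 16). Several series may be pooled —
#' e.g. all stations of one sub-watershed — by passing a list; windows
#' never straddle series boundaries and each pooled series is split
#' chronologically on its own.
#'
#' @param y Numeric series (original units), or a list of such series to
#'   pool.
#' @param xreg Optional exogenous input matrix (or list of matrices,
#'   matching \code{y}), same number of rows as \code{y}.
#' @param lookback Candidate lookback lengths in steps; default
#'   \code{c(8, 16)}.
#' @param units Candidate LSTM cell counts; default \code{c(16, 32)}.
#' @param split Chronological train/validation/test fractions, positive,
#'   summing to 1; default \code{c(0.7, 0.15, 0.15)}.
#' @param epochs,batch_size,learning_rate Optimizer settings (Adam on
#'   mean-squared error over standardized values).
#' @param interval Sampling interval of the series in hours (default 4,
#'   the water-quality feed cadence); used when resampling predictions.
#' @param seed Integer seed governing weight initialization and batch
#'   shuffling.
#' @return An object of class \code{"wq_lstm"} with components including
#'   \code{par} (network weights), \code{scalers}, \code{grid} (per-config
#'   validation scores), \code{metrics} (CC, NSE and verdict per split)
#'   and \code{fitted}/\code{residuals} on the training segment.
#' @seealso [predict.wq_lstm()], [predict_day()], [cc_verdict()]
#' @examples
#' set.seed(1)
#' y <- as.numeric(arima.sim(list(ar = 0.8), 300)) + 10
#' fit <- wq_lstm(y, lookback = 8, units = 8, epochs = 10)
#' fit
#' @export
wq_lstm <- function(y, xreg = NULL, lookback = c(8, 16), units = c(16, 32),
                    split = c(0.7, 0.15, 0.15), epochs = 50,
                    batch_size = 32, learning_rate = 0.01, interval = 4,
                    seed = 1) {
  cl <- match.call()
  if (!is.list(y)) y <- list(y)
  if (!is.null(xreg) && !is.list(xreg)) xreg <- list(xreg)
  if (any(split <= 0) || abs(sum(split) - 1) > 1e-8)
    stop("`split` fractions must be positive and sum to 1", call. = FALSE)
  ally <- unlist(y)
  if (all(is.na(ally)) || sd(ally, na.rm = TRUE) == 0)
    stop("cannot train on a constant (zero-variance) series", call. = FALSE)

  # per-series matrices: target first, exogenous columns after
  mats <- lapply(seq_along(y), function(i) {
    m <- matrix(as.numeric(y[[i]]), ncol = 1)
    if (!is.null(xreg)) {
      xr <- as.matrix(xreg[[i]])
      if (nrow(xr) != nrow(m))
        stop("`xreg` and `y` lengths differ", call. = FALSE)
      m <- cbind(m, xr)
    }
    m
  })
  D <- ncol(mats[[1L]])
  var_names <- c("target", if (D > 1) paste0("x", seq_len(D - 1L)))

  # scalers from pooled training segments only
  bounds <- lapply(mats, function(m) .split_bounds(nrow(m), split))
  train_pool <- do.call(rbind, lapply(seq_along(mats), function(i)
    mats[[i]][seq_len(bounds[[i]]["train_end"]), , drop = FALSE]))
  scalers <- lapply(seq_len(D), function(j)
    fit_scaler(train_pool[, j], var_names[j]))
  zmats <- lapply(mats, function(m) {
    for (j in seq_len(D)) m[, j] <- standardize(m[, j], scalers[[j]])
    m
  })

  pool_windows <- function(L) {
    sets <- list(train = list(), val = list(), test = list())
    for (i in seq_along(zmats)) {
      w <- make_windows(zmats[[i]], L, 1L)
      b <- bounds[[i]]
      seg <- ifelse(w$target_index <= b["train_end"], "train",
                    ifelse(w$target_index <= b["val_end"], "val", "test"))
      for (s in names(sets)) {
        k <- seg == s
        if (any(k))
          sets[[s]] <- c(sets[[s]],
                         list(list(X = w$X[k, , , drop = FALSE],
                                   y = w$y[k],
                                   series = i, idx = w$target_index[k])))
      }
    }
    lapply(sets, function(parts) {
      if (!length(parts)) return(NULL)
      list(X = do.call(abind3, lapply(parts, `[[`, "X")),
           y = unlist(lapply(parts, `[[`, "y")),
           series = unlist(lapply(parts, function(p)
             rep(p$series, length(p$y)))),
           idx = unlist(lapply(parts, `[[`, "idx")))
    })
  }

  grid <- expand.grid(units = units, lookback = lookback,
                      KEEP.OUT.ATTRS = FALSE)
  grid$val_cc <- NA_real_
  fits <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    L <- grid$lookback[gi]
    sets <- pool_windows(L)
    if (is.null(sets$train) || length(sets$train$y) < 2L)
      stop("training split yields too few windows; series too short or split degenerate",
           call. = FALSE)
    # the network learns the standardized one-step increment: an
    # untrained net then starts from the persistence forecast (the last
    # window value) and training only has to model the correction
    last_of <- function(st) st$X[, dim(st$X)[2L], 1L]
    tr_d <- sets$train$y - last_of(sets$train)
    has_val <- !is.null(sets$val) && length(sets$val$y) >= 3L
    par <- lstm_train(sets$train$X, tr_d, units = grid$units[gi],
                      epochs = epochs, batch_size = batch_size,
                      learning_rate = learning_rate,
                      seed = child_seed(seed, "fit", gi),
                      val_X = if (has_val) sets$val$X,
                      val_y = if (has_val) sets$val$y - last_of(sets$val))
    val_cc <- if (has_val)
      tryCatch(cor_pearson(sets$val$y, .predict_levels(par, sets$val$X)),
               error = function(e) NA_real_)
    else NA_real_
    grid$val_cc[gi] <- val_cc
    fits[[gi]] <- list(par = par, sets = sets)
  }
  best <- if (all(is.na(grid$val_cc))) 1L else which.max(grid$val_cc)
  par <- fits[[best]]$par
  sets <- fits[[best]]$sets
  L <- grid$lookback[best]

  # per-split skill in original units
  ysc <- scalers[[1L]]
  metrics <- do.call(rbind, lapply(c("train", "val", "test"), function(s) {
    st <- sets[[s]]
    if (is.null(st) || length(st$y) < 3L)
      return(data.frame(split = s, n = if (is.null(st)) 0L else
        length(st$y), CC = NA_real_, NSE = NA_real_,
        verdict = NA_character_, stringsAsFactors = FALSE))
    obs <- inverse_standardize(st$y, ysc)
    sim <- inverse_standardize(.predict_levels(par, st$X), ysc)
    ccv <- cor_pearson(obs, sim)
    data.frame(split = s, n = length(obs), CC = ccv, NSE = nse(obs, sim),
               verdict = cc_verdict(ccv), stringsAsFactors = FALSE)
  }))

  tr <- sets$train
  fitted_tr <- inverse_standardize(.predict_levels(par, tr$X), ysc)
  obs_tr <- inverse_standardize(tr$y, ysc)

  structure(list(call = cl, par = par, scalers = scalers,
                 units = grid$units[best], lookback = L, n_inputs = D,
                 grid = grid, metrics = metrics, split = split,
                 epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, interval = interval,
                 seed = seed, loss = par$loss,
                 fitted.values = fitted_tr,
                 residuals = obs_tr - fitted_tr,
                 train_obs = obs_tr,
                 series = mats, bounds = bounds),
            class = "wq_lstm")
}

# standardized level prediction: last window value plus the network's
# predicted increment
.predict_levels <- function(par, X) {
  X[, dim(X)[2L], 1L] + lstm_predict(par, X)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1L) return(arrs[[1L]])
  d <- dim(arrs[[1L]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1L], 0L)),
                           d[2L], d[3L]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1L]
    if (n) out[at + seq_len(n), , ] <- a
    at <- at + n
  }
  out
}

#' @export
print.wq_lstm <- function(x, ...) {
  cat("Single-layer LSTM forecaster\n")
  cat(sprintf("  units: %d  lookback: %d steps  inputs: %d  interval: %g h\n",
              x$units, x$lookback, x$n_inputs, x$interval))
  tst <- x$metrics[x$metrics$split == "test", ]
  if (nrow(tst) && !is.na(tst$CC))
    cat(sprintf("  test CC: %.3f (%s)  test NSE: %.3f\n", tst$CC,
                tst$verdict, tst$NSE))
  invisible(x)
}

#' @export
summary.wq_lstm <- function(object, ...) {
  structure(list(fit = object), class = "summary.wq_lstm")
}

#' @export
print.summary.wq_lstm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nHyperparameter grid (selected by validation CC):\n")
  g <- f$grid
  g$selected <- ifelse(seq_len(nrow(g)) ==
                         which(g$units == f$units &
                                 g$lookback == f$lookback)[1L], "*", "")
  print(g, row.names = FALSE)
  cat("\nSkill by chronological split:\n")
  m <- f$metrics
  m$CC <- round(m$CC, 4); m$NSE <- round(m$NSE, 4)
  print(m, row.names = FALSE)
  invisible(x)
}

#' @export
coef.wq_lstm <- function(object, ...) {
  object$par[c("W", "b", "Wy", "by")]
}

#' @export
residuals.wq_lstm <- function(object, ...) object$residuals

#' @export
fitted.wq_lstm <- function(object, ...) object$fitted.values

#' Plot method for LSTM forecasters
#'
#' Draws the held-out test segment: observed values and one-step-ahead
#' predictions, annotated with test CC and NSE.
#'
#' @param x A [wq_lstm()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.wq_lstm <- function(x, ...) {
  st <- .model_split_sets(x, "test")
  if (is.null(st)) stop("no test windows to plot", call. = FALSE)
  obs <- st$obs; sim <- st$sim
  graphics::plot(obs, type = "l", col = "grey30",
                 xlab = "test-step index", ylab = "value",
                 main = "Held-out test segment", ...)
  graphics::lines(sim, col = "firebrick")
  tst <- x$metrics[x$metrics$split == "test", ]
  graphics::legend("topleft", bty = "n",
                   legend = c("observed",
                              sprintf("predicted (CC %.2f, NSE %.2f)",
                                      tst$CC, tst$NSE)),
                   col = c("grey30", "firebrick"), lty = 1)
  invisible(x)
}

# observed/simulated pairs (original units) for one split of a fit
.model_split_sets <- function(object, split_name) {
  # rebuild the windows of the selected configuration
  ysc <- object$scalers[[1L]]
  zmats <- lapply(object$series, function(m) {
    for (j in seq_len(ncol(m)))
      m[, j] <- standardize(m[, j], object$scalers[[j]])
    m
  })
  obs <- c(); sim <- c()
  for (i in seq_along(zmats)) {
    w <- make_windows(zmats[[i]], object$lookback, 1L)
    b <- object$bounds[[i]]
    k <- switch(split_name,
                train = w$target_index <= b["train_end"],
                val = w$target_index > b["train_end"] &
                  w$target_index <= b["val_end"],
                test = w$target_index > b["val_end"])
    if (!any(k)) next
    obs <- c(obs, inverse_standardize(w$y[k], ysc))
    sim <- c(sim, inverse_standardize(
      .predict_levels(object$par, w$X[k, , , drop = FALSE]), ysc))
  }
  if (!length(obs)) return(NULL)
  list(obs = obs, sim = sim)
}

#' Predict from an LSTM forecaster
#'
#' Recursive multi-step prediction at the model's native sampling
#' interval: each predicted value is appended to the history and fed back
#' as input for the next step. Exogenous inputs, if the model has any, are
#' held at their last observed value through the recursion.
#'
#' @param object A [wq_lstm()] fit.
#' @param n_ahead Number of native steps to predict.
#' @param newdata Optional numeric history (original units, most recent
#'   last, length >= lookback), or a matrix with the target in column 1
#'   and exogenous inputs after. Defaults to the end of the training
#'   series.
#' @param ... Unused.
#' @return Numeric vector of \code{n_ahead} predictions in original units.
#' @export
predict.wq_lstm <- function(object, n_ahead = 1, newdata = NULL, ...) {
  L <- object$lookback
  D <- object$n_inputs
  hist_mat <- if (is.null(newdata)) {
    object$series[[length(object$series)]]
  } else if (is.matrix(newdata)) newdata else matrix(newdata, ncol = 1)
  if (ncol(hist_mat) != D)
    stop(sprintf("model expects %d input column(s), got %d", D,
                 ncol(hist_mat)), call. = FALSE)
  hist_mat <- hist_mat[!apply(hist_mat, 1, anyNA), , drop = FALSE]
  if (nrow(hist_mat) < L)
    stop(sprintf("need at least %d complete history steps, got %d", L,
                 nrow(hist_mat)), call. = FALSE)
  z <- hist_mat
  for (j in seq_len(D)) z[, j] <- standardize(z[, j], object$scalers[[j]])
  window <- z[(nrow(z) - L + 1L):nrow(z), , drop = FALSE]
  last_exog <- if (D > 1) window[L, -1L] else NULL
  out <- numeric(n_ahead)
  for (s in seq_len(n_ahead)) {
    X <- array(window, c(1L, L, D))
    yz <- window[L, 1L] + lstm_predict(object$par, X)
    out[s] <- yz
    new_row <- c(yz, last_exog)
    window <- rbind(window[-1L, , drop = FALSE], new_row)
  }
  inverse_standardize(out, object$scalers[[1L]])
}

#' Next-day hourly prediction with grades
#'
#' Produces the daily forecast product: recursive predictions at the
#' model's native interval (4 h for water quality), resampled by linear
#' interpolation to one value per \code{step_hours} over
#' \code{horizon_hours}, so the default call yields exactly 24 hourly
#' values. When a grading scheme is supplied each value also receives its
#' water-quality class.
#'
#' @param model A [wq_lstm()] fit.
#' @param history Numeric history vector (original units, most recent
#'   last), or a data frame with \code{time} and \code{value} columns.
#'   Length must reach the model's lookback.
#' @param horizon_hours Forecast horizon; default 24.
#' @param step_hours Output resolution; default 1.
#' @param start_time POSIXct start of the forecast day (defaults to the
#'   last history timestamp when available, else unset times).
#' @param indicator,scheme Optional indicator key and [grading_scheme()];
#'   when both are given a \code{class} column is added.
#' @return Data frame with \code{time} (POSIXct or NA), \code{hour_ahead},
#'   \code{value} and optionally \code{class}; exactly
#'   \code{horizon_hours / step_hours} rows.
#' @export
predict_day <- function(model, history = NULL, horizon_hours = 24,
                        step_hours = 1, start_time = NULL,
                        indicator = NULL, scheme = NULL) {
  if (horizon_hours <= 0 || step_hours <= 0)
    stop("`horizon_hours` and `step_hours` must be positive", call. = FALSE)
  hvec <- history
  if (is.data.frame(history)) {
    if (is.null(start_time)) start_time <- max(history$time)
    hvec <- history$value[order(history$time)]
  }
  iv <- model$interval
  n_native <- ceiling(horizon_hours / iv)
  native <- predict(model, n_ahead = n_native, newdata = hvec)
  # anchor interpolation at the last observation, then native steps
  anchor <- if (is.null(hvec))
    utils::tail(model$series[[length(model$series)]][, 1L], 1L)
  else utils::tail(hvec[!is.na(hvec)], 1L)
  knots_h <- c(0, iv * seq_len(n_native))
  hours <- seq(step_hours, horizon_hours, by = step_hours)
  vals <- approx(knots_h, c(anchor, native), xout = hours)$y
  out <- data.frame(
    time = if (is.null(start_time)) as.POSIXct(rep(NA, length(hours)))
           else start_time + hours * 3600,
    hour_ahead = hours, value = vals)
  if (!is.null(indicator) && !is.null(scheme))
    out$class <- grade_value(indicator, out$value, scheme)
  out
}
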