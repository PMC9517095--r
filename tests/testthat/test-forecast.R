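# a small, quick fit reused across tests in this file
fit_small <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      st <- tiny_network()[1, ]
      y <- tiny_series(st, days = 120, seed = 8)$COD_Mn
      memo <<- wq_lstm(y, lookback = 6, units = 8, epochs = 15, seed = 1)
    }
    memo
  }
})

test_that("standardization round-trips and is train-split-anchored", {
  x <- c(3, 8, 1, 9, 4)
  sc <- fit_scaler(x, "COD_Mn")
  z <- standardize(x, sc)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(inverse_standardize(z, sc), x, tolerance = 1e-10)
  # a train-fitted scaler does not center other data
  expect_false(abs(mean(standardize(x + 5, sc))) < 1e-6)
  expect_error(fit_scaler(rep(2, 4), "DO"), "DO")
})

test_that("make_windows counts, aligns and never leaks targets", {
  w <- make_windows(1:10, L = 4, H = 1)
  expect_equal(dim(w$X), c(6, 4, 1))
  expect_equal(w$y, 5:10)
  expect_equal(w$target_index, 5:10)
  # inputs end strictly before targets
  for (i in seq_along(w$y))
    expect_lt(max(w$X[i, , 1]), w$y[i])

  w1 <- make_windows(1:5, L = 3, H = 2)
  expect_equal(dim(w1$X)[1], 1)
  expect_error(make_windows(1:5, L = 5, H = 1), "too short")

  # windows touching NA are dropped
  v <- c(1:5, NA, 7:12)
  wn <- make_windows(v, L = 3, H = 1)
  expect_false(any(is.na(wn$X)))
  expect_false(any(is.na(wn$y)))
})

test_that("registry enumerates watershed x position x indicator exactly once", {
  net <- generate_network(10, 1, seed = 7)
  reg <- build_registry(net)
  expect_equal(nrow(reg), 210)
  expect_equal(anyDuplicated(reg$key), 0)
  expect_true(all(reg$trainable))

  reg1 <- build_registry(generate_network(1, 1, seed = 1),
                         indicators = "DO")
  expect_equal(nrow(reg1), 3)

  # duplicate station rows leave the registry unchanged
  net2 <- rbind(net, net[1:5, ])
  expect_equal(build_registry(net2), reg)

  # a watershed with no stations still yields (untrainable) keys
  reg3 <- build_registry(net, watersheds = c(unique(net$watershed), "WS99"))
  expect_equal(nrow(reg3), 231)
  expect_false(any(reg3$trainable[reg3$watershed == "WS99"]))
})

test_that("wq_lstm validates inputs and records its configuration", {
  expect_error(wq_lstm(rep(3, 200)), "constant")
  expect_error(wq_lstm(rnorm(200), split = c(0.9, 0.2, 0.1)), "sum to 1")

  f <- fit_small()
  expect_s3_class(f, "wq_lstm")
  expect_equal(nrow(f$grid), 1)       # grid of one point: that point kept
  expect_equal(f$units, 8)
  expect_equal(f$lookback, 6)
  expect_named(f$metrics, c("split", "n", "CC", "NSE", "verdict"))
  expect_length(residuals(f), length(fitted(f)))
  expect_true(all(c("W", "b", "Wy", "by") %in% names(coef(f))))
  out <- capture.output(print(summary(f)))
  expect_true(any(grepl("Skill by chronological split", out)))
})

test_that("validation and test windows lie strictly after training windows", {
  f <- fit_small()
  b <- f$bounds[[1]]
  n <- nrow(f$series[[1]])
  expect_lt(b["train_end"], b["val_end"])
  expect_lt(b["val_end"], n)
  # window partition respects the chronology by construction of
  # target_index; check the derived sets directly
  zs <- standardize(f$series[[1]][, 1], f$scalers[[1]])
  w <- make_windows(zs, f$lookback, 1)
  tr_idx <- w$target_index[w$target_index <= b["train_end"]]
  te_idx <- w$target_index[w$target_index > b["val_end"]]
  expect_lt(max(tr_idx), min(te_idx))
})

test_that("a converged fit on a deterministic ramp continues the ramp", {
  # constant-increment series: the increment read-out must converge to a
  # constant function, so predictions continue the line
  y <- seq(10, 50, by = 0.25)
  f <- wq_lstm(y, lookback = 4, units = 4, epochs = 200,
               learning_rate = 0.02, seed = 2)
  p <- predict(f, n_ahead = 4)
  expect_equal(p, max(y) + 0.25 * (1:4), tolerance = 0.05)
})

test_that("predict_day emits exactly horizon/step values on the hour", {
  f <- fit_small()
  hist <- tiny_series(tiny_network()[1, ], days = 20, seed = 12)$COD_Mn
  p24 <- predict_day(f, hist, start_time = parse_wq_time("2021-03-26 00:00"))
  expect_equal(nrow(p24), 24)
  expect_equal(p24$hour_ahead, 1:24)
  expect_equal(p24$time[1], parse_wq_time("2021-03-26 01:00"))
  expect_true(all(is.finite(p24$value)))

  p12 <- predict_day(f, hist, horizon_hours = 12)
  expect_equal(nrow(p12), 12)
  p6 <- predict_day(f, hist, horizon_hours = 24, step_hours = 4)
  expect_equal(nrow(p6), 6)

  expect_error(predict(f, newdata = hist[1:3]), "at least")
  # grading attached when a scheme is supplied
  pg <- predict_day(f, hist, indicator = "COD_Mn", scheme = toy_scheme())
  expect_true("class" %in% names(pg))
})

test_that("pooled multi-series training uses windows from every series", {
  st <- tiny_network(1, 2)
  y1 <- tiny_series(st[1, ], days = 60, seed = 1)$COD_Mn
  y2 <- tiny_series(st[2, ], days = 60, seed = 2)$COD_Mn
  f <- wq_lstm(list(y1, y2), lookback = 6, units = 4, epochs = 5, seed = 3)
  n_tr <- f$metrics$n[f$metrics$split == "train"]
  b1 <- floor(0.7 * length(y1)); b2 <- floor(0.7 * length(y2))
  expect_equal(n_tr, (b1 - 6) + (b2 - 6))
})

test_that("trained forecaster beats persistence on a learnable series", {
  # a diel cycle sampled six times per day: persistence lags the cycle
  # systematically, so a forecaster that learns the structure must win
  st <- tiny_network()[1, ]
  sp <- series_spec("DO", 8, seasonal_amplitude = 1.5,
                    seasonal_period = 24, ar_coefficient = 0.6,
                    noise_sd = 0.3)
  end <- format(parse_wq_time("2021-01-01 00:00") + 900 * 4 * 3600,
                "%Y-%m-%d %H:%M")
  y <- generate_series(st, sp, "2021-01-01 00:00", end, seed = 1)$DO
  f <- wq_lstm(y, lookback = 8, units = 16, epochs = 30, seed = 1)
  m <- f$metrics[f$metrics$split == "test", ]
  ps <- persistence_skill(y, floor(0.85 * length(y)) + 1L)
  expect_gte(m$CC, ps$cc)
  expect_gte(m$NSE, ps$nse)
  expect_gte(m$CC, 0.65)
})
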