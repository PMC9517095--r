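test_that("pearson matches the hand formula and guards its domain", {
  expect_equal(cor_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  x <- c(1.5, 2.2, 5.1, 0.3, 4.4)
  expect_equal(cor_pearson(x, x), 1)
  expect_equal(cor_pearson(x, -x), -1)
  expect_error(cor_pearson(rep(1, 5), x), "constant")
  expect_error(cor_pearson(x, x[-1]), "length")
  expect_error(cor_pearson(1:2, 2:1), "at least 3")
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(15); b <- rnorm(15)
    expect_equal(cor_pearson(a, b), pearson_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cosine similarity follows the inner-product formula", {
  expect_equal(cor_cosine(c(1, 0), c(0, 1)), 0)
  expect_equal(cor_cosine(c(3, 4), c(4, 3)), 0.96)
  x <- c(2, 5, 1)
  expect_equal(cor_cosine(x, 2 * x), 1)
  expect_error(cor_cosine(c(0, 0), c(1, 1)), "zero vector")
})

test_that("distance correlation: exact cases and brute-force agreement", {
  x <- c(0.2, 1.4, 2.2, 3.9, 5.0)
  expect_equal(cor_dcor(x, 3 * x + 2), 1, tolerance = 1e-12)
  expect_equal(cor_dcor(rep(2, 5), x), 0)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    a <- rnorm(n); b <- if (i %% 2) rnorm(n) else a^2 + rnorm(n, 0, 0.1)
    v <- cor_dcor(a, b)
    expect_equal(v, dcor_oracle(a, b), tolerance = 1e-10)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, cor_dcor(b, a), tolerance = 1e-12)   # symmetry
  }
})

test_that("MIC: functional dependence, null level, and grid enumeration", {
  set.seed(21)
  x <- runif(128)
  expect_gte(cor_mic(x, x^3 + 1), 0.99)      # strictly monotone map
  # independent pair stays low at n = 500
  xi <- rnorm(500); yi <- rnorm(500)
  expect_lt(cor_mic(xi, yi), 0.3)
  # exhaustive-grid oracle agreement on small series
  for (i in 1:10) {
    n <- sample(8:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(cor_mic(a, b), mic_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("pearson, dcor and mic are invariant to positive affine maps", {
  set.seed(31)
  x <- rnorm(64); y <- x + rnorm(64, 0, 0.5)
  x2 <- 3 * x + 7; y2 <- 0.5 * y - 2
  expect_equal(cor_pearson(x, y), cor_pearson(x2, y2), tolerance = 1e-12)
  expect_equal(cor_dcor(x, y), cor_dcor(x2, y2), tolerance = 1e-10)
  expect_equal(cor_mic(x, y), cor_mic(x2, y2), tolerance = 1e-12)
})

test_that("lag_scan recovers a constructed shift and keeps its contract", {
  set.seed(41)
  x <- as.numeric(arima.sim(list(ar = 0.7), 400))
  y <- c(rep(0, 3), x[1:397])     # y_t = x_{t-3}
  s <- lag_scan(x[20:400], y[20:400], K = 12, metric = "pearson")
  expect_s3_class(s, "lag_scan")
  expect_equal(s$best_lag, 3)
  expect_equal(s$values[3], 1, tolerance = 1e-10)
  expect_length(s$values, 12)

  wn <- lag_scan(rnorm(200), rnorm(200), K = 12)
  expect_length(wn$values, 12)
  expect_true(all(abs(wn$values) < 0.3))

  expect_error(lag_scan(rnorm(10), rnorm(10), K = 10), "too short")
})

test_that("select_inputs keeps coupled candidates above the threshold", {
  set.seed(51)
  n <- 400
  driver <- as.numeric(arima.sim(list(ar = 0.8), n))
  target <- c(rep(0, 2), driver[1:(n - 2)]) + rnorm(n, 0, 0.3)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  d <- data.frame(COD_Mn = target, NH4 = driver, Tub = noise1,
                  TP = noise2)
  sel <- select_inputs(d, "COD_Mn", threshold = 0.5, K = 12)
  expect_equal(sel$input[1], "COD_Mn")        # own history first
  expect_equal(setdiff(sel$input, "COD_Mn"), "NH4")
  # verified independently: the coupled pair really clears 0.5
  expect_gt(abs(pearson_oracle(driver[1:(n - 2)], target[3:n])), 0.5)

  all_in <- select_inputs(d, "COD_Mn", threshold = 0)
  expect_setequal(all_in$input, names(d))
  none <- select_inputs(d, "COD_Mn", threshold = 1.01)
  expect_equal(none$input, "COD_Mn")          # history-only model
  hist_only <- select_inputs(d, "COD_Mn", candidates = character())
  expect_equal(hist_only$input, "COD_Mn")
})
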