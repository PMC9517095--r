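test_that("generate_network lays out watersheds x positions x slots", {
  net <- generate_network(10, 1, seed = 7)
  expect_equal(nrow(net), 30)
  expect_length(unique(net$watershed), 10)
  expect_setequal(unique(net$position),
                  c("upstream", "middle", "downstream"))
  # one station per position in each watershed
  tab <- table(net$watershed, net$position)
  expect_true(all(tab == 1))

  expect_equal(nrow(generate_network(1, 2, seed = 0)), 6)
  expect_identical(generate_network(3, 2, seed = 42),
                   generate_network(3, 2, seed = 42))
  expect_error(generate_network(0, 1), ">= 1")
  expect_error(generate_network(2, 0), ">= 1")
})

test_that("generate_series respects cadence, structure and determinism", {
  st <- tiny_network()[1, ]
  sp <- series_spec("COD_Mn", baseline = 5)
  x <- generate_series(st, sp, "2021-03-01 00:00", "2021-03-02 00:00",
                       seed = 1)
  expect_equal(nrow(x), 6)  # four-hourly records over one day
  expect_true(all(diff(as.numeric(x$time)) == 4 * 3600))
  # degenerate spec: constant at baseline
  expect_true(all(x$COD_Mn == 5))

  # seeded determinism, strict time ordering without injections
  a <- tiny_series(st, seed = 9)
  b <- tiny_series(st, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(as.numeric(a$time)) > 0))

  expect_error(generate_series(st, sp, "2021-03-02 00:00",
                               "2021-03-01 00:00"), "after")
})

test_that("generated AR(1) series has the requested lag-1 autocorrelation", {
  st <- tiny_network()[1, ]
  for (phi in c(0.3, 0.8)) {
    sp <- series_spec("NH4", baseline = 1, ar_coefficient = phi,
                      noise_sd = 0.2)
    end <- format(parse_wq_time("2000-01-01 00:00") + 5000 * 4 * 3600,
                  "%Y-%m-%d %H:%M")
    x <- generate_series(st, sp, "2000-01-01 00:00", end, seed = 4)
    v <- x$NH4
    acf1 <- cor(v[-1], v[-length(v)])
    expect_lt(abs(acf1 - phi), 0.05)
  }
})

test_that("pure-noise series mean stays near baseline", {
  st <- tiny_network()[1, ]
  sp <- series_spec("TP", baseline = 0.1, noise_sd = 0.02)
  end <- format(parse_wq_time("2000-01-01 00:00") + 2000 * 4 * 3600,
                "%Y-%m-%d %H:%M")
  x <- generate_series(st, sp, "2000-01-01 00:00", end, seed = 5)
  expect_lt(abs(mean(x$TP) - 0.1), 3 * 0.02 / sqrt(nrow(x)))
})

test_that("missing and duplicate injection hit close to their rates", {
  st <- tiny_network()[1, ]
  sp <- series_spec("DO", baseline = 8, noise_sd = 0.1,
                    missing_rate = 0.1, duplicate_rate = 0.1)
  end <- format(parse_wq_time("2021-01-01 00:00") + 2000 * 4 * 3600,
                "%Y-%m-%d %H:%M")
  x <- generate_series(st, sp, "2021-01-01 00:00", end, seed = 6)
  expect_gt(nrow(x), 2000)                     # duplicates added
  expect_gt(sum(duplicated(x)), 0)
  frac_na <- mean(is.na(x$DO))
  expect_lt(abs(frac_na - 0.1), 0.03)
  # duplicates are exact copies of an existing record
  dups <- x[duplicated(x), ]
  expect_true(all(dups$time %in% x$time[!duplicated(x)]))
})

test_that("inject_spike changes exactly the windowed records", {
  st <- tiny_network()[1, ]
  x <- generate_series(st, series_spec("COD_Mn", 5),
                       "2021-03-26 00:00", "2021-03-27 00:00", seed = 1)
  ev0 <- spike_event(st$station_id, "COD_Mn", "2021-03-26 04:00", 8,
                     magnitude = 0)
  expect_equal(inject_spike(x, ev0), x)

  ev <- spike_event(st$station_id, "COD_Mn", "2021-03-26 04:00", 8,
                    magnitude = 3)
  y <- inject_spike(x, ev)
  changed <- which(y$COD_Mn != x$COD_Mn)
  expect_length(changed, 2)   # two 4-h records inside an 8-h window
  expect_equal(y$COD_Mn[changed], x$COD_Mn[changed] + 3)
  expect_equal(y[-changed, ], x[-changed, ])

  expect_error(spike_event(st$station_id, "XX", "2021-03-26 04:00", 8, 1),
               "unknown indicator")
  far <- spike_event(st$station_id, "COD_Mn", "2022-01-01 00:00", 4, 1)
  expect_error(inject_spike(x, far), "overlap")
})

test_that("DO spikes default to depletion, others to enrichment", {
  e1 <- spike_event("S1", "DO", "2021-01-01 00:00", 4, magnitude = 2)
  expect_equal(e1$magnitude, -2)
  e2 <- spike_event("S1", "NH4", "2021-01-01 00:00", 4, magnitude = 2)
  expect_equal(e2$magnitude, 2)
  e3 <- spike_event("S1", "DO", "2021-01-01 00:00", 4, magnitude = 2,
                    direction = "raw")
  expect_equal(e3$magnitude, 2)
})

test_that("a boundary-crossing spike worsens the downstream grade", {
  st <- tiny_network()[1, ]
  x <- generate_series(st, series_spec("COD_Mn", 5),
                       "2021-03-26 00:00", "2021-03-27 00:00", seed = 1)
  sch <- toy_scheme()
  before <- grade_value("COD_Mn", x$COD_Mn, sch)
  y <- inject_spike(x, spike_event(st$station_id, "COD_Mn",
                                   "2021-03-26 08:00", 8, magnitude = 4))
  after <- grade_value("COD_Mn", y$COD_Mn, sch)
  win <- y$COD_Mn != x$COD_Mn
  expect_true(all(after[win] > before[win]))
  expect_identical(after[!win], before[!win])
})

test_that("crawl payloads round-trip losslessly, including nulls", {
  st <- tiny_network()[1, ]
  x <- tiny_series(st, days = 3)
  x$COD_Mn[2] <- NA
  f <- withr::local_tempfile(fileext = ".json")
  write_crawl_payload(x, f, station_name = "North Station")
  y <- read_crawl_payload(f)
  expect_equal(y$COD_Mn, x$COD_Mn)
  expect_equal(format(y$time), format(x$time))
  expect_equal(y$station_id, x$station_id)
  expect_equal(attr(y, "station_name"), "North Station")
  expect_true(is.na(y$COD_Mn[2]))
  # null is spelled out in the file
  expect_match(paste(readLines(f), collapse = ""), "null")
  expect_error(write_crawl_payload(x[0, ], f), "empty")
})

test_that("station metadata CSV round-trips and validates positions", {
  net <- tiny_network(2, 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_station_metadata(net, f)
  back <- read_station_metadata(f)
  expect_equal(back, net)
  bad <- net; bad$position[1] <- "source"
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_station_metadata(bad, f2)
  expect_error(read_station_metadata(f2), "position")
})
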