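make_payload_file <- function(records, dir, name) {
  write_crawl_payload(records, file.path(dir, name))
}

test_that("detect_update keys on the latest measurement time", {
  st <- tiny_network()[1, ]
  x <- tiny_series(st, days = 2)
  store <- wq_store()
  expect_true(detect_update(x, store))        # unknown station
  upsert_records(clean_records(x), store)
  expect_false(detect_update(x, store))       # same latest time
  x2 <- x
  x2$time <- x2$time + 4 * 3600
  expect_true(detect_update(x2, store))       # 4 h newer
})

test_that("clean_records removes duplicates and null records, idempotently", {
  st <- tiny_network()[1, ]
  x <- tiny_series(st, days = 1)              # 6 records
  x <- x[c(1, 2, 2, 3, 3), ]                  # 5 rows, 2 exact duplicates
  cl <- clean_records(x)
  expect_equal(nrow(cl), 3)

  y <- tiny_series(st, days = 1)
  y$COD_Mn[4] <- NA                           # all-null record (only ind.)
  cl2 <- clean_records(y)
  expect_equal(nrow(cl2), 5)
  expect_false(parse_wq_time("2021-01-01 12:00") %in% cl2$time)

  expect_identical(clean_records(cl2), cl2)   # idempotent
  # surviving values are untouched
  expect_equal(cl2$COD_Mn, y$COD_Mn[-4])
  expect_identical(clean_records(y[0, ]), y[0, ])
})

test_that("clean_records nulls negative concentrations but keeps the record", {
  st <- tiny_network()[1, ]
  x <- tiny_series(st, days = 1)
  x$DO <- 8
  x$COD_Mn[2] <- -1
  cl <- clean_records(x)
  expect_equal(nrow(cl), 6)
  expect_true(is.na(cl$COD_Mn[2]))
  expect_equal(cl$DO[2], 8)
})

test_that("conflicting values for one key resolve to the later-parsed row", {
  st <- tiny_network()[1, ]
  x <- tiny_series(st, days = 1)
  dup <- x[3, ]; dup$COD_Mn <- 99
  expect_message(cl <- clean_records(rbind(x, dup)), "conflict")
  expect_equal(nrow(cl), 6)
  expect_equal(cl$COD_Mn[3], 99)
})

test_that("upsert inserts unseen keys only and registers new stations", {
  st <- tiny_network()[1, ]
  x <- clean_records(tiny_series(st, days = 1))
  store <- wq_store()
  s1 <- upsert_records(x, store)
  expect_equal(unname(s1), c(6L, 0L))
  expect_true(st$station_id %in% store$stations$station_id)
  expect_true(st$station_id %in% store$water_quality_stations$station_id)
  s2 <- upsert_records(x, store)
  expect_equal(unname(s2), c(0L, 6L))

  # mixed batch: 4 new records + 2 already stored
  more <- clean_records(tiny_series(st, days = 1))
  more$time <- more$time + 4 * 4 * 3600       # shift by 4 steps
  s3 <- upsert_records(more, store)
  expect_equal(unname(s3), c(4L, 2L))

  dirty <- rbind(x, x)
  expect_error(upsert_records(dirty, store), "duplicate")
})

test_that("poll_feed ingests fresh payloads, skips stale and corrupt ones", {
  st <- tiny_network(1, 2)
  dir <- withr::local_tempdir()
  x1 <- tiny_series(st[1, ], days = 2, seed = 1)
  x2 <- tiny_series(st[2, ], days = 2, seed = 2)
  make_payload_file(x1, dir, "a.json")
  make_payload_file(x2, dir, "b.json")
  writeLines("{not json", file.path(dir, "c.json"))
  store <- wq_store()
  expect_message(res <- poll_feed(dir, store, st), "skipping")
  expect_equal(res$status, c("ingested", "ingested", "error"))
  expect_true(all(res$inserted[1:2] > 0))

  res2 <- poll_feed(dir, store, st)
  expect_true(all(res2$inserted == 0))
  expect_error(poll_feed(file.path(dir, "nope"), store), "exist")
})

test_that("store uniqueness and monotone growth hold over random polls", {
  st <- tiny_network(1, 3)
  store <- wq_store()
  last_n <- 0L
  set.seed(99)
  for (rep in 1:8) {
    dir <- withr::local_tempdir()
    i <- sample(3, 1)
    x <- tiny_series(st[i, ], days = sample(3, 1), seed = sample(5, 1),
                     missing_rate = 0.2, duplicate_rate = 0.2)
    make_payload_file(x, dir, "p.json")
    poll_feed(dir, store, st)
    d <- store_records(store)
    key <- paste(d$station_id, format(d$time))
    expect_false(anyDuplicated(key) > 0)
    expect_gte(nrow(d), last_n)
    last_n <- nrow(d)
  }
})

test_that("a store round-trips through its CSV directory form", {
  st <- tiny_network()[1, ]
  store <- wq_store()
  upsert_records(clean_records(tiny_series(st, days = 2)), store, st)
  dir <- withr::local_tempdir()
  save_store(store, dir)
  back <- load_store(dir)
  expect_equal(store_counts(back), store_counts(store))
  expect_equal(store_records(back)$COD_Mn, store_records(store)$COD_Mn)
})
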