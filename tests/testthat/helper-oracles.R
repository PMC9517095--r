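# Independent brute-force oracles used to cross-check the package's
# implementations. These are written from the defining formulas, with
# explicit loops, and share no code with the package internals.

pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / (sqrt(dx) * sqrt(dy))
}

nse_oracle <- function(obs, sim) {
  m <- sum(obs) / length(obs)
  num <- 0; den <- 0
  for (i in seq_along(obs)) {
    num <- num + (obs[i] - sim[i])^2
    den <- den + (obs[i] - m)^2
  }
  1 - num / den
}

# O(n^2) distance correlation by explicit double centering
dcor_oracle <- function(x, y) {
  n <- length(x)
  a <- matrix(0, n, n); b <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a[i, j] <- abs(x[i] - x[j])
    b[i, j] <- abs(y[i] - y[j])
  }
  center <- function(d) {
    A <- matrix(0, n, n)
    rm_ <- apply(d, 1, mean); cm_ <- apply(d, 2, mean); gm <- mean(d)
    for (i in seq_len(n)) for (j in seq_len(n))
      A[i, j] <- d[i, j] - rm_[i] - cm_[j] + gm
    A
  }
  A <- center(a); B <- center(b)
  dcov2 <- sum(A * B) / n^2
  dvx <- sum(A * A) / n^2
  dvy <- sum(B * B) / n^2
  if (dvx * dvy <= 0) return(0)
  sqrt(max(dcov2 / sqrt(dvx * dvy), 0))
}

# exhaustive equipartition-grid MIC: every (nx, ny) with nx, ny >= 2 and
# nx * ny < n^0.6; equal-frequency bins taken as consecutive runs of the
# sort order with sizes floor(n*j/k) - floor(n*(j-1)/k)
mic_oracle <- function(x, y) {
  n <- length(x)
  bins_of <- function(v, k) {
    sizes <- diff(floor(n * (0:k) / k))
    b <- integer(n)
    ord <- order(v)
    at <- 0L
    for (j in seq_len(k)) {
      if (sizes[j] > 0) b[ord[(at + 1L):(at + sizes[j])]] <- j
      at <- at + sizes[j]
    }
    b
  }
  mi_of <- function(bx, by, nx, ny) {
    cnt <- matrix(0, nx, ny)
    for (i in seq_len(n)) cnt[bx[i], by[i]] <- cnt[bx[i], by[i]] + 1
    p <- cnt / n
    px <- rowSums(p); py <- colSums(p)
    mi <- 0
    for (a in seq_len(nx)) for (b in seq_len(ny))
      if (p[a, b] > 0)
        mi <- mi + p[a, b] * log2(p[a, b] / (px[a] * py[b]))
    mi
  }
  best <- 0
  bound <- n^0.6
  for (nx in 2:n) for (ny in 2:n) {
    if (nx * ny >= bound) next
    v <- mi_of(bins_of(x, nx), bins_of(y, ny), nx, ny) / log2(min(nx, ny))
    if (v > best) best <- v
  }
  min(best, 1)
}

persistence_skill <- function(y, test_start) {
  n <- length(y)
  obs <- y[test_start:n]
  prev <- y[(test_start - 1L):(n - 1L)]
  list(cc = pearson_oracle(obs, prev), nse = nse_oracle(obs, prev))
}

# small shared fixtures -------------------------------------------------

tiny_network <- function(n_watersheds = 1, per = 1, seed = 1)
  generate_network(n_watersheds, per, seed = seed)

tiny_series <- function(station, indicator = "COD_Mn", days = 30,
                        seed = 1, ...) {
  sp <- series_spec(indicator, baseline = 6, seasonal_amplitude = 1,
                    ar_coefficient = 0.7, noise_sd = 0.4, ...)
  t1 <- format(parse_wq_time("2021-01-01 00:00") + days * 86400,
               "%Y-%m-%d %H:%M")
  generate_series(station, sp, "2021-01-01 00:00", t1, seed = seed)
}

# a deliberately synthetic grading scheme with round boundaries, so the
# tests do not depend on the shipped standard's values
toy_scheme <- function() {
  grading_scheme(
    COD_Mn = list(direction = "higher_is_worse",
                  boundaries = c(2, 4, 6, 10, 15)),
    DO = list(direction = "lower_is_worse",
              boundaries = c(7.5, 6, 5, 3, 2)),
    PH = list(direction = "range", boundaries = c(6, 9)),
    WT = list(direction = "none", boundaries = numeric()))
}
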