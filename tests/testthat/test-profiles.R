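test_that("identical categorical series recur fully at lag zero", {
  x <- c(1, 2, 1, 3, 2, 1, 3, 2)
  p <- diagonalRecurrenceProfile(x, x, maxLag = 2,
                                 datatype = "categorical")
  expect_equal(p@rr[p@lags == 0], 100)
  expect_equal(p@maxlag, 0L)
  expect_equal(p@maxrec, 100)
})

test_that("a shifted copy peaks at minus the shift (sign convention)", {
  set.seed(61)
  x <- sample(1:3, 120, replace = TRUE)
  for (k in 1:4) {
    y <- c(rep(99, k), x[seq_len(120 - k)])  # y(t) = x(t - k)
    p <- diagonalRecurrenceProfile(x, y, maxLag = 5,
                                   datatype = "categorical")
    expect_equal(p@rr[p@lags == -k], 100)
    expect_equal(p@maxlag, -k)
  }
})

test_that("profile rates equal the per-diagonal density of the full plot", {
  set.seed(62)
  x <- rnorm(80); y <- rnorm(80)
  W <- 6
  p <- diagonalRecurrenceProfile(x, y, maxLag = W, radius = 0.9)
  R <- as.matrix(crossRecurrenceMatrix(x, y, radius = 0.9)@points)
  n <- nrow(R)
  for (l in -W:W) {
    d <- -l
    onDiag <- sum(R[cbind(seq.int(max(1, 1 - d), min(n, n - d)),
                          seq.int(max(1, 1 - d), min(n, n - d)) + d)])
    expect_equal(p@rr[p@lags == l], 100 * onDiag / (n - abs(l)))
  }
})

test_that("per-lag denominators use the valid comparisons, not fixed T", {
  x <- rep(1, 10)
  p <- diagonalRecurrenceProfile(x, x, maxLag = 4,
                                 datatype = "categorical")
  expect_equal(unname(p@rr), rep(100, 9))  # would deflate at the edges otherwise
})

test_that("non-event exclusion drops only simultaneous non-events", {
  x <- c(0, 1, 0, 0, 1, 0)
  y <- c(0, 1, 0, 1, 0, 0)
  p0 <- diagonalRecurrenceProfile(x, y, maxLag = 0,
                                  datatype = "categorical")
  pE <- diagonalRecurrenceProfile(x, y, maxLag = 0,
                                  datatype = "categorical",
                                  excludeNonevent = "0")
  expect_equal(p0@rr, 100 * 4 / 6)  # three 0-0 pairs and one 1-1 pair
  expect_equal(pE@rr, 100 * 1 / 6)
  # all-excluded numerator: zero profile, not an error
  z <- rep(0, 8)
  pz <- diagonalRecurrenceProfile(z, z, maxLag = 2,
                                  datatype = "categorical",
                                  excludeNonevent = "0")
  expect_equal(unname(pz@rr), rep(0, 5))
})

test_that("maxlag ties resolve to the smallest absolute, then negative, lag", {
  expect_equal(xrqa:::.tieBreakMax(-3:3, c(1, 5, 5, 2, 5, 5, 1)), -1L)
  expect_equal(xrqa:::.tieBreakMax(-3:3, c(5, 1, 1, 5, 1, 1, 5)), 0L)
  expect_equal(xrqa:::.tieBreakMax(-3:3, rep(7, 7)), 0L)
})

test_that("lag windows wider than the series are rejected", {
  expect_error(diagonalRecurrenceProfile(1:5, 1:5, maxLag = 5,
                                         datatype = "categorical"),
               "smaller than")
})

test_that("windowed profile tracks local agreement along the time course", {
  x <- rep(1, 60)
  p <- windowedRecurrenceProfile(x, x, windowSize = 20, step = 5,
                                 lagWindow = 3, datatype = "categorical")
  expect_equal(p@values$rr, rep(100, length(p@starts)))
  expect_equal(p@starts, seq(1L, 41L, by = 5L))

  # equal first half, disjoint constant codes in the second half
  y1 <- c(rep(1, 30), rep(2, 30))
  y2 <- c(rep(1, 30), rep(3, 30))
  pw <- windowedRecurrenceProfile(y1, y2, windowSize = 10, step = 10,
                                  lagWindow = 2, datatype = "categorical")
  inFirst <- pw@starts + 9 <= 30
  expect_equal(pw@values$rr[inFirst], rep(100, sum(inFirst)))
  expect_equal(pw@values$rr[pw@starts > 30], rep(0, sum(pw@starts > 30)))

  expect_error(windowedRecurrenceProfile(1:10, 1:10, windowSize = 20,
                                         step = 1, lagWindow = 2),
               "shorter than the window")
  expect_error(windowedRecurrenceProfile(1:50, 1:50, windowSize = 10,
                                         step = 1, lagWindow = 10),
               "smaller than windowSize")
})

test_that("one window covering everything equals the global analysis", {
  set.seed(71)
  x <- sample(1:4, 50, replace = TRUE)
  y <- sample(1:4, 50, replace = TRUE)
  w <- windowedCRQA(x, y, windowSize = 50, step = 1,
                    datatype = "categorical")
  g <- as.data.frame(crqa(x, y, datatype = "categorical"))
  expect_equal(nrow(w@values), 1L)
  expect_equal(as.numeric(w@values[1, ]), as.numeric(g))
})

test_that("a shifted copy of a non-repeating sequence is fully deterministic", {
  # unique codes: the only recurrent cells are the shifted diagonal
  x <- as.numeric(1:70)
  y <- c(99, x[-70])
  w <- windowedCRQA(x, y, windowSize = 30, step = 13,
                    datatype = "categorical")
  expect_equal(w@values$DET, rep(100, length(w@starts)))
  expect_equal(w@values$Lmax, rep(29, length(w@starts)))
})

test_that("windows are pure: results match independent recomputation", {
  set.seed(72)
  x <- sample(1:3, 70, replace = TRUE)
  y <- c(99, x[-70])
  w <- windowedCRQA(x, y, windowSize = 30, step = 13,
                    datatype = "categorical")
  pair <- codeCategorical(x, y)
  for (k in seq_along(w@starts)) {
    idx <- seq(w@starts[k], w@starts[k] + 29)
    solo <- as.data.frame(crqa(pair[[1]]@values[idx],
                               pair[[2]]@values[idx]))
    expect_equal(as.numeric(w@values[k, ]), as.numeric(solo))
  }
})

test_that("profile serialization writes lag table and summary sidecar", {
  p <- diagonalRecurrenceProfile(c(1, 2, 1, 2), c(2, 1, 2, 1), 1,
                                 datatype = "categorical")
  f <- tempfile(fileext = ".csv")
  writeProfile(p, f)
  expect_equal(utils::read.csv(f), data.frame(lag = -1:1, rr = p@rr),
               ignore_attr = TRUE)
  side <- jsonlite::read_json(sub("csv$", "json", f),
                              simplifyVector = TRUE)
  expect_equal(side$maxlag, p@maxlag)
})
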