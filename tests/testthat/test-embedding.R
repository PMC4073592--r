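test_that("delay embedding reproduces its defining layout", {
  x <- rnorm(50)
  e <- embedSeries(x, delay = 5, embedDim = 1)
  expect_identical(dim(e@points), c(50L, 1L))
  expect_equal(e@points[, 1], x)

  e2 <- embedSeries(1:5, delay = 1, embedDim = 2)
  expect_equal(e2@points,
               cbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))

  e3 <- embedSeries(rnorm(1000), delay = 10, embedDim = 3)
  expect_identical(dim(e3@points), c(980L, 3L))

  expect_error(embedSeries(rnorm(10), delay = 5, embedDim = 3),
               "insufficient length.*minimum length 11")
})

test_that("embedding matches a loop-based construction", {
  set.seed(11)
  for (cfg in list(c(1, 1), c(2, 3), c(4, 2), c(3, 4))) {
    v <- rnorm(60)
    expect_equal(embedSeries(v, cfg[1], cfg[2])@points,
                 oracleEmbed(v, cfg[1], cfg[2]))
  }
})

test_that("cross distances are Euclidean, symmetric and oracle-exact", {
  a <- embedSeries(c(0, 1, 2), 1, 1)
  b <- embedSeries(c(0, 0, 0), 1, 1)
  expect_equal(crossDistanceMatrix(a, b),
               rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)))

  set.seed(21)
  v <- rnorm(52)
  e <- embedSeries(v, 1, 3)
  D <- crossDistanceMatrix(e, e)
  expect_equal(unname(diag(D)), rep(0, nrow(D)), tolerance = 1e-6)
  expect_equal(D, t(D))

  w <- rnorm(52)
  D2 <- crossDistanceMatrix(e, embedSeries(w, 1, 3))
  expect_equal(D2, oracleDist(e@points, oracleEmbed(w, 1, 3)))

  expect_error(crossDistanceMatrix(e, embedSeries(w, 1, 2)),
               "dimensions differ")
})

test_that("distance rescaling divides by the mean or max, as a percentage", {
  set.seed(3)
  e1 <- embedSeries(rnorm(30), 1, 2)
  e2 <- embedSeries(rnorm(30), 1, 2)
  D <- crossDistanceMatrix(e1, e2)
  expect_equal(crossDistanceMatrix(e1, e2, "mean"), 100 * D / mean(D))
  expect_equal(crossDistanceMatrix(e1, e2, "max"), 100 * D / max(D))
  expect_equal(max(crossDistanceMatrix(e1, e2, "max")), 100)
})

test_that("thresholding marks exactly the cells within the radius", {
  R <- crossRecurrenceMatrix(c(0, 1, 0), c(0, 0, 1), radius = 0.5)
  expect_equal(recurrentPoints(R),
               data.frame(i = c(1L, 1L, 2L, 3L, 3L),
                          j = c(1L, 2L, 3L, 1L, 2L)))
  expect_equal(recurrenceRate(R), 100 * 5 / 9)

  # categorical limit: near-zero radius admits only identical codes
  x <- c(1, 2, 3, 2); y <- c(2, 2, 1, 3)
  Rc <- crossRecurrenceMatrix(x, y, radius = 0.001,
                              datatype = "categorical")
  expect_equal(as.matrix(Rc@points), outer(x, y, "=="),
               ignore_attr = TRUE)

  # saturation
  D <- crossDistanceMatrix(embedSeries(rnorm(8), 1, 1),
                           embedSeries(rnorm(8), 1, 1))
  expect_equal(recurrenceRate(thresholdRecurrence(D, max(D))), 100)
  expect_error(thresholdRecurrence(D, -1), "non-negative")
})

test_that("recurrence count is monotone in the radius", {
  set.seed(5)
  D <- crossDistanceMatrix(embedSeries(rnorm(40), 2, 2),
                           embedSeries(rnorm(40), 2, 2))
  counts <- vapply(seq(0, max(D), length.out = 12),
                   function(r) nrow(recurrentPoints(thresholdRecurrence(D, r))),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[12], length(D))
})

test_that("swapping the series transposes the recurrence matrix", {
  set.seed(6)
  for (k in 1:5) {
    x <- rnorm(30); y <- rnorm(25)
    R1 <- crossRecurrenceMatrix(x, y, radius = 0.8)
    R2 <- crossRecurrenceMatrix(y, x, radius = 0.8)
    expect_equal(as.matrix(R1@points), t(as.matrix(R2@points)),
                 ignore_attr = TRUE)
  }
})

test_that("identical inputs at radius 0 recur along the whole LOC", {
  x <- rnorm(20)
  R <- crossRecurrenceMatrix(x, x, radius = 0)
  pts <- recurrentPoints(R)
  expect_true(all(paste(1:20, 1:20) %in% paste(pts$i, pts$j)))
})

test_that("Theiler masking removes exactly the requested diagonals", {
  R <- recurrenceFromPoints(rep(1:3, each = 3), rep(1:3, 3), c(3, 3))
  expect_identical(applyTheilerWindow(R, 0), R)
  expect_equal(nrow(recurrentPoints(applyTheilerWindow(R, 1))), 6L)
  R2 <- applyTheilerWindow(R, 2)
  expect_equal(recurrentPoints(R2),
               data.frame(i = c(1L, 3L), j = c(3L, 1L)))
  expect_equal(theilerWindow(R2), 2L)
  expect_error(applyTheilerWindow(R, 3), "mask every diagonal")
  Rrect <- recurrenceFromPoints(1, 1, c(2, 3))
  expect_error(applyTheilerWindow(Rrect, 1), "square")
})

test_that("sparse export round-trips coordinates and metadata", {
  R <- crossRecurrenceMatrix(c(1, 2, 1), c(1, 1, 2), radius = 0.001,
                             datatype = "categorical")
  csv <- tempfile(fileext = ".csv")
  side <- exportRecurrence(R, csv)
  expect_equal(utils::read.csv(csv), recurrentPoints(R))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  expect_equal(meta$dims, c(3L, 3L))
  expect_equal(meta$radius, 0.001)
})
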