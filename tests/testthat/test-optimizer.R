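test_that("AMI matches a loop-based recomputation and picks the first minimum", {
  x <- sin(2 * pi * seq_len(1000) / 100)   # 100 samples per cycle
  res <- amiDelay(x, maxLag = 40)
  curve <- oracleAMI(x, 40)
  expect_equal(unname(res$ami), curve, tolerance = 1e-10)
  oracleDelay <- firstLocalMin(curve)
  expect_lte(abs(res$delay - oracleDelay), 2)
  expect_lte(abs(res$delay - 25), 2)       # quarter period
})

test_that("structureless noise needs no delay", {
  set.seed(91)
  x <- rnorm(2000)
  res <- amiDelay(x, maxLag = 20)
  expect_true(all(res$ami[-1] < 0.1))      # near zero beyond lag 0
  expect_equal(res$delay, 1L)
})

test_that("constant series are rejected before any AMI computation", {
  expect_error(amiDelay(rep(2, 100)), "zero variance")
  expect_error(optimizeParams(rep(1, 200), rnorm(200)),
               "delay \\(AMI\\).*zero variance")
})

test_that("delay combination averages close delays, keeps distant maxima", {
  expect_equal(combineDelays(10, 10), 10L)
  expect_equal(combineDelays(10, 14), 12L)
  expect_equal(combineDelays(14, 10), 12L)
  expect_equal(combineDelays(5, 40), 40L)
})

test_that("false nearest neighbours unfold a sine onto a circle", {
  x <- sin(2 * pi * seq_len(600) / 100)
  res <- fnnEmbedding(x, delay = 25, maxDim = 4)
  expect_equal(res$embedDim, 2L)
  expect_gt(res$fnn[1], res$fnn[2])
  expect_lte(res$fnn[2], 0.05)
  # forced single dimension
  expect_equal(fnnEmbedding(rnorm(100), delay = 1, maxDim = 1)$embedDim, 1L)
  expect_error(fnnEmbedding(rnorm(10), delay = 20, maxDim = 2),
               "too short")
})

test_that("radius search lands in the target recurrence band", {
  set.seed(92)
  x <- rnorm(800); y <- rnorm(800)
  res <- radiusSearch(x, y, delay = 1, embedDim = 1)
  expect_gte(res$achievedRR, 2)
  expect_lte(res$achievedRR, 5)
  # achieved rate is the exact recurrence rate at that radius
  R <- crossRecurrenceMatrix(x, y, radius = res$radius)
  expect_equal(recurrenceRate(R), res$achievedRR, tolerance = 1e-10)
})

test_that("integer-coded series only recur below the unit distance gap", {
  set.seed(93)
  x <- as.numeric(sample(1:4, 300, replace = TRUE))
  y <- as.numeric(sample(1:4, 300, replace = TRUE))
  res <- radiusSearch(x, y, delay = 1, embedDim = 1,
                      targetRR = c(10, 40))
  expect_lt(res$radius, 1)   # any candidate below 1 admits exact matches only
  R <- crossRecurrenceMatrix(x, y, radius = res$radius)
  expect_equal(as.matrix(R@points), outer(x, y, "=="), ignore_attr = TRUE)
})

test_that("widening the target band never increases the returned radius", {
  set.seed(94)
  x <- rnorm(500); y <- rnorm(500)
  r1 <- radiusSearch(x, y, targetRR = c(2, 5))$radius
  r2 <- radiusSearch(x, y, targetRR = c(2, 10))$radius
  r3 <- radiusSearch(x, y, targetRR = c(1, 10))$radius
  expect_lte(r2, r1)
  expect_lte(r3, r2)
})

test_that("unreachable targets error and carry the evaluation trace", {
  x <- as.numeric(rep(1:2, 50))
  y <- as.numeric(rep(1:2, 50))
  # distances are only ever 0 or 1: a 1e-6-wide band between them is unreachable
  err <- tryCatch(radiusSearch(x, y, targetRR = c(1e-7, 2e-7)),
                  xrqa_radius_error = function(e) e)
  expect_s3_class(err, "xrqa_radius_error")
  expect_true(is.data.frame(err$trace) && nrow(err$trace) > 0)
})

test_that("the three-step optimizer recovers sensible parameters", {
  # two incommensurate sines: a 2-torus flow proxy needing dim >= 2
  mk <- function(ph) sin(2 * pi * seq_len(700) / 80 + ph) +
                     0.7 * sin(2 * pi * sqrt(2) * seq_len(700) / 80 + ph)
  worstDelay <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- mk(stats::runif(1, 0, 2 * pi)) + stats::rnorm(700, sd = 0.02)
    curve <- oracleAMI(x, 40)
    res <- amiDelay(x, maxLag = 40)
    oracleD <- firstLocalMin(curve)
    if (!is.na(oracleD))
      worstDelay <- max(worstDelay, abs(res$delay - oracleD))
    fnn <- fnnEmbedding(x, delay = res$delay, maxDim = 5)
    expect_gte(fnn$embedDim, 2)
  }
  expect_lte(worstDelay, 2)
})

test_that("the composed optimizer reports an RR inside its band", {
  t <- seq_len(500)
  x <- sin(2 * pi * t / 100)
  y <- sin(2 * pi * t / 100 + 0.4)
  opt <- optimizeParams(x, y, maxLag = 40, maxDim = 4)
  expect_lte(abs(opt@delay - 25), 3)
  expect_equal(opt@embedDim, 2L)
  expect_gte(opt@achievedRR, 2)
  expect_lte(opt@achievedRR, 5)
  expect_named(opt@diagnostics,
               c("amiX", "amiY", "delayX", "delayY", "fnnX", "fnnY",
                 "radiusTrace"))
})
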