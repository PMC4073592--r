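test_that("contingency tables count lagged co-occurrences", {
  # identical series at lag 0: diagonal = state frequencies
  x <- c(1, 2, 1, 1, 3)
  st <- contingencyStack(x, x, maxLag = 0)
  tb <- contingencyTable(st, 0)
  expect_equal(unname(diag(tb)), c(3, 1, 1))
  expect_equal(sum(tb) - sum(diag(tb)), 0)

  # alternating series, lag 0: pure mismatch
  st2 <- contingencyStack(c(1, 2, 1, 2), c(2, 1, 2, 1), maxLag = 1)
  tb0 <- contingencyTable(st2, 0)
  expect_equal(tb0["1", "2"], 2)
  expect_equal(tb0["2", "1"], 2)
  expect_equal(unname(diag(tb0)), c(0, 0))

  # aligning y one step later matches perfectly: x(t) vs y(t + 1),
  # which is lag -1 under the display convention
  tbl <- contingencyTable(st2, -1)
  expect_equal(tbl["1", "1"], 2)
  expect_equal(tbl["2", "2"], 1)
  expect_equal(sum(tbl), 3)
  expect_equal(contingencyProfile(st2)@rr[st2@lags == -1], 100)
})

test_that("per-lag totals equal the valid comparison count", {
  set.seed(81)
  x <- sample(letters[1:4], 40, replace = TRUE)
  y <- sample(letters[2:6], 40, replace = TRUE)
  st <- contingencyStack(x, y, maxLag = 6)
  for (k in seq_along(st@lags))
    expect_equal(sum(st@tables[, , k]), 40 - abs(st@lags[k]))
})

test_that("disjoint alphabets are rejected with both alphabets named", {
  expect_error(contingencyStack(c("a", "b"), c("c", "d"), 0),
               "no shared states.*a, b.*c, d")
})

test_that("contingency recurrence equals the diagonal profile exactly", {
  set.seed(82)
  for (k in 1:50) {
    n <- sample(20:60, 1)
    S <- sample(2:6, 1)
    x <- sample(seq_len(S), n, replace = TRUE)
    y <- sample(seq_len(S), n, replace = TRUE)
    W <- sample(1:5, 1)
    fromCT <- contingencyProfile(contingencyStack(x, y, W))
    direct <- diagonalRecurrenceProfile(x, y, W, datatype = "categorical")
    expect_identical(fromCT@lags, direct@lags)
    expect_equal(fromCT@rr, direct@rr)
    expect_equal(fromCT@maxlag, direct@maxlag)
  }
})

test_that("states unique to one series stay as not-k mass", {
  x <- c("a", "a", "b")   # "b" never occurs in y
  y <- c("a", "c", "a")   # "c" never occurs in x
  st <- contingencyStack(x, y, 0)
  expect_equal(st@commonStates, "a")
  expect_equal(sum(contingencyTable(st, 0)), 3)
  p <- contingencyProfile(st)
  expect_equal(p@rr, 100 * 1 / 3)  # only the (a, a) pair at t = 1
})

test_that("phi matches the 2x2 closed form and its limits", {
  phiOf <- function(tb2) {
    a <- tb2[1, 1]; b <- tb2[1, 2]; cc <- tb2[2, 1]; d <- tb2[2, 2]
    (a * d - b * cc) / sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
  }
  # perfect match on k and not-k
  x <- c(1, 1, 2, 2, 1); y <- x
  st <- contingencyStack(x, y, 0)
  expect_equal(phiProfile(st, "1")@phi, 1)
  # independence: collapsed table (1,1),(1,1)
  x2 <- c(1, 1, 2, 2); y2 <- c(1, 2, 1, 2)
  expect_equal(phiProfile(contingencyStack(x2, y2, 0), "1")@phi, 0)
  # collapsed table (2,1),(1,2) -> 3/9 = 1/3
  x3 <- c(1, 1, 1, 2, 2, 2); y3 <- c(1, 1, 2, 1, 2, 2)
  got <- phiProfile(contingencyStack(x3, y3, 0), "1")@phi
  expect_equal(got, (4 - 1) / sqrt(81))
  expect_equal(got, phiOf(matrix(c(2, 1, 1, 2), 2, byrow = TRUE)))
})

test_that("zero margins yield NaN with a warning count", {
  x <- c(1, 1, 1); y <- c(1, 2, 1)   # x never leaves state 1
  expect_warning(p <- phiProfile(contingencyStack(x, y, 0), "1"),
                 "zero margin")
  expect_true(is.nan(p@phi))
  expect_equal(p@nUndefined, 1L)
})

test_that("phi is invariant under relabeling the state in both series", {
  set.seed(83)
  x <- sample(c("a", "b", "c"), 60, replace = TRUE)
  y <- sample(c("a", "b", "c"), 60, replace = TRUE)
  p1 <- phiProfile(contingencyStack(x, y, 3), "a")
  relab <- function(v) ifelse(v == "a", "z", v)
  p2 <- phiProfile(contingencyStack(relab(x), relab(y), 3), "z")
  expect_equal(p1@phi, p2@phi)
})

test_that("stack export is long-format (lag, state_i, state_j, count)", {
  st <- contingencyStack(c(1, 2), c(2, 1), 1)
  f <- tempfile(fileext = ".csv")
  writeContingency(st, f)
  df <- utils::read.csv(f)
  expect_equal(names(df), c("lag", "state_i", "state_j", "count"))
  expect_equal(sum(df$count[df$lag == 0]), 2)
})
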