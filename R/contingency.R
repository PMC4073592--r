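## Contingency-table recurrence for categorical sequences.
##
## At each displayed lag l the S x S table counts co-occurrences of state
## i in series 1 at time t with state j in series 2 at time t - l (same
## sign convention as the diagonal profiles: negative l = series 1 leads).
## Summing the diagonal cells over the states shared by both series and
## dividing by the table total reproduces the lagged matching recurrence
## rate, which makes categorical cross-recurrence a form of lag
## sequential analysis.

.stackAlphabet <- function(x, y) {
  if (is(x, "CodedTimeSeries") && is(y, "CodedTimeSeries") &&
      identical(x@datatype, "categorical") &&
      identical(y@datatype, "categorical") &&
      identical(x@levels, y@levels)) {
    list(vx = x@values, vy = y@values, levels = x@levels)
  } else {
    lx <- if (is(x, "CodedTimeSeries")) .seriesLabels(x) else as.character(x)
    ly <- if (is(y, "CodedTimeSeries")) .seriesLabels(y) else as.character(y)
    pair <- codeCategorical(lx, ly)
    list(vx = pair[[1L]]@values, vy = pair[[2L]]@values,
         levels = pair[[1L]]@levels)
  }
}

#' Per-lag contingency tables of two categorical series
#'
#' For each lag in -maxLag..+maxLag, builds the table of co-occurrence
#' counts between the states of the two series, over the valid time
#' points at that lag (so each table totals T - |lag|). The state list is
#' the union of both alphabets, shared states first; at least one shared
#' state is required.
#'
#' @param x,y categorical series (vectors of labels or
#'   [CodedTimeSeries-class] objects).
#' @param maxLag integer lag window W.
#' @return a [ContingencyStack-class].
#' @examples
#' contingencyStack(c(1, 2, 1, 2), c(2, 1, 2, 1), maxLag = 1)
#' @export
contingencyStack <- function(x, y, maxLag) {
  maxLag <- as.integer(maxLag)
  if (is.na(maxLag) || maxLag < 0L)
    stop("maxLag must be a non-negative integer")
  ab <- .stackAlphabet(x, y)
  vx <- ab$vx; vy <- ab$vy
  n <- min(length(vx), length(vy))
  vx <- vx[seq_len(n)]; vy <- vy[seq_len(n)]
  if (maxLag >= n)
    stop("maxLag must be smaller than the comparable series length")
  common <- intersect(ab$levels[unique(vx)], ab$levels[unique(vy)])
  common <- ab$levels[ab$levels %in% common]   # keep alphabet order
  if (length(common) == 0L)
    stop(sprintf("no shared states: series 1 uses {%s}, series 2 uses {%s}",
                 paste(sort(unique(ab$levels[vx])), collapse = ", "),
                 paste(sort(unique(ab$levels[vy])), collapse = ", ")))
  S <- length(ab$levels)
  lags <- seq.int(-maxLag, maxLag)
  tabs <- array(0, dim = c(S, S, length(lags)),
                dimnames = list(ab$levels, ab$levels, as.character(lags)))
  for (k in seq_along(lags)) {
    l <- lags[k]
    ts <- seq.int(max(1L, 1L + l), min(n, n + l))
    js <- ts - l
    tabs[, , k] <- table(factor(vx[ts], levels = seq_len(S)),
                         factor(vy[js], levels = seq_len(S)))
  }
  new("ContingencyStack", states = ab$levels, commonStates = common,
      lags = as.integer(lags), tables = tabs)
}

#' Accessor: per-lag contingency table
#'
#' @param stack a [ContingencyStack-class].
#' @param lag integer lag present in the stack.
#' @return S x S numeric count matrix with state dimnames.
#' @export
contingencyTable <- function(stack, lag) {
  stopifnot(is(stack, "ContingencyStack"))
  k <- match(as.integer(lag), stack@lags)
  if (is.na(k)) stop("lag not present in the stack")
  stack@tables[, , k]
}

#' Recurrence profile from a contingency stack
#'
#' The per-lag recurrence rate is the summed diagonal of the table over
#' the shared states (matching states), divided by the table total. On
#' the same categorical inputs this reproduces
#' [diagonalRecurrenceProfile()] lag by lag.
#'
#' @param stack a [ContingencyStack-class].
#' @return a [DiagonalProfile-class].
#' @export
contingencyProfile <- function(stack) {
  stopifnot(is(stack, "ContingencyStack"))
  ci <- match(stack@commonStates, stack@states)
  rr <- vapply(seq_along(stack@lags), function(k) {
    tb <- stack@tables[, , k]
    100 * sum(tb[cbind(ci, ci)]) / sum(tb)
  }, numeric(1))
  new("DiagonalProfile", lags = stack@lags, rr = rr,
      maxrec = max(rr), maxlag = .tieBreakMax(stack@lags, rr))
}

#' Per-state phi-coefficient profile
#'
#' Collapses each lag's table to the 2 x 2 table over {k, not-k} and
#' computes the Pearson phi coefficient
#' \deqn{\phi = (ad - bc) / \sqrt{(a+b)(c+d)(a+c)(b+d)}}
#' with a = both in k, b = series 1 in k only, c = series 2 in k only,
#' d = neither. Phi grows with matching visits to k (and to not-k) and
#' shrinks with mismatches. Lags with any zero margin are NaN and counted
#' in \code{nUndefined}.
#'
#' @param stack a [ContingencyStack-class].
#' @param state a state label shared by both series.
#' @return a [PhiProfile-class].
#' @export
phiProfile <- function(stack, state) {
  stopifnot(is(stack, "ContingencyStack"))
  state <- as.character(state)
  if (!state %in% stack@commonStates)
    stop(sprintf("state '%s' is not shared by both series", state))
  ki <- match(state, stack@states)
  phi <- vapply(seq_along(stack@lags), function(k) {
    tb <- stack@tables[, , k]
    a <- tb[ki, ki]
    b <- sum(tb[ki, ]) - a
    cc <- sum(tb[, ki]) - a
    d <- sum(tb) - a - b - cc
    denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
    if (denom == 0) return(NaN)
    (a * d - b * cc) / sqrt(denom)
  }, numeric(1))
  if (any(is.nan(phi)))
    warning(sprintf("%d of %d lags have a zero margin; phi is NaN there",
                    sum(is.nan(phi)), length(phi)))
  new("PhiProfile", state = state, lags = stack@lags, phi = phi,
      nUndefined = sum(is.nan(phi)))
}

#' Export a contingency stack as long-format CSV
#'
#' One row per (lag, state_i, state_j) with the co-occurrence count.
#'
#' @param stack a [ContingencyStack-class].
#' @param file CSV path.
#' @return invisibly, \code{file}.
#' @export
writeContingency <- function(stack, file) {
  stopifnot(is(stack, "ContingencyStack"))
  S <- length(stack@states)
  grid <- expand.grid(state_i = stack@states, state_j = stack@states,
                      lag = stack@lags, stringsAsFactors = FALSE)
  grid$count <- as.vector(stack@tables)
  utils::write.csv(grid[, c("lag", "state_i", "state_j", "count")], file,
                   row.names = FALSE)
  invisible(file)
}
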