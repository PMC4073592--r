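## Diagonal-wise and windowed recurrence profiles.
##
## Lag sign convention: rr(l) compares x(t) with y(t - l), so negative
## lags mean the first series LEADS the second. A recurrent point on
## diagonal offset d = j - i of the plot contributes to lag l = -d.

.tieBreakMax <- function(lags, values) {
  ## largest value; ties -> smallest |lag|; still tied -> negative lag
  ord <- order(-values, abs(lags), lags)
  lags[ord[1L]]
}

## Original-label view of a series, for non-event exclusion.
.seriesLabels <- function(s) {
  if (is(s, "CodedTimeSeries") && identical(s@datatype, "categorical"))
    s@levels[s@values]
  else as.character(seriesValues(s))
}

.drpCore <- function(vx, vy, W, delay, embedDim, radius, rescale = "none",
                     mx = NULL, my = NULL) {
  n <- min(length(vx), length(vy))
  vx <- vx[seq_len(n)]; vy <- vy[seq_len(n)]
  ex <- embedSeries(vx, delay, embedDim)@points
  ey <- embedSeries(vy, delay, embedDim)@points
  ne <- nrow(ex)
  if (W >= ne)
    stop(sprintf("lag window W = %d must be smaller than the %d comparable points",
                 W, ne))
  if (!is.null(mx) && embedDim > 1L)
    stop("non-event exclusion is only defined for unembedded (embedDim = 1) series")
  if (!is.null(mx)) { mx <- mx[seq_len(n)]; my <- my[seq_len(n)] }
  useD <- !identical(rescale, "none")
  if (useD) {
    D <- crossDistanceMatrix(
      embedSeries(vx, delay, embedDim), embedSeries(vy, delay, embedDim),
      rescale = rescale)
  }
  lags <- seq.int(-W, W)
  rr <- vapply(lags, function(l) {
    ts <- seq.int(max(1L, 1L + l), min(ne, ne + l))
    js <- ts - l
    d <- if (useD) D[cbind(ts, js)]
         else sqrt(rowSums((ex[ts, , drop = FALSE] -
                            ey[js, , drop = FALSE])^2))
    rec <- d <= radius
    if (!is.null(mx)) rec <- rec & !(mx[ts] & my[js])
    100 * sum(rec) / length(ts)
  }, numeric(1))
  list(lags = as.integer(lags), rr = rr)
}

#' Diagonal-wise recurrence profile
#'
#' Recurrence rate per lag over a symmetric window of lags around the
#' line of coincidence: rr(l) is the percentage of time points t at which
#' x(t) and y(t - l) recur, out of the valid comparisons at that lag
#' (T - |l|). The profile's argmax estimates the leader-follower lag;
#' negative lags mean the first series leads.
#'
#' For categorical sequences use a radius near 0 (e.g. 0.001), so only
#' identical states recur. \code{excludeNonevent} drops matches where both
#' series sit in the named state (typically the non-event code 0) from the
#' numerator, so that recurrence counts events only.
#'
#' @inheritParams crossRecurrenceMatrix
#' @param maxLag integer W; the profile covers lags -W..+W and requires
#'   W to be smaller than the number of comparable points.
#' @param excludeNonevent optional state (original label) whose
#'   simultaneous occurrence in both series is not counted as recurrence;
#'   only meaningful for unembedded series.
#' @return a [DiagonalProfile-class] with per-lag rates, the maximum rate
#'   and the lag attaining it (ties resolved towards the smallest
#'   absolute, then the negative, lag).
#' @examples
#' x <- rep(1:3, 20)
#' y <- c(9, x[-60])   # y trails x by one step
#' diagonalRecurrenceProfile(x, y, maxLag = 3, datatype = "categorical")
#' @export
diagonalRecurrenceProfile <- function(x, y, maxLag, delay = 1L,
                                      embedDim = 1L, radius = 0.001,
                                      datatype = c("continuous",
                                                   "categorical"),
                                      normalize = c("none", "zscore"),
                                      rescale = c("none", "mean", "max"),
                                      excludeNonevent = NULL) {
  datatype <- match.arg(datatype)
  maxLag <- as.integer(maxLag)
  if (is.na(maxLag) || maxLag < 0L)
    stop("maxLag must be a non-negative integer")
  pair <- .seriesPair(x, y, datatype, match.arg(normalize))
  mx <- my <- NULL
  if (!is.null(excludeNonevent)) {
    ne <- as.character(excludeNonevent)
    mx <- .seriesLabels(if (is(x, "CodedTimeSeries")) x else
                          .asSeries(x, pair$datatype)) == ne
    my <- .seriesLabels(if (is(y, "CodedTimeSeries")) y else
                          .asSeries(y, pair$datatype)) == ne
  }
  core <- .drpCore(pair$x, pair$y, maxLag, delay, embedDim, radius,
                   match.arg(rescale), mx, my)
  new("DiagonalProfile", lags = core$lags, rr = core$rr,
      maxrec = max(core$rr),
      maxlag = .tieBreakMax(core$lags, core$rr))
}

.windowStarts <- function(n, windowSize, step) {
  if (windowSize > n)
    stop(sprintf("series of %d comparable points is shorter than the window size %d",
                 n, windowSize))
  seq.int(1L, n - windowSize + 1L, by = step)
}

#' Windowed diagonal recurrence profile
#'
#' Tracks how recurrence develops along the time course: in overlapping
#' windows advanced by \code{step}, the diagonal recurrence profile over
#' lags -lagWindow..+lagWindow is computed within the window and averaged
#' over the lags, yielding one recurrence value per window. Trailing
#' partial windows are dropped.
#'
#' @inheritParams diagonalRecurrenceProfile
#' @param windowSize integer window length (samples).
#' @param step integer advance between window starts (>= 1).
#' @param lagWindow integer lag window; the delays considered must be
#'   smaller than the size of the window.
#' @return a [WindowedProfile-class] whose \code{values} data frame has
#'   one \code{rr} column.
#' @export
windowedRecurrenceProfile <- function(x, y, windowSize, step, lagWindow,
                                      delay = 1L, embedDim = 1L,
                                      radius = 0.001,
                                      datatype = c("continuous",
                                                   "categorical"),
                                      normalize = c("none", "zscore"),
                                      rescale = c("none", "mean", "max"),
                                      excludeNonevent = NULL) {
  datatype <- match.arg(datatype); rescale <- match.arg(rescale)
  windowSize <- as.integer(windowSize); step <- as.integer(step)
  lagWindow <- as.integer(lagWindow)
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  if (is.na(lagWindow) || lagWindow < 0L)
    stop("lagWindow must be a non-negative integer")
  if (lagWindow >= windowSize)
    stop("lagWindow must be smaller than windowSize: the delays considered must be smaller than the size of the window")
  pair <- .seriesPair(x, y, datatype, match.arg(normalize))
  n <- min(length(pair$x), length(pair$y))
  mx <- my <- NULL
  if (!is.null(excludeNonevent)) {
    ne <- as.character(excludeNonevent)
    mx <- .seriesLabels(if (is(x, "CodedTimeSeries")) x else
                          .asSeries(x, pair$datatype)) == ne
    my <- .seriesLabels(if (is(y, "CodedTimeSeries")) y else
                          .asSeries(y, pair$datatype)) == ne
  }
  starts <- .windowStarts(n, windowSize, step)
  vals <- vapply(starts, function(s) {
    idx <- seq.int(s, s + windowSize - 1L)
    core <- .drpCore(pair$x[idx], pair$y[idx], lagWindow, delay, embedDim,
                     radius, rescale,
                     if (is.null(mx)) NULL else mx[idx],
                     if (is.null(my)) NULL else my[idx])
    mean(core$rr)
  }, numeric(1))
  new("WindowedProfile", starts = starts, windowSize = windowSize,
      step = step, lagWindow = lagWindow,
      values = data.frame(rr = vals))
}

#' Windowed full cross-recurrence quantification
#'
#' Computes the complete set of recurrence measures (see [rqaMeasures()])
#' in overlapping windows along the common time course. Degenerate
#' windows (e.g. zero variance under z-scoring) yield NaN measures rather
#' than aborting the sweep.
#'
#' @inheritParams windowedRecurrenceProfile
#' @param minline minimum line length for the line-based measures.
#' @param theilerWindow diagonals to mask within each window.
#' @return a [WindowedProfile-class] whose \code{values} data frame has
#'   columns RR, DET, L, Lmax, ENTR, LAM, TT.
#' @export
windowedCRQA <- function(x, y, windowSize, step, delay = 1L, embedDim = 1L,
                         radius = 0.001, theilerWindow = 0L, minline = 2L,
                         datatype = c("continuous", "categorical"),
                         normalize = c("none", "zscore"),
                         rescale = c("none", "mean", "max")) {
  datatype <- match.arg(datatype)
  normalize <- match.arg(normalize); rescale <- match.arg(rescale)
  windowSize <- as.integer(windowSize); step <- as.integer(step)
  if (is.na(step) || step < 1L) stop("step must be a positive integer")
  pair <- .seriesPair(x, y, datatype, "none")
  n <- min(length(pair$x), length(pair$y))
  starts <- .windowStarts(n, windowSize, step)
  nanRow <- data.frame(RR = NaN, DET = NaN, L = NaN, Lmax = NaN,
                       ENTR = NaN, LAM = NaN, TT = NaN)
  rows <- lapply(starts, function(s) {
    idx <- seq.int(s, s + windowSize - 1L)
    tryCatch(as.data.frame(
      crqa(pair$x[idx], pair$y[idx], delay = delay, embedDim = embedDim,
           radius = radius, theilerWindow = theilerWindow,
           minline = minline, datatype = "continuous",
           normalize = normalize, rescale = rescale)),
      error = function(e) nanRow)
  })
  new("WindowedProfile", starts = starts, windowSize = windowSize,
      step = step, lagWindow = NA_integer_,
      values = do.call(rbind, rows))
}

#' Write a profile object to CSV (plus JSON summary for lag profiles)
#'
#' Diagonal profiles are written as a (lag, rr) CSV with a JSON sidecar
#' recording \code{maxrec} and \code{maxlag}; windowed profiles as a
#' (window_start, value...) CSV.
#'
#' @param p a [DiagonalProfile-class] or [WindowedProfile-class].
#' @param file CSV path.
#' @return invisibly, \code{file}.
#' @export
writeProfile <- function(p, file) {
  if (is(p, "DiagonalProfile")) {
    utils::write.csv(as.data.frame(p), file, row.names = FALSE)
    side <- paste0(sub("\\.[^.]*$", "", file), ".json")
    jsonlite::write_json(list(maxrec = p@maxrec, maxlag = p@maxlag),
                         side, auto_unbox = TRUE, digits = NA)
  } else if (is(p, "WindowedProfile")) {
    utils::write.csv(cbind(window_start = p@starts, p@values), file,
                     row.names = FALSE)
  } else stop("not a profile object")
  invisible(file)
}
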