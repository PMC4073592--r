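#' @import methods
#' @importClassesFrom Matrix ngCMatrix
NULL

## Central S4 containers. All index pairs are 1-based; i runs along the
## first series (horizontal axis of a recurrence plot), j along the second.

#' Coded time series
#'
#' A univariate time series typed as categorical or continuous. Categorical
#' series store integer state codes together with the original labels;
#' continuous series store finite real values.
#'
#' @slot values numeric vector of observations (integer codes for
#'   categorical series).
#' @slot datatype either \code{"categorical"} or \code{"continuous"}.
#' @slot levels character vector of original state labels for categorical
#'   series, in code order; empty for continuous series.
#'
#' @seealso [codedSeries()], [codeCategorical()]
#' @export
setClass("CodedTimeSeries",
  representation(values = "numeric", datatype = "character",
                 levels = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) < 1L)
      msg <- c(msg, "series must contain at least one observation")
    if (length(object@datatype) != 1L ||
        !object@datatype %in% c("categorical", "continuous"))
      msg <- c(msg, "datatype must be 'categorical' or 'continuous'")
    if (identical(object@datatype, "continuous") &&
        any(!is.finite(object@values)))
      msg <- c(msg, "continuous series must not contain non-finite values")
    if (identical(object@datatype, "categorical")) {
      v <- object@values
      if (any(!is.finite(v)) || any(v != round(v)) || any(v < 1))
        msg <- c(msg, "categorical codes must be positive integers")
      else if (length(object@levels) < max(v))
        msg <- c(msg, "categorical codes exceed the label table")
    }
    if (length(msg)) msg else TRUE
  })

#' Delay-embedded series
#'
#' A series unfolded into delay coordinates: row t holds
#' (X(t), X(t + tau), ..., X(t + (m - 1) tau)), giving
#' T - (m - 1) tau rows for a source of length T.
#'
#' @slot points numeric matrix of delay coordinates, one row per
#'   reconstructed phase-space point.
#' @slot sourceLength integer, length T of the raw series.
#' @slot delay integer embedding delay tau (samples).
#' @slot embedDim integer number of delayed copies m.
#'
#' @seealso [embedSeries()]
#' @export
setClass("EmbeddedSeries",
  representation(points = "matrix", sourceLength = "integer",
                 delay = "integer", embedDim = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@delay < 1L) msg <- c(msg, "delay must be >= 1")
    if (object@embedDim < 1L) msg <- c(msg, "embedDim must be >= 1")
    expect <- object@sourceLength - (object@embedDim - 1L) * object@delay
    if (nrow(object@points) != expect)
      msg <- c(msg, sprintf("expected %d rows, found %d", expect,
                            nrow(object@points)))
    if (nrow(object@points) < 1L)
      msg <- c(msg, "embedding produced no points")
    if (ncol(object@points) != object@embedDim)
      msg <- c(msg, "column count must equal embedDim")
    if (length(msg)) msg else TRUE
  })

#' Recurrence matrix
#'
#' The thresholded cross-recurrence plot of two (embedded) series, stored
#' sparsely. Rows index points of the first series, columns points of the
#' second; cell (i, j) is recurrent when the two phase-space points fall
#' within the radius of each other.
#'
#' @slot points sparse pattern matrix (\code{ngCMatrix}) of recurrent cells.
#' @slot theilerWindow integer; diagonals with |j - i| <= tw - 1 have been
#'   masked out (0 means no masking, the cross-recurrence default; 1 masks
#'   exactly the main diagonal).
#' @slot radius numeric radius used for thresholding (may be length 0 when
#'   the matrix was built directly from points).
#'
#' @seealso [thresholdRecurrence()], [applyTheilerWindow()],
#'   [crossRecurrenceMatrix()]
#' @export
setClass("RecurrenceMatrix",
  representation(points = "ngCMatrix", theilerWindow = "integer",
                 radius = "numeric"),
  validity = function(object) {
    msg <- character()
    tw <- object@theilerWindow
    if (length(tw) != 1L || is.na(tw) || tw < 0L)
      msg <- c(msg, "theilerWindow must be a single non-negative integer")
    if (length(tw) == 1L && !is.na(tw) && tw >= 1L) {
      d <- dim(object@points)
      if (d[1L] != d[2L])
        msg <- c(msg, "Theiler masking requires a square matrix")
      else {
        tm <- as(object@points, "TsparseMatrix")
        if (length(tm@i) && any(abs(tm@j - tm@i) <= tw - 1L))
          msg <- c(msg, "points remain inside the Theiler band")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' The seven classical recurrence measures
#'
#' Scalar summaries of a recurrence plot: recurrence rate (RR), percentage
#' determinism (DET), mean (L) and maximal (Lmax) diagonal line length,
#' diagonal length entropy (ENTR, nats), laminarity (LAM) and trapping
#' time (TT). Line measures use maximal runs of length at least
#' \code{minline}; when no run qualifies, percentages are 0 and mean/max
#' lengths are NaN.
#'
#' @slot RR,DET,LAM numeric percentages in [0, 100].
#' @slot L,TT numeric mean qualifying diagonal / vertical line length.
#' @slot Lmax numeric longest qualifying diagonal line.
#' @slot ENTR numeric Shannon entropy (natural log) of the qualifying
#'   diagonal length distribution.
#' @slot minline integer minimum line length used.
#' @slot nPoints integer number of recurrent points.
#' @slot dims integer(2), matrix dimensions (series 1, series 2).
#'
#' @seealso [rqaMeasures()], [crqa()]
#' @export
setClass("RQAMeasures",
  representation(RR = "numeric", DET = "numeric", L = "numeric",
                 Lmax = "numeric", ENTR = "numeric", LAM = "numeric",
                 TT = "numeric", minline = "integer", nPoints = "integer",
                 dims = "integer"),
  validity = function(object) {
    msg <- character()
    pct <- c(object@RR, object@DET, object@LAM)
    if (any(!is.nan(pct) & (pct < 0 | pct > 100)))
      msg <- c(msg, "RR, DET and LAM must lie in [0, 100]")
    if (object@minline < 1L) msg <- c(msg, "minline must be >= 1")
    if (length(object@dims) != 2L) msg <- c(msg, "dims must have length 2")
    if (length(msg)) msg else TRUE
  })

#' Diagonal-wise recurrence profile
#'
#' Per-lag recurrence rate over a symmetric lag window around the line of
#' coincidence. Negative lags mean the first series leads the second.
#'
#' @slot lags integer vector -W..+W.
#' @slot rr numeric recurrence-rate percentage per lag.
#' @slot maxrec numeric maximum of \code{rr}.
#' @slot maxlag integer lag attaining \code{maxrec} (ties broken towards
#'   the smallest absolute lag, then the negative one).
#'
#' @seealso [diagonalRecurrenceProfile()], [contingencyProfile()]
#' @export
setClass("DiagonalProfile",
  representation(lags = "integer", rr = "numeric", maxrec = "numeric",
                 maxlag = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@lags) != length(object@rr))
      msg <- c(msg, "lags and rr must have equal length")
    if (any(object@rr < -1e-9 | object@rr > 100 + 1e-9, na.rm = TRUE))
      msg <- c(msg, "recurrence rates must lie in [0, 100]")
    if (length(object@maxlag) == 1L && object@maxlag %in% object@lags) {
      got <- object@rr[match(object@maxlag, object@lags)]
      if (is.finite(got) && is.finite(object@maxrec) &&
          abs(got - object@maxrec) > 1e-9)
        msg <- c(msg, "maxrec must equal rr at maxlag")
    }
    if (length(msg)) msg else TRUE
  })

#' Windowed recurrence profile
#'
#' Recurrence summaries in overlapping windows advanced along the common
#' time course of two series. For the diagonal-profile flavour each window
#' carries one value (the mean recurrence rate over the lag window); for
#' the full-CRQA flavour each window carries the seven recurrence measures.
#'
#' @slot starts integer window start indices (1-based).
#' @slot windowSize,step integer window geometry.
#' @slot lagWindow integer lag window (NA for the full-CRQA flavour).
#' @slot values data.frame with one row per window: column \code{rr}, or
#'   columns RR, DET, L, Lmax, ENTR, LAM, TT.
#'
#' @seealso [windowedRecurrenceProfile()], [windowedCRQA()]
#' @export
setClass("WindowedProfile",
  representation(starts = "integer", windowSize = "integer",
                 step = "integer", lagWindow = "integer",
                 values = "data.frame"),
  validity = function(object) {
    if (nrow(object@values) != length(object@starts))
      "one row of values per window start" else TRUE
  })

#' Per-lag contingency tables of two categorical series
#'
#' For each lag, an S x S table counting co-occurrences of state i in the
#' first series with state j in the (lagged) second series. The state list
#' is the union of both alphabets with the shared (common) states first;
#' only common states contribute to diagonal recurrence.
#'
#' @slot states character state labels indexing table rows/columns.
#' @slot commonStates character labels occurring in both series.
#' @slot lags integer vector -W..+W (display convention: negative lag =
#'   first series leads).
#' @slot tables numeric array S x S x length(lags) of counts.
#'
#' @seealso [contingencyStack()], [contingencyProfile()], [phiProfile()]
#' @export
setClass("ContingencyStack",
  representation(states = "character", commonStates = "character",
                 lags = "integer", tables = "array"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@tables)
    if (length(d) != 3L || d[1L] != length(object@states) ||
        d[2L] != length(object@states) || d[3L] != length(object@lags))
      msg <- c(msg, "tables must be S x S x nLags")
    if (!all(object@commonStates %in% object@states))
      msg <- c(msg, "commonStates must be a subset of states")
    if (length(object@commonStates) < 1L)
      msg <- c(msg, "at least one common state is required")
    tb <- object@tables
    if (any(tb < 0) || any(tb != round(tb)))
      msg <- c(msg, "counts must be non-negative integers")
    if (length(msg)) msg else TRUE
  })

#' Per-state phi-coefficient profile
#'
#' The 2 x 2 phi association coefficient between "being in state k" in the
#' two series, per lag. Lags with a zero margin are NaN.
#'
#' @slot state character, the state k.
#' @slot lags integer lags.
#' @slot phi numeric phi per lag, in [-1, 1] or NaN.
#' @slot nUndefined integer count of NaN lags (zero-margin tables).
#'
#' @seealso [phiProfile()]
#' @export
setClass("PhiProfile",
  representation(state = "character", lags = "integer", phi = "numeric",
                 nUndefined = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@lags) != length(object@phi))
      msg <- c(msg, "lags and phi must have equal length")
    ok <- is.nan(object@phi) | (object@phi >= -1 - 1e-9 &
                                object@phi <= 1 + 1e-9)
    if (!all(ok)) msg <- c(msg, "phi must lie in [-1, 1] or be NaN")
    if (length(msg)) msg else TRUE
  })

#' Optimized embedding parameters
#'
#' Result of the three-step parameter search: delay by average mutual
#' information, embedding dimension by false nearest neighbours, radius by
#' targeted recurrence-rate search. Diagnostics retain the AMI curves, FNN
#' fractions and the radius trace.
#'
#' @slot delay integer embedding delay (samples).
#' @slot embedDim integer embedding dimension.
#' @slot radius numeric selected radius.
#' @slot achievedRR numeric recurrence rate (percent) at the selected
#'   radius; inside the target band on success.
#' @slot diagnostics list of per-step diagnostic curves.
#'
#' @seealso [optimizeParams()]
#' @export
setClass("OptimalParams",
  representation(delay = "integer", embedDim = "integer",
                 radius = "numeric", achievedRR = "numeric",
                 diagnostics = "list"),
  validity = function(object) {
    msg <- character()
    if (object@delay < 1L) msg <- c(msg, "delay must be >= 1")
    if (object@embedDim < 1L) msg <- c(msg, "embedDim must be >= 1")
    if (object@radius < 0) msg <- c(msg, "radius must be >= 0")
    if (length(msg)) msg else TRUE
  })

## ---- accessors & show methods -------------------------------------------

#' @rdname recurrentPoints
#' @export
setMethod("recurrentPoints", "RecurrenceMatrix", function(object) {
  tm <- as(object@points, "TsparseMatrix")
  ord <- order(tm@i, tm@j)
  data.frame(i = tm@i[ord] + 1L, j = tm@j[ord] + 1L)
})

#' @rdname recurrenceRate
#' @export
setMethod("recurrenceRate", "RecurrenceMatrix", function(object) {
  d <- dim(object@points)
  100 * length(as(object@points, "TsparseMatrix")@i) / (d[1L] * d[2L])
})

#' @rdname recurrenceRate
#' @export
setMethod("recurrenceRate", "RQAMeasures", function(object) object@RR)

#' @rdname recurrenceRate
#' @export
setMethod("recurrenceRate", "DiagonalProfile", function(object) {
  stats::setNames(object@rr, object@lags)
})

#' @rdname theilerWindow
#' @export
setMethod("theilerWindow", "RecurrenceMatrix",
          function(object) object@theilerWindow)

#' @rdname profileLags
#' @export
setMethod("profileLags", "DiagonalProfile", function(object) object@lags)

#' @rdname profileLags
#' @export
setMethod("profileLags", "PhiProfile", function(object) object@lags)

#' @rdname profileLags
#' @export
setMethod("profileLags", "ContingencyStack", function(object) object@lags)

#' @describeIn RecurrenceMatrix matrix dimensions (series 1, series 2).
#' @param x a \code{RecurrenceMatrix}.
#' @export
setMethod("dim", "RecurrenceMatrix", function(x) dim(x@points))

setMethod("show", "CodedTimeSeries", function(object) {
  cat(sprintf("CodedTimeSeries: %s, length %d\n", object@datatype,
              length(object@values)))
  if (identical(object@datatype, "categorical"))
    cat("  states:", paste(object@levels, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "EmbeddedSeries", function(object) {
  cat(sprintf("EmbeddedSeries: %d points in %d dimensions (delay %d, T = %d)\n",
              nrow(object@points), object@embedDim, object@delay,
              object@sourceLength))
  invisible(NULL)
})

setMethod("show", "RecurrenceMatrix", function(object) {
  d <- dim(object@points)
  cat(sprintf("RecurrenceMatrix: %d x %d, %d recurrent points (RR = %.2f%%)\n",
              d[1L], d[2L], length(as(object@points, "TsparseMatrix")@i),
              recurrenceRate(object)))
  cat(sprintf("  Theiler window: %d\n", object@theilerWindow))
  invisible(NULL)
})

setMethod("show", "RQAMeasures", function(object) {
  cat("RQA measures (minline =", object@minline, "):\n")
  print(as.data.frame(object), row.names = FALSE, digits = 4)
  invisible(NULL)
})

setMethod("show", "DiagonalProfile", function(object) {
  cat(sprintf("DiagonalProfile over lags %d..%d\n", min(object@lags),
              max(object@lags)))
  cat(sprintf("  maxrec = %.3f%% at lag %d\n", object@maxrec, object@maxlag))
  invisible(NULL)
})

setMethod("show", "WindowedProfile", function(object) {
  cat(sprintf("WindowedProfile: %d windows of size %d (step %d)\n",
              length(object@starts), object@windowSize, object@step))
  invisible(NULL)
})

setMethod("show", "ContingencyStack", function(object) {
  cat(sprintf("ContingencyStack: %d states (%d common), lags %d..%d\n",
              length(object@states), length(object@commonStates),
              min(object@lags), max(object@lags)))
  invisible(NULL)
})

setMethod("show", "PhiProfile", function(object) {
  cat(sprintf("PhiProfile for state '%s', lags %d..%d (%d undefined)\n",
              object@state, min(object@lags), max(object@lags),
              object@nUndefined))
  invisible(NULL)
})

setMethod("show", "OptimalParams", function(object) {
  cat(sprintf("OptimalParams: delay = %d, embedDim = %d, radius = %g (RR = %.2f%%)\n",
              object@delay, object@embedDim, object@radius,
              object@achievedRR))
  invisible(NULL)
})

#' Coerce RQA measures to a one-row data frame
#'
#' Fixed column order RR, DET, L, Lmax, ENTR, LAM, TT.
#'
#' @param x an [RQAMeasures-class] object.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return one-row \code{data.frame}.
#' @export
as.data.frame.RQAMeasures <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(RR = x@RR, DET = x@DET, L = x@L, Lmax = x@Lmax,
             ENTR = x@ENTR, LAM = x@LAM, TT = x@TT)
}

#' Coerce a diagonal profile to a data frame
#'
#' @param x a [DiagonalProfile-class] object.
#' @param row.names,optional,... ignored.
#' @return \code{data.frame} with columns \code{lag} and \code{rr}.
#' @export
as.data.frame.DiagonalProfile <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(lag = x@lags, rr = x@rr)
}
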