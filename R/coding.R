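#' Construct a coded time series
#'
#' Wraps a vector as a typed series. Continuous input must be numeric and
#' finite. Categorical input may be integer codes, numeric labels or
#' character labels; labels are recoded to consecutive positive integers in
#' order of first appearance. To share one alphabet across two series (the
#' normal case for cross-recurrence) use [codeCategorical()].
#'
#' @param x numeric or character vector of observations.
#' @param datatype \code{"categorical"} or \code{"continuous"}.
#' @return a [CodedTimeSeries-class] object.
#' @examples
#' codedSeries(rnorm(100), "continuous")
#' codedSeries(c("dog", "cat", "dog"), "categorical")
#' @export
codedSeries <- function(x, datatype = c("continuous", "categorical")) {
  datatype <- match.arg(datatype)
  if (length(x) < 1L)
    stop("series must contain at least one observation")
  if (anyNA(x))
    stop("series contains missing values")
  if (datatype == "continuous") {
    if (!is.numeric(x))
      stop("continuous series must be numeric")
    return(new("CodedTimeSeries", values = as.numeric(x),
               datatype = "continuous", levels = character()))
  }
  labs <- as.character(x)
  lev <- unique(labs)
  new("CodedTimeSeries", values = as.numeric(match(labs, lev)),
      datatype = "categorical", levels = lev)
}

#' Code two categorical series over a shared alphabet
#'
#' Assigns consecutive integer codes shared by both series, with the
#' common states (those occurring in both) coded first in order of first
#' appearance, followed by states unique to each series.
#'
#' @param x,y vectors of state labels (numeric or character).
#' @return list of two [CodedTimeSeries-class] objects with identical
#'   \code{levels}.
#' @examples
#' codeCategorical(c("a", "b", "a"), c("b", "c", "b"))
#' @export
codeCategorical <- function(x, y) {
  if (anyNA(x) || anyNA(y)) stop("series contain missing values")
  lx <- as.character(x); ly <- as.character(y)
  ux <- unique(lx); uy <- unique(ly)
  common <- ux[ux %in% uy]
  lev <- c(common, setdiff(ux, common), setdiff(uy, common))
  mk <- function(l) new("CodedTimeSeries",
                        values = as.numeric(match(l, lev)),
                        datatype = "categorical", levels = lev)
  list(mk(lx), mk(ly))
}

## Accept plain vectors anywhere a series is expected.
.asSeries <- function(x, datatype = "continuous") {
  if (is(x, "CodedTimeSeries")) return(x)
  codedSeries(x, datatype)
}

## z-score a value vector; errors on zero variance.
.zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot z-score series")
  (v - mean(v)) / s
}

## Resolve the pair of value vectors for an analysis, honouring datatype
## (shared categorical coding) and normalization.
.seriesPair <- function(x, y, datatype = "continuous",
                        normalize = c("none", "zscore")) {
  normalize <- match.arg(normalize)
  if (is(x, "CodedTimeSeries") && is(y, "CodedTimeSeries")) {
    datatype <- x@datatype
    if (datatype == "categorical" && !identical(x@levels, y@levels)) {
      ## different alphabets: unify via the original labels
      pair <- codeCategorical(x@levels[x@values], y@levels[y@values])
      vx <- pair[[1L]]@values; vy <- pair[[2L]]@values
    } else {
      vx <- x@values; vy <- y@values
    }
  } else if (datatype == "categorical") {
    pair <- codeCategorical(if (is(x, "CodedTimeSeries")) x@values else x,
                            if (is(y, "CodedTimeSeries")) y@values else y)
    vx <- pair[[1L]]@values; vy <- pair[[2L]]@values
  } else {
    vx <- .asSeries(x, "continuous")@values
    vy <- .asSeries(y, "continuous")@values
  }
  if (normalize == "zscore" && datatype == "continuous") {
    vx <- .zscore(vx); vy <- .zscore(vy)
  }
  list(x = vx, y = vy, datatype = datatype)
}

#' Values of a coded series
#'
#' @param x a [CodedTimeSeries-class] object or plain numeric vector.
#' @return numeric vector of (coded) observations.
#' @export
seriesValues <- function(x) {
  if (is(x, "CodedTimeSeries")) x@values else as.numeric(x)
}
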