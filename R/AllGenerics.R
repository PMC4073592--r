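#' Recurrent point coordinates
#'
#' Extract the recurrent cells of a recurrence matrix as 1-based
#' \code{(i, j)} index pairs, where \code{i} indexes the first series
#' (horizontal axis of the plot) and \code{j} the second.
#'
#' @param object a [RecurrenceMatrix-class] object.
#' @return A two-column \code{data.frame} with integer columns \code{i}
#'   and \code{j}.
#' @export
setGeneric("recurrentPoints", function(object) standardGeneric("recurrentPoints"))

#' Recurrence rate of an object
#'
#' The percentage of cells of a recurrence matrix that are recurrent, or
#' the stored recurrence-rate vector of a profile object.
#'
#' @param object a [RecurrenceMatrix-class], [RQAMeasures-class] or
#'   [DiagonalProfile-class] object.
#' @return Numeric; a scalar percentage for matrices and measure sets, a
#'   per-lag percentage vector for profiles.
#' @export
setGeneric("recurrenceRate", function(object) standardGeneric("recurrenceRate"))

#' Theiler window of a recurrence matrix
#'
#' @param object a [RecurrenceMatrix-class] object.
#' @return Integer Theiler window (0 when no diagonals are masked).
#' @export
setGeneric("theilerWindow", function(object) standardGeneric("theilerWindow"))

#' Lags of a profile object
#'
#' @param object a [DiagonalProfile-class], [PhiProfile-class] or
#'   [ContingencyStack-class] object.
#' @return Integer vector of lags, negative lags meaning the first series
#'   leads the second.
#' @export
setGeneric("profileLags", function(object) standardGeneric("profileLags"))
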