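## Line-based recurrence quantification.
##
## Diagonal lines (offset d = j - i constant) trace sequences of revisited
## trajectory regions; vertical lines (column j constant, consecutive i)
## trace dwelling of series 1 against a fixed moment of series 2.

## Maximal run lengths along diagonals or columns from sparse coordinates.
## `i`, `j` are 1-based; returns an integer vector of run lengths.
.lineLengths <- function(i, j, kind = c("diagonal", "vertical")) {
  kind <- match.arg(kind)
  if (length(i) == 0L) return(integer())
  if (kind == "diagonal") {
    grp <- j - i
    pos <- i
  } else {
    grp <- j
    pos <- i
  }
  ord <- order(grp, pos)
  grp <- grp[ord]; pos <- pos[ord]
  ## a new run starts where the group changes or positions are not adjacent
  newrun <- c(TRUE, diff(grp) != 0L | diff(pos) != 1L)
  runid <- cumsum(newrun)
  tabulate(runid)
}

#' Histogram of maximal line lengths in a recurrence plot
#'
#' Counts maximal contiguous runs of recurrent points along all diagonals
#' (constant offset j - i) or all verticals (constant j, consecutive i).
#' Runs are maximal: they cannot be extended at either end.
#'
#' @param R a [RecurrenceMatrix-class] (Theiler mask, if any, already
#'   applied).
#' @param kind \code{"diagonal"} or \code{"vertical"}.
#' @return a named integer vector mapping line length to the number of
#'   runs of that length (empty for an empty plot). The counts conserve
#'   points: sum(length * count) equals the number of recurrent points.
#' @examples
#' R <- recurrenceFromPoints(1:5, 1:5, c(5, 5))
#' lineHistogram(R, "diagonal")
#' @export
lineHistogram <- function(R, kind = c("diagonal", "vertical")) {
  stopifnot(is(R, "RecurrenceMatrix"))
  pts <- recurrentPoints(R)
  lens <- .lineLengths(pts$i, pts$j, match.arg(kind))
  if (length(lens) == 0L) return(integer())
  tab <- table(lens)
  stats::setNames(as.integer(tab), names(tab))
}

.entropyNats <- function(lengths) {
  if (length(lengths) == 0L) return(0)
  p <- as.numeric(table(lengths)) / length(lengths)
  -sum(p * log(p))
}

#' The seven recurrence measures of a plot
#'
#' Computes recurrence rate (RR), determinism (DET), mean (L) and maximal
#' (Lmax) diagonal line length, diagonal length entropy (ENTR, natural
#' log), laminarity (LAM) and trapping time (TT) from the line structures
#' of a recurrence matrix.
#'
#' RR is the percentage of recurrent cells over the full matrix area
#' (masked Theiler cells count as non-recurrent). DET (LAM) is the
#' percentage of recurrent points lying on diagonal (vertical) lines of
#' length at least \code{minline}; L, Lmax and TT summarise the qualifying
#' lines. With no qualifying lines, DET, LAM and ENTR are 0 and L, Lmax,
#' TT are NaN (never an error), so degenerate plots cannot silently dilute
#' downstream averages.
#'
#' @param R a [RecurrenceMatrix-class].
#' @param minline integer minimum line length (default 2).
#' @return an [RQAMeasures-class] object.
#' @examples
#' R <- crossRecurrenceMatrix(c(1, 1, 2, 3, 1), c(1, 2, 2, 3, 1),
#'                            datatype = "categorical")
#' rqaMeasures(R)
#' @export
rqaMeasures <- function(R, minline = 2L) {
  stopifnot(is(R, "RecurrenceMatrix"))
  minline <- as.integer(minline)
  if (is.na(minline) || minline < 1L)
    stop("minline must be a positive integer")
  d <- dim(R@points)
  pts <- recurrentPoints(R)
  np <- nrow(pts)
  RR <- 100 * np / (as.double(d[1L]) * d[2L])
  dl <- .lineLengths(pts$i, pts$j, "diagonal")
  vl <- .lineLengths(pts$i, pts$j, "vertical")
  qd <- dl[dl >= minline]
  qv <- vl[vl >= minline]
  new("RQAMeasures",
      RR = RR,
      DET = if (np > 0L) 100 * sum(qd) / np else 0,
      L = if (length(qd)) mean(qd) else NaN,
      Lmax = if (length(qd)) as.numeric(max(qd)) else NaN,
      ENTR = .entropyNats(qd),
      LAM = if (np > 0L) 100 * sum(qv) / np else 0,
      TT = if (length(qv)) mean(qv) else NaN,
      minline = minline, nPoints = as.integer(np),
      dims = as.integer(d))
}

#' Full cross-recurrence quantification of two series
#'
#' The core analysis: embeds both series, thresholds their Euclidean
#' cross-distances at the radius, applies the Theiler window, and returns
#' the seven line-based recurrence measures. Defaults suit categorical
#' sequences (no embedding, radius near 0 so that only identical states
#' recur, Theiler window 0 as appropriate for cross-recurrence).
#'
#' @inheritParams crossRecurrenceMatrix
#' @param minline minimum line length for DET, L, Lmax, ENTR, LAM, TT.
#' @param returnMatrix also return the recurrence matrix (attribute
#'   \code{"matrix"} on the result).
#' @return an [RQAMeasures-class] object.
#' @examples
#' set.seed(1)
#' x <- sample(1:3, 200, replace = TRUE)
#' y <- c(x[-1], 1)   # y anticipates x by one step
#' crqa(x, y, datatype = "categorical")
#' @export
crqa <- function(x, y, delay = 1L, embedDim = 1L, radius = 0.001,
                 theilerWindow = 0L, minline = 2L,
                 datatype = c("continuous", "categorical"),
                 normalize = c("none", "zscore"),
                 rescale = c("none", "mean", "max"),
                 returnMatrix = FALSE) {
  R <- crossRecurrenceMatrix(x, y, delay = delay, embedDim = embedDim,
                             radius = radius,
                             theilerWindow = theilerWindow,
                             datatype = match.arg(datatype),
                             normalize = match.arg(normalize),
                             rescale = match.arg(rescale))
  m <- rqaMeasures(R, minline)
  if (isTRUE(returnMatrix)) attr(m, "matrix") <- R
  m
}

#' Write RQA measures to disk
#'
#' Serializes the measures as a one-row CSV (fixed column order RR, DET,
#' L, Lmax, ENTR, LAM, TT) or flat JSON, depending on the file extension.
#'
#' @param m an [RQAMeasures-class] object.
#' @param file output path ending in \code{.csv} or \code{.json}.
#' @return invisibly, \code{file}.
#' @export
writeMeasures <- function(m, file) {
  stopifnot(is(m, "RQAMeasures"))
  df <- as.data.frame(m)
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::write_json(as.list(df), file, auto_unbox = TRUE, digits = NA)
  else
    utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
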