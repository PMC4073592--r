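## Phase-space reconstruction and recurrence-matrix construction.
##
## Dense distance matrices are guarded by getOption("xrqa.maxDense"):
## matrices larger than maxDense x maxDense cells are refused so that a
## mistyped series length cannot exhaust memory. Recurrence matrices
## themselves are stored sparsely throughout.

.denseGuard <- function(n1, n2) {
  guard <- getOption("xrqa.maxDense", 4000)
  if (as.double(n1) * n2 > as.double(guard)^2)
    stop(sprintf(paste0("distance matrix of %d x %d cells exceeds the dense",
                        " size guard (%d x %d); raise options(xrqa.maxDense=)",
                        " if this is intended"), n1, n2, guard, guard))
  invisible(NULL)
}

#' Time-delay embedding of a series
#'
#' Unfolds a scalar series into delay coordinates: point t is
#' (X(t), X(t + tau), ..., X(t + (m - 1) tau)). With \code{embedDim = 1}
#' the embedded series is the raw series as a one-column matrix.
#'
#' @param x numeric vector or [CodedTimeSeries-class].
#' @param delay integer embedding delay tau, in samples (>= 1).
#' @param embedDim integer number of delayed copies m (>= 1).
#' @return an [EmbeddedSeries-class] with \code{T - (m - 1) * tau} rows.
#' @examples
#' embedSeries(sin(seq(0, 20, 0.1)), delay = 10, embedDim = 3)
#' @export
embedSeries <- function(x, delay = 1L, embedDim = 1L) {
  v <- seriesValues(x)
  delay <- as.integer(delay); embedDim <- as.integer(embedDim)
  if (is.na(delay) || delay < 1L) stop("delay must be a positive integer")
  if (is.na(embedDim) || embedDim < 1L)
    stop("embedDim must be a positive integer")
  T <- length(v)
  need <- (embedDim - 1L) * delay + 1L
  if (T < need)
    stop(sprintf(paste0("insufficient length: series of length %d cannot be",
                        " embedded with delay %d and dimension %d",
                        " (minimum length %d)"), T, delay, embedDim, need))
  n <- T - (embedDim - 1L) * delay
  pts <- vapply(seq_len(embedDim) - 1L,
                function(k) v[seq_len(n) + k * delay], numeric(n))
  if (n == 1L) pts <- matrix(pts, nrow = 1L)
  new("EmbeddedSeries", points = pts, sourceLength = T,
      delay = delay, embedDim = embedDim)
}

#' Euclidean cross-distance matrix of two embedded series
#'
#' D[i, j] is the Euclidean distance between point i of \code{a} and point
#' j of \code{b}. With \code{rescale = "mean"} (or \code{"max"}) every
#' entry is divided by the mean (or maximum) of D and expressed as a
#' percentage, so a radius of e.g. 10 then means 10% of the mean distance.
#'
#' @param a,b [EmbeddedSeries-class] objects with equal embedding
#'   dimension.
#' @param rescale one of \code{"none"}, \code{"mean"}, \code{"max"}.
#' @return numeric matrix, \code{nrow(a)} x \code{nrow(b)}.
#' @export
crossDistanceMatrix <- function(a, b, rescale = c("none", "mean", "max")) {
  rescale <- match.arg(rescale)
  stopifnot(is(a, "EmbeddedSeries"), is(b, "EmbeddedSeries"))
  if (a@embedDim != b@embedDim)
    stop(sprintf("embedding dimensions differ: %d vs %d",
                 a@embedDim, b@embedDim))
  A <- a@points; B <- b@points
  .denseGuard(nrow(A), nrow(B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # numerical noise from the expansion
  D <- sqrt(d2)
  if (rescale == "mean") D <- 100 * D / mean(D)
  else if (rescale == "max") D <- 100 * D / max(D)
  D
}

## Build the sparse pattern matrix from logical dense input; the general
## (non-symmetric) storage class is forced so downstream coordinate
## extraction sees every cell.
.sparsePattern <- function(mat) {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  m <- as(as(as(m, "generalMatrix"), "CsparseMatrix"), "nMatrix")
  as(m, "ngCMatrix")
}

#' Threshold a distance matrix into a recurrence matrix
#'
#' Cell (i, j) is recurrent when \code{D[i, j] <= radius}. A radius of 0
#' admits only exact matches; an empty result is legal.
#'
#' @param D numeric distance matrix (from [crossDistanceMatrix()]).
#' @param radius non-negative threshold, in the units of \code{D}.
#' @return a [RecurrenceMatrix-class] with Theiler window 0.
#' @export
thresholdRecurrence <- function(D, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) ||
      radius < 0)
    stop("radius must be a single non-negative number")
  new("RecurrenceMatrix", points = .sparsePattern(D <= radius),
      theilerWindow = 0L, radius = as.numeric(radius))
}

#' Construct a recurrence matrix from explicit points
#'
#' Mostly useful in tests and for importing externally computed plots.
#'
#' @param i,j integer vectors of 1-based recurrent coordinates (i: series
#'   1, j: series 2).
#' @param dims integer(2) matrix dimensions.
#' @return a [RecurrenceMatrix-class] with Theiler window 0.
#' @export
recurrenceFromPoints <- function(i, j, dims) {
  dims <- as.integer(dims)
  pts <- Matrix::sparseMatrix(i = as.integer(i), j = as.integer(j),
                              dims = dims)
  new("RecurrenceMatrix", points = as(pts, "ngCMatrix"),
      theilerWindow = 0L, radius = numeric())
}

#' Mask diagonals around the line of coincidence
#'
#' Removes all points with \code{|j - i| <= tw - 1}: \code{tw = 1} removes
#' exactly the main diagonal, \code{tw = 0} is the identity. Intended for
#' auto-recurrence, where trivial self-matches crowd the main diagonal;
#' for cross-recurrence of two different series the window should stay 0,
#' since the series are maximally synced along the LOC.
#'
#' @param R a [RecurrenceMatrix-class]; must be square when \code{tw >= 1}.
#' @param tw non-negative integer Theiler window.
#' @return a [RecurrenceMatrix-class] with the band removed and
#'   \code{theilerWindow} set to \code{tw}.
#' @export
applyTheilerWindow <- function(R, tw) {
  stopifnot(is(R, "RecurrenceMatrix"))
  tw <- as.integer(tw)
  if (is.na(tw) || tw < 0L) stop("tw must be a non-negative integer")
  if (tw == 0L) return(R)
  d <- dim(R@points)
  if (d[1L] != d[2L])
    stop("Theiler masking requires a square recurrence matrix")
  if (tw >= d[1L])
    stop(sprintf("tw = %d would mask every diagonal of a %d x %d matrix",
                 tw, d[1L], d[2L]))
  tm <- as(R@points, "TsparseMatrix")
  keep <- abs(tm@j - tm@i) > tw - 1L
  pts <- Matrix::sparseMatrix(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                              dims = d)
  new("RecurrenceMatrix", points = as(pts, "ngCMatrix"),
      theilerWindow = tw, radius = R@radius)
}

#' Cross-recurrence matrix of two series
#'
#' Convenience pipeline: optional z-scoring, delay embedding of both
#' series, Euclidean cross-distances with optional rescaling, radius
#' thresholding and Theiler masking. For categorical series use a radius
#' near 0 (e.g. 0.001) so that only identical states recur.
#'
#' @param x,y numeric vectors or [CodedTimeSeries-class] objects.
#' @param delay,embedDim embedding parameters (see [embedSeries()]).
#' @param radius recurrence threshold (see [thresholdRecurrence()]).
#' @param theilerWindow diagonals to mask (see [applyTheilerWindow()]);
#'   requires equal embedded lengths when >= 1.
#' @param datatype \code{"categorical"} or \code{"continuous"}; with plain
#'   vector input, categorical data are recoded over a shared alphabet.
#' @param normalize \code{"none"} or \code{"zscore"} (continuous only).
#' @param rescale distance-matrix rescaling (see [crossDistanceMatrix()]).
#' @return a [RecurrenceMatrix-class].
#' @examples
#' crossRecurrenceMatrix(c(1, 2, 1, 3), c(2, 1, 3, 1),
#'                       datatype = "categorical", radius = 0.001)
#' @export
crossRecurrenceMatrix <- function(x, y, delay = 1L, embedDim = 1L,
                                  radius = 0.001, theilerWindow = 0L,
                                  datatype = c("continuous", "categorical"),
                                  normalize = c("none", "zscore"),
                                  rescale = c("none", "mean", "max")) {
  datatype <- match.arg(datatype)
  pair <- .seriesPair(x, y, datatype, match.arg(normalize))
  ex <- embedSeries(pair$x, delay, embedDim)
  ey <- embedSeries(pair$y, delay, embedDim)
  D <- crossDistanceMatrix(ex, ey, match.arg(rescale))
  applyTheilerWindow(thresholdRecurrence(D, radius), theilerWindow)
}

#' Export a recurrence matrix as sparse CSV plus JSON sidecar
#'
#' Writes the recurrent cells as a two-column CSV of 1-based (i, j) pairs
#' and a JSON sidecar (same path with extension \code{.json}) recording
#' dimensions, radius and Theiler window.
#'
#' @param R a [RecurrenceMatrix-class].
#' @param file path of the CSV to write.
#' @return invisibly, the sidecar path.
#' @export
exportRecurrence <- function(R, file) {
  stopifnot(is(R, "RecurrenceMatrix"))
  utils::write.csv(recurrentPoints(R), file, row.names = FALSE)
  side <- sub("\\.[^.]*$", "", file)
  side <- paste0(side, ".json")
  meta <- list(dims = dim(R@points), theilerWindow = R@theilerWindow,
               radius = if (length(R@radius)) R@radius else NULL,
               nPoints = nrow(recurrentPoints(R)))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}
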