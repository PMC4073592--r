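## Three-step embedding-parameter selection for continuous series:
## delay by the first minimum of average mutual information, dimension by
## false nearest neighbours, radius by searching for a target recurrence
## rate (2-5% by default).

#' Average mutual information delay selection
#'
#' Computes the average mutual information (AMI, nats) between x(t) and
#' x(t + l) for l = 0..maxLag from an equal-width two-dimensional
#' histogram, and selects the first local minimum of the curve - the
#' point where shared information has dropped and levels off, so a
#' delayed copy contributes maximally new information. A minimum counts
#' only when it is prominent: lower, by a small tolerance (1% of the
#' curve's range), than every value within three lags on either side;
#' this keeps histogram-quantization micro-dips on steep descents from
#' being mistaken for the minimum. If the curve has no such minimum, the
#' first lag from which the onward decrease stays below \code{levelTol}
#' of the initial AMI is returned (with a warning if even that never
#' happens).
#'
#' @param x continuous series (numeric vector or
#'   [CodedTimeSeries-class]); must not be constant.
#' @param maxLag largest lag examined; must be below half the series
#'   length. Default \code{min(40, T/2 - 1)}.
#' @param bins number of equal-width histogram bins per axis (default
#'   10).
#' @param levelTol leveling tolerance, as a fraction of AMI(0) (default
#'   0.05).
#' @return list with \code{delay} (integer) and \code{ami} (named
#'   numeric, lags 0..maxLag).
#' @examples
#' x <- sin(2 * pi * seq_len(1000) / 100)
#' amiDelay(x, maxLag = 40)$delay   # about a quarter period
#' @export
amiDelay <- function(x, maxLag = NULL, bins = 10L, levelTol = 0.05) {
  v <- seriesValues(x)
  T <- length(v)
  if (stats::sd(v) == 0) stop("zero variance: series is constant")
  if (is.null(maxLag)) maxLag <- max(1L, min(40L, floor(T / 2) - 1L))
  maxLag <- as.integer(maxLag)
  if (maxLag < 1L || maxLag >= T / 2)
    stop("maxLag must be at least 1 and below half the series length")
  brk <- seq(min(v), max(v), length.out = bins + 1L)
  binOf <- findInterval(v, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
  ami <- vapply(0:maxLag, function(l) {
    a <- binOf[seq_len(T - l)]
    b <- binOf[seq_len(T - l) + l]
    joint <- table(a, b) / (T - l)
    pa <- rowSums(joint); pb <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  }, numeric(1))
  names(ami) <- 0:maxLag
  tie <- 0.01 * diff(range(ami))
  win <- 3L
  delay <- NA_integer_
  for (l in seq_len(maxLag)) {
    nb <- seq.int(max(0L, l - win), min(maxLag, l + win))
    nb <- nb[nb != l]
    if (all(ami[l + 1L] < ami[nb + 1L] - tie)) { delay <- l; break }
  }
  if (is.na(delay)) {
    ## leveling: first lag l >= 1 whose onward drop ami(l) - ami(l+1)
    ## stays below the tolerance
    fwd <- ami[seq_len(maxLag - 1L) + 1L] - ami[seq_len(maxLag - 1L) + 2L]
    lev <- which(fwd < levelTol * ami[1L])
    if (length(lev)) delay <- lev[1L]
    else {
      warning("AMI never reaches a minimum or levels off; returning maxLag")
      delay <- maxLag
    }
  }
  list(delay = as.integer(delay), ami = ami)
}

#' Combine the delays of two series
#'
#' When one series needs a considerably longer delay (ratio above
#' \code{closenessRatio}), the longer one is taken so that new
#' information is gained for both series; when the two are close, their
#' rounded mean is used.
#'
#' @param d1,d2 positive integer delays.
#' @param closenessRatio ratio threshold deciding "considerably longer"
#'   (default 2).
#' @return integer combined delay.
#' @examples
#' combineDelays(10, 14)  # 12
#' combineDelays(5, 40)   # 40
#' @export
combineDelays <- function(d1, d2, closenessRatio = 2) {
  d1 <- as.integer(d1); d2 <- as.integer(d2)
  if (is.na(d1) || is.na(d2) || d1 < 1L || d2 < 1L)
    stop("delays must be positive integers")
  if (max(d1, d2) / min(d1, d2) > closenessRatio) max(d1, d2)
  else as.integer(round(mean(c(d1, d2))))
}

#' False-nearest-neighbour embedding dimension
#'
#' For each candidate dimension d, embeds the series at d and asks how
#' often a point's nearest neighbour stops being a neighbour once the
#' (d+1)-th delay coordinate is added: the neighbour is false when the
#' new coordinate separation exceeds \code{rTol} times the distance in d
#' dimensions. The selected dimension is the first whose false-neighbour
#' fraction drops below \code{fnnTol}, or at which the fraction stops
#' decreasing (it has bottomed out).
#'
#' @param x continuous series.
#' @param delay embedding delay (see [amiDelay()]).
#' @param maxDim largest dimension examined.
#' @param rTol distance-ratio tolerance of the false-neighbour criterion
#'   (default 10).
#' @param fnnTol acceptable false-neighbour fraction (default 0.05).
#' @param maxPoints at most this many phase-space points are used for the
#'   neighbour search (the leading ones), bounding the quadratic cost.
#' @return list with \code{embedDim} (integer) and \code{fnn} (fraction
#'   per dimension 1..maxDim, NA where the series is too short).
#' @examples
#' x <- sin(2 * pi * seq_len(600) / 100)
#' fnnEmbedding(x, delay = 25, maxDim = 4)$embedDim  # 2: a circle
#' @export
fnnEmbedding <- function(x, delay, maxDim = 6L, rTol = 10, fnnTol = 0.05,
                         maxPoints = 1000L) {
  v <- seriesValues(x)
  if (stats::sd(v) == 0) stop("zero variance: series is constant")
  delay <- as.integer(delay); maxDim <- as.integer(maxDim)
  T <- length(v)
  if (T <= delay + 1L)
    stop(sprintf("series too short (length %d) for delay %d", T, delay))
  frac <- rep(NA_real_, maxDim)
  for (d in seq_len(maxDim)) {
    nAvail <- T - d * delay        # points that also have coordinate d+1
    if (nAvail < 2L) {
      if (d == 1L)
        stop(sprintf("series too short for maxDim %d at delay %d",
                     maxDim, delay))
      break
    }
    n <- min(nAvail, maxPoints)
    emb <- embedSeries(v, delay, d)@points[seq_len(n), , drop = FALSE]
    dm <- as.matrix(stats::dist(emb))
    diag(dm) <- Inf
    nn <- apply(dm, 1L, which.min)
    dNear <- dm[cbind(seq_len(n), nn)]
    extra <- abs(v[seq_len(n) + d * delay] - v[nn + d * delay])
    ## guard against exact revisits: separations at floating-point noise
    ## level (relative to the signal scale) are not false neighbours
    guard <- 1e-8 * stats::sd(v)
    false <- extra > guard & (dNear == 0 | extra / dNear > rTol)
    frac[d] <- mean(false)
  }
  ok <- which(!is.na(frac))
  embedDim <- NA_integer_
  for (d in ok) {
    if (frac[d] <= fnnTol) { embedDim <- d; break }
    if (d > 1L && !is.na(frac[d - 1L]) && frac[d] >= frac[d - 1L]) {
      embedDim <- d - 1L; break    # bottomed out one dimension earlier
    }
  }
  if (is.na(embedDim)) embedDim <- max(ok)
  list(embedDim = as.integer(embedDim), fnn = frac)
}

## Exact recurrence-rate (percent) at each radius, without materializing
## the full distance matrix. A: n1 x m, B: n2 x m; radii ascending.
.rrCurve <- function(A, B, radii) {
  n1 <- nrow(A); n2 <- nrow(B)
  K <- length(radii)
  total <- as.double(n1) * n2
  if (ncol(A) == 1L) {
    bs <- sort(B[, 1L])
    a <- A[, 1L]
    cnt <- vapply(radii, function(r) {
      sum(findInterval(a + r, bs) -
          findInterval(a - r, bs, left.open = TRUE))
    }, numeric(1))
    return(100 * cnt / total)
  }
  tab <- numeric(K + 1L)
  b2 <- rowSums(B^2)
  blk <- max(1L, floor(2e6 / n2))
  for (s in seq.int(1L, n1, by = blk)) {
    e <- min(n1, s + blk - 1L)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, "+") - 2 * tcrossprod(Ab, B)
    d2[d2 < 0] <- 0
    f <- findInterval(sqrt(d2), radii, left.open = TRUE)
    t0 <- tabulate(f + 1L, nbins = K + 1L)
    tab <- tab + t0
  }
  100 * cumsum(tab)[seq_len(K)] / total
}

.radiusError <- function(msg, trace, call = sys.call(-1L)) {
  stop(structure(class = c("xrqa_radius_error", "error", "condition"),
                 list(message = msg, call = call, trace = trace)))
}

#' Search a radius yielding a target recurrence rate
#'
#' Generates equally spaced candidate radii spanning the distance scale
#' at which roughly \code{startRR} percent of cell pairs recur, down to
#' zero, and evaluates the exact recurrence rate at each candidate from
#' the smallest radius upward. The first candidate whose recurrence rate
#' falls inside \code{targetRR} is returned. If the grid jumps over the
#' band (the rate is below the band at one candidate and above it at the
#' next), the gap is re-sampled at finer granularity, up to
#' \code{maxRounds} times; an unreachable target raises an error carrying
#' the full (radius, rr) trace. The grid is deterministic, so results do
#' not depend on a seed.
#'
#' @param x,y continuous series.
#' @param delay,embedDim embedding parameters.
#' @param targetRR numeric(2) target recurrence-rate band in percent
#'   (default \code{c(2, 5)}).
#' @param nSamples candidate radii per round (default 20).
#' @param maxRounds maximum refinement rounds (default 3).
#' @param startRR percent recurrence at the top of the initial grid
#'   (default 25).
#' @param normalize \code{"none"} or \code{"zscore"}.
#' @return list with \code{radius}, \code{achievedRR} (percent) and
#'   \code{trace} (data frame of all evaluated radii and rates).
#' @export
radiusSearch <- function(x, y, delay = 1L, embedDim = 1L,
                         targetRR = c(2, 5), nSamples = 20L,
                         maxRounds = 3L, startRR = 25,
                         normalize = c("none", "zscore")) {
  pair <- .seriesPair(x, y, "continuous", match.arg(normalize))
  A <- embedSeries(pair$x, delay, embedDim)@points
  B <- embedSeries(pair$y, delay, embedDim)@points
  lo <- min(targetRR); hi <- max(targetRR)
  if (lo <= 0 || hi > 100 || lo >= hi)
    stop("targetRR must be an increasing pair of percentages in (0, 100]")
  ## distance scale from a deterministic thinned subsample of pairs
  ia <- unique(round(seq(1L, nrow(A), length.out = min(nrow(A), 1500L))))
  ib <- unique(round(seq(1L, nrow(B), length.out = min(nrow(B), 1500L))))
  sub <- sqrt(pmax(0, outer(rowSums(A[ia, , drop = FALSE]^2),
                            rowSums(B[ib, , drop = FALSE]^2), "+") -
                      2 * tcrossprod(A[ia, , drop = FALSE],
                                     B[ib, , drop = FALSE])))
  rmax <- as.numeric(stats::quantile(sub, startRR / 100))
  trace <- data.frame(radius = numeric(), rr = numeric())
  if (rmax <= 0) {
    ## heavily tied (e.g. integer-coded) data: span up to the smallest
    ## positive separation instead
    pos <- sub[sub > 0]
    if (length(pos) == 0L)
      .radiusError("degenerate distances: cannot span a radius grid", trace)
    rmax <- min(pos)
  }
  loR <- 0; hiR <- rmax
  for (round in seq_len(maxRounds)) {
    radii <- seq(loR, hiR, length.out = nSamples + 1L)[-1L]
    rr <- .rrCurve(A, B, radii)
    trace <- rbind(trace, data.frame(radius = radii, rr = rr))
    inside <- which(rr >= lo & rr <= hi)
    if (length(inside))
      return(list(radius = radii[inside[1L]],
                  achievedRR = rr[inside[1L]], trace = trace))
    if (all(rr < lo)) {            # subsampled scale underestimated
      loR <- radii[nSamples]; hiR <- 2 * hiR
      next
    }
    jump <- which(rr > hi)[1L]     # rr is non-decreasing in the radius
    if (!is.na(jump) && jump > 1L) {
      ## grid jumped over the band: refine between the bracketing radii
      loR <- radii[jump - 1L]; hiR <- radii[jump]
    } else if (!is.na(jump) && jump == 1L && loR == 0) {
      hiR <- radii[1L]             # band sits below the smallest candidate
    } else {
      .radiusError(sprintf("no radius with recurrence rate in [%g, %g]%%",
                           lo, hi), trace)
    }
  }
  .radiusError(sprintf(
    "target band [%g, %g]%% not reached after %d refinement rounds",
    lo, hi, maxRounds), trace)
}

#' Three-step parameter optimization for continuous CRQA
#'
#' Composes the full procedure: AMI delay for each series combined with
#' [combineDelays()], false-nearest-neighbour dimension for each series
#' (the larger is kept so both are sufficiently unfolded), and a radius
#' targeting the requested recurrence-rate band. All per-step diagnostic
#' curves are retained. Errors of any step are re-raised with the step
#' name.
#'
#' @param x,y continuous series.
#' @param maxLag,bins,levelTol passed to [amiDelay()].
#' @param maxDim,rTol,fnnTol passed to [fnnEmbedding()].
#' @param targetRR,nSamples,maxRounds,startRR passed to [radiusSearch()].
#' @param normalize \code{"none"} or \code{"zscore"}.
#' @return an [OptimalParams-class] object.
#' @export
optimizeParams <- function(x, y, maxLag = NULL, bins = 10L,
                           levelTol = 0.05, maxDim = 6L, rTol = 10,
                           fnnTol = 0.05, targetRR = c(2, 5),
                           nSamples = 20L, maxRounds = 3L, startRR = 25,
                           normalize = c("none", "zscore")) {
  normalize <- match.arg(normalize)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("step '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  a1 <- step("delay (AMI)", amiDelay(x, maxLag, bins, levelTol))
  a2 <- step("delay (AMI)", amiDelay(y, maxLag, bins, levelTol))
  delay <- combineDelays(a1$delay, a2$delay)
  f1 <- step("embedding dimension (FNN)", fnnEmbedding(x, delay, maxDim,
                                                       rTol, fnnTol))
  f2 <- step("embedding dimension (FNN)", fnnEmbedding(y, delay, maxDim,
                                                       rTol, fnnTol))
  embedDim <- max(f1$embedDim, f2$embedDim)
  rs <- step("radius search", radiusSearch(x, y, delay, embedDim,
                                           targetRR, nSamples, maxRounds,
                                           startRR, normalize))
  new("OptimalParams", delay = as.integer(delay),
      embedDim = as.integer(embedDim), radius = rs$radius,
      achievedRR = rs$achievedRR,
      diagnostics = list(amiX = a1$ami, amiY = a2$ami,
                         delayX = a1$delay, delayY = a2$delay,
                         fnnX = f1$fnn, fnnY = f2$fnn,
                         radiusTrace = rs$trace))
}
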