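## Coupled binary-agent simulator: a "confederate" C whose event rate is
## experimentally set drives a "participant" S. Used throughout as the
## synthetic fixture for profile and measure validation.

#' Simulate two coupled binary event series
#'
#' Per time step, agent C emits an event (1) with base probability
#' \code{pC}, or repeats its previous event with probability \code{pCC};
#' agent S emits an event with probability \code{pSC} when C emitted one
#' (by default at the *previous* step, so C leads S by one step), with
#' base probability \code{pS}, or repeats its own previous event with
#' probability \code{pSS}. Each rule draws its own uniform variate, so
#' the emission probability is the complement of all rules failing.
#'
#' C's stationary event rate has the closed form
#' \code{pC / (1 - (1 - pC) * pCC)} (two-state Markov chain), which the
#' test-suite uses as a calibration oracle.
#'
#' @param pC,pS base event rates of C and S.
#' @param pCC,pSS event-repetition probabilities.
#' @param pSC coupling probability: S's event rate given C's event.
#' @param steps number of time steps (default 1000).
#' @param seed optional integer seed; the global RNG state is restored
#'   afterwards, and the same seed reproduces the series bit for bit.
#' @param coupling \code{"previous"} (default; S reacts to C's previous
#'   step, so coupling appears at lag -1) or \code{"same"} (S reacts to
#'   C's simultaneous output).
#' @return list with numeric 0/1 vectors \code{C} and \code{S}.
#' @examples
#' ts <- simulateCoupledBinary(pC = 0.25, pSC = 0.33, seed = 7)
#' mean(ts$C)
#' @export
simulateCoupledBinary <- function(pC = 0.25, pS = 0.05, pCC = 0.05,
                                  pSS = 0.05, pSC = 0.33, steps = 1000L,
                                  seed = NULL,
                                  coupling = c("previous", "same")) {
  coupling <- match.arg(coupling)
  p <- c(pC = pC, pS = pS, pCC = pCC, pSS = pSS, pSC = pSC)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all probabilities must lie in [0, 1]")
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be a positive integer")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  u <- matrix(stats::runif(5L * steps), nrow = 5L)
  C <- S <- numeric(steps)
  prevC <- 0; prevS <- 0
  for (t in seq_len(steps)) {
    C[t] <- as.numeric(u[1L, t] < pC || (prevC == 1 && u[2L, t] < pCC))
    driver <- if (coupling == "previous") prevC else C[t]
    S[t] <- as.numeric((driver == 1 && u[3L, t] < pSC) ||
                       u[4L, t] < pS ||
                       (prevS == 1 && u[5L, t] < pSS))
    prevC <- C[t]; prevS <- S[t]
  }
  list(C = C, S = S)
}

#' Lagged Pearson cross-correlation profile
#'
#' r(l) is the Pearson correlation of x(t) with y(t - l) over the valid
#' time points, for l in -maxLag..+maxLag - the same sign convention as
#' the recurrence profiles: negative lags mean the first series leads.
#' Lags where either segment has zero variance yield NaN.
#'
#' @param x,y numeric series (binary 0/1 allowed).
#' @param maxLag lag window W < length of the shorter series.
#' @return data.frame with columns \code{lag} and \code{r}, carrying
#'   attributes \code{maxr} and \code{maxlag} (ties resolved towards the
#'   smallest absolute, then negative, lag).
#' @examples
#' x <- rnorm(200); y <- c(0, x[-200])  # y trails x by one step
#' attr(crossCorrelationProfile(x, y, 5), "maxlag")  # -1
#' @export
crossCorrelationProfile <- function(x, y, maxLag) {
  vx <- seriesValues(x); vy <- seriesValues(y)
  n <- min(length(vx), length(vy))
  vx <- vx[seq_len(n)]; vy <- vy[seq_len(n)]
  maxLag <- as.integer(maxLag)
  if (is.na(maxLag) || maxLag < 0L || maxLag >= n)
    stop("maxLag must be a non-negative integer below the series length")
  lags <- seq.int(-maxLag, maxLag)
  r <- vapply(lags, function(l) {
    ts <- seq.int(max(1L, 1L + l), min(n, n + l))
    a <- vx[ts]; b <- vy[ts - l]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NaN)
    stats::cor(a, b)
  }, numeric(1))
  out <- data.frame(lag = lags, r = r)
  fin <- is.finite(r)
  if (any(fin)) {
    attr(out, "maxr") <- max(r[fin])
    attr(out, "maxlag") <- .tieBreakMax(lags[fin], r[fin])
  } else {
    attr(out, "maxr") <- NaN
    attr(out, "maxlag") <- NA_integer_
  }
  out
}

#' Write simulated series as a two-column CSV
#'
#' @param sim list with components \code{C} and \code{S} (from
#'   [simulateCoupledBinary()]).
#' @param file CSV path.
#' @return invisibly, \code{file}.
#' @export
writeSimulation <- function(sim, file) {
  utils::write.csv(data.frame(C = sim$C, S = sim$S), file,
                   row.names = FALSE)
  invisible(file)
}
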