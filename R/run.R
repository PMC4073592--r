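## Method dispatcher mirroring the "one wrapper, many methods" pattern:
## a validated configuration chooses between profile, windowed, full-plot,
## contingency, phi, optimizer and simulator runs. Configuration errors
## are classed "xrqa_validation_error" (exit code 2 in the CLI), data
## errors "xrqa_data_error" (exit code 3).

.validationError <- function(msg) {
  stop(structure(class = c("xrqa_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' Default parameters of every analysis method
#'
#' @return named list: per method, the accepted parameters and the
#'   package defaults where one exists.
#' @export
runDefaults <- function() {
  list(
    profile  = list(delay = 1L, embedDim = 1L, radius = 0.001,
                    maxLag = 10L, datatype = "continuous",
                    normalize = "none", rescale = "none",
                    excludeNonevent = NULL),
    window   = list(delay = 1L, embedDim = 1L, radius = 0.001,
                    windowSize = 100L, step = 10L, lagWindow = 10L,
                    datatype = "continuous", normalize = "none",
                    rescale = "none", excludeNonevent = NULL,
                    full = FALSE, theilerWindow = 0L, minline = 2L),
    crqa     = list(delay = 1L, embedDim = 1L, radius = 0.001,
                    theilerWindow = 0L, minline = 2L,
                    datatype = "continuous", normalize = "none",
                    rescale = "none"),
    ct       = list(maxLag = 10L),
    phi      = list(maxLag = 10L, state = NULL),
    optimize = list(maxLag = NULL, bins = 10L, levelTol = 0.05,
                    maxDim = 6L, rTol = 10, fnnTol = 0.05,
                    targetRR = c(2, 5), nSamples = 20L, maxRounds = 3L,
                    startRR = 25, normalize = "none"),
    simulate = list(pC = 0.25, pS = 0.05, pCC = 0.05, pSS = 0.05,
                    pSC = 0.33, steps = 1000L, seed = NULL,
                    coupling = "previous"))
}

.checkConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) .validationError("config must be a list or a JSON path")
  method <- config$method
  if (is.null(method) || !method %in% names(runDefaults()))
    .validationError(sprintf("method must be one of: %s",
                             paste(names(runDefaults()), collapse = ", ")))
  defaults <- runDefaults()[[method]]
  given <- config[setdiff(names(config), c("method", "input", "input2",
                                           "output"))]
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    .validationError(sprintf("unknown parameter(s) for method '%s': %s",
                             method, paste(unknown, collapse = ", ")))
  params <- utils::modifyList(defaults, given)
  num <- params[vapply(params, is.numeric, logical(1))]
  if (any(vapply(num, function(v) any(!is.finite(v)), logical(1))))
    .validationError("numeric parameters must be finite")
  if (method == "window" &&
      params$lagWindow >= params$windowSize)
    .validationError(paste("lagWindow must be smaller than windowSize:",
                           "the delays considered must be smaller than",
                           "the size of the window"))
  if (method == "phi" && is.null(params$state))
    .validationError("method 'phi' requires a 'state'")
  list(method = method, params = params, config = config)
}

#' Run an analysis described by a configuration
#'
#' Validates a configuration (a named list or the path of a JSON file)
#' and dispatches to the corresponding analysis: \code{"profile"}
#' ([diagonalRecurrenceProfile()]), \code{"window"}
#' ([windowedRecurrenceProfile()] or, with \code{full = TRUE},
#' [windowedCRQA()]), \code{"crqa"} ([crqa()]), \code{"ct"}
#' ([contingencyStack()] + [contingencyProfile()]), \code{"phi"}
#' ([phiProfile()]), \code{"optimize"} ([optimizeParams()]) and
#' \code{"simulate"} ([simulateCoupledBinary()]). All parameters are
#' validated before any computation; unknown keys are rejected. Results
#' are numerically identical to calling the underlying function
#' directly.
#'
#' @param config named list with a \code{method} field and per-method
#'   parameters (see [runDefaults()]), or the path of a JSON file with
#'   the same structure; file inputs may be given as \code{input} /
#'   \code{input2} fields with \code{datatype}.
#' @param x,y input series; may be omitted when the config names input
#'   files or for \code{method = "simulate"}.
#' @return the result object of the dispatched analysis; for
#'   \code{"ct"}, a list with the [ContingencyStack-class] and its
#'   [DiagonalProfile-class].
#' @examples
#' sim <- simulateCoupledBinary(seed = 1)
#' runAnalysis(list(method = "profile", maxLag = 5,
#'                  datatype = "categorical", excludeNonevent = "0"),
#'             sim$C, sim$S)
#' @export
runAnalysis <- function(config, x = NULL, y = NULL) {
  cfg <- .checkConfig(config)
  p <- cfg$params
  if (is.null(x) && !is.null(cfg$config$input)) {
    pair <- readSeries(cfg$config$input, cfg$config$input2,
                       datatype = if (is.null(p$datatype)) "continuous"
                                  else p$datatype)
    x <- pair[[1L]]; y <- pair[[2L]]
  }
  if (cfg$method != "simulate" && (is.null(x) || is.null(y)))
    .validationError("two input series are required for this method")
  switch(cfg$method,
    profile = diagonalRecurrenceProfile(
      x, y, maxLag = p$maxLag, delay = p$delay, embedDim = p$embedDim,
      radius = p$radius, datatype = p$datatype, normalize = p$normalize,
      rescale = p$rescale, excludeNonevent = p$excludeNonevent),
    window = if (isTRUE(p$full))
      windowedCRQA(x, y, windowSize = p$windowSize, step = p$step,
                   delay = p$delay, embedDim = p$embedDim,
                   radius = p$radius, theilerWindow = p$theilerWindow,
                   minline = p$minline, datatype = p$datatype,
                   normalize = p$normalize, rescale = p$rescale)
    else
      windowedRecurrenceProfile(
        x, y, windowSize = p$windowSize, step = p$step,
        lagWindow = p$lagWindow, delay = p$delay, embedDim = p$embedDim,
        radius = p$radius, datatype = p$datatype,
        normalize = p$normalize, rescale = p$rescale,
        excludeNonevent = p$excludeNonevent),
    crqa = crqa(x, y, delay = p$delay, embedDim = p$embedDim,
                radius = p$radius, theilerWindow = p$theilerWindow,
                minline = p$minline, datatype = p$datatype,
                normalize = p$normalize, rescale = p$rescale),
    ct = {
      stack <- contingencyStack(x, y, maxLag = p$maxLag)
      list(stack = stack, profile = contingencyProfile(stack))
    },
    phi = phiProfile(contingencyStack(x, y, maxLag = p$maxLag),
                     p$state),
    optimize = optimizeParams(
      x, y, maxLag = p$maxLag, bins = p$bins, levelTol = p$levelTol,
      maxDim = p$maxDim, rTol = p$rTol, fnnTol = p$fnnTol,
      targetRR = p$targetRR, nSamples = p$nSamples,
      maxRounds = p$maxRounds, startRR = p$startRR,
      normalize = p$normalize),
    simulate = simulateCoupledBinary(
      pC = p$pC, pS = p$pS, pCC = p$pCC, pSS = p$pSS, pSC = p$pSC,
      steps = p$steps, seed = p$seed, coupling = p$coupling))
}

#' Write an analysis result with provenance
#'
#' Serializes a result object into \code{dir}: CSV for tabular parts,
#' plus a \code{provenance.json} recording the method, parameters,
#' package version and timestamp.
#'
#' @param result object returned by [runAnalysis()].
#' @param dir output directory (created if missing).
#' @param config the configuration that produced the result.
#' @return invisibly, the directory.
#' @export
writeResults <- function(result, dir, config = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(dir, f)
  if (is(result, "DiagonalProfile")) writeProfile(result, out("profile.csv"))
  else if (is(result, "WindowedProfile")) writeProfile(result, out("windows.csv"))
  else if (is(result, "RQAMeasures")) writeMeasures(result, out("measures.csv"))
  else if (is(result, "PhiProfile"))
    utils::write.csv(data.frame(lag = result@lags, phi = result@phi),
                     out("phi.csv"), row.names = FALSE)
  else if (is(result, "OptimalParams"))
    jsonlite::write_json(
      list(delay = result@delay, embedDim = result@embedDim,
           radius = result@radius, achievedRR = result@achievedRR,
           diagnostics = result@diagnostics),
      out("optimal_params.json"), auto_unbox = TRUE, digits = NA)
  else if (is.list(result) && !is.null(result$stack)) {
    writeContingency(result$stack, out("contingency.csv"))
    writeProfile(result$profile, out("profile.csv"))
  } else if (is.list(result) && !is.null(result$C))
    writeSimulation(result, out("simulation.csv"))
  prov <- list(package = "xrqa",
               version = as.character(utils::packageVersion("xrqa")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               config = config)
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
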