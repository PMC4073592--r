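## Delimited-text input of series pairs. Errors raised while reading are
## classed "xrqa_data_error" so the command-line wrapper can map them to
## a distinct exit code.

.dataError <- function(msg) {
  stop(structure(class = c("xrqa_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

.sepFor <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

.readTable <- function(path, sep = NULL, header = "auto") {
  if (!file.exists(path)) .dataError(sprintf("file not found: %s", path))
  sep <- .sepFor(path, sep)
  if (identical(header, "auto")) {
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    header <- any(is.na(suppressWarnings(as.numeric(first))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = character())
  if (nrow(df) == 0L) .dataError(sprintf("no data rows in %s", path))
  df
}

.checkColumn <- function(col, path, name, datatype) {
  blank <- which(is.na(col) | trimws(col) == "")
  if (length(blank))
    .dataError(sprintf("missing value in %s, column '%s', row %d",
                       path, name, blank[1L]))
  if (datatype == "continuous") {
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num))
    if (length(bad))
      .dataError(sprintf(
        "non-numeric value '%s' in %s, column '%s', row %d",
        col[bad[1L]], path, name, bad[1L]))
    num
  } else col
}

#' Read a pair of series from delimited text
#'
#' Reads two series either from one file with (at least) two columns or
#' from two single-column files. The separator is inferred from the
#' extension (tab for \code{.tsv}/\code{.tab}, comma otherwise) unless
#' given; a header row is detected automatically when its fields are
#' non-numeric, or can be forced. Missing or blank cells are rejected
#' with the offending row and column named. Categorical input is recoded
#' over a shared alphabet (see [codeCategorical()]).
#'
#' @param path path of the (first) input file.
#' @param path2 optional second file; when NULL both columns come from
#'   \code{path}.
#' @param datatype \code{"continuous"} or \code{"categorical"}.
#' @param columns column names or indices to use (length 2 for a single
#'   file, length 1 or 2 for two files; default: the first columns).
#' @param sep field separator override.
#' @param header TRUE, FALSE or \code{"auto"}.
#' @return list of two [CodedTimeSeries-class] objects.
#' @export
readSeries <- function(path, path2 = NULL,
                       datatype = c("continuous", "categorical"),
                       columns = NULL, sep = NULL, header = "auto") {
  datatype <- match.arg(datatype)
  pick <- function(df, sel, path) {
    if (is.numeric(sel)) {
      if (sel > ncol(df))
        .dataError(sprintf("%s has only %d column(s)", path, ncol(df)))
      nm <- names(df)[sel]
    } else {
      if (!sel %in% names(df))
        .dataError(sprintf("no column '%s' in %s", sel, path))
      nm <- sel
    }
    .checkColumn(df[[nm]], path, nm, datatype)
  }
  if (is.null(path2)) {
    df <- .readTable(path, sep, header)
    if (is.null(columns)) columns <- c(1L, 2L)
    if (ncol(df) < 2L && is.numeric(columns))
      .dataError(sprintf("%s must contain two columns (found %d)",
                         path, ncol(df)))
    c1 <- pick(df, columns[[1L]], path)
    c2 <- pick(df, columns[[2L]], path)
  } else {
    df1 <- .readTable(path, sep, header)
    df2 <- .readTable(path2, sep, header)
    if (is.null(columns)) columns <- c(1L, 1L)
    if (length(columns) == 1L) columns <- rep(columns, 2L)
    c1 <- pick(df1, columns[[1L]], path)
    c2 <- pick(df2, columns[[2L]], path2)
  }
  if (datatype == "categorical") codeCategorical(c1, c2)
  else list(codedSeries(c1, "continuous"), codedSeries(c2, "continuous"))
}

#' Write a pair of series as delimited text
#'
#' Categorical series are written as their original labels, so a write
#' followed by [readSeries()] reproduces the pair exactly.
#'
#' @param x,y series ([CodedTimeSeries-class] or numeric vectors).
#' @param file output path (separator inferred from the extension).
#' @param sep separator override.
#' @return invisibly, \code{file}.
#' @export
writeSeries <- function(x, y, file, sep = NULL) {
  col <- function(s)
    if (is(s, "CodedTimeSeries") && identical(s@datatype, "categorical"))
      .seriesLabels(s) else seriesValues(s)
  a <- col(x); b <- col(y)
  n <- max(length(a), length(b))
  if (length(a) != length(b))
    stop("series of unequal length cannot share one file")
  utils::write.table(data.frame(series1 = a, series2 = b), file,
                     sep = .sepFor(file, sep), row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
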