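# Reading empirical two-column series and small diagnostics.

#' Read a two-column series from CSV
#'
#' Parses the first two numeric columns of a delimited text file (header
#' row optional, delimiter sniffed among comma/semicolon/tab, empty cells
#' treated as missing) into a [bivariate_series()]. With
#' `standardize = TRUE` each column is z-scored using its observed values
#' only — the usual preparation for mood-diary data rated on different
#' instruments.
#'
#' @param path file path.
#' @param standardize z-score each column (default `FALSE`).
#' @return A [bivariate_series()]; rows with any missing cell are flagged
#'   unobserved.
#' @seealso [write_series_csv()]
#' @export
read_series_csv <- function(path, standardize = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("file too short to contain a series", call. = FALSE)
  counts <- vapply(c(",", ";", "\t"), function(d) {
    sum(lengths(gregexpr(d, lines[1:min(5, length(lines))], fixed = TRUE)) *
          (regexpr(d, lines[1], fixed = TRUE) > 0))
  }, numeric(1))
  sep <- c(",", ";", "\t")[which.max(counts)]
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))) & nzchar(trimws(first)))
  df <- utils::read.table(text = lines, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, fill = TRUE,
                          na.strings = c("", "NA"))
  num_cols <- which(vapply(df, is.numeric, logical(1)))
  if (length(num_cols) < 2) {
    # columns read as character (e.g. decimal commas not supported): fail loudly
    stop("could not find two numeric columns in ", path, call. = FALSE)
  }
  y1 <- df[[num_cols[1]]]; y2 <- df[[num_cols[2]]]
  observed <- !(is.na(y1) | is.na(y2))
  if (sum(observed) < 20) stop("fewer than 20 complete rows in ", path, call. = FALSE)
  if (standardize) {
    z <- function(v) (v - mean(v[observed])) / stats::sd(v[observed])
    y1 <- z(y1); y2 <- z(y2)
  }
  y1[!observed] <- NA_real_; y2[!observed] <- NA_real_
  bivariate_series(y1, y2, observed = observed,
                   meta = list(source = path, standardized = standardize))
}

#' Sample autocorrelation function
#'
#' Autocorrelations at lags `0..max_lag`, normalized so lag 0 equals 1.
#'
#' @param x numeric sequence (non-constant).
#' @param max_lag largest lag (must be below `length(x)/2`).
#' @return Numeric vector of length `max_lag + 1`.
#' @export
series_acf <- function(x, max_lag) {
  if (stats::var(x) == 0) stop("constant series", call. = FALSE)
  if (max_lag >= length(x) / 2) stop("`max_lag` must be below length(x)/2", call. = FALSE)
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}
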