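#' Daily multivariate panel
#'
#' The basic data container of the package: a run of consecutive calendar
#' dates, a numeric T x m value matrix, and a logical missingness mask of the
#' same shape.  Missing cells carry `NA` in `values` and `TRUE` in
#' `missing_mask`; the two encodings are kept consistent by the constructor.
#'
#' @param dates `Date` vector, strictly increasing by one day, no gaps.
#' @param values numeric matrix (or data.frame) with one row per date.
#' @param names character vector of variable names; defaults to the column
#'   names of `values`.
#' @param missing_mask logical matrix marking unavailable cells; defaults to
#'   `is.na(values)`.
#' @return An object of class `daily_panel` with fields `dates`, `values`,
#'   `missing_mask` and `names`.
#' @examples
#' p <- daily_panel(as.Date("2020-01-01") + 0:4,
#'                  cbind(new = 0:4, pek = 5:9))
#' nrow_panel(p)
#' @export
daily_panel <- function(dates, values, names = colnames(values),
                        missing_mask = NULL) {
  dates <- as.Date(dates)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(dates) != nrow(values))
    stop("length(dates) must equal nrow(values)")
  if (length(dates) > 1) {
    gaps <- diff(as.integer(dates))
    if (any(gaps != 1L)) {
      bad <- which(gaps != 1L)[1]
      stop(sprintf("dates must be consecutive calendar days; gap between %s and %s",
                   dates[bad], dates[bad + 1]))
    }
  }
  if (is.null(names)) names <- paste0("y", seq_len(ncol(values)))
  if (length(names) != ncol(values))
    stop("names must have one entry per column of values")
  if (is.null(missing_mask)) missing_mask <- is.na(values)
  missing_mask <- as.matrix(missing_mask)
  if (!identical(dim(missing_mask), dim(values)))
    stop("missing_mask must match the shape of values")
  values[missing_mask] <- NA_real_
  if (any(is.na(values) & !missing_mask))
    stop("values contain NA cells not flagged in missing_mask")
  colnames(values) <- names
  colnames(missing_mask) <- names
  structure(list(dates = dates, values = values,
                 missing_mask = missing_mask, names = names),
            class = "daily_panel")
}

#' @export
print.daily_panel <- function(x, ...) {
  cat(sprintf("<daily_panel> %d days (%s .. %s), %d series: %s\n",
              length(x$dates), format(x$dates[1]),
              format(x$dates[length(x$dates)]), length(x$names),
              paste(x$names, collapse = ", ")))
  nmiss <- sum(x$missing_mask)
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(x$missing_mask)))
  invisible(x)
}

#' @export
as.data.frame.daily_panel <- function(x, ...) {
  data.frame(date = x$dates, x$values, check.names = FALSE)
}

#' Number of rows (days) in a panel
#' @param panel a `daily_panel` or `adjusted_panel`.
#' @return integer day count.
#' @export
nrow_panel <- function(panel) length(panel$dates)

#' Read and write daily panels as CSV
#'
#' The on-disk format is one header line `date,<name1>,...`, ISO-8601 dates,
#' and empty cells for missing values.  `read_panel` validates that the dates
#' form a gap-free daily calendar and refuses unknown layouts;
#' `write_panel(read_panel(p))` round-trips canonical files byte-identically.
#'
#' @param path file path.
#' @return `read_panel` returns a [daily_panel()].
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "date")
    stop("first column must be 'date', got '", names(df)[1], "'")
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) stop("malformed date(s): ",
                         paste(head(df$date[is.na(dates)], 3), collapse = ", "))
  vals <- sapply(df[-1], function(col) {
    col[col == ""] <- NA_character_
    as.numeric(col)
  })
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = ncol(df) - 1)
  colnames(vals) <- names(df)[-1]
  daily_panel(dates, vals)
}

#' @rdname read_panel
#' @param panel a [daily_panel()].
#' @export
write_panel <- function(panel, path) {
  vals <- panel$values
  txt <- apply(vals, 2, function(col)
    ifelse(is.na(col), "", format_number(col)))
  if (is.null(dim(txt))) txt <- matrix(txt, ncol = ncol(vals))
  lines <- c(paste(c("date", panel$names), collapse = ","),
             paste(format(panel$dates), apply(txt, 1, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

# plain decimal printing: no scientific notation, no trailing-zero padding
format_number <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- format(v, scientific = FALSE, trim = TRUE, digits = 15)
    s
  }, character(1))
  out
}

#' Previous-year monthly baseline
#'
#' One mean level per (variable, month-of-year) pair, taken from the year
#' preceding the study window and subtracted from the daily values during
#' seasonal adjustment.  Every month 1..12 must be present for every variable.
#'
#' @param df data.frame with columns `variable`, `month`, `mean`.
#' @return object of class `monthly_baseline` (a validated data.frame).
#' @export
monthly_baseline <- function(df) {
  stopifnot(all(c("variable", "month", "mean") %in% names(df)))
  df$month <- as.integer(df$month)
  df$mean <- as.numeric(df$mean)
  for (v in unique(df$variable)) {
    mo <- sort(df$month[df$variable == v])
    if (!identical(mo, 1:12))
      stop("baseline for '", v, "' must cover months 1..12")
  }
  structure(df[order(df$variable, df$month), c("variable", "month", "mean")],
            class = c("monthly_baseline", "data.frame"))
}

#' @rdname monthly_baseline
#' @param path file path for CSV with columns variable, month, mean.
#' @export
read_baseline <- function(path) {
  if (!file.exists(path)) stop("no such baseline file: ", path)
  monthly_baseline(read.csv(path))
}

#' @rdname monthly_baseline
#' @param baseline a `monthly_baseline`.
#' @export
write_baseline <- function(baseline, path) {
  write.csv(as.data.frame(baseline), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up a baseline value
#' @param baseline a `monthly_baseline`.
#' @param variable variable name.
#' @param month month of year, 1..12.
#' @return numeric mean level.
#' @export
baseline_value <- function(baseline, variable, month) {
  hit <- baseline$variable == variable & baseline$month == month
  if (!any(hit))
    stop("baseline has no entry for variable '", variable, "', month ", month)
  baseline$mean[hit][1]
}
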