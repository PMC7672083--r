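#' Monthly multivariate series table
#'
#' The common data container of the pipeline: a rectangular table of monthly
#' observations, one numeric column per named variable, with a contiguous
#' month index starting at `start_month`. All modelling is done on the
#' (typically log-transformed) values as stored; the `log_transformed` flags
#' only record how each column should be interpreted when reporting
#' elasticities.
#'
#' @param values numeric matrix or data.frame, one column per variable, no
#'   missing values.
#' @param start_month first month as an ISO `"YYYY-MM"` string.
#' @param log_transformed logical vector (recycled) flagging which columns are
#'   on the natural-log scale. Defaults to `TRUE` for every column.
#' @return An object of class `monthly_panel`: a data.frame with a leading
#'   `month` character column (`"YYYY-MM"`) and one numeric column per
#'   variable, with attribute `log_transformed`.
#' @export
monthly_panel <- function(values, start_month = "2001-01", log_transformed = TRUE) {
  values <- as.data.frame(values)
  if (ncol(values) < 1L || nrow(values) < 1L)
    stop("panel must have at least one variable and one row", call. = FALSE)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("every panel column must be named", call. = FALSE)
  if (anyDuplicated(names(values)))
    stop("duplicated variable names: ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "),
         call. = FALSE)
  if (!all(vapply(values, is.numeric, logical(1))))
    stop("all panel columns must be numeric", call. = FALSE)
  if (anyNA(values))
    stop("panel must not contain missing values", call. = FALSE)
  months <- month_seq(start_month, nrow(values))
  out <- cbind(data.frame(month = months, stringsAsFactors = FALSE), values)
  attr(out, "log_transformed") <-
    stats::setNames(rep_len(log_transformed, ncol(values)), names(values))
  class(out) <- c("monthly_panel", "data.frame")
  out
}

#' @export
print.monthly_panel <- function(x, ...) {
  cat("Monthly panel: ", nrow(x), " months (", x$month[1L], " to ",
      x$month[nrow(x)], "), ", length(panel_vars(x)), " variables\n", sep = "")
  cat("Variables:", paste(panel_vars(x), collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Variable names of a monthly panel (excluding the month index)
#' @param panel a `monthly_panel`.
#' @return character vector of variable names.
#' @export
panel_vars <- function(panel) setdiff(names(panel), "month")

#' Extract the numeric value matrix of a panel
#' @param panel a `monthly_panel`.
#' @param vars optional subset of variable names.
#' @return numeric matrix, one column per variable.
#' @export
panel_matrix <- function(panel, vars = panel_vars(panel)) {
  missing <- setdiff(vars, panel_vars(panel))
  if (length(missing))
    stop("variables not in panel: ", paste(missing, collapse = ", "), call. = FALSE)
  as.matrix(as.data.frame(panel)[vars])
}

## ---- month index helpers ---------------------------------------------------

parse_month <- function(m) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", m)
  if (!all(ok))
    stop("malformed month string(s): ", paste(m[!ok], collapse = ", "),
         " (expected YYYY-MM)", call. = FALSE)
  12L * as.integer(substr(m, 1L, 4L)) + as.integer(substr(m, 6L, 7L)) - 1L
}

format_month <- function(idx) {
  sprintf("%04d-%02d", idx %/% 12L, idx %% 12L + 1L)
}

month_seq <- function(start_month, n) {
  format_month(parse_month(start_month) + seq_len(n) - 1L)
}

## ---- CSV reader / writer ---------------------------------------------------

#' Write a monthly panel to CSV
#'
#' The on-disk dialect is a plain CSV with a leading ISO `month` column
#' (`YYYY-MM`) and a header row of variable names.
#'
#' @param panel a `monthly_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "monthly_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a monthly panel from CSV
#'
#' Rejects malformed month strings, month gaps, duplicated months and
#' missing or non-numeric cells with errors naming the offending row. For raw
#' (not yet log-transformed) burned-area records containing zeros, a
#' `log1p`-style transform applied upstream is a common convention; the reader
#' itself never transforms values.
#'
#' @param path CSV file path (dialect of [write_panel()]).
#' @param log_transformed logical flags passed to [monthly_panel()].
#' @return a `monthly_panel`.
#' @export
read_panel <- function(path, log_transformed = TRUE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"month" %in% names(raw))
    stop("panel CSV must have a leading 'month' column", call. = FALSE)
  idx <- parse_month(raw$month)
  if (anyDuplicated(idx)) {
    dup <- raw$month[duplicated(idx)]
    stop("duplicated month(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(idx))
    stop("months out of order starting at row ",
         which(diff(idx) < 0L)[1L] + 1L, call. = FALSE)
  gaps <- which(diff(idx) > 1L)
  if (length(gaps)) {
    miss <- format_month(idx[gaps[1L]] + 1L)
    stop("month gap: ", miss, " is missing (after row ", gaps[1L], ")",
         call. = FALSE)
  }
  vals <- raw[setdiff(names(raw), "month")]
  for (v in names(vals)) {
    if (!is.numeric(vals[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[v]]))))[1L]
      stop("non-numeric cell in '", v, "' at row ", bad, call. = FALSE)
    }
    if (anyNA(vals[[v]]))
      stop("missing cell in '", v, "' at row ", which(is.na(vals[[v]]))[1L],
           call. = FALSE)
  }
  monthly_panel(vals, start_month = raw$month[1L],
                log_transformed = log_transformed)
}
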