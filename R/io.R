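# Delimited-text schemas for plot measurements, monthly series, tethering
# outcomes and result tables. All files are comma-separated UTF-8 with a
# header row; synthetic and field data use the same schemas and round-trip
# losslessly through the writers/readers.

plot_table_columns <- c(
  "plot_id", "treatment", "measurement", "replicate", "time", "value"
)
series_columns <- c("plot_id", "treatment", "year", "month", "count")
tethering_columns <- c("plot_id", "treatment", "n_placed", "n_eaten")

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(
      what, " `", path, "` is missing required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
}

check_numeric <- function(df, cols, what, path) {
  for (col in cols) {
    if (all(is.na(df[[col]]))) next # e.g. `time` unused by any measurement
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
        !is.na(df[[col]]))
      stop(
        what, " `", path, "`: column `", col, "` has non-numeric value(s)",
        if (length(bad)) paste0(" at row(s) ", paste(utils::head(bad, 5),
          collapse = ", "
        )),
        call. = FALSE
      )
    }
  }
}

read_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) {
    stop(what, " `", path, "` does not exist", call. = FALSE)
  }
  df <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  )
  if (nrow(df) == 0) {
    stop(what, " `", path, "` is empty", call. = FALSE)
  }
  check_columns(df, required, what, path)
  check_numeric(df, numeric_cols, what, path)
  df
}

validate_plot_table <- function(raw, path = "<in-memory>") {
  check_columns(raw, plot_table_columns, "plot table", path)
  check_numeric(raw, c("replicate", "time", "value"), "plot table", path)
  if (any(is.na(raw$value))) {
    stop("plot table `", path, "` has missing `value` cells", call. = FALSE)
  }
  invisible(raw)
}

#' Read and write the delimited-text data tables
#'
#' `read_plot_table()` reads the long-format raw measurement table (columns
#' `plot_id, treatment, measurement, replicate, time, value`);
#' `read_series()` the monthly count series (`plot_id, treatment, year,
#' month, count`); `read_tethering()` the tethered-crab outcomes (`plot_id,
#' treatment, n_placed, n_eaten`). Schema violations (missing columns,
#' non-numeric cells, unknown treatment labels, empty files) raise errors
#' naming the offending column or rows. `write_plot_table()` and friends
#' write the same schemas; write-then-read round-trips are lossless to
#' double precision.
#'
#' @param path File path (CSV, UTF-8, header row).
#' @param treatments Allowed treatment labels; `NULL` skips the check.
#' @return A tibble in the corresponding schema.
#' @export
read_plot_table <- function(path, treatments = marsh_treatments()) {
  df <- read_checked(
    path, plot_table_columns, c("replicate", "time", "value"), "plot table"
  )
  validate_plot_table(df, path)
  check_treatments(df, treatments, path)
  df
}

check_treatments <- function(df, treatments, path) {
  if (!is.null(treatments)) {
    unknown <- setdiff(unique(df$treatment), treatments)
    if (length(unknown) > 0) {
      stop("`", path, "` has unknown treatment label(s): ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(df)
}

#' @rdname read_plot_table
#' @export
read_series <- function(path, treatments = marsh_treatments()) {
  df <- read_checked(
    path, series_columns, c("year", "month", "count"), "series table"
  )
  check_treatments(df, treatments, path)
  df
}

#' @rdname read_plot_table
#' @export
read_tethering <- function(path, treatments = marsh_treatments()) {
  df <- read_checked(
    path, tethering_columns, c("n_placed", "n_eaten"), "tethering table"
  )
  check_treatments(df, treatments, path)
  df
}

#' @rdname read_plot_table
#' @param x Tibble in the corresponding schema.
#' @export
write_plot_table <- function(x, path) {
  validate_plot_table(x, path)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_plot_table
#' @export
write_series <- function(x, path) {
  check_columns(x, series_columns, "series table", path)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a set of result tables to a directory
#'
#' Writes every tibble/data frame in a named list as `<name>.csv` under
#' `dir` (created if needed); non-tabular elements are skipped.
#'
#' @param dir Output directory.
#' @param objects Named list of tibbles.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(dir, objects) {
  if (is.null(names(objects)) || any(names(objects) == "")) {
    stop("`objects` must be a fully named list", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      readr::write_csv(obj, p, progress = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
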