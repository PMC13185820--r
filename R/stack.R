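#' Annual field stacks
#'
#' An `annual_stack` is a gridded annual variable: a numeric array with
#' dimensions (row, col, year) carrying the year labels and units as
#' attributes. Cells that are invalid everywhere are `NA`. This is the
#' exchange container between the world generator, the index builder, the
#' upscaler, and the stability/coupling stages.
#'
#' @param x numeric array, dim = c(rows, cols, n_years).
#' @param years integer vector of year labels, length = dim(x)[3].
#' @param units unit string (e.g. "g C m-2 yr-1").
#' @param varname variable name.
#' @return an `annual_stack`.
#' @export
annual_stack <- function(x, years, units = "", varname = "") {
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("`x` must be a 3-d array (row, col, year)", call. = FALSE)
  }
  if (length(years) != dim(x)[3]) {
    stop("`years` length must match the third dimension of `x`", call. = FALSE)
  }
  structure(x, years = as.integer(years), units = units, varname = varname,
            class = c("annual_stack", "array"))
}

#' @export
print.annual_stack <- function(x, ...) {
  d <- dim(x)
  yrs <- attr(x, "years")
  cat(sprintf("<annual_stack> %s [%d x %d x %d years %d-%d] %s\n",
              attr(x, "varname"), d[1], d[2], d[3], min(yrs), max(yrs),
              attr(x, "units")))
  invisible(x)
}

#' @rdname annual_stack
#' @export
stack_years <- function(x) attr(x, "years")

#' Subset an annual stack by years
#'
#' @param x an `annual_stack`.
#' @param years year labels to keep (must all be present).
#' @return an `annual_stack` restricted to `years`.
#' @export
stack_subset_years <- function(x, years) {
  yrs <- stack_years(x)
  idx <- match(years, yrs)
  if (anyNA(idx)) stop("requested years outside the stack range", call. = FALSE)
  annual_stack(x[, , idx, drop = FALSE], years = yrs[idx],
               units = attr(x, "units"), varname = attr(x, "varname"))
}

#' Write / read an annual stack as long-format CSV
#'
#' Plain-text persistence (`row,col,year,value`); round-trips exactly at
#' full double precision.
#'
#' @param x an `annual_stack`.
#' @param path file path.
#' @export
write_stack_csv <- function(x, path) {
  d <- dim(x)
  yrs <- stack_years(x)
  df <- data.frame(
    row = rep(seq_len(d[1]), times = d[2] * d[3]),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    year = rep(yrs, each = d[1] * d[2]),
    value = as.vector(x)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @param units,varname metadata restored on read.
#' @export
read_stack_csv <- function(path, units = "", varname = "") {
  df <- utils::read.csv(path)
  rows <- max(df$row); cols <- max(df$col)
  yrs <- sort(unique(df$year))
  arr <- array(NA_real_, dim = c(rows, cols, length(yrs)))
  arr[cbind(df$row, df$col, match(df$year, yrs))] <- df$value
  annual_stack(arr, years = yrs, units = units, varname = varname)
}

#' Apply a function over the year dimension of a stack
#'
#' @param x an `annual_stack`.
#' @param f function taking a numeric vector (one cell's annual series).
#' @return a matrix (rows x cols).
#' @keywords internal
stack_cell_apply <- function(x, f) {
  apply(unclass(x), c(1, 2), f)
}
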