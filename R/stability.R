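#' Temporal stability of an annual series
#'
#' Stability is the ratio of the mean to the sample standard deviation
#' (n-1 denominator) of annual values: higher means smaller relative
#' interannual fluctuation. A zero-variance series has undefined stability
#' and returns `NA` (never infinity), so downstream correlations can skip
#' such cells explicitly.
#'
#' @param series numeric vector of annual values (>= 2 non-missing).
#' @param na.rm drop missing values before computing.
#' @return mean/SD, or `NA` if the SD is zero.
#' @export
stability <- function(series, na.rm = TRUE) {
  if (na.rm) series <- series[!is.na(series)]
  if (length(series) < 2) stop("stability needs >= 2 values", call. = FALSE)
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0) return(NA_real_)
  mean(series) / s
}

#' Per-cell stability map of an annual stack
#'
#' @param stack an [annual_stack].
#' @param years `NULL` (full period) or a vector of year labels.
#' @return a `stability_map`: matrix of per-cell mean/SD values (NA where
#'   undefined), with the window and source variable recorded.
#' @export
stability_map <- function(stack, years = NULL) {
  stopifnot(inherits(stack, "annual_stack"))
  if (!is.null(years)) {
    if (length(years) == 0) stop("empty year range", call. = FALSE)
    stack <- stack_subset_years(stack, years)
  }
  if (dim(stack)[3] < 2) stop("need >= 2 years for stability", call. = FALSE)
  vals <- stack_cell_apply(stack, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    s <- stats::sd(x)
    if (s == 0) NA_real_ else mean(x) / s
  })
  structure(vals,
            window = range(stack_years(stack)),
            varname = attr(stack, "varname"),
            class = c("stability_map", "matrix"))
}

#' Moving-window stability of an annual stack
#'
#' One stability map per window start: `n_years - window + 1` maps
#' (34 years with a 10-year window give 25, labelled 1985-1994 through
#' 2009-2018 for a 1985 start).
#'
#' @param stack an [annual_stack].
#' @param window window length in years (default 10).
#' @return a `window_stability` object: `$maps` array (rows x cols x
#'   windows), `$windows` data.frame(start, end), `$window`, `$varname`.
#' @export
moving_window_stability <- function(stack, window = 10) {
  stopifnot(inherits(stack, "annual_stack"))
  yrs <- stack_years(stack)
  ny <- length(yrs)
  if (window > ny) stop("window longer than the series", call. = FALSE)
  if (window < 2) stop("window must be >= 2", call. = FALSE)
  k <- ny - window + 1
  d <- dim(stack)
  maps <- array(NA_real_, c(d[1], d[2], k))
  for (i in seq_len(k)) {
    maps[, , i] <- stability_map(stack, years = yrs[i:(i + window - 1)])
  }
  structure(list(maps = maps,
                 windows = data.frame(start = yrs[seq_len(k)],
                                      end = yrs[seq_len(k)] + window - 1L),
                 window = window, varname = attr(stack, "varname")),
            class = "window_stability")
}

#' @export
print.window_stability <- function(x, ...) {
  cat(sprintf("<window_stability> %s: %d windows of %d years (%d-%d ... %d-%d)\n",
              x$varname, nrow(x$windows), x$window,
              x$windows$start[1], x$windows$end[1],
              x$windows$start[nrow(x$windows)], x$windows$end[nrow(x$windows)]))
  invisible(x)
}

#' Aridity index and aridity classes
#'
#' The aridity index (AI) is annual MAP divided by annual PET, per cell and
#' year; cells are classified by their mean AI over the period using the
#' standard breakpoints (hyper-arid < 0.05 < arid < 0.20 < semi-arid <
#' 0.50 < dry sub-humid < 0.65 < humid). Boundary values belong to the
#' drier class. Cells with non-positive PET in any year are masked.
#'
#' @param map_stack annual precipitation stack (mm).
#' @param pet_stack annual potential evapotranspiration stack (mm).
#' @param edges class bin edges (increasing).
#' @return an `aridity_class_map`: `$ai_mean` matrix, `$class` factor
#'   matrix (levels dry to humid), `$ai_annual` [annual_stack], `$edges`.
#' @export
aridity <- function(map_stack, pet_stack,
                    edges = c(0.05, 0.20, 0.50, 0.65)) {
  stopifnot(inherits(map_stack, "annual_stack"),
            inherits(pet_stack, "annual_stack"),
            identical(dim(map_stack), dim(pet_stack)))
  pet <- unclass(pet_stack)
  bad <- pet <= 0
  ai <- unclass(map_stack) / ifelse(bad, NA_real_, pet)
  ai_stack <- annual_stack(ai, stack_years(map_stack), units = "MAP/PET",
                           varname = "AI")
  ai_mean <- apply(ai, c(1, 2), function(x) {
    if (anyNA(x)) NA_real_ else mean(x)
  })
  lv <- c("hyper-arid", "arid", "semi-arid", "dry sub-humid", "humid")
  ## right-closed bins: a value at an edge falls in the drier class
  cls <- cut(ai_mean, breaks = c(-Inf, edges, Inf), labels = lv, right = TRUE)
  class_mat <- matrix(as.character(cls), nrow(ai_mean), ncol(ai_mean))
  structure(list(ai_mean = ai_mean, class = class_mat, ai_annual = ai_stack,
                 edges = edges, levels = lv),
            class = "aridity_class_map")
}

#' @export
print.aridity_class_map <- function(x, ...) {
  cat("<aridity_class_map> cells per class:\n")
  print(table(factor(unlist(x$class), levels = x$levels)))
  invisible(x)
}
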