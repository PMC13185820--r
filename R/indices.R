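#' Trailing moving average of an annual stack
#'
#' Value at year t is the mean of years max(1, t-window+1)..t: a trailing
#' window, shortened at the start of the series so the output has the same
#' length as the input. Captures cumulative (past-years) effects.
#'
#' @param stack an [annual_stack] (or plain numeric vector).
#' @param window window length in years (>= 1, <= series length).
#' @return object of the same shape as `stack`.
#' @export
moving_average <- function(stack, window = 3) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  ma_vec <- function(x) {
    n <- length(x)
    if (window > n) stop("window longer than the series", call. = FALSE)
    cs <- cumsum(x)
    lo <- pmax(0, seq_len(n) - window)
    (cs - c(0, cs)[lo + 1]) / (seq_len(n) - lo)
  }
  if (is.numeric(stack) && is.null(dim(stack))) return(ma_vec(stack))
  stopifnot(inherits(stack, "annual_stack"))
  ny <- dim(stack)[3]
  if (window > ny) stop("window longer than the series", call. = FALSE)
  out <- unclass(stack)
  cs <- out
  for (t in seq_len(ny)[-1]) cs[, , t] <- cs[, , t - 1] + out[, , t]
  res <- out
  for (t in seq_len(ny)) {
    lo <- max(0, t - window)
    res[, , t] <- (cs[, , t] - if (lo > 0) cs[, , lo] else 0) / (t - lo)
  }
  annual_stack(res, stack_years(stack), units = attr(stack, "units"),
               varname = paste0(attr(stack, "varname"), "_ma"))
}

flatten_vars <- function(vars, include_moving_avg, ma_window) {
  time_varying <- vapply(vars, function(v) inherits(v, "annual_stack"), TRUE)
  if (any(time_varying) && !all(time_varying)) {
    stop("cannot mix time-varying and static variables in one category",
         call. = FALSE)
  }
  if (all(time_varying)) {
    cols <- list()
    for (nm in names(vars)) {
      cols[[nm]] <- as.vector(unclass(vars[[nm]]))
      if (include_moving_avg) {
        cols[[paste0(nm, "_ma", ma_window)]] <-
          as.vector(unclass(moving_average(vars[[nm]], ma_window)))
      }
    }
    list(X = do.call(cbind, cols), time_varying = TRUE,
         dim3 = dim(vars[[1]]), years = stack_years(vars[[1]]))
  } else {
    X <- do.call(cbind, lapply(vars, as.vector))
    colnames(X) <- names(vars)
    list(X = X, time_varying = FALSE, dim2 = dim(vars[[1]]))
  }
}

#' Build one composite (PC1) category index
#'
#' Standardizes the category's variables (z-score over the PCA sample),
#' takes the first principal component, fixes its sign so that the loading
#' of a designated reference variable is positive, and evaluates the index
#' everywhere by projecting the standardized variables onto the PC1
#' loadings. Time-varying categories may contribute each variable together
#' with its trailing moving average.
#'
#' @param vars named list of [annual_stack]s (time-varying category) or
#'   matrices (static category); >= 2 variables.
#' @param include_moving_avg add each variable's trailing moving average as
#'   an extra column (time-varying categories only).
#' @param ma_window moving-average window (years).
#' @param sign_ref variable whose loading is oriented positive (default:
#'   the first variable).
#' @param sample_idx integer rows (cell-years, or cells for static
#'   categories) used to fit the standardization and the PCA; default all.
#' @return list with `index` (stack or matrix), `loadings` (unit-norm PC1
#'   weights), `var_explained`, `center`, `scale`, `variables`.
#' @export
build_category_index <- function(vars, include_moving_avg = FALSE,
                                 ma_window = 3, sign_ref = NULL,
                                 sample_idx = NULL) {
  if (length(vars) < 2) stop("need >= 2 variables for a category index", call. = FALSE)
  if (is.null(names(vars)) || any(names(vars) == "")) {
    stop("`vars` must be a fully named list", call. = FALSE)
  }
  fl <- flatten_vars(vars, include_moving_avg, ma_window)
  X <- fl$X
  sample_idx <- sample_idx %||% seq_len(nrow(X))
  Xs <- X[sample_idx, , drop = FALSE]
  ctr <- colMeans(Xs)
  scl <- apply(Xs, 2, stats::sd)
  if (any(scl == 0 | !is.finite(scl))) {
    bad <- colnames(X)[scl == 0 | !is.finite(scl)]
    stop(sprintf("constant variable(s) over the PCA sample: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  Z <- sweep(sweep(Xs, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  w <- pc$rotation[, 1]
  ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  sign_ref <- sign_ref %||% colnames(X)[1]
  if (!sign_ref %in% colnames(X)) stop("unknown sign_ref variable", call. = FALSE)
  if (w[sign_ref] < 0) w <- -w
  scores <- as.vector(sweep(sweep(X, 2, ctr), 2, scl, "/") %*% w)
  index <- if (fl$time_varying) {
    annual_stack(array(scores, fl$dim3), fl$years, units = "index (PC1)",
                 varname = "index")
  } else {
    matrix(scores, fl$dim2[1], fl$dim2[2])
  }
  list(index = index, loadings = w, var_explained = ve,
       center = ctr, scale = scl, variables = colnames(X))
}

#' Build the six composite environmental indices of a world
#'
#' Climate (Cli) and vegetation (Plant) indices are time-varying and include
#' each variable's 3-year trailing moving average in the PCA; topography
#' (Gra), microbial (Mic), soil physical (Phy) and soil chemical (Chem)
#' indices are static. Sign conventions: MAT, NPP, elevation, MBC, clay, and
#' SOC loadings are oriented positive in their respective categories.
#'
#' @param world a [generate_world()] result (or any list with the same
#'   `climate`, `vegetation`, `soil`, `topo` components).
#' @param sample_frac fraction of cell-years (cells for static categories)
#'   used as the PCA fitting sample; default 1 (all, deterministic).
#' @param seed seed for the PCA subsample when `sample_frac < 1`.
#' @param ma_window moving-average window for time-varying categories.
#' @return a `composite_indices` object: `$Cli`, `$Plant` ([annual_stack]s),
#'   `$Gra`, `$Mic`, `$Phy`, `$Chem` (matrices), `$loadings`,
#'   `$var_explained`, `$standardization`.
#' @export
composite_indices <- function(world, sample_frac = 1, seed = NULL,
                              ma_window = 3) {
  stopifnot_fraction(sample_frac, "sample_frac")
  cat_spec <- list(
    Cli   = list(vars = world$climate, ma = TRUE,  ref = "MAT"),
    Plant = list(vars = world$vegetation[c("NPP", "LAI", "FVC", "CUE", "WUE")],
                 ma = TRUE, ref = "NPP"),
    Gra   = list(vars = world$topo, ma = FALSE, ref = "elevation"),
    Mic   = list(vars = world$soil[c("MBC", "MBN", "MBP")], ma = FALSE,
                 ref = "MBC"),
    Phy   = list(vars = world$soil[c("sand", "silt", "clay", "bulk_density",
                                     "VWC", "pH", "CEC")], ma = FALSE,
                 ref = "clay"),
    Chem  = list(vars = world$soil[c("SOC", "TN", "CN")], ma = FALSE,
                 ref = "SOC")
  )
  out <- list(loadings = list(), var_explained = numeric(0),
              standardization = list())
  for (nm in names(cat_spec)) {
    sp <- cat_spec[[nm]]
    n_rows <- if (sp$ma) prod(dim(sp$vars[[1]])) else length(sp$vars[[1]])
    sample_idx <- if (sample_frac < 1) {
      with_seed(seed, sample.int(n_rows, max(2, round(sample_frac * n_rows))))
    } else NULL
    ci <- build_category_index(sp$vars, include_moving_avg = sp$ma,
                               ma_window = ma_window, sign_ref = sp$ref,
                               sample_idx = sample_idx)
    if (inherits(ci$index, "annual_stack")) {
      attr(ci$index, "varname") <- nm
    }
    out[[nm]] <- ci$index
    out$loadings[[nm]] <- ci$loadings
    out$var_explained[nm] <- ci$var_explained
    out$standardization[[nm]] <- list(center = ci$center, scale = ci$scale)
  }
  structure(out, class = "composite_indices")
}

#' @export
print.composite_indices <- function(x, ...) {
  cat("<composite_indices> PC1 variance explained:\n")
  print(round(x$var_explained, 3))
  invisible(x)
}

nearest_index <- function(x, centers) {
  ## nearest center; ties resolve to the lower index (which.min's rule)
  vapply(x, function(v) which.min(abs(v - centers)), 1L)
}

#' Extract composite indices at site records
#'
#' Maps each record's coordinates to the nearest grid cell (ties to the
#' lower index) and its measurement year (floor of the fractional midyear)
#' to the index year, producing one design row per record with the six index
#' values, the ecosystem class, and the observed soil respiration. Records
#' falling outside the grid or the year range are dropped and counted.
#'
#' @param indices a [composite_indices()] set.
#' @param records filtered record table with `Latitude`, `Longitude`,
#'   `Study_midyear`, `Rs_annual`, `Site_ID`, `Ecosystem_type` columns.
#' @param geo grid geometry (`world$geo`): `lat`, `lon` cell-center vectors.
#' @return design data.frame (attribute `n_dropped` counts out-of-range
#'   records).
#' @export
extract_at_sites <- function(indices, records, geo) {
  stopifnot(inherits(indices, "composite_indices"))
  years <- stack_years(indices$Cli)
  if (nrow(records) == 0) {
    out <- data.frame(Site_ID = character(0), Ecosystem_type = character(0),
                      row = integer(0), col = integer(0), year = integer(0),
                      Rs = numeric(0), Cli = numeric(0), Plant = numeric(0),
                      Gra = numeric(0), Mic = numeric(0), Phy = numeric(0),
                      Chem = numeric(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  yr <- floor(records$Study_midyear)
  half_lat <- if (length(geo$lat) > 1) diff(geo$lat[1:2]) / 2 else Inf
  half_lon <- if (length(geo$lon) > 1) diff(geo$lon[1:2]) / 2 else Inf
  in_grid <- records$Latitude >= min(geo$lat) - half_lat &
    records$Latitude <= max(geo$lat) + half_lat &
    records$Longitude >= min(geo$lon) - half_lon &
    records$Longitude <= max(geo$lon) + half_lon
  in_years <- yr %in% years
  keep <- which(in_grid & in_years & !is.na(records$Latitude) &
                  !is.na(records$Longitude) & !is.na(yr))
  n_dropped <- nrow(records) - length(keep)
  if (n_dropped > 0) {
    message(sprintf("extract_at_sites: dropped %d record(s) outside the grid/date range",
                    n_dropped))
  }
  rec <- records[keep, , drop = FALSE]
  r <- nearest_index(rec$Latitude, geo$lat)
  c_ <- nearest_index(rec$Longitude, geo$lon)
  t_ <- match(floor(rec$Study_midyear), years)
  cli <- unclass(indices$Cli)[cbind(r, c_, t_)]
  pla <- unclass(indices$Plant)[cbind(r, c_, t_)]
  out <- data.frame(
    Site_ID = rec$Site_ID,
    Ecosystem_type = rec$Ecosystem_type,
    row = r, col = c_, year = years[t_],
    Rs = rec$Rs_annual,
    Cli = cli, Plant = pla,
    Gra = indices$Gra[cbind(r, c_)],
    Mic = indices$Mic[cbind(r, c_)],
    Phy = indices$Phy[cbind(r, c_)],
    Chem = indices$Chem[cbind(r, c_)]
  )
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
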