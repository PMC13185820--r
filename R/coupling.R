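#' Critical Pearson correlation at a two-sided level
#'
#' The |r| threshold at which a Pearson correlation over `n` pairs reaches
#' two-sided significance `alpha` under the t distribution with n-2 df.
#'
#' @param n number of pairs.
#' @param alpha two-sided significance level.
#' @return critical |r|.
#' @export
r_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3", call. = FALSE)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Bivariate low/high overlap classification of two stability maps
#'
#' Each map is split at its own `p_low`th and `p_high`th percentiles
#' (computed over its valid cells). Cells low (<= low threshold) or high
#' (>= high threshold) in both maps get a corner class; everything else is
#' `intermediate`. If a map's two thresholds coincide (degenerate
#' distribution), all its cells are treated as intermediate.
#'
#' @param stabA,stabB `stability_map`s on the same grid.
#' @param p_low,p_high percentile thresholds (defaults 10 and 90).
#' @return a `bivariate_class_map`: `$class` character matrix with levels
#'   low-low / low-high / high-low / high-high / intermediate (NA where
#'   either map is undefined), `$thresholds`.
#' @export
bivariate_class_map <- function(stabA, stabB, p_low = 10, p_high = 90) {
  if (!identical(dim(stabA), dim(stabB))) stop("grid mismatch", call. = FALSE)
  a <- unclass(stabA); b <- unclass(stabB)
  thr <- function(x) stats::quantile(x[is.finite(x)],
                                     probs = c(p_low, p_high) / 100,
                                     names = FALSE)
  ta <- thr(a); tb <- thr(b)
  lev <- function(x, t) {
    if (t[1] >= t[2]) return(ifelse(is.finite(x), "mid", NA_character_))
    ifelse(!is.finite(x), NA_character_,
           ifelse(x <= t[1], "low", ifelse(x >= t[2], "high", "mid")))
  }
  la <- lev(a, ta); lb <- lev(b, tb)
  cls <- ifelse(is.na(la) | is.na(lb), NA_character_,
                ifelse(la != "mid" & lb != "mid",
                       paste(la, lb, sep = "-"), "intermediate"))
  structure(list(class = matrix(cls, nrow(a), ncol(a)),
                 thresholds = list(A = ta, B = tb),
                 levels = c("low-low", "low-high", "high-low", "high-high",
                            "intermediate")),
            class = "bivariate_class_map")
}

#' Windowed coupling of two stability series
#'
#' Per-cell Pearson correlation between two moving-window stability series
#' (e.g., soil-respiration stability vs NPP stability across 10-year
#' windows), with a significance flag against the t-based critical value at
#' the analysis's number of windows. Cells with any undefined window value
#' in either series are masked (listwise).
#'
#' @param seriesA,seriesB `window_stability` objects with equal window
#'   counts (>= 3).
#' @param alpha two-sided significance level.
#' @return a `coupling_map`: `$r` matrix, `$sig` logical matrix,
#'   `$r_crit`, `$n_windows`, `$alpha`.
#' @export
windowed_coupling <- function(seriesA, seriesB, alpha = 0.05) {
  stopifnot(inherits(seriesA, "window_stability"),
            inherits(seriesB, "window_stability"))
  ka <- dim(seriesA$maps)[3]; kb <- dim(seriesB$maps)[3]
  if (ka != kb) stop("window counts differ", call. = FALSE)
  if (ka < 3) stop("need >= 3 windows", call. = FALSE)
  if (!identical(dim(seriesA$maps)[1:2], dim(seriesB$maps)[1:2])) {
    stop("grid mismatch", call. = FALSE)
  }
  d <- dim(seriesA$maps)
  A <- matrix(seriesA$maps, d[1] * d[2], d[3])
  B <- matrix(seriesB$maps, d[1] * d[2], d[3])
  ok <- rowSums(!is.finite(A)) == 0 & rowSums(!is.finite(B)) == 0
  r <- rep(NA_real_, nrow(A))
  if (any(ok)) {
    Ac <- A[ok, , drop = FALSE] - rowMeans(A[ok, , drop = FALSE])
    Bc <- B[ok, , drop = FALSE] - rowMeans(B[ok, , drop = FALSE])
    num <- rowSums(Ac * Bc)
    den <- sqrt(rowSums(Ac^2) * rowSums(Bc^2))
    r[ok] <- ifelse(den > 0, num / den, NA_real_)
  }
  rc <- r_critical(ka, alpha)
  structure(list(r = matrix(r, d[1], d[2]),
                 sig = matrix(!is.na(r) & abs(r) >= rc, d[1], d[2]),
                 r_crit = rc, n_windows = ka, alpha = alpha,
                 vars = c(seriesA$varname, seriesB$varname)),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  r <- x$r[is.finite(x$r)]
  cat(sprintf("<coupling_map> %s vs %s: mean r %.3f over %d cells; %d windows, r_crit %.3f, %.1f%% significant\n",
              x$vars[1], x$vars[2], mean(r), length(r), x$n_windows, x$r_crit,
              100 * mean(x$sig[is.finite(x$r)])))
  invisible(x)
}

#' Stratified summary of a coupling map
#'
#' Mean, SD and cell count of the per-cell coupling correlation within each
#' stratum of an ecosystem map or an aridity class map (ordered dry to
#' humid for aridity strata).
#'
#' @param coupling a [windowed_coupling()] result.
#' @param strata an integer/character matrix aligned with the coupling grid,
#'   or an `aridity_class_map`.
#' @param labels optional stratum labels for integer strata.
#' @return data.frame (stratum, mean_r, sd_r, n).
#' @export
stratified_mean_r <- function(coupling, strata, labels = NULL) {
  stopifnot(inherits(coupling, "coupling_map"))
  if (inherits(strata, "aridity_class_map")) {
    lv <- strata$levels
    s <- strata$class
  } else {
    s <- strata
    lv <- labels %||% sort(unique(as.vector(s)))
    if (!is.null(labels) && is.numeric(s)) {
      s <- matrix(labels[s], nrow(s), ncol(s))
    }
  }
  if (!identical(dim(s), dim(coupling$r))) {
    stop("strata grid does not match the coupling grid", call. = FALSE)
  }
  r <- as.vector(coupling$r)
  g <- factor(as.vector(s), levels = lv)
  out <- data.frame(
    stratum = lv,
    mean_r = as.numeric(tapply(r, g, function(x) mean(x, na.rm = TRUE))),
    sd_r = as.numeric(tapply(r, g, function(x) stats::sd(x, na.rm = TRUE))),
    n = as.integer(tapply(is.finite(r), g, sum))
  )
  out$n[is.na(out$n)] <- 0L
  out$mean_r[out$n == 0] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Dominant predictor of interannual soil-respiration variation
#'
#' Per cell, the predictor whose annual series contributes most to the
#' interannual variation of soil respiration. Contribution is the absolute
#' Pearson correlation between the predictor's and the response's annual
#' series (default), or the absolute standardized regression coefficient of
#' a joint linear fit (`method = "std_beta"`). Ties break by predictor
#' order.
#'
#' @param rs_stack response [annual_stack].
#' @param predictor_stacks named list of aligned predictor stacks (e.g.
#'   NPP, LAI, temperature, precipitation, AI).
#' @param method contribution definition.
#' @return a `dominant_map`: `$dominant` character matrix (NA where all
#'   contributions are undefined), `$contribution` matrix of the winning
#'   statistic, `$predictors`.
#' @export
dominant_predictor_map <- function(rs_stack, predictor_stacks,
                                   method = c("correlation", "std_beta")) {
  method <- match.arg(method)
  stopifnot(inherits(rs_stack, "annual_stack"), length(predictor_stacks) >= 1)
  d <- dim(rs_stack)
  if (d[3] < 3) stop("need >= 3 years", call. = FALSE)
  for (p in predictor_stacks) {
    if (!identical(dim(p), d)) stop("predictor stack not aligned", call. = FALSE)
  }
  pn <- names(predictor_stacks)
  dom <- matrix(NA_character_, d[1], d[2])
  con <- matrix(NA_real_, d[1], d[2])
  y_all <- unclass(rs_stack)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      y <- y_all[i, j, ]
      if (anyNA(y) || stats::sd(y) == 0) next
      contrib <- rep(NA_real_, length(pn))
      if (method == "correlation") {
        for (k in seq_along(pn)) {
          x <- unclass(predictor_stacks[[k]])[i, j, ]
          if (!anyNA(x) && stats::sd(x) > 0) {
            contrib[k] <- abs(stats::cor(x, y))
          }
        }
      } else {
        X <- vapply(predictor_stacks, function(p) unclass(p)[i, j, ],
                    numeric(d[3]))
        ok <- apply(X, 2, function(x) !anyNA(x) && stats::sd(x) > 0)
        if (any(ok)) {
          Z <- scale(X[, ok, drop = FALSE])
          fit <- stats::lm.fit(cbind(1, Z), as.vector(scale(y)))
          contrib[ok] <- abs(fit$coefficients[-1])
        }
      }
      if (all(is.na(contrib))) next
      k_best <- which.max(contrib)  # first index wins ties
      dom[i, j] <- pn[k_best]
      con[i, j] <- contrib[k_best]
    }
  }
  structure(list(dominant = dom, contribution = con, predictors = pn,
                 method = method),
            class = "dominant_map")
}
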