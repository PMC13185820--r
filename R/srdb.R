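#' Default SRDB column mapping
#'
#' Maps the roles the filter chain needs onto SRDB column names. Override
#' any entry for CSV dialects with different headers.
#' @export
srdb_columns <- function(site_id = "Site_ID", latitude = "Latitude",
                         longitude = "Longitude", year = "Study_midyear",
                         rs_annual = "Rs_annual",
                         ecosystem = "Ecosystem_type") {
  list(site_id = site_id, latitude = latitude, longitude = longitude,
       year = year, rs_annual = rs_annual, ecosystem = ecosystem)
}

#' Read an SRDB-style CSV of site-year soil respiration records
#'
#' One row per record. Numeric fields that fail to parse become `NA`,
#' never zero; records with missing metadata are retained here (the filter
#' chain removes them with full accounting).
#'
#' @param path CSV file path.
#' @param columns column mapping from [srdb_columns()].
#' @return data.frame with canonical columns `Site_ID`, `Latitude`,
#'   `Longitude`, `Study_midyear`, `Rs_annual`, `Ecosystem_type` (missing
#'   ecosystem column tolerated, filled with `NA`) plus any extra input
#'   columns.
#' @export
read_srdb <- function(path, columns = srdb_columns()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", "", "N/A"))
  if (nrow(raw) == 0) stop("empty SRDB file: no records", call. = FALSE)
  required <- columns[c("site_id", "latitude", "longitude", "year", "rs_annual")]
  absent <- setdiff(unlist(required), names(raw))
  if (length(absent)) {
    stop(sprintf("missing required SRDB column(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- raw
  out$Site_ID <- as.character(raw[[columns$site_id]])
  out$Latitude <- num(raw[[columns$latitude]])
  out$Longitude <- num(raw[[columns$longitude]])
  out$Study_midyear <- num(raw[[columns$year]])
  out$Rs_annual <- num(raw[[columns$rs_annual]])
  out$Ecosystem_type <- if (columns$ecosystem %in% names(raw)) {
    as.character(raw[[columns$ecosystem]])
  } else NA_character_
  out
}

#' Filter soil-respiration records
#'
#' The four-step chain: (1) keep annual measurements (non-missing annual
#' flux); (2) keep records with complete longitude, latitude and
#' measurement year; (3) keep measurement years within
#' `[year_min, year_max]` (fractional midyears floor to the integer year);
#' (4) remove outliers beyond `mean +/- sd_k * SD` of the annual flux,
#' where mean and SD are computed over the records surviving steps 1-3
#' (pooled by default, per ecosystem behind a flag). A single outlier pass
#' is applied.
#'
#' @param raw record table from [read_srdb()].
#' @param year_min,year_max inclusive year range.
#' @param sd_k outlier half-width in standard deviations.
#' @param per_ecosystem compute outlier bounds within each ecosystem class
#'   instead of pooled.
#' @return list with `records` (filtered table) and `report` (a
#'   `filter_report`: counts after each step, sites retained, outlier
#'   bounds, and the site/record counts with and without a known ecosystem
#'   class).
#' @export
filter_records <- function(raw, year_min = 1985, year_max = 2018, sd_k = 3,
                           per_ecosystem = FALSE) {
  n_raw <- nrow(raw)
  annual <- raw[!is.na(raw$Rs_annual), , drop = FALSE]
  meta <- annual[!is.na(annual$Latitude) & !is.na(annual$Longitude) &
                   !is.na(annual$Study_midyear), , drop = FALSE]
  yr <- floor(meta$Study_midyear)
  inrange <- meta[yr >= year_min & yr <= year_max, , drop = FALSE]

  if (nrow(inrange) > 0) {
    if (per_ecosystem) {
      grp <- ifelse(is.na(inrange$Ecosystem_type), "<unknown>",
                    inrange$Ecosystem_type)
      mu <- tapply(inrange$Rs_annual, grp, mean)
      sg <- tapply(inrange$Rs_annual, grp, stats::sd)
      sg[is.na(sg)] <- 0
      lo <- mu[grp] - sd_k * sg[grp]; hi <- mu[grp] + sd_k * sg[grp]
      keep <- sg[grp] == 0 | (inrange$Rs_annual >= lo & inrange$Rs_annual <= hi)
      bounds <- c(lower = NA_real_, upper = NA_real_)
    } else {
      mu <- mean(inrange$Rs_annual)
      sg <- stats::sd(inrange$Rs_annual)
      if (is.na(sg)) sg <- 0
      keep <- if (sg == 0) rep(TRUE, nrow(inrange)) else {
        abs(inrange$Rs_annual - mu) <= sd_k * sg
      }
      bounds <- c(lower = mu - sd_k * sg, upper = mu + sd_k * sg)
    }
    final <- inrange[keep, , drop = FALSE]
  } else {
    final <- inrange
    bounds <- c(lower = NA_real_, upper = NA_real_)
  }

  has_eco <- !is.na(final$Ecosystem_type)
  report <- structure(list(
    counts = c(raw = n_raw, annual = nrow(annual), metadata = nrow(meta),
               year_range = nrow(inrange), post_outlier = nrow(final)),
    n_sites = length(unique(final$Site_ID)),
    n_records_with_ecosystem = sum(has_eco),
    n_sites_with_ecosystem = length(unique(final$Site_ID[has_eco])),
    outlier_bounds = bounds, sd_k = sd_k,
    year_range = c(year_min, year_max), per_ecosystem = per_ecosystem
  ), class = "filter_report")
  if (any(diff(report$counts) > 0)) {
    stop("internal error: filter counts must be non-increasing", call. = FALSE)
  }
  list(records = final, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n  records: ",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " -> "),
      "\n", sep = "")
  cat(sprintf("  sites retained: %d (%d with known ecosystem)\n",
              x$n_sites, x$n_sites_with_ecosystem))
  if (!is.na(x$outlier_bounds[1])) {
    cat(sprintf("  outlier bounds (mean +/- %g SD): [%.2f, %.2f]\n",
                x$sd_k, x$outlier_bounds[1], x$outlier_bounds[2]))
  }
  invisible(x)
}

#' Site-blocked train/test split
#'
#' Assigns every record of a site to the same fold, with the share of a
#' class's sites in the training fold as close as achievable to
#' `train_frac`. An ecosystem with a single site sends it to train with a
#' warning. Fold assignment is a seeded shuffle.
#'
#' @param records filtered record table (`Site_ID`, `Ecosystem_type`).
#' @param train_frac target share of sites in the training fold.
#' @param per_ecosystem stratify the split within each ecosystem class.
#' @param seed integer seed.
#' @return character vector (`"train"`/`"test"`) aligned with `records`
#'   rows; attribute `site_folds` maps Site_ID to fold.
#' @export
site_blocked_split <- function(records, train_frac = 0.8,
                               per_ecosystem = TRUE, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot_fraction(train_frac, "train_frac")
  site_tbl <- unique(records[, c("Site_ID", "Ecosystem_type")])
  ## a site is assigned once, under its first-seen class
  site_tbl <- site_tbl[!duplicated(site_tbl$Site_ID), , drop = FALSE]
  groups <- if (per_ecosystem) {
    split(site_tbl$Site_ID, ifelse(is.na(site_tbl$Ecosystem_type), "<unknown>",
                                   site_tbl$Ecosystem_type))
  } else list(all = site_tbl$Site_ID)
  fold <- character(0)
  with_seed(seed, {
    for (g in names(groups)) {
      ids <- groups[[g]]
      if (length(ids) == 1) {
        warning(sprintf("ecosystem '%s' has a single site; assigned to train", g),
                call. = FALSE)
        fold[ids] <- "train"
        next
      }
      n_train <- round(train_frac * length(ids))
      n_train <- max(1L, min(length(ids) - 1L, n_train))
      shuffled <- sample(ids)
      fold[shuffled] <- c(rep("train", n_train),
                          rep("test", length(ids) - n_train))
    }
  })
  out <- unname(fold[records$Site_ID])
  attr(out, "site_folds") <- fold
  out
}
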