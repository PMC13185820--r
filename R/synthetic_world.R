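#' Candidate regression terms of the soil-respiration model
#'
#' The twelve non-constant candidate terms: each composite index and its
#' square, in fixed order. Coefficient vectors are length 13 (`beta0` first).
#' @export
RS_MODEL_TERMS <- c("Cli", "Cli2", "Plant", "Plant2", "Gra", "Gra2",
               "Mic", "Mic2", "Phy", "Phy2", "Chem", "Chem2")

ECO_NAMES <- c("bareland", "shrubland", "grassland", "cropland",
               "needleleaf forest", "broadleaf forest", "mixed forest",
               "wetland")

#' Default generative coefficients
#'
#' Per-ecosystem coefficients for the quadratic index model used to generate
#' true soil respiration. The support (which terms are nonzero) is shared
#' across ecosystems — vegetation dominant, climate secondary, modest soil
#' physical/chemical effects, no topographic or microbial effect — while the
#' magnitudes vary smoothly by ecosystem. Flux units g C m-2 yr-1 per unit
#' of (PC1) index.
#'
#' @param n_ecosystems number of ecosystem classes.
#' @return matrix n_ecosystems x 13, columns `beta0` then [RS_MODEL_TERMS].
#' @export
default_beta_true <- function(n_ecosystems = 8) {
  sc <- seq(0.9, 1.1, length.out = n_ecosystems)
  b <- matrix(0, n_ecosystems, 13,
              dimnames = list(NULL, c("beta0", RS_MODEL_TERMS)))
  ## magnitudes sized to the PC1 index scales so the deterministic flux
  ## stays positive over the realized index ranges (quadratics positive,
  ## vegetation dominant in the interannual signal)
  b[, "beta0"]  <- seq(700, 1300, length.out = n_ecosystems)
  b[, "Cli"]    <- 30 * sc
  b[, "Cli2"]   <- 4 * sc
  b[, "Plant"]  <- 120 * sc
  b[, "Plant2"] <- 10 * sc
  b[, "Phy"]    <- 35 * sc
  b[, "Chem"]   <- 45 * sc
  b
}

#' Configuration of the synthetic gridded world
#'
#' The generator emulates the study design the pipeline targets: 34 annual
#' steps (1985-2018 analogue), an aridity gradient across columns
#' (mean MAP/PET), an interannual temperature-variability gradient across
#' rows, vegetation driven by climate plus noise, and true soil respiration
#' produced by the quadratic composite-index model with known per-ecosystem
#' coefficients plus Gaussian noise (floored at zero).
#'
#' @param grid_rows,grid_cols grid dimensions (cells).
#' @param n_years number of annual steps (>= 12, so that at least three
#'   10-year windows exist).
#' @param year0 first year label.
#' @param n_ecosystems number of ecosystem classes (2..8).
#' @param aridity_gradient range of mean MAP/PET spanned by the columns.
#' @param temp_stability_gradient range of interannual temperature SD (deg C)
#'   spanned by the rows.
#' @param beta_true generative coefficient matrix ([default_beta_true]).
#' @param noise_sd absolute SD of the generative noise on soil respiration
#'   (flux units); if `NULL`, derived from `noise_frac`.
#' @param noise_frac noise SD as a fraction of the SD of the deterministic
#'   soil-respiration signal (used when `noise_sd` is `NULL`).
#' @param coupling_mode `"coupled"` (soil respiration responds to the
#'   vegetation index) or `"decoupled"` (the vegetation term is replaced by
#'   an independent random series before generation, so belowground
#'   stability is statistically independent of vegetation stability).
#' @param seed integer seed; mandatory.
#' @return a `world_config` list.
#' @export
world_config <- function(grid_rows = 30, grid_cols = 30, n_years = 34,
                         year0 = 1985, n_ecosystems = 8,
                         aridity_gradient = c(0.05, 1.5),
                         temp_stability_gradient = c(0.3, 2.0),
                         beta_true = NULL, noise_sd = NULL, noise_frac = 0.1,
                         coupling_mode = c("coupled", "decoupled"),
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory in world_config()", call. = FALSE)
  coupling_mode <- match.arg(coupling_mode)
  if (grid_rows < 1 || grid_cols < 1) stop("non-positive grid dimensions", call. = FALSE)
  if (n_years < 12) {
    stop("n_years must be >= 12 (at least three 10-year windows)", call. = FALSE)
  }
  if (n_ecosystems < 2 || n_ecosystems > 8) {
    stop("n_ecosystems must be in 2..8", call. = FALSE)
  }
  if (any(temp_stability_gradient <= 0)) stop("temperature SDs must be > 0", call. = FALSE)
  if (any(aridity_gradient <= 0)) stop("aridity gradient must be > 0", call. = FALSE)
  beta_true <- beta_true %||% default_beta_true(n_ecosystems)
  stopifnot(is.matrix(beta_true), nrow(beta_true) == n_ecosystems,
            ncol(beta_true) == 13)
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    n_years = as.integer(n_years), year0 = as.integer(year0),
    n_ecosystems = as.integer(n_ecosystems),
    aridity_gradient = aridity_gradient,
    temp_stability_gradient = temp_stability_gradient,
    beta_true = beta_true, noise_sd = noise_sd, noise_frac = noise_frac,
    coupling_mode = coupling_mode, seed = as.integer(seed)
  ), class = "world_config")
}

rnorm3 <- function(dim, sd = 1) array(stats::rnorm(prod(dim), 0, sd), dim = dim)

#' Generate a synthetic gridded world
#'
#' Produces climate, vegetation, static soil, topography and ecosystem
#' fields on a (row, col, year) grid, computes the six composite PC1 indices
#' from them, and generates true annual soil respiration from the quadratic
#' index model with the configured per-ecosystem coefficients plus Gaussian
#' noise truncated at zero. Identical configuration (including seed) yields a
#' bit-identical world.
#'
#' @param config a [world_config()].
#' @return a `synthetic_world` list: `$climate`, `$vegetation` (lists of
#'   [annual_stack]s), `$soil`, `$topo` (lists of matrices), `$ecosystem`
#'   (integer matrix with `eco_names`), `$rs_true` ([annual_stack]),
#'   `$indices` (the generative [composite_indices()] set), `$beta_true`,
#'   `$noise_sd`, `$geo` (pseudo lat/lon mapping), `$config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  nr <- config$grid_rows; nc <- config$grid_cols; ny <- config$n_years
  years <- config$year0 + seq_len(ny) - 1L
  dim3 <- c(nr, nc, ny)

  world <- with_seed(config$seed, {
    ## --- climate ----------------------------------------------------------
    mat_base <- matrix(seq(24, -4, length.out = nr), nr, nc) +
      matrix(stats::rnorm(nr * nc, 0, 0.8), nr, nc)
    tsd_row <- seq(config$temp_stability_gradient[1],
                   config$temp_stability_gradient[2], length.out = nr)
    ai_col <- seq(config$aridity_gradient[1], config$aridity_gradient[2],
                  length.out = nc)
    MAT <- array(0, dim3)
    for (t in seq_len(ny)) {
      MAT[, , t] <- mat_base + matrix(stats::rnorm(nr * nc, 0, tsd_row),
                                      nr, nc, byrow = FALSE)
    }
    Tmax <- MAT + 8 + abs(rnorm3(dim3, 0.5))
    Tmin <- MAT - 8 - abs(rnorm3(dim3, 0.5))
    PET <- pmax(650 + 45 * MAT + rnorm3(dim3, 25), 150)
    ai_target <- array(rep(ai_col, each = nr), dim3)
    MAP <- ai_target * PET * exp(rnorm3(dim3, 0.15))
    AET <- pmin(0.9 * MAP, PET)
    RAD <- 170 + 3.5 * MAT + rnorm3(dim3, 8)
    AI_t <- MAP / PET

    ## --- vegetation (climate-driven + lognormal noise) --------------------
    NPP <- 1300 * (AI_t / (AI_t + 0.4)) *
      exp(-(MAT - 18)^2 / (2 * 10^2)) * exp(rnorm3(dim3, 0.12))
    CUE <- pmin(pmax(0.45 + rnorm3(dim3, 0.02), 0.25), 0.65)
    GPP <- NPP / CUE
    LAI <- 6.5 * NPP / (NPP + 450) * exp(rnorm3(dim3, 0.05))
    FVC <- 1 - exp(-0.55 * LAI)

    ## --- ecosystem map: a balanced seeded mosaic --------------------------
    ## Classes are interleaved across the whole grid rather than carved out
    ## of climate space: biome types overlap broadly along real climate
    ## gradients, and a mosaic keeps every per-class regression identifiable
    ## (each class samples the full index range). Geography is a non-goal.
    eco <- matrix(sample(rep_len(seq_len(config$n_ecosystems), nr * nc)),
                  nr, nc)
    if (length(unique(as.vector(eco))) < 2) {
      stop("degenerate world: fewer than 2 ecosystem classes represented",
           call. = FALSE)
    }

    ## --- static soil fields: ecosystem means + cell noise -----------------
    e <- as.vector(eco)
    cellfield <- function(mu_by_eco, sd, lower = -Inf) {
      matrix(pmax(lower, mu_by_eco[e] + stats::rnorm(nr * nc, 0, sd)), nr, nc)
    }
    ## within-class cell noise is comparable to the between-class spread:
    ## soil properties vary enormously within a biome, and the per-class
    ## regressions must be able to see the soil indices move
    ne <- config$n_ecosystems
    SOC <- cellfield(seq(35, 85, length.out = ne), 20, lower = 1)
    TN <- pmax(0.05, SOC / (12 + stats::rnorm(nr * nc, 0, 1.6)))
    CN <- SOC / TN
    sand_mu <- seq(55, 40, length.out = ne)
    clay_mu <- seq(18, 30, length.out = ne)
    sand_r <- pmax(1, sand_mu[e] + stats::rnorm(nr * nc, 0, 11))
    clay_r <- pmax(1, clay_mu[e] + stats::rnorm(nr * nc, 0, 8))
    silt_r <- pmax(1, 100 - sand_r - clay_r + stats::rnorm(nr * nc, 0, 5))
    tot <- sand_r + silt_r + clay_r
    SAND <- matrix(100 * sand_r / tot, nr, nc)
    SILT <- matrix(100 * silt_r / tot, nr, nc)
    CLAY <- matrix(100 * clay_r / tot, nr, nc)
    BD  <- cellfield(seq(1.45, 1.15, length.out = ne), 0.12, lower = 0.6)
    VWC <- cellfield(seq(0.15, 0.30, length.out = ne), 0.07, lower = 0.01)
    PH  <- cellfield(seq(7.6, 5.8, length.out = ne), 0.6, lower = 3.5)
    CEC <- cellfield(seq(14, 26, length.out = ne), 5, lower = 1)
    MBC <- cellfield(seq(300, 700, length.out = ne), 160, lower = 5)
    MBN <- pmax(1, MBC / (8 + stats::rnorm(nr * nc, 0, 1)))
    MBP <- pmax(0.2, MBC / (30 + stats::rnorm(nr * nc, 0, 4)))

    ## --- topography -------------------------------------------------------
    ELEV <- matrix(300 + 25 * rev(seq_len(nr)) + stats::rnorm(nr * nc, 0, 60),
                   nr, nc)
    SLOPE <- matrix(abs(stats::rnorm(nr * nc, 5, 3)), nr, nc)
    ASPECT <- matrix(stats::runif(nr * nc, 0, 360), nr, nc)

    st <- function(x, u, v) annual_stack(x, years, units = u, varname = v)
    list(
      climate = list(
        MAT = st(MAT, "deg C", "MAT"), Tmax = st(Tmax, "deg C", "Tmax"),
        Tmin = st(Tmin, "deg C", "Tmin"), MAP = st(MAP, "mm", "MAP"),
        RAD = st(RAD, "W m-2", "RAD"), AET = st(AET, "mm", "AET"),
        PET = st(PET, "mm", "PET")
      ),
      vegetation = list(
        NPP = st(NPP, "g C m-2 yr-1", "NPP"),
        LAI = st(LAI, "m2 m-2", "LAI"),
        FVC = st(FVC, "fraction", "FVC"),
        GPP = st(GPP, "g C m-2 yr-1", "GPP"),
        CUE = st(CUE, "fraction", "CUE"),
        WUE = st(NPP / pmax(AET, 1), "g C m-2 mm-1", "WUE")
      ),
      soil = list(SOC = SOC, TN = TN, CN = CN, sand = SAND, silt = SILT,
                  clay = CLAY, bulk_density = BD, VWC = VWC, pH = PH,
                  CEC = CEC, MBC = MBC, MBN = MBN, MBP = MBP),
      topo = list(elevation = ELEV, slope = SLOPE, aspect = ASPECT),
      ecosystem = eco
    )
  })

  world$eco_names <- ECO_NAMES[seq_len(config$n_ecosystems)]
  world$years <- years
  ## 0.2 deg per fine cell: a 5x5 block is one 1-degree coarse cell
  world$geo <- list(cell_deg = 0.2,
                    lat = (seq_len(nr) - 0.5) * 0.2,
                    lon = (seq_len(nc) - 0.5) * 0.2)
  world$config <- config
  class(world) <- "synthetic_world"

  ## --- composite indices, then true Rs from the generative model ----------
  world$indices <- composite_indices(world)
  idx <- world$indices
  plant_for_rs <- unclass(idx$Plant)
  if (config$coupling_mode == "decoupled") {
    plant_for_rs <- with_seed(stage_seed(config$seed, "decouple"), {
      array(stats::rnorm(prod(dim3), 0, stats::sd(idx$Plant)), dim3)
    })
  }
  eta <- array(0, dim3)
  for (ecls in seq_len(config$n_ecosystems)) {
    cells <- which(world$ecosystem == ecls)
    if (!length(cells)) next
    b <- config$beta_true[ecls, ]
    for (t in seq_len(ny)) {
      off <- (t - 1L) * nr * nc
      cli <- unclass(idx$Cli)[, , t][cells]
      pla <- plant_for_rs[, , t][cells]
      gra <- idx$Gra[cells]; mic <- idx$Mic[cells]
      phy <- idx$Phy[cells]; chem <- idx$Chem[cells]
      eta[cells + off] <-
        b["beta0"] + b["Cli"] * cli + b["Cli2"] * cli^2 +
        b["Plant"] * pla + b["Plant2"] * pla^2 +
        b["Gra"] * gra + b["Gra2"] * gra^2 +
        b["Mic"] * mic + b["Mic2"] * mic^2 +
        b["Phy"] * phy + b["Phy2"] * phy^2 +
        b["Chem"] * chem + b["Chem2"] * chem^2
    }
  }
  noise_sd <- config$noise_sd %||% (config$noise_frac * stats::sd(eta))
  rs <- with_seed(stage_seed(config$seed, "rs_noise"), {
    pmax(eta + rnorm3(dim3, noise_sd), 0)
  })
  world$rs_true <- annual_stack(rs, years, units = "g C m-2 yr-1",
                                varname = "Rs")
  world$rs_deterministic <- annual_stack(eta, years, units = "g C m-2 yr-1",
                                         varname = "Rs_det")
  world$beta_true <- config$beta_true
  world$noise_sd <- noise_sd
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d x %d cells, %d years (%d-%d), %d ecosystems, %s\n",
              x$config$grid_rows, x$config$grid_cols, x$config$n_years,
              min(x$years), max(x$years),
              length(unique(as.vector(x$ecosystem))), x$config$coupling_mode))
  invisible(x)
}

#' Sample site-year records from a synthetic world
#'
#' Emulates a community soil-respiration database: each site is pinned to one
#' grid cell with a unique Site ID; site-years are drawn without replacement;
#' a fraction of records get a blanked coordinate or year (to exercise the
#' metadata filters); a fraction are pushed beyond +/- 3 SD of the record
#' mean (to exercise the outlier rule). Observed values are the world's true
#' soil respiration plus optional site-level and record-level noise.
#'
#' @param world a [generate_world()] result.
#' @param n_sites number of sites (<= number of cells).
#' @param max_years_per_site per site, years are drawn uniformly in
#'   1..`max_years_per_site` then sampled without replacement.
#' @param missing_frac fraction of records with a blanked latitude,
#'   longitude, or measurement year.
#' @param outlier_frac fraction of records replaced by values beyond
#'   +/- 3 SD of the (pre-injection) record mean.
#' @param obs_noise_sd record-level observation noise SD (flux units).
#' @param site_effect_sd SD of a per-site random intercept (flux units);
#'   creates site-level dependence for leakage studies.
#' @param seed integer seed.
#' @return data.frame with SRDB-compatible columns (`Site_ID`, `Latitude`,
#'   `Longitude`, `Study_midyear`, `Rs_annual`, `Ecosystem_type`) plus
#'   provenance columns (`row`, `col`, `year`, `injected_missing`,
#'   `injected_outlier`).
#' @export
sample_sites <- function(world, n_sites, max_years_per_site = 10,
                         missing_frac = 0, outlier_frac = 0,
                         obs_noise_sd = 0, site_effect_sd = 0, seed) {
  stopifnot(inherits(world, "synthetic_world"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot_fraction(missing_frac, "missing_frac")
  stopifnot_fraction(outlier_frac, "outlier_frac")
  nr <- world$config$grid_rows; nc <- world$config$grid_cols
  ny <- world$config$n_years
  if (n_sites > nr * nc) stop("n_sites exceeds the number of cells", call. = FALSE)

  with_seed(seed, {
    cells <- sample.int(nr * nc, n_sites)
    rows <- ((cells - 1L) %% nr) + 1L
    cols <- ((cells - 1L) %/% nr) + 1L
    site_eff <- stats::rnorm(n_sites, 0, site_effect_sd)
    rec <- vector("list", n_sites)
    for (i in seq_len(n_sites)) {
      k <- sample.int(max_years_per_site, 1)
      yrs_idx <- sort(sample.int(ny, min(k, ny)))
      rs <- unclass(world$rs_true)[rows[i], cols[i], yrs_idx] + site_eff[i] +
        stats::rnorm(length(yrs_idx), 0, obs_noise_sd)
      rec[[i]] <- data.frame(
        Site_ID = sprintf("S%05d", i),
        Latitude = world$geo$lat[rows[i]],
        Longitude = world$geo$lon[cols[i]],
        Study_midyear = world$years[yrs_idx] + 0.5,
        Rs_annual = rs,
        Ecosystem_type = world$eco_names[world$ecosystem[rows[i], cols[i]]],
        row = rows[i], col = cols[i], year = world$years[yrs_idx]
      )
    }
    out <- do.call(rbind, rec)
    rownames(out) <- NULL
    n <- nrow(out)
    out$injected_missing <- FALSE
    out$injected_outlier <- FALSE

    n_miss <- round(missing_frac * n)
    if (n_miss > 0) {
      miss_rows <- sample.int(n, n_miss)
      fields <- rep(c("Latitude", "Longitude", "Study_midyear"),
                    length.out = n_miss)
      for (j in seq_len(n_miss)) out[miss_rows[j], fields[j]] <- NA
      out$injected_missing[miss_rows] <- TRUE
    }
    n_out <- round(outlier_frac * n)
    if (n_out > 0) {
      cand <- which(!out$injected_missing)
      out_rows <- sample(cand, min(n_out, length(cand)))
      m <- mean(out$Rs_annual, na.rm = TRUE)
      s <- stats::sd(out$Rs_annual, na.rm = TRUE)
      sgn <- sample(c(-1, 1), length(out_rows), replace = TRUE)
      out$Rs_annual[out_rows] <- m + sgn * stats::runif(length(out_rows), 4, 6) * s
      out$injected_outlier[out_rows] <- TRUE
    }
    out
  })
}
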