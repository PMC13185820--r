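# Shared fixtures, built in code. Worlds are cached per configuration so the
# suite does not regenerate them test by test.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(seed, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(world_config(seed = seed, ...))
  }
  .world_cache[[key]]
}

# A design table drawn directly from a known coefficient vector: the
# independent generative oracle for the regression fitter (no world, no PCA).
make_design <- function(n, beta, noise_sd, seed, eco = "grassland",
                        index_sd = c(Cli = 2, Plant = 1.5, Gra = 1, Mic = 1,
                                     Phy = 1.2, Chem = 1)) {
  set.seed(seed)
  d <- data.frame(
    Site_ID = sprintf("S%04d", seq_len(n)),
    Ecosystem_type = eco,
    Cli = rnorm(n, 0, index_sd["Cli"]),
    Plant = rnorm(n, 0, index_sd["Plant"]),
    Gra = rnorm(n, 0, index_sd["Gra"]),
    Mic = rnorm(n, 0, index_sd["Mic"]),
    Phy = rnorm(n, 0, index_sd["Phy"]),
    Chem = rnorm(n, 0, index_sd["Chem"])
  )
  d2 <- add_quadratic_terms(d)
  X <- as.matrix(cbind(1, d2[, RS_MODEL_TERMS]))
  d$Rs <- as.vector(X %*% beta) + rnorm(n, 0, noise_sd)
  d
}

beta_named <- function(...) {
  b <- stats::setNames(numeric(13), c("beta0", RS_MODEL_TERMS))
  args <- list(...)
  b[names(args)] <- unlist(args)
  b
}

# SRDB-format CSV fixture: 12 tight "good" annual records, one seasonal-only,
# one missing year, one dated before the window, one extreme value.
# Hand-derived chain: 16 -> 15 (annual) -> 14 (metadata) -> 13 (year range)
# -> 12 (outlier).
write_srdb_fixture <- function(path) {
  good <- data.frame(
    Site_ID = sprintf("G%02d", 1:12), Latitude = 40 + (1:12) / 10,
    Longitude = -100 + (1:12) / 10, Study_midyear = 1990.5 + (1:12 %% 5),
    Rs_annual = seq(480, 535, length.out = 12),
    Ecosystem_type = rep(c("grassland", "cropland"), 6)
  )
  bad <- data.frame(
    Site_ID = c("B1", "B2", "B3", "B4"),
    Latitude = c(10, 11, 12, 13),
    Longitude = c(20, 21, 22, 23),
    Study_midyear = c(1995.5, NA, 1980.5, 2000.5),
    Rs_annual = c(NA, 500, 510, 50000),  # seasonal-only, ok, ok, extreme
    Ecosystem_type = "grassland"
  )
  utils::write.csv(rbind(good, bad), path, row.names = FALSE)
  path
}

# Minimal composite_indices stand-in with constant index fields, for
# prediction tests that need full control over the index values.
flat_indices <- function(nr, nc, ny, years = 2000 + seq_len(ny) - 1,
                         cli = 0, plant = 0, gra = 0, mic = 0, phy = 0,
                         chem = 0) {
  st <- function(v) annual_stack(array(v, c(nr, nc, ny)), years)
  structure(list(Cli = st(cli), Plant = st(plant),
                 Gra = matrix(gra, nr, nc), Mic = matrix(mic, nr, nc),
                 Phy = matrix(phy, nr, nc), Chem = matrix(chem, nr, nc),
                 loadings = list(), var_explained = numeric(0),
                 standardization = list()),
            class = "composite_indices")
}

# Linear-Gaussian path-model generator: temp/precip/ai exogenous ->
# productivity -> soil-respiration stability, with direct climate paths.
# The generative oracle for the SEM recovery checks.
gen_path_data <- function(n, b_tp, b_pp, b_ap, b_pr, b_tr, b_prr, b_ar, seed) {
  set.seed(seed)
  temp_stab <- rnorm(n); precip_stab <- rnorm(n); ai_stab <- rnorm(n)
  prod_pc1 <- b_tp * temp_stab + b_pp * precip_stab + b_ap * ai_stab +
    rnorm(n, 0, sqrt(max(1 - b_tp^2 - b_pp^2 - b_ap^2, 0.05)))
  rs_stab <- b_pr * prod_pc1 + b_tr * temp_stab + b_prr * precip_stab +
    b_ar * ai_stab + rnorm(n, 0, 0.5)
  data.frame(temp_stab = temp_stab, precip_stab = precip_stab,
             ai_stab = ai_stab, prod_pc1 = prod_pc1, rs_stab = rs_stab)
}

# Hand-built fit set (bypasses stepwise) for prediction-side unit tests.
manual_fit_set <- function(betas) {
  fits <- lapply(betas, function(b) {
    list(beta = b, selected = stats::setNames(b[RS_MODEL_TERMS] != 0, RS_MODEL_TERMS),
         residual_sd = 0, n_train = NA_integer_, r_squared = NA_real_)
  })
  structure(list(fits = fits,
                 selection = list(criterion = "manual", direction = "none")),
            class = "regression_fit_set")
}
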