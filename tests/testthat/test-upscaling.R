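test_that("stepwise fit recovers a sparse generative model", {
  b <- beta_named(beta0 = 2, Cli = 3, Plant2 = -1)
  d <- make_design(500, b, noise_sd = 0.01, seed = 21)
  fits <- fit_rs_model(d)
  f <- fits$fits[["grassland"]]
  expect_setequal(names(which(f$selected)), c("Cli", "Plant2"))
  expect_equal(unname(f$beta["beta0"]), 2, tolerance = 0.05)
  expect_equal(unname(f$beta["Cli"]), 3, tolerance = 0.05)
  expect_equal(unname(f$beta["Plant2"]), -1, tolerance = 0.05)
  expect_true(all(f$beta[setdiff(RS_MODEL_TERMS, c("Cli", "Plant2"))] == 0))
})

test_that("a pure-noise response retains only the intercept almost always", {
  hits <- 0
  for (k in 1:50) {
    d <- make_design(300, beta_named(beta0 = 5), noise_sd = 1, seed = 700 + k)
    f <- fit_rs_model(d)$fits[["grassland"]]
    if (!any(f$selected)) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)
})

test_that("a noiseless fully-dense model is recovered to numerical precision", {
  b <- beta_named(beta0 = 10, Cli = 2, Cli2 = -0.5, Plant = 3, Plant2 = 0.8,
                  Gra = -1.2, Gra2 = 0.3, Mic = 0.9, Mic2 = -0.4, Phy = 1.5,
                  Phy2 = 0.25, Chem = -2, Chem2 = 0.6)
  d <- make_design(400, b, noise_sd = 0, seed = 5)
  f <- suppressWarnings(fit_rs_model(d))$fits[["grassland"]]  # exact-fit warnings
  expect_true(all(f$selected))
  expect_equal(unname(f$beta), unname(b), tolerance = 1e-6)
})

test_that("underpopulated classes are skipped with a warning", {
  d <- make_design(100, beta_named(beta0 = 1, Cli = 2), noise_sd = 0.1,
                   seed = 3)
  d$Ecosystem_type[1:5] <- "wetland"
  d$Ecosystem_type[6:100] <- "grassland"
  expect_warning(fits <- fit_rs_model(d), "wetland")
  expect_null(fits$fits[["wetland"]])
  expect_false(is.null(fits$fits[["grassland"]]))
})

test_that("grid prediction returns beta0 for all-zero indices and is local", {
  betas <- list(grassland = beta_named(beta0 = 400, Cli = 10),
                wetland = beta_named(beta0 = 900, Plant = 5))
  fits <- manual_fit_set(betas)
  eco <- matrix(1L, 4, 4); eco[2, 3] <- 2L
  idx <- flat_indices(4, 4, 3)
  p <- predict_grid(fits, idx, eco, c("grassland", "wetland"))
  expect_equal(unclass(p)[1, 1, ], rep(400, 3))
  expect_equal(unclass(p)[2, 3, ], rep(900, 3))
  # changing one cell's class changes only that cell
  eco2 <- eco; eco2[4, 4] <- 2L
  p2 <- predict_grid(fits, idx, eco2, c("grassland", "wetland"))
  diff_cells <- which(unclass(p) != unclass(p2), arr.ind = TRUE)
  expect_true(all(diff_cells[, 1] == 4 & diff_cells[, 2] == 4))
  # unmapped class without fallback errors; with fallback it predicts
  eco3 <- eco; eco3[1, 1] <- 2L
  fits1 <- manual_fit_set(betas["grassland"])
  expect_error(predict_grid(fits1, idx, eco3, c("grassland", "wetland")),
               "no fit")
  p3 <- predict_grid(fits1, idx, eco3, c("grassland", "wetland"),
                     fallback = "grassland")
  expect_equal(unclass(p3)[2, 3, 1], 400)
})

test_that("negative predictions are floored at zero and counted", {
  fits <- manual_fit_set(list(grassland = beta_named(beta0 = -50)))
  idx <- flat_indices(2, 2, 2)
  p <- predict_grid(fits, idx, matrix(1L, 2, 2), "grassland")
  expect_true(all(unclass(p) == 0))
  expect_equal(attr(p, "n_floored"), 8)
})

test_that("validation metrics behave in exact and degenerate cases", {
  b <- beta_named(beta0 = 50, Cli = 2)   # flux stays positive: no flooring
  d <- make_design(60, b, noise_sd = 0, seed = 11)
  folds <- rep(c("train", "test"), 30)
  fits <- manual_fit_set(list(grassland = b))
  v <- validate(fits, d, folds)
  expect_equal(unname(v$overall["R"]), 1)
  expect_equal(unname(v$overall["MAE"]), 0)
  expect_equal(unname(v$overall["RMSE"]), 0)
  # constant prediction: R undefined (NA), MAE = mean|y - c|
  fits_c <- manual_fit_set(list(grassland = beta_named(beta0 = 4)))
  vc <- validate(fits_c, d, folds)
  expect_true(is.na(vc$overall["R"]))
  expect_equal(unname(vc$overall["MAE"]),
               mean(abs(d$Rs[folds == "test"] - 4)))
  expect_gte(vc$overall[["RMSE"]], vc$overall[["MAE"]])
  expect_error(validate(fits, d, rep("train", 60)), "empty test fold")
})

test_that("held-out RMSE approximates the generative noise level", {
  w <- cached_world(302, grid_rows = 25, grid_cols = 25)
  s <- sample_sites(w, 250, max_years_per_site = 8, seed = 61)
  d <- extract_at_sites(w$indices, s, w$geo)
  folds <- suppressWarnings(site_blocked_split(d, seed = 62))
  fits <- suppressWarnings(fit_rs_model(d[folds == "train", ], min_n = 16))
  v <- validate(fits, d, folds, fallback = names(fits$fits)[1])
  expect_lt(abs(v$overall[["RMSE"]] - w$noise_sd) / w$noise_sd, 0.2)
})

test_that("the vegetation guard rejects tainted features by name", {
  d <- make_design(50, beta_named(beta0 = 1), noise_sd = 1, seed = 9)
  for (bad in list(c("Cli", "NPP"), c("Plant"), c("Cli", "LAI_ma3"),
                   c("GPP", "Phy"))) {
    expect_error(fit_rf_novegetation(d, features = bad, seed = 1),
                 "vegetation-tainted")
  }
  expect_error(fit_rf_novegetation(d, features = c("Cli", "nope"), seed = 1),
               "missing feature")
})

test_that("the vegetation-free forest is seeded and collapses under shuffling", {
  w <- cached_world(301, grid_rows = 12, grid_cols = 12)
  s <- sample_sites(w, 120, max_years_per_site = 6, seed = 71)
  d <- extract_at_sites(w$indices, s, w$geo)
  m1 <- fit_rf_novegetation(d, n_trees = 150, seed = 5)
  m2 <- fit_rf_novegetation(d, n_trees = 150, seed = 5)
  expect_identical(m1$metrics, m2$metrics)
  expect_gt(m1$metrics[["R"]], 0.5)
  set.seed(81)
  d2 <- d; d2$Rs <- sample(d2$Rs)
  m3 <- fit_rf_novegetation(d2, n_trees = 150, seed = 5)
  expect_lt(abs(m3$metrics[["R"]]), 0.1)
})
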