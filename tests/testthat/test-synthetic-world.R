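test_that("identical configs yield bit-identical worlds and site tables", {
  w1 <- generate_world(world_config(seed = 1, grid_rows = 8, grid_cols = 8,
                                    n_years = 14))
  w2 <- generate_world(world_config(seed = 1, grid_rows = 8, grid_cols = 8,
                                    n_years = 14))
  expect_identical(unclass(w1$rs_true), unclass(w2$rs_true))
  expect_identical(w1$soil, w2$soil)
  expect_identical(unclass(w1$climate$MAP), unclass(w2$climate$MAP))
  expect_identical(w1$ecosystem, w2$ecosystem)
  s1 <- sample_sites(w1, 20, seed = 9)
  s2 <- sample_sites(w2, 20, seed = 9)
  expect_identical(s1, s2)
})

test_that("world invariants hold", {
  w <- cached_world(301, grid_rows = 12, grid_cols = 12)
  expect_true(all(unclass(w$climate$PET) >= unclass(w$climate$AET)))
  expect_true(all(unclass(w$climate$AET) >= 0))
  fvc <- unclass(w$vegetation$FVC)
  expect_true(all(fvc >= 0 & fvc <= 1))
  tex <- w$soil$sand + w$soil$silt + w$soil$clay
  expect_true(all(abs(tex - 100) < 0.5))
  expect_true(all(unclass(w$vegetation$GPP) >= unclass(w$vegetation$NPP)))
  expect_true(all(unclass(w$vegetation$NPP) >= 0))
  expect_true(all(unclass(w$rs_true) >= 0))
  expect_gte(length(unique(as.vector(w$ecosystem))), 2)
})

test_that("config validation rejects impossible worlds", {
  expect_error(world_config(seed = 1, grid_rows = 0), "grid")
  expect_error(world_config(seed = 1, n_years = 10), "n_years")
  expect_error(world_config(seed = 1, temp_stability_gradient = c(0, 1)),
               "SD")
  expect_error(world_config(seed = 1, n_ecosystems = 1), "n_ecosystems")
  expect_error(world_config(), "seed")
})

test_that("a noiseless world is exactly recovered by OLS on exhaustive cells", {
  w <- generate_world(world_config(seed = 77, grid_rows = 10, grid_cols = 10,
                                   n_years = 16, noise_sd = 0))
  idx <- w$indices
  e_target <- 2
  cells <- which(w$ecosystem == e_target)
  rows <- ((cells - 1) %% 10) + 1; cols <- ((cells - 1) %/% 10) + 1
  d <- do.call(rbind, lapply(seq_along(cells), function(i) {
    data.frame(Rs = unclass(w$rs_true)[rows[i], cols[i], ],
               Cli = unclass(idx$Cli)[rows[i], cols[i], ],
               Plant = unclass(idx$Plant)[rows[i], cols[i], ],
               Gra = idx$Gra[cells[i]], Mic = idx$Mic[cells[i]],
               Phy = idx$Phy[cells[i]], Chem = idx$Chem[cells[i]])
  }))
  d <- add_quadratic_terms(d)
  fit <- lm(as.formula(paste("Rs ~", paste(RS_MODEL_TERMS, collapse = "+"))),
            data = d)
  est <- coef(fit); est[is.na(est)] <- 0
  truth <- w$beta_true[e_target, ]
  expect_equal(unname(est["(Intercept)"]), unname(truth["beta0"]),
               tolerance = 1e-6)
  expect_equal(unname(est[RS_MODEL_TERMS]), unname(truth[RS_MODEL_TERMS]),
               tolerance = 1e-6)
})

test_that("site sampling respects counts, ids, and injection fractions", {
  w <- cached_world(301, grid_rows = 12, grid_cols = 12)
  s <- sample_sites(w, n_sites = 100, max_years_per_site = 5, seed = 4)
  expect_lte(nrow(s), 500)
  expect_equal(length(unique(s$Site_ID)), 100)
  # no injections: everything survives the filter chain
  f <- filter_records(s, year_min = min(w$years), year_max = max(w$years))
  expect_equal(unname(f$report$counts["post_outlier"]),
               unname(f$report$counts["raw"]))
  expect_error(sample_sites(w, 12 * 12 + 1, seed = 1), "n_sites")
  expect_error(sample_sites(w, 10, missing_frac = 1.2, seed = 1),
               "missing_frac")
})

test_that("injected outliers are flagged by the 3 SD rule", {
  w <- cached_world(302, grid_rows = 25, grid_cols = 25)
  s <- sample_sites(w, n_sites = 220, max_years_per_site = 9,
                    outlier_frac = 0.02, seed = 13)
  n_inj <- sum(s$injected_outlier)
  expect_equal(n_inj, round(0.02 * nrow(s)))
  f <- filter_records(s, year_min = min(w$years), year_max = max(w$years))
  removed <- setdiff(seq_len(nrow(s)),
                     as.integer(rownames(f$records)))
  flagged_injected <- sum(s$injected_outlier[removed])
  expect_gte(flagged_injected, 0.9 * n_inj)     # nearly all injected caught
  expect_lte(length(removed), n_inj + 0.005 * nrow(s))  # few innocents
})

test_that("coupled and decoupled worlds separate in windowed coupling", {
  r_mean <- function(seed, mode) {
    w <- generate_world(world_config(seed = seed, grid_rows = 12,
                                     grid_cols = 12, n_years = 24,
                                     coupling_mode = mode))
    cm <- windowed_coupling(moving_window_stability(w$rs_true, 10),
                            moving_window_stability(w$vegetation$NPP, 10))
    mean(cm$r[is.finite(cm$r)])
  }
  coupled <- vapply(1:10, r_mean, 1, mode = "coupled")
  decoupled <- vapply(11:20, r_mean, 1, mode = "decoupled")
  tt <- t.test(coupled, decoupled, alternative = "greater")
  expect_lt(tt$p.value, 1e-4)
  expect_true(all(coupled > 0))
  expect_lt(abs(mean(decoupled)), 0.1)
})
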