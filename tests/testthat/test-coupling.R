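mk_map <- function(m) structure(m, class = c("stability_map", "matrix"))

test_that("the critical correlation matches the t-distribution closed form", {
  expect_equal(r_critical(25), 0.396, tolerance = 5e-4)
  tc <- qt(0.975, 23)
  expect_equal(r_critical(25), tc / sqrt(tc^2 + 23), tolerance = 1e-12)
  expect_error(r_critical(2), "n >= 3")
})

test_that("proportional window series give perfect coupling everywhere", {
  set.seed(14)
  maps <- array(rnorm(6 * 6 * 12, 5, 1), c(6, 6, 12))
  wsA <- structure(list(maps = maps,
                        windows = data.frame(start = 1:12, end = 10:21),
                        window = 10, varname = "A"),
                   class = "window_stability")
  wsB <- wsA; wsB$maps <- 2 * maps; wsB$varname <- "B"
  cm <- windowed_coupling(wsA, wsB)
  expect_true(all(abs(cm$r - 1) < 1e-12))
  expect_true(all(cm$sig))
  # symmetry
  cm_ba <- windowed_coupling(wsB, wsA)
  expect_equal(cm$r, cm_ba$r)
})

test_that("coupling masks cells with undefined windows and checks inputs", {
  set.seed(15)
  maps <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  maps2 <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  maps[2, 2, 4] <- NA
  ws <- function(m) structure(list(maps = m, windows = NULL, window = 5,
                                   varname = "x"), class = "window_stability")
  cm <- windowed_coupling(ws(maps), ws(maps2))
  expect_true(is.na(cm$r[2, 2]))
  expect_false(cm$sig[2, 2])
  expect_true(all(is.finite(cm$r[-5])))  # cell (2,2) is linear index 5
  short <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  expect_error(windowed_coupling(ws(short), ws(short)), ">= 3 windows")
  expect_error(windowed_coupling(ws(maps), ws(maps2[, , 1:5])), "differ")
})

test_that("windowed correlation has high power at generative rho = 0.8", {
  set.seed(16)
  n_cell <- 400; k <- 25
  a <- matrix(rnorm(n_cell * k), n_cell, k)
  b <- 0.8 * a + sqrt(1 - 0.8^2) * matrix(rnorm(n_cell * k), n_cell, k)
  ws <- function(m) structure(list(maps = array(m, c(20, 20, k)),
                                   windows = NULL, window = 10, varname = "x"),
                              class = "window_stability")
  cm <- windowed_coupling(ws(a), ws(b))
  expect_gte(mean(cm$sig), 0.8)
})

test_that("bivariate classification covers the stated corner cases", {
  set.seed(17)
  a <- mk_map(matrix(runif(200 * 200), 200, 200))
  b <- mk_map(matrix(runif(200 * 200), 200, 200))
  bc <- bivariate_class_map(a, b)
  frac_hh <- mean(bc$class == "high-high")
  expect_gt(frac_hh, 0.005); expect_lt(frac_hh, 0.016)  # ~ 1% in expectation
  counts <- table(factor(as.vector(bc$class), levels = bc$levels))
  expect_equal(sum(counts), 200 * 200)
  # identity: only concordant corners and intermediate occur
  bi <- bivariate_class_map(a, a)
  expect_setequal(unique(as.vector(bi$class)),
                  c("low-low", "high-high", "intermediate"))
  # degenerate all-equal maps resolve to intermediate
  flat <- mk_map(matrix(1, 4, 4))
  bf <- bivariate_class_map(flat, flat)
  expect_true(all(bf$class == "intermediate"))
  expect_error(bivariate_class_map(a, mk_map(matrix(1, 2, 2))), "mismatch")
})

test_that("stratified means honour strata and degenerate inputs", {
  cm <- structure(list(r = matrix(0.5, 6, 6), sig = matrix(TRUE, 6, 6),
                       r_crit = 0.3, n_windows = 10, alpha = 0.05,
                       vars = c("a", "b")), class = "coupling_map")
  strata <- matrix(rep(1:3, each = 12), 6, 6)
  out <- stratified_mean_r(cm, strata, labels = c("x", "y", "z"))
  expect_equal(out$mean_r, rep(0.5, 3))
  expect_equal(sum(out$n), 36)
  # single stratum equals the global mean
  one <- stratified_mean_r(cm, matrix(1, 6, 6), labels = "all")
  expect_equal(one$mean_r, mean(cm$r))
  # empty stratum reported with n = 0
  out2 <- stratified_mean_r(cm, strata, labels = c("x", "y", "z", "ghost"))
  expect_equal(out2$n[out2$stratum == "ghost"], 0L)
})

test_that("dominant predictor identification follows constructed dominance", {
  set.seed(18)
  ny <- 20
  npp <- annual_stack(array(rnorm(10 * 10 * ny), c(10, 10, ny)), 1:ny)
  pre <- annual_stack(array(rnorm(10 * 10 * ny), c(10, 10, ny)), 1:ny)
  rs_npp <- annual_stack(unclass(npp) + 0, 1:ny)
  dm <- dominant_predictor_map(rs_npp, list(NPP = npp, precip = pre))
  expect_true(all(dm$dominant == "NPP"))
  rs_mix <- annual_stack(unclass(pre) + 0.1 * unclass(npp), 1:ny)
  dm2 <- dominant_predictor_map(rs_mix, list(NPP = npp, precip = pre))
  expect_gte(mean(dm2$dominant == "precip"), 0.95)
  # standardized-coefficient variant agrees on the constructed case
  dm3 <- dominant_predictor_map(rs_mix, list(NPP = npp, precip = pre),
                                method = "std_beta")
  expect_gte(mean(dm3$dominant == "precip"), 0.95)
})

test_that("independent-noise responses spread dominance evenly", {
  set.seed(19)
  ny <- 30
  mk <- function() annual_stack(array(rnorm(50 * 50 * ny), c(50, 50, ny)), 1:ny)
  preds <- list(a = mk(), b = mk(), c = mk(), d = mk())
  dm <- dominant_predictor_map(mk(), preds)
  counts <- table(factor(as.vector(dm$dominant), levels = names(preds)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})
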