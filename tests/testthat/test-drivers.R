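test_that("degree aggregation matches arithmetic and a group-by oracle", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)   # one 2x2 block: mean 2.5
  out <- aggregate_to_degree(list(v = m), matrix(1L, 2, 2), "grassland",
                             block = 2)
  expect_equal(out$v, 2.5)
  # uniform map aggregates to the constant
  u <- aggregate_to_degree(list(v = matrix(7, 6, 6)), matrix(1L, 6, 6),
                           "grassland", block = 3)
  expect_true(all(u$v == 7))
  # brute-force oracle on a random map with NAs
  set.seed(23)
  mm <- matrix(rnorm(100), 10, 10)
  mm[sample(100, 12)] <- NA
  eco <- matrix(sample(1:3, 100, TRUE), 10, 10)
  out2 <- aggregate_to_degree(list(v = mm), eco, c("a", "b", "c"),
                              block = 5, min_frac = 0)
  for (i in seq_len(nrow(out2))) {
    rr <- ((out2$deg_row[i] - 1) * 5 + 1):(out2$deg_row[i] * 5)
    cc <- ((out2$deg_col[i] - 1) * 5 + 1):(out2$deg_col[i] * 5)
    expect_equal(out2$v[i], mean(mm[rr, cc], na.rm = TRUE))
    tab <- table(eco[rr, cc][!is.na(mm[rr, cc])])
    expect_equal(out2$Ecosystem_type[i],
                 c("a", "b", "c")[as.integer(names(which.max(tab)))])
  }
  # blocks below the validity threshold are dropped; none left is an error
  mm2 <- matrix(NA_real_, 10, 10); mm2[1:5, 1:5] <- 2
  out3 <- aggregate_to_degree(list(v = mm2), eco, c("a", "b", "c"),
                              block = 5, min_frac = 0.25)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$v, 2)
  mm3 <- matrix(NA_real_, 10, 10); mm3[1, 1] <- 1
  expect_error(aggregate_to_degree(list(v = mm3), eco, c("a", "b", "c"),
                                   block = 5, min_frac = 0.25),
               "no coarse cell")
})

test_that("productivity PC1 behaves in identity, independence, and oracle cases", {
  set.seed(24)
  x <- rnorm(300)
  p1 <- productivity_pc1(x, x)
  expect_equal(p1$var_explained, 1.0, tolerance = 1e-12)
  expect_equal(cor(p1$scores, x), 1, tolerance = 1e-12)
  y <- rnorm(300)
  p2 <- productivity_pc1(x, y)
  expect_equal(p2$var_explained, 0.5, tolerance = 0.1)
  # eigen oracle
  Z <- cbind(scale(x), scale(y))
  ev <- eigen(cor(Z))
  w <- ev$vectors[, 1]; if (w[1] < 0) w <- -w
  expect_equal(p2$scores, as.vector(Z %*% w), tolerance = 1e-8)
  expect_error(productivity_pc1(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("partial correlations satisfy trivial cases and the residual oracle", {
  set.seed(25)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(rs_stab = x1, prod_pc1 = x1, temp_stab = x2)
  out <- partial_correlations(d, predictors = c("prod_pc1", "temp_stab"))
  expect_equal(out$partial_r[out$predictor == "prod_pc1"], 1, tolerance = 1e-8)
  expect_lt(abs(out$partial_r[out$predictor == "temp_stab"]), 0.15)
  # y = x1 + x2 with x1 independent of x2, no noise: both partials are 1
  d2 <- data.frame(rs_stab = x1 + x2, prod_pc1 = x1, temp_stab = x2)
  out2 <- partial_correlations(d2, predictors = c("prod_pc1", "temp_stab"))
  expect_equal(out2$partial_r, c(1, 1), tolerance = 1e-8)
  # precision-matrix identity as the independent oracle, per group
  d3 <- data.frame(rs_stab = rnorm(n), prod_pc1 = rnorm(n),
                   temp_stab = rnorm(n), precip_stab = rnorm(n),
                   g = rep(c("u", "v"), n / 2))
  out3 <- partial_correlations(d3, predictors = c("prod_pc1", "temp_stab",
                                                  "precip_stab"),
                               group = "g")
  for (g in c("u", "v")) {
    dg <- d3[d3$g == g, c("rs_stab", "prod_pc1", "temp_stab", "precip_stab")]
    P <- solve(cor(dg))
    for (j in 2:4) {
      oracle <- -P[1, j] / sqrt(P[1, 1] * P[j, j])
      expect_equal(out3$partial_r[out3$group == g &
                                    out3$predictor == names(dg)[j]],
                   oracle, tolerance = 1e-8)
    }
  }
  expect_true(all(out3$p_adjusted >= out3$p_value - 1e-15))
})

test_that("variance partition closes exactly and matches limit cases", {
  set.seed(26)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(rs_stab = x1 + rnorm(n, 0, 0.5), s1 = x1, s2a = x2,
                  s2b = rnorm(n))
  vp <- variance_partition(d, set1 = "s1", set2 = c("s2a", "s2b"))
  expect_equal(unname(sum(vp$raw)), 1, tolerance = 1e-10)
  expect_gt(vp$fractions[["unique1"]], 0.5)
  expect_lt(abs(vp$raw[["shared"]]), 0.05)
  # duplicated predictor: uniques collapse, shared carries the signal
  d2 <- data.frame(rs_stab = x1 + rnorm(n, 0, 0.5), s1 = x1, s2 = x1)
  vp2 <- variance_partition(d2, set1 = "s1", set2 = "s2")
  expect_lt(abs(vp2$raw[["unique1"]]), 0.02)
  expect_lt(abs(vp2$raw[["unique2"]]), 0.02)
  expect_gt(vp2$fractions[["shared"]], 0.5)
})

test_that("variance partition agrees with vegan::varpart", {
  set.seed(27)
  n <- 150
  d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$y <- 0.8 * d$a + 0.5 * d$b + rnorm(n, 0, 0.7)
  vp <- variance_partition(d, response = "y", set1 = "a", set2 = c("b", "c"))
  vv <- vegan::varpart(d$y, ~ a, ~ b + c, data = d)
  ind <- vv$part$indfract$Adj.R.square  # rows: X1|X2, X2|X1, shared, resid
  expect_equal(unname(vp$raw[["unique1"]]), ind[1], tolerance = 1e-10)
  expect_equal(unname(vp$raw[["unique2"]]), ind[2], tolerance = 1e-10)
  expect_equal(unname(vp$raw[["shared"]]), ind[3], tolerance = 1e-10)
  expect_equal(unname(vp$raw[["unexplained"]]), ind[4], tolerance = 1e-10)
})

test_that("random-forest importance flags a perfect signal and ranks drivers", {
  set.seed(28)
  n <- 150
  d <- data.frame(prod_pc1 = rnorm(n), temp_stab = rnorm(n),
                  precip_stab = rnorm(n), ai_stab = rnorm(n))
  d$rs_stab <- d$prod_pc1
  imp <- rf_importance(d, n_perm = 39, n_trees = 150, seed = 7)
  expect_equal(imp$predictor[1], "prod_pc1")
  expect_lt(imp$p_value[1], 0.05)
  expect_error(rf_importance(transform(d, rs_stab = 1), n_perm = 3,
                             seed = 1), "constant response")
  imp2 <- rf_importance(d, n_perm = 19, n_trees = 150, seed = 7)
  expect_equal(imp$importance, imp2$importance)  # seeded observed fit
})
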