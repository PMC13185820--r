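#' Aggregate stability maps to coarse (1-degree analogue) cells
#'
#' Groups fine cells into square blocks (the pseudo-geographic mapping puts
#' 0.2 degrees on a fine cell, so a block of 5 is one degree), averages each
#' map over the valid fine cells of a block, takes the modal ecosystem
#' class, and drops blocks whose fraction of fully-valid fine cells is
#' below `min_frac`.
#'
#' @param maps named list of matrices (stability maps or plain fields).
#' @param ecosystem integer matrix of class codes.
#' @param eco_names class names aligned with the codes.
#' @param block block edge in fine cells (default 5 = 1 degree at 0.2
#'   degrees per cell).
#' @param min_frac minimum fraction of valid fine cells per block.
#' @return data.frame: `deg_row`, `deg_col`, one column per map,
#'   `Ecosystem_type`, `n_valid`.
#' @export
aggregate_to_degree <- function(maps, ecosystem, eco_names, block = 5,
                                min_frac = 0.25) {
  stopifnot(length(maps) >= 1, !is.null(names(maps)))
  d <- dim(maps[[1]])
  for (m in maps) stopifnot(identical(dim(m), d))
  gr <- ceiling(row(maps[[1]]) / block)
  gc <- ceiling(col(maps[[1]]) / block)
  key <- paste(gr, gc, sep = "_")
  valid <- Reduce(`&`, lapply(maps, function(m) is.finite(unclass(m))))
  keys <- unique(key)
  rows <- lapply(keys, function(k) {
    i <- which(key == k)
    ok <- i[valid[i]]
    if (length(ok) / length(i) < min_frac) return(NULL)
    vals <- vapply(maps, function(m) mean(unclass(m)[ok]), numeric(1))
    eco_tab <- table(ecosystem[ok])
    out <- data.frame(deg_row = gr[i[1]], deg_col = gc[i[1]])
    for (nm in names(vals)) out[[nm]] <- vals[[nm]]
    out$Ecosystem_type <- eco_names[as.integer(names(which.max(eco_tab)))]
    out$n_valid <- length(ok)
    out
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) stop("no coarse cell passed the validity threshold", call. = FALSE)
  out <- do.call(rbind, rows)
  out[order(out$deg_row, out$deg_col), , drop = FALSE]
}

#' Productivity-stability composite (PC1 of NPP and LAI stability)
#'
#' First principal component of the two z-scored stability columns,
#' sign-oriented so that NPP stability loads positively.
#'
#' @param npp_stab,lai_stab numeric vectors (finite).
#' @return list: `scores`, `loadings`, `var_explained`.
#' @export
productivity_pc1 <- function(npp_stab, lai_stab) {
  stopifnot(length(npp_stab) == length(lai_stab))
  if (stats::sd(npp_stab) == 0 || stats::sd(lai_stab) == 0) {
    stop("zero variance in a stability column", call. = FALSE)
  }
  Z <- cbind(npp = as.vector(scale(npp_stab)), lai = as.vector(scale(lai_stab)))
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  w <- pc$rotation[, 1]
  if (w["npp"] < 0) w <- -w
  list(scores = as.vector(Z %*% w), loadings = w,
       var_explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Permutation-based random-forest importance of stability drivers
#'
#' Fits a random forest of the response on the predictors, records each
#' predictor's permutation importance, and attaches a permutation p-value
#' obtained by refitting the forest on `n_perm` response shuffles
#' (p = (1 + #{null importance >= observed}) / (n_perm + 1)).
#'
#' @param sample driver sample table.
#' @param response response column name.
#' @param predictors predictor column names.
#' @param n_perm number of response permutations.
#' @param n_trees trees per forest.
#' @param seed integer seed.
#' @return data.frame (predictor, importance, p_value) sorted by
#'   importance; attribute `r_squared` holds the forest's OOB R^2.
#' @export
rf_importance <- function(sample, response = "rs_stab",
                          predictors = c("prod_pc1", "temp_stab",
                                         "precip_stab", "ai_stab"),
                          n_perm = 999, n_trees = 500, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  d <- sample[, c(response, predictors)]
  names(d)[1] <- "y"
  if (stats::sd(d$y) == 0) stop("constant response", call. = FALSE)
  fit <- ranger::ranger(y ~ ., data = d, num.trees = n_trees,
                        importance = "permutation",
                        seed = stage_seed(seed, "rf_imp"), num.threads = 1)
  obs <- fit$variable.importance[predictors]
  null_ge <- stats::setNames(numeric(length(predictors)), predictors)
  for (b in seq_len(n_perm)) {
    db <- d
    db$y <- with_seed(stage_seed(seed, paste0("perm", b)), sample(db$y))
    fb <- ranger::ranger(y ~ ., data = db, num.trees = n_trees,
                         importance = "permutation",
                         seed = stage_seed(seed, paste0("rf_perm", b)),
                         num.threads = 1)
    null_ge <- null_ge + (fb$variable.importance[predictors] >= obs)
  }
  out <- data.frame(predictor = predictors,
                    importance = as.numeric(obs),
                    p_value = as.numeric((1 + null_ge) / (n_perm + 1)))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "r_squared") <- fit$r.squared
  out
}

#' Partial correlations of a response with each predictor, per group
#'
#' The partial correlation of the response with one predictor controls for
#' all the other predictors: the correlation of the two residual vectors
#' after regressing each on the controls (robust to exactly collinear
#' inputs, where the precision-matrix identity breaks down). p-values use
#' the t approximation with n - k - 2 degrees of freedom and are
#' Benjamini-Hochberg adjusted across the whole group x predictor table.
#'
#' @param sample driver sample table.
#' @param response response column.
#' @param predictors predictor columns.
#' @param group optional grouping column (e.g. `Ecosystem_type`); `NULL`
#'   pools all rows.
#' @return data.frame (group, predictor, partial_r, n, p_value, p_adjusted);
#'   singular groups yield `NA` entries.
#' @export
partial_correlations <- function(sample, response = "rs_stab",
                                 predictors = c("prod_pc1", "temp_stab",
                                                "precip_stab", "ai_stab"),
                                 group = NULL) {
  grp <- if (is.null(group)) rep("all", nrow(sample)) else sample[[group]]
  res <- list()
  for (g in unique(grp)) {
    d <- sample[grp == g, c(response, predictors), drop = FALSE]
    d <- d[stats::complete.cases(d), , drop = FALSE]
    n <- nrow(d)
    k <- length(predictors) - 1  # controls per test
    pr <- rep(NA_real_, length(predictors))
    pv <- rep(NA_real_, length(predictors))
    if (n > length(predictors) + 2) {
      for (i in seq_along(predictors)) {
        ctrl <- setdiff(predictors, predictors[i])
        ry <- stats::resid(stats::lm(stats::reformulate(ctrl, response),
                                     data = d))
        rx <- stats::resid(stats::lm(stats::reformulate(ctrl, predictors[i]),
                                     data = d))
        if (stats::sd(ry) > 0 && stats::sd(rx) > 0) {
          pr[i] <- stats::cor(ry, rx)
        }
      }
      df <- n - k - 2
      tt <- pr * sqrt(pmax(df, 1) / pmax(1 - pr^2, .Machine$double.eps))
      pv <- 2 * stats::pt(-abs(tt), df = pmax(df, 1))
    }
    res[[g]] <- data.frame(group = g, predictor = predictors,
                           partial_r = pr, n = n, p_value = pv)
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Variance partitioning between two predictor sets
#'
#' Adjusted-R^2 partition of the response's variance into the unique
#' contribution of each set, their shared part, and the unexplained
#' remainder: unique1 = R2(full) - R2(set2), unique2 = R2(full) - R2(set1),
#' shared = R2(set1) + R2(set2) - R2(full). Components sum to R2(full)
#' exactly before flooring; small negative components are floored at zero
#' with a flag.
#'
#' @param sample driver sample table.
#' @param response response column.
#' @param set1,set2 character vectors of predictor columns.
#' @return list: `fractions` (unique1, unique2, shared, unexplained),
#'   `raw` (unfloored), `r_squared` (set1, set2, full), `floored`.
#' @export
variance_partition <- function(sample, response = "rs_stab",
                               set1 = "prod_pc1",
                               set2 = c("temp_stab", "precip_stab", "ai_stab")) {
  d <- sample[stats::complete.cases(sample[, c(response, set1, set2)]),
              c(response, set1, set2), drop = FALSE]
  adj_r2 <- function(vars) {
    f <- stats::as.formula(paste(response, "~",
                                 paste(vars, collapse = " + ")))
    summary(stats::lm(f, data = d))$adj.r.squared
  }
  r1 <- adj_r2(set1); r2 <- adj_r2(set2); rf <- adj_r2(c(set1, set2))
  if (!is.finite(rf)) stop("collinear full model", call. = FALSE)
  raw <- c(unique1 = rf - r2, unique2 = rf - r1, shared = r1 + r2 - rf,
           unexplained = 1 - rf)
  floored <- any(raw[1:3] < 0)
  fr <- raw
  fr[1:3] <- pmax(fr[1:3], 0)
  list(fractions = fr, raw = raw,
       r_squared = c(set1 = r1, set2 = r2, full = rf), floored = floored)
}
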