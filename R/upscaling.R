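#' Add quadratic candidate terms to a design table
#'
#' @param design design table with index columns Cli, Plant, Gra, Mic, Phy,
#'   Chem (from [extract_at_sites()]).
#' @return the table with the six squared-index columns appended.
#' @export
add_quadratic_terms <- function(design) {
  for (v in c("Cli", "Plant", "Gra", "Mic", "Phy", "Chem")) {
    design[[paste0(v, "2")]] <- design[[v]]^2
  }
  design
}

#' Fit the quadratic composite-index soil-respiration model per ecosystem
#'
#' For each ecosystem class, stepwise selection (bidirectional, starting at
#' the intercept-only model) chooses among the twelve candidate terms —
#' each composite index and its square — and ordinary least squares is fit
#' on the selected terms. The default selection penalty is the extended BIC
#' (log n + 2 log p with p = 12 candidates), which controls the
#' false-inclusion rate over a correlated candidate set far better than AIC
#' or plain BIC while costing essentially no power against the effect sizes
#' a usable upscaling model requires; both alternatives are available.
#' Deterministic given the design table. Classes with too few rows are
#' skipped with a warning.
#'
#' @param design design table with `Rs`, `Ecosystem_type` and the six index
#'   columns (squares added automatically).
#' @param selection list: `criterion` ("ebic", "bic" or "aic"), `direction`
#'   (passed to [stats::step()]).
#' @param min_n minimum rows per class (terms + intercept + margin).
#' @return a `regression_fit_set`: per class, the full 13-coefficient vector
#'   (`beta0` then [RS_MODEL_TERMS]; excluded terms exactly 0), selected-term
#'   flags, residual SD, n_train.
#' @export
fit_rs_model <- function(design, selection = list(criterion = "ebic",
                                             direction = "both"),
                    min_n = 20) {
  design <- add_quadratic_terms(design)
  criterion <- match.arg(selection$criterion %||% "ebic",
                         c("ebic", "bic", "aic"))
  direction <- selection$direction %||% "both"
  classes <- sort(unique(design$Ecosystem_type))
  fits <- list()
  for (cl in classes) {
    d <- design[design$Ecosystem_type == cl, , drop = FALSE]
    if (nrow(d) < min_n) {
      warning(sprintf("ecosystem '%s': only %d rows (< %d); skipped",
                      cl, nrow(d), min_n), call. = FALSE)
      next
    }
    k_pen <- switch(criterion,
                    ebic = log(nrow(d)) + 2 * log(length(RS_MODEL_TERMS)),
                    bic = log(nrow(d)),
                    aic = 2)
    full <- stats::as.formula(paste("Rs ~", paste(RS_MODEL_TERMS, collapse = " + ")))
    base_fit <- stats::lm(Rs ~ 1, data = d)
    sel <- stats::step(base_fit, scope = list(lower = ~1, upper = full),
                       direction = direction, k = k_pen, trace = 0)
    beta <- stats::setNames(numeric(13), c("beta0", RS_MODEL_TERMS))
    cf <- stats::coef(sel)
    beta["beta0"] <- cf["(Intercept)"]
    sel_terms <- setdiff(names(cf), "(Intercept)")
    beta[sel_terms] <- cf[sel_terms]
    fits[[cl]] <- list(
      beta = beta,
      selected = stats::setNames(RS_MODEL_TERMS %in% sel_terms, RS_MODEL_TERMS),
      residual_sd = stats::sigma(sel),
      n_train = nrow(d),
      r_squared = summary(sel)$r.squared
    )
  }
  if (!length(fits)) stop("no ecosystem class had enough rows", call. = FALSE)
  structure(list(fits = fits,
                 selection = list(criterion = criterion, direction = direction)),
            class = "regression_fit_set")
}

#' @export
print.regression_fit_set <- function(x, ...) {
  cat(sprintf("<regression_fit_set> %d ecosystem fits (%s stepwise)\n",
              length(x$fits), toupper(x$selection$criterion)))
  for (cl in names(x$fits)) {
    f <- x$fits[[cl]]
    cat(sprintf("  %-18s n=%-5d terms: %s\n", cl, f$n_train,
                paste(names(which(f$selected)), collapse = " ")))
  }
  invisible(x)
}

eval_beta <- function(beta, cli, pla, gra, mic, phy, chem) {
  beta["beta0"] + beta["Cli"] * cli + beta["Cli2"] * cli^2 +
    beta["Plant"] * pla + beta["Plant2"] * pla^2 +
    beta["Gra"] * gra + beta["Gra2"] * gra^2 +
    beta["Mic"] * mic + beta["Mic2"] * mic^2 +
    beta["Phy"] * phy + beta["Phy2"] * phy^2 +
    beta["Chem"] * chem + beta["Chem2"] * chem^2
}

#' Predict gridded annual soil respiration from per-ecosystem fits
#'
#' Evaluates each cell-year with the coefficients of the cell's ecosystem
#' class. Negative predictions are floored at zero and counted. An
#' ecosystem class without a fit uses `fallback` (a class name) or errors.
#'
#' @param fits a [fit_rs_model()] result.
#' @param indices a [composite_indices()] set.
#' @param ecosystem integer matrix of class codes.
#' @param eco_names class names aligned with the codes in `ecosystem`.
#' @param fallback class name used for unmapped classes (default: none).
#' @return an [annual_stack] of predicted soil respiration; attribute
#'   `n_floored` counts negative predictions floored at 0.
#' @export
predict_grid <- function(fits, indices, ecosystem, eco_names,
                         fallback = NULL) {
  stopifnot(inherits(fits, "regression_fit_set"),
            inherits(indices, "composite_indices"))
  years <- stack_years(indices$Cli)
  d <- dim(indices$Cli)
  out <- array(NA_real_, d)
  cli_a <- unclass(indices$Cli); pla_a <- unclass(indices$Plant)
  for (code in sort(unique(as.vector(ecosystem)))) {
    cl <- eco_names[code]
    f <- fits$fits[[cl]]
    if (is.null(f)) {
      if (is.null(fallback) || is.null(fits$fits[[fallback]])) {
        stop(sprintf("no fit for ecosystem '%s' and no fallback", cl),
             call. = FALSE)
      }
      f <- fits$fits[[fallback]]
    }
    cells <- which(ecosystem == code)
    for (t in seq_along(years)) {
      off <- (t - 1L) * d[1] * d[2]
      out[cells + off] <- eval_beta(
        f$beta,
        cli_a[, , t][cells], pla_a[, , t][cells],
        indices$Gra[cells], indices$Mic[cells],
        indices$Phy[cells], indices$Chem[cells])
    }
  }
  n_floored <- sum(out < 0, na.rm = TRUE)
  out <- pmax(out, 0)
  res <- annual_stack(out, years, units = "g C m-2 yr-1", varname = "Rs_pred")
  attr(res, "n_floored") <- n_floored
  res
}

#' Predict records from per-ecosystem fits
#'
#' @param fits a [fit_rs_model()] result.
#' @param design design table rows to predict.
#' @param fallback class name used for unmapped classes.
#' @return numeric predictions (negative values floored at 0).
#' @export
predict_records <- function(fits, design, fallback = NULL) {
  pred <- rep(NA_real_, nrow(design))
  for (cl in unique(design$Ecosystem_type)) {
    f <- fits$fits[[cl]] %||% (if (!is.null(fallback)) fits$fits[[fallback]])
    if (is.null(f)) stop(sprintf("no fit for ecosystem '%s'", cl), call. = FALSE)
    i <- design$Ecosystem_type == cl
    pred[i] <- eval_beta(f$beta, design$Cli[i], design$Plant[i],
                         design$Gra[i], design$Mic[i], design$Phy[i],
                         design$Chem[i])
  }
  pmax(pred, 0)
}

metrics_table <- function(obs, pred) {
  r <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) NA_real_ else {
    stats::cor(obs, pred)
  }
  c(R = r, MAE = mean(abs(obs - pred)),
    RMSE = sqrt(mean((obs - pred)^2)), n = length(obs))
}

#' Held-out validation metrics
#'
#' Pearson R, MAE and RMSE of held-out records (overall and per ecosystem).
#' A constant prediction vector yields an undefined R, reported as `NA`.
#'
#' @param fits fits trained on the training fold only.
#' @param design full design table.
#' @param folds fold vector from [site_blocked_split()] (or any
#'   "train"/"test" vector aligned with `design`).
#' @param fallback class name used for classes without a fit.
#' @return a `validation_metrics` list: `$overall`, `$per_ecosystem`.
#' @export
validate <- function(fits, design, folds, fallback = NULL) {
  test <- design[folds == "test", , drop = FALSE]
  if (nrow(test) == 0) stop("empty test fold", call. = FALSE)
  pred <- predict_records(fits, test, fallback = fallback)
  per <- do.call(rbind, lapply(split(seq_len(nrow(test)), test$Ecosystem_type),
                               function(i) metrics_table(test$Rs[i], pred[i])))
  structure(list(overall = metrics_table(test$Rs, pred),
                 per_ecosystem = as.data.frame(per)),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("<validation_metrics> R=%.3f MAE=%.2f RMSE=%.2f (n=%d)\n",
              x$overall["R"], x$overall["MAE"], x$overall["RMSE"],
              as.integer(x$overall["n"])))
  invisible(x)
}

VEGETATION_FEATURES <- c("Plant", "NPP", "LAI", "FVC", "GPP", "CUE", "WUE",
                         "NDVI", "EVI", "SIF", "biomass")

#' Vegetation-free random-forest soil-respiration model
#'
#' The robustness twin of the regression upscaler: a random forest trained
#' only on non-vegetation predictors (climate, soil physical/chemical,
#' microbial, topographic indices), with k-fold cross-validated metrics and,
#' optionally, predictions for every grid cell-year so the stability
#' coupling can be recomputed without any vegetation input. A guard rejects
#' vegetation-derived feature names outright.
#'
#' @param design design table with `Rs` and the feature columns.
#' @param features feature column names; must not contain vegetation-derived
#'   variables.
#' @param n_trees number of trees.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed.
#' @param indices,ecosystem optional [composite_indices()] set and class
#'   matrix; when given, grid predictions are returned.
#' @return an `rf_noveg_fit`: `$metrics` (CV R/MAE/RMSE), `$model` (ranger
#'   fit on all rows), `$grid_pred` ([annual_stack] or NULL).
#' @export
fit_rf_novegetation <- function(design,
                                features = c("Cli", "Gra", "Mic", "Phy", "Chem"),
                                n_trees = 5000, cv_folds = 10, seed,
                                indices = NULL, ecosystem = NULL) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  tainted <- features[vapply(features, function(f) {
    any(vapply(VEGETATION_FEATURES, function(v) grepl(v, f, fixed = TRUE), TRUE))
  }, TRUE)]
  if (length(tainted)) {
    stop(sprintf("vegetation-tainted feature(s) rejected: %s",
                 paste(tainted, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(features, names(design))
  if (length(absent)) {
    stop(sprintf("missing feature column(s): %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  }
  d <- design[, c("Rs", features)]
  n <- nrow(d)
  fold_id <- with_seed(stage_seed(seed, "rf_folds"),
                       sample(rep_len(seq_len(cv_folds), n)))
  pred <- rep(NA_real_, n)
  for (k in seq_len(cv_folds)) {
    tr <- d[fold_id != k, , drop = FALSE]
    te <- d[fold_id == k, , drop = FALSE]
    if (!nrow(te)) next
    m <- ranger::ranger(Rs ~ ., data = tr, num.trees = n_trees,
                        seed = stage_seed(seed, paste0("rf_cv", k)),
                        num.threads = 1)
    pred[fold_id == k] <- stats::predict(m, te)$predictions
  }
  metrics <- metrics_table(d$Rs, pred)
  model <- ranger::ranger(Rs ~ ., data = d, num.trees = n_trees,
                          seed = stage_seed(seed, "rf_full"),
                          num.threads = 1)
  grid_pred <- NULL
  if (!is.null(indices)) {
    stopifnot(!is.null(ecosystem))
    dm <- dim(indices$Cli)
    years <- stack_years(indices$Cli)
    out <- array(NA_real_, dm)
    for (t in seq_along(years)) {
      newd <- data.frame(
        Cli = as.vector(unclass(indices$Cli)[, , t]),
        Gra = as.vector(indices$Gra), Mic = as.vector(indices$Mic),
        Phy = as.vector(indices$Phy), Chem = as.vector(indices$Chem)
      )[, features, drop = FALSE]
      out[, , t] <- matrix(stats::predict(model, newd)$predictions,
                           dm[1], dm[2])
    }
    grid_pred <- annual_stack(out, years, units = "g C m-2 yr-1",
                              varname = "Rs_rf_noveg")
  }
  structure(list(metrics = metrics, model = model, grid_pred = grid_pred,
                 features = features, n_trees = n_trees,
                 cv_folds = cv_folds, seed = seed),
            class = "rf_noveg_fit")
}
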