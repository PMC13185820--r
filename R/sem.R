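#' Structural equation model (recursive path analysis)
#'
#' Fits a recursive system of linear structural equations on standardized
#' complete cases: each equation is estimated by least squares (which is
#' the maximum-likelihood estimate for a recursive model with uncorrelated
#' disturbances), and global fit is evaluated from the maximum-likelihood
#' discrepancy between the model-implied and the sample covariance.
#' Exogenous variances/covariances are free; endogenous disturbances are
#' independent.
#'
#' Fit statistics: chi-square (with its df and P), chi-square/df, RMSEA,
#' and CFI against the independence baseline. A model with zero degrees of
#' freedom (saturated) fits trivially and is flagged as such. The
#' conventional pass rule is chi2/df <= 2, P > 0.05 and RMSEA <= 0.05.
#'
#' @param data data.frame holding every model variable.
#' @param model list of formulas, one per endogenous variable, in causal
#'   order (e.g. `list(prod_pc1 ~ temp_stab + precip_stab + ai_stab,
#'   rs_stab ~ prod_pc1 + temp_stab + precip_stab + ai_stab)`).
#' @param standardize z-score all variables first (standardized path
#'   coefficients).
#' @return a `sem_result`: `$paths` (from, to, coefficient, se, p_value,
#'   significant), `$r_squared` per endogenous variable, `$fit` (chisq, df,
#'   p_value, chisq_df, rmsea, cfi, n), `$pass`, `$saturated`.
#' @export
fit_sem <- function(data, model = default_sem_model(), standardize = TRUE) {
  stopifnot(is.list(model), length(model) >= 1)
  endo <- vapply(model, function(f) all.vars(f)[1], "")
  vars <- unique(unlist(lapply(model, all.vars)))
  exog <- setdiff(vars, endo)
  d <- data[stats::complete.cases(data[, vars, drop = FALSE]), vars,
            drop = FALSE]
  n <- nrow(d)
  if (n < length(vars) + 2) stop("too few complete cases for the SEM", call. = FALSE)
  if (standardize) d[] <- lapply(d, function(x) as.vector(scale(x)))

  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  psi <- stats::setNames(numeric(length(endo)), endo)
  paths <- list()
  r2 <- stats::setNames(numeric(length(endo)), endo)
  known <- exog
  for (i in seq_along(model)) {
    f <- model[[i]]
    y <- endo[i]
    rhs <- setdiff(all.vars(f), y)
    if (!all(rhs %in% known)) {
      stop(sprintf("non-recursive model: '%s' depends on a later endogenous variable",
                   y), call. = FALSE)
    }
    fit <- stats::lm(f, data = d)
    if (!fit$qr$rank == length(rhs) + 1) {
      stop(sprintf("equation for '%s' did not converge (singular design)", y),
           call. = FALSE)
    }
    sm <- summary(fit)$coefficients
    for (x in rhs) {
      B[y, x] <- stats::coef(fit)[x]
      paths[[length(paths) + 1]] <- data.frame(
        from = x, to = y,
        coefficient = sm[x, "Estimate"], se = sm[x, "Std. Error"],
        p_value = sm[x, "Pr(>|t|)"])
    }
    psi[y] <- sum(stats::residuals(fit)^2) / n   # ML residual variance
    r2[y] <- summary(fit)$r.squared
    known <- c(known, y)
  }
  paths <- do.call(rbind, paths)
  paths$significant <- paths$p_value < 0.05

  ## implied covariance of a recursive system: (I-B)^-1 U (I-B)^-T
  S <- stats::cov(d) * (n - 1) / n
  U <- matrix(0, p, p, dimnames = list(vars, vars))
  if (length(exog)) U[exog, exog] <- S[exog, exog, drop = FALSE]
  for (y in endo) U[y, y] <- psi[[y]]
  IB <- solve(diag(p) - B)
  Sigma <- IB %*% U %*% t(IB)

  q_free <- nrow(paths) + length(endo) + length(exog) * (length(exog) + 1) / 2
  df <- p * (p + 1) / 2 - q_free
  F_ml <- as.numeric(determinant(Sigma)$modulus - determinant(S)$modulus +
                       sum(diag(S %*% solve(Sigma))) - p)
  chisq <- max(0, (n - 1) * F_ml)
  saturated <- df <= 0
  p_chisq <- if (saturated) NA_real_ else stats::pchisq(chisq, df,
                                                        lower.tail = FALSE)
  rmsea <- if (saturated) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))
  ## independence baseline for CFI
  Sigma0 <- diag(diag(S)); dimnames(Sigma0) <- dimnames(S)
  F0 <- as.numeric(determinant(Sigma0)$modulus - determinant(S)$modulus +
                     sum(diag(S %*% solve(Sigma0))) - p)
  chisq0 <- max(0, (n - 1) * F0)
  df0 <- p * (p - 1) / 2
  cfi <- 1 - max(chisq - df, 0) / max(chisq0 - df0, chisq - df, .Machine$double.eps)
  chisq_df <- if (saturated) 0 else chisq / df
  pass <- if (saturated) TRUE else {
    (chisq_df <= 2) && (p_chisq > 0.05) && (rmsea <= 0.05)
  }
  structure(list(
    paths = paths, r_squared = r2,
    fit = c(chisq = chisq, df = df, p_value = p_chisq, chisq_df = chisq_df,
            rmsea = rmsea, cfi = cfi, n = n),
    pass = pass, saturated = saturated,
    model = model, variables = list(endogenous = endo, exogenous = exog)
  ), class = "sem_result")
}

#' Default SEM topology for the stability-coupling analysis
#'
#' Climate stabilities (temperature, precipitation, aridity index) drive
#' productivity stability, and climate plus productivity stability drive
#' soil-respiration stability.
#' @return list of formulas for [fit_sem()].
#' @export
default_sem_model <- function() {
  list(prod_pc1 ~ temp_stab + precip_stab + ai_stab,
       rs_stab ~ prod_pc1 + temp_stab + precip_stab + ai_stab)
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("<sem_result> n=%d, chisq=%.2f (df=%g), chisq/df=%.2f, RMSEA=%.3f, CFI=%.3f%s -> %s\n",
              as.integer(x$fit["n"]), x$fit["chisq"], x$fit["df"],
              x$fit["chisq_df"], x$fit["rmsea"], x$fit["cfi"],
              if (x$saturated) " [saturated]" else "",
              if (x$pass) "fit acceptable" else "fit rejected"))
  sig <- x$paths[x$paths$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    cat(sprintf("  %s -> %s: %.3f (p=%.2g)\n", sig$from[i], sig$to[i],
                sig$coefficient[i], sig$p_value[i]))
  }
  invisible(x)
}
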