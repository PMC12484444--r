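#' Rank-based inverse normal transform
#'
#' Blom transform: ranks (average ranks for ties) are mapped to normal
#' quantiles via `qnorm((r - 3/8) / (n + 1/4))`.  Missing values stay
#' missing and do not enter the rank computation.
#'
#' @param values Numeric vector with at least 3 non-missing values.
#' @param offset Rank offset constant (default 3/8, the Blom
#'   convention).
#' @return Numeric vector of transformed values.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values", call. = FALSE)
  if (length(unique(values[ok])) == 1L)
    stop("all values identical; no rank information", call. = FALSE)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

## Shared OLS core: intercept added, rank checked, coefficient table
## computed from the QR decomposition.  Used by fit_linear() and by the
## mediation bootstrap so both produce bit-identical coefficients.
ols_core <- function(y, X) {
  qrx <- qr(X)
  p <- ncol(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  res <- y - qr.fitted(qrx, y)
  n <- length(y)
  df <- n - p
  sigma2 <- sum(res^2) / df
  R <- qr.R(qrx)
  V <- chol2inv(R)
  unpiv <- order(qrx$pivot)
  V <- V[unpiv, unpiv, drop = FALSE]
  se <- sqrt(diag(V) * sigma2)
  list(beta = beta, se = se, df = df, sigma2 = sigma2, rss = sum(res^2))
}

as_design <- function(X, add_intercept = TRUE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0, ncol = 0)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (is.null(colnames(X)) && ncol(X) > 0)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (add_intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Ordinary least squares fit
#'
#' Linear regression via the QR decomposition with an intercept added,
#' two-sided t-tests on `n - p` degrees of freedom.  Rows with missing
#' values are dropped; a rank-deficient design raises an error naming
#' the collinear columns.
#'
#' @param y Numeric outcome.
#' @param X Covariate matrix or data.frame (intercept added
#'   automatically).
#' @return A list of class `cellprs_fit` with `coefficients` (a
#'   data.frame: `term`, `estimate`, `se`, `statistic`, `p_value`),
#'   `n`, `df`, `rss` and `family = "linear"`.
#' @export
fit_linear <- function(y, X) {
  X <- as_design(X)
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) <= ncol(X)) stop("not enough observations", call. = FALSE)
  fit <- ols_core(y, X)
  tstat <- fit$beta / fit$se
  pv <- 2 * stats::pt(-abs(tstat), df = fit$df)
  structure(list(coefficients = data.frame(
    term = colnames(X), estimate = unname(fit$beta),
    se = unname(fit$se), statistic = unname(tstat),
    p_value = unname(pv), stringsAsFactors = FALSE),
    n = length(y), df = fit$df, rss = fit$rss, family = "linear"),
    class = "cellprs_fit")
}

#' Logistic regression fit
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`glm.fit`, convergence tolerance 1e-8, at most 100 iterations)
#' with Wald z-tests.  Requires both outcome classes; apparent perfect
#' separation (diverging coefficients or non-convergence) raises an
#' error rather than returning a silent result.
#'
#' @param status Binary (0/1) outcome.
#' @param X Covariate matrix or data.frame (intercept added).
#' @return A list of class `cellprs_fit` with the same shape as
#'   [fit_linear()] and `family = "logistic"`.
#' @export
fit_logistic <- function(status, X) {
  X <- as_design(X)
  ok <- stats::complete.cases(status, X)
  status <- status[ok]; X <- X[ok, , drop = FALSE]
  if (length(unique(status)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, status, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8,
                                                maxit = 100)))
  if (!fit$converged || any(abs(fit$coefficients) > 15))
    stop("logistic fit did not converge (possible perfect separation)",
         call. = FALSE)
  p <- ncol(X)
  R <- qr.R(fit$qr)
  V <- chol2inv(R)
  unpiv <- order(fit$qr$pivot)
  V <- V[unpiv, unpiv, drop = FALSE]
  se <- sqrt(diag(V))
  z <- fit$coefficients / se
  pv <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = data.frame(
    term = colnames(X), estimate = unname(fit$coefficients),
    se = unname(se), statistic = unname(z), p_value = unname(pv),
    stringsAsFactors = FALSE),
    n = length(status), df = length(status) - p,
    deviance = fit$deviance, family = "logistic"),
    class = "cellprs_fit")
}

#' @export
print.cellprs_fit <- function(x, ...) {
  cat(sprintf("<cellprs_fit> %s regression, n = %d\n", x$family, x$n))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

coef_row <- function(fit, term) {
  fit$coefficients[fit$coefficients$term == term, , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvalues Numeric vector with values in `(0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Default association plan
#'
#' Enumerates the main analysis family for one outcome: every score
#' type (six cell types plus `full`) at all seven P-value thresholds,
#' under both APOE modes (region included / excluded), i.e. 7 x 7 x 2
#' = 98 models.
#'
#' @param score_types Score types (default six cell types + `"full"`).
#' @param thresholds Integer threshold indices (default 1:7).
#' @param apoe_modes `"include"`, `"exclude"`, or both (default).
#' @return A data.frame with one row per model.
#' @export
default_assoc_plan <- function(score_types = c(default_cell_types(),
                                               "full"),
                               thresholds = 1:7,
                               apoe_modes = c("include", "exclude")) {
  expand.grid(score_type = score_types, threshold = thresholds,
              apoe_mode = apoe_modes, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

base_covariates <- function() c("age", "sex", paste0("PC", 1:10))

#' Run one association family with FDR correction
#'
#' Fits the planned models for a single outcome and applies
#' Benjamini-Hochberg FDR within the family.  Linear outcomes are
#' rank-based inverse normal transformed first (`int_outcome = TRUE`);
#' the logistic family uses the binary outcome as is.  Covariates are
#' age, sex and PC1-PC10; models for APOE-excluded scores additionally
#' adjust for APOE e4 and e2 allele counts, and `adjust_abeta` adds
#' amyloid status.  With `interaction = TRUE` the reported test is the
#' score-by-amyloid interaction term.
#'
#' @param scores Either a `cellprs_scores` matrix (used for every APOE
#'   mode in the plan) or a named list with elements `include` and
#'   `exclude`.
#' @param phenotypes Phenotype data.frame (see
#'   [simulate_phenotypes()]).
#' @param outcome Name of the outcome column.
#' @param family `"linear"` or `"logistic"`.
#' @param plan Model plan from [default_assoc_plan()].
#' @param covariates Baseline covariate names.
#' @param int_outcome Inverse-normal transform the linear outcome.
#' @param adjust_abeta Add amyloid status as a covariate.
#' @param interaction Test the score x amyloid-status interaction
#'   instead of the score main effect.
#' @return A data.frame of class `cellprs_assoc` with one row per
#'   model: `outcome`, `score_type`, `threshold`, `apoe_mode`, `n`,
#'   `beta`, `se`, `statistic`, `p_value`, `p_fdr`.
#' @export
run_family <- function(scores, phenotypes, outcome,
                       family = c("linear", "logistic"),
                       plan = default_assoc_plan(),
                       covariates = base_covariates(),
                       int_outcome = TRUE, adjust_abeta = FALSE,
                       interaction = FALSE) {
  family <- match.arg(family)
  if (!is.list(scores) || is.data.frame(scores))
    scores <- list(include = scores, exclude = scores)
  y_raw <- phenotypes[[outcome]]
  if (is.null(y_raw)) stop("outcome not found: ", outcome, call. = FALSE)
  y <- if (family == "linear" && int_outcome)
    inverse_normal_transform(y_raw) else y_raw
  have <- lapply(scores, colnames)
  miss <- unlist(lapply(unique(plan$apoe_mode), function(md)
    setdiff(paste0(plan$score_type[plan$apoe_mode == md], "_PRS",
                   plan$threshold[plan$apoe_mode == md]),
            have[[md]])))
  if (length(miss))
    stop("missing score column(s): ",
         paste(unique(miss), collapse = ", "), call. = FALSE)
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    md <- plan$apoe_mode[i]
    col <- paste0(plan$score_type[i], "_PRS", plan$threshold[i])
    covs <- covariates
    if (md == "exclude") covs <- c(covs, "apoe4_count", "apoe2_count")
    X <- as.matrix(phenotypes[, covs, drop = FALSE])
    score <- scores[[md]][, col]
    if (interaction) {
      fit <- interaction_test(y, score, phenotypes$abeta_status, X)
      info <- coef_row(fit, "score:abeta")
    } else {
      if (adjust_abeta) X <- cbind(X, abeta_status = phenotypes$abeta_status)
      D <- cbind(score = score, X)
      fit <- if (family == "linear") fit_linear(y, D)
             else fit_logistic(y, D)
      info <- coef_row(fit, "score")
    }
    rows[[i]] <- data.frame(outcome = outcome,
                            score_type = plan$score_type[i],
                            threshold = plan$threshold[i],
                            apoe_mode = md, n = fit$n,
                            beta = info$estimate, se = info$se,
                            statistic = info$statistic,
                            p_value = info$p_value,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_value)
  class(out) <- c("cellprs_assoc", "data.frame")
  out
}

#' Score-by-amyloid interaction test
#'
#' Fits `y ~ covariates + score + abeta + score:abeta` by OLS and
#' returns the fit; the interaction coefficient is the row named
#' `score:abeta`.
#'
#' @param y Numeric outcome (already transformed as desired).
#' @param score Standardized score vector.
#' @param abeta Amyloid status (0/1).
#' @param X Covariate matrix.
#' @return A `cellprs_fit` object.
#' @export
interaction_test <- function(y, score, abeta, X) {
  D <- cbind(score = score, abeta = abeta,
             `score:abeta` = score * abeta, X)
  fit_linear(y, D)
}

#' Attenuation test across APOE modes
#'
#' Compares the per-threshold association t-values of a score type
#' when the APOE region is included versus excluded.  The default
#' (`"paired"`) is a one-sample t-test on the differences, accounting
#' for the dependency among the nested PRS thresholds; a Welch
#' unpaired mode is available for sensitivity.
#'
#' @param t_incl,t_excl Equal-length numeric vectors of t (or z)
#'   statistics, paired by threshold.
#' @param mode `"paired"` (default) or `"welch"`.
#' @return A list with `statistic`, `p_value`, `df` and `mode`.
#' @export
attenuation_paired_t <- function(t_incl, t_excl,
                                 mode = c("paired", "welch")) {
  mode <- match.arg(mode)
  if (length(t_incl) != length(t_excl) || length(t_incl) < 2)
    stop("need equal-length vectors of length >= 2", call. = FALSE)
  if (mode == "paired") {
    d <- t_incl - t_excl
    if (stats::sd(d) == 0)
      stop("zero-variance differences; paired t-test undefined",
           call. = FALSE)
    tt <- stats::t.test(t_incl, t_excl, paired = TRUE)
  } else {
    tt <- stats::t.test(t_incl, t_excl, var.equal = FALSE)
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mode = mode)
}

#' Likelihood-ratio test for a score-by-time effect on decline
#'
#' Fits nested linear mixed models by maximum likelihood with random
#' intercept and slope per subject:
#' `outcome ~ covariates + score + time + score:time + (1 + time | id)`
#' against the model without the `score:time` term, and compares them
#' with a 1-df likelihood-ratio chi-square.
#'
#' @param data Long-format data.frame containing the outcome, `time`,
#'   the subject `id`, the score column and covariates.
#' @param outcome Outcome column name.
#' @param score Score column name.
#' @param covariates Covariate column names.
#' @param time,id Column names of the time variable and subject id.
#' @return A list with `chisq`, `df`, `p_value`, and the two fitted
#'   models (`full`, `reduced`); non-convergence yields a warning and
#'   `NA` statistics.
#' @export
longitudinal_lrt <- function(data, outcome, score,
                             covariates = base_covariates(),
                             time = "time", id = "id") {
  rhs0 <- paste(c(covariates, score, time), collapse = " + ")
  re <- sprintf("(1 + %s | %s)", time, id)
  f_full <- stats::as.formula(
    sprintf("%s ~ %s + %s:%s + %s", outcome, rhs0, score, time, re))
  f_red <- stats::as.formula(sprintf("%s ~ %s + %s", outcome, rhs0, re))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fits <- tryCatch({
    full <- lme4::lmer(f_full, data = data, REML = FALSE, control = ctrl)
    red <- lme4::lmer(f_red, data = data, REML = FALSE, control = ctrl)
    list(full = full, red = red)
  }, error = function(e) {
    warning("mixed model did not converge: ", conditionMessage(e))
    NULL
  })
  if (is.null(fits))
    return(list(chisq = NA_real_, df = 1L, p_value = NA_real_,
                full = NULL, reduced = NULL))
  chisq <- 2 * (as.numeric(stats::logLik(fits$full)) -
                  as.numeric(stats::logLik(fits$red)))
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(max(chisq, 0), df = 1,
                               lower.tail = FALSE),
       full = fits$full, reduced = fits$red)
}
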