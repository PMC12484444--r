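## score coefficient from y ~ intercept + score + covariates,
## via the same QR core as fit_linear (bit-identical estimates)
score_coef <- function(y, score, X) {
  D <- as_design(cbind(score = score, X))
  ols_core(y, D)$beta[["score"]]
}

#' Amyloid mediation by the difference-of-coefficients method
#'
#' Quantifies how much of a score's effect on a continuous outcome is
#' mediated by a third variable: the total effect `c` comes from
#' `y ~ covariates + score`, the direct effect `c'` from
#' `y ~ covariates + score + mediator`, the mediated (indirect) effect
#' is `c - c'` and the proportion mediated `(c - c') / c`.  A
#' nonparametric bootstrap resampling whole individuals with
#' replacement gives the percentile 95% confidence interval of the
#' mediated effect; the mediation is called significant when the CI
#' excludes 0.  A product-of-coefficients cross-check (`a * b` from
#' `mediator ~ score` and `y ~ mediator + score`) is available for
#' continuous mediators.
#'
#' @param y Continuous outcome (typically the inverse-normal
#'   transformed pTau217).
#' @param score Standardized PRS.
#' @param mediator Mediator variable (binary amyloid status or the
#'   continuous CSF ratio).
#' @param X Optional covariate matrix/data.frame.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param method `"difference"` (default, the c - c' estimator) or
#'   `"product"` (a * b cross-check).
#' @return A list of class `cellprs_mediation` with `c`, `c_prime`,
#'   `mediated`, `prop_mediated`, `prop_mediated_pct`, `ci_low`,
#'   `ci_high`, `significant`, `n_boot`, `seed`, `n`, `n_redrawn`.
#' @export
mediate_c_cprime <- function(y, score, mediator, X = NULL,
                             n_boot = 1000, seed = NULL,
                             method = c("difference", "product")) {
  method <- match.arg(method)
  keep <- stats::complete.cases(y, score, mediator,
                                if (is.null(X)) rep(TRUE, length(y)) else X)
  y <- y[keep]; score <- score[keep]; mediator <- mediator[keep]
  if (!is.null(X)) X <- as.matrix(X)[keep, , drop = FALSE]
  n <- length(y)
  if (stats::sd(mediator) == 0)
    stop("mediator is constant", call. = FALSE)
  Xm <- if (is.null(X)) NULL else X
  point <- function(yy, ss, mm, XX) {
    if (method == "difference") {
      cc <- score_coef(yy, ss, XX)
      cp <- score_coef(yy, ss, cbind(mediator = mm, XX))
      c(cc, cp, cc - cp)
    } else {
      a <- score_coef(mm, ss, XX)
      D <- as_design(cbind(mediator = mm, score = ss, XX))
      b <- ols_core(yy, D)$beta[["mediator"]]
      cc <- score_coef(yy, ss, XX)
      c(cc, cc - a * b, a * b)
    }
  }
  est <- point(y, score, mediator, Xm)
  c_tot <- est[1]; c_prime <- est[2]; mediated <- est[3]
  prop <- if (abs(c_tot) < 1e-10) NA_real_ else mediated / c_tot
  if (is.na(prop))
    warning("total effect is ~0; proportion mediated undefined")
  if (!is.null(seed)) set.seed(seed)
  boot <- numeric(n_boot)
  n_redrawn <- 0L
  b <- 1L
  while (b <= n_boot) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(
      point(y[idx], score[idx], mediator[idx],
            if (is.null(Xm)) NULL else Xm[idx, , drop = FALSE])[3],
      error = function(e) NA_real_)
    if (is.na(val)) {           # degenerate draw (e.g. constant column)
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 10L * n_boot)
        stop("bootstrap failed to produce valid draws", call. = FALSE)
      next
    }
    boot[b] <- val
    b <- b + 1L
  }
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  structure(list(c = c_tot, c_prime = c_prime, mediated = mediated,
                 prop_mediated = prop,
                 prop_mediated_pct = 100 * prop,
                 ci_low = ci[1], ci_high = ci[2],
                 significant = !is.na(ci[1]) && (ci[1] > 0 | ci[2] < 0),
                 n_boot = n_boot, seed = seed, n = n,
                 n_redrawn = n_redrawn, method = method),
            class = "cellprs_mediation")
}

#' @export
print.cellprs_mediation <- function(x, ...) {
  cat("<cellprs_mediation>", x$method, "estimator\n")
  cat(sprintf("  c = %.4f, c' = %.4f, mediated = %.4f\n",
              x$c, x$c_prime, x$mediated))
  cat(sprintf("  proportion mediated = %.1f%% (95%% CI of mediated effect: [%.4f, %.4f], %d bootstraps)\n",
              x$prop_mediated_pct, x$ci_low, x$ci_high, x$n_boot))
  cat("  significant:", x$significant, "\n")
  invisible(x)
}
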