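test_that("inverse normal transform follows the Blom convention", {
  x <- c(10, 2, 5)
  z <- inverse_normal_transform(x)
  ## n = 3: middle rank maps to qnorm(0.5) = 0
  expect_equal(z[3], 0)
  expect_equal(z[2], qnorm((1 - 3 / 8) / 3.25))
  expect_equal(z[2], -0.8694238, tolerance = 1e-6)
  expect_equal(z[1], -z[2])                  # symmetric ranks
  ## missing values stay missing, others unaffected
  z2 <- inverse_normal_transform(c(10, NA, 2, 5))
  expect_true(is.na(z2[2]))
  expect_equal(z2[-2], z)
  ## tie-free input correlates perfectly with normal quantiles
  set.seed(1)
  y <- rexp(100)
  expect_equal(cor(inverse_normal_transform(y),
                   qnorm((rank(y) - 3 / 8) / 100.25)), 1)
  expect_error(inverse_normal_transform(rep(1, 5)), "identical")
  expect_error(inverse_normal_transform(c(1, 2)), "3 non-missing")
})

test_that("OLS matches the normal-equations oracle", {
  X <- cbind(x1 = c(1, 2, 3, 4, 5), x2 = c(0, 1, 0, 1, 1))
  y <- c(1.2, 1.9, 3.4, 3.8, 5.3)
  fit <- fit_linear(y, X)
  Xd <- cbind(1, X)
  beta_o <- solve(t(Xd) %*% Xd, t(Xd) %*% y)[, 1]
  expect_equal(fit$coefficients$estimate, unname(beta_o),
               tolerance = 1e-10)
  res <- y - Xd %*% beta_o
  s2 <- sum(res^2) / (5 - 3)
  se_o <- sqrt(diag(solve(t(Xd) %*% Xd)) * s2)
  expect_equal(fit$coefficients$se, unname(se_o), tolerance = 1e-10)
  ## exact fit recovers the slope with zero residual
  fit2 <- fit_linear(2 * (1:6), cbind(x = 1:6))
  expect_equal(fit2$coefficients$estimate[2], 2)
  expect_equal(fit2$rss, 0, tolerance = 1e-20)
  ## collinear design errors with the column named
  expect_error(fit_linear(y, cbind(a = 1:5, b = 2 * (1:5))), "b")
})

test_that("OLS p-values are calibrated under the null", {
  set.seed(4)
  p <- replicate(300, {
    x <- rnorm(40); y <- rnorm(40)
    fit_linear(y, cbind(x = x))$coefficients$p_value[2]
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("logistic fit equals the closed-form log odds ratio", {
  ## 2x2 table: exposed 20/10, unexposed 10/20 -> OR = 4
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  fit <- fit_logistic(y, cbind(x = x))
  expect_equal(fit$coefficients$estimate[2], log(4), tolerance = 1e-6)
  ## Wald SE oracle for a 2x2 table: sqrt(sum of reciprocal counts)
  expect_equal(fit$coefficients$se[2], sqrt(1/20 + 1/10 + 1/10 + 1/20),
               tolerance = 1e-6)
  expect_error(fit_logistic(rep(1, 30), cbind(x = rnorm(30))),
               "both outcome classes")
  ## perfect separation is flagged, not silently returned
  xs <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic(xs, cbind(x = xs)), "converge")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    got <- bh_fdr(p)
    expect_equal(got, naive_bh(p), tolerance = 1e-12)
    expect_true(all(got >= p))
  }
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("the default plan enumerates 98 models per outcome", {
  plan <- default_assoc_plan()
  expect_equal(nrow(plan), 98L)
  expect_equal(length(unique(plan$score_type)), 7L)
  expect_equal(length(unique(plan$threshold)), 7L)
  expect_equal(length(unique(plan$apoe_mode)), 2L)
  small <- default_assoc_plan(score_types = "microglia",
                              apoe_modes = "include")
  expect_equal(nrow(small), 7L)
})

test_that("run_family fits the whole plan and applies family-wise FDR", {
  co <- simulate_cohort(small_cfg(seed = 31))
  run <- suppressMessages(suppressWarnings(
    run_pipeline(run_config(seed = 31, mediation_boot = 25,
                            sim = list(n_individuals = 300,
                                       n_variants = 120, n_genes = 30,
                                       cells_per_type = 30,
                                       discovery_n = 1500)),
                 cohort = co)))
  for (oc in c("abeta_status", "ptau217")) {
    res <- run$associations[[oc]]
    expect_equal(nrow(res), 98L)
    expect_true(all(res$p_fdr >= res$p_value))
    expect_equal(res$p_fdr, bh_fdr(res$p_value))
    expect_true(all(res$n == 300))
  }
  ## missing columns raise a listing error
  sm <- run$scores$include[, 1:3]
  expect_error(run_family(sm, co$phenotypes, "ptau217", "linear"),
               "missing score column")
})

test_that("identical p-values are their own BH fixed point in a family", {
  p <- rep(0.03, 98)
  expect_equal(bh_fdr(p), p)
})

test_that("interaction test recovers a pure interaction and stays calibrated", {
  set.seed(11)
  n <- 400
  score <- rnorm(n); ab <- rbinom(n, 1, 0.4); X <- cbind(age = rnorm(n))
  ## pure interaction: score matters only in amyloid positives
  y <- score * ab + rnorm(n, 0, 0.5)
  fit <- interaction_test(y, score, ab, X)
  co <- fit$coefficients
  expect_equal(co$term[which.max(abs(co$statistic[-1])) + 1],
               "score:abeta")
  expect_lt(co$p_value[co$term == "score:abeta"], 1e-10)
  ## hand-checked toy against the OLS oracle
  y8 <- c(1, 2, 3, 4, 2, 4, 6, 8)
  s8 <- c(1, 2, 3, 4, 1, 2, 3, 4)
  a8 <- rep(c(0, 1), each = 4)
  f8 <- interaction_test(y8, s8, a8, NULL)
  D <- cbind(1, s8, a8, s8 * a8)
  bo <- solve(t(D) %*% D, t(D) %*% y8)[, 1]
  expect_equal(f8$coefficients$estimate, unname(bo), tolerance = 1e-10)
})

test_that("paired attenuation t-test matches the closed form", {
  t_incl <- c(2, 3, 4, 5, 6, 7, 8)
  t_excl <- c(1, 1, 1, 1, 1, 1, 1)
  d <- t_incl - t_excl                      # 1..7
  res <- attenuation_paired_t(t_incl, t_excl)
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(7)))
  expect_equal(res$statistic, 4.89898, tolerance = 1e-5)
  ## sign flip negates t, keeps p
  res2 <- attenuation_paired_t(t_excl, t_incl)
  expect_equal(res2$statistic, -res$statistic)
  expect_equal(res2$p_value, res$p_value)
  expect_error(attenuation_paired_t(t_incl, t_incl), "zero-variance")
  ## Welch mode falls back to the unpaired test
  resw <- attenuation_paired_t(t_incl, t_excl, mode = "welch")
  expect_equal(resw$p_value,
               t.test(t_incl, t_excl, var.equal = FALSE)$p.value)
})

test_that("longitudinal LRT detects an injected score-by-time effect", {
  cfg <- small_cfg(seed = 41, cog_time_effect = c(microglia = 0.4))
  co <- simulate_cohort(cfg)
  long <- merge(co$longitudinal,
                co$phenotypes[, c("id", "age", "sex",
                                  paste0("PC", 1:10))], by = "id")
  long$score <- co$truth$scores[match(long$id, co$phenotypes$id),
                                "microglia"]
  r <- longitudinal_lrt(long, outcome = "mmse", score = "score")
  expect_lt(r$p_value, 1e-4)
  ## nesting: reduced log-likelihood cannot exceed the full model's
  expect_gte(r$chisq, -1e-6)
  ## no injected effect on the full score at a different seed: p not tiny
  cfg0 <- small_cfg(seed = 42)
  co0 <- simulate_cohort(cfg0)
  long0 <- merge(co0$longitudinal,
                 co0$phenotypes[, c("id", "age", "sex",
                                    paste0("PC", 1:10))], by = "id")
  long0$score <- rnorm(nrow(co0$phenotypes))[
    match(long0$id, co0$phenotypes$id)]
  r0 <- longitudinal_lrt(long0, outcome = "mmse", score = "score")
  expect_gt(r0$p_value, 1e-4)
})
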