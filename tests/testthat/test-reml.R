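test_that("restricted likelihood reduces to the closed-form OLS case", {
  set.seed(41)
  n <- 10
  X <- cbind(1, rnorm(n))
  y <- rnorm(n, 5, 2)
  sigma2 <- 1.7
  fit <- lm(y ~ X - 1)
  rss <- sum(resid(fit)^2)
  ll_closed <- -0.5 * ((n - 2) * log(sigma2) + log(det(crossprod(X))) +
                         rss / sigma2 + (n - 2) * log(2 * pi))
  ll <- reml_loglik(c(0, 0, sigma2), y, X, rep(1:2, each = 5), rep(1:5, each = 2))
  expect_equal(ll, ll_closed, tolerance = 1e-10)
})

test_that("rescaling data and components shifts the likelihood by its Jacobian", {
  set.seed(43)
  n <- 24
  sire <- rep(1:4, each = 6)
  dam <- rep(1:8, each = 3)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n, 10, 3)
  theta <- c(2, 1, 4)
  cc <- 3.7
  ll1 <- reml_loglik(theta, y, X, sire, dam)
  ll2 <- reml_loglik(cc^2 * theta, cc * y, X, sire, dam)
  expect_equal(ll2, ll1 - (n - 2) * log(cc), tolerance = 1e-8)
})

test_that("structured likelihood matches the dense error-contrast oracle", {
  set.seed(47)
  n <- 30
  sire <- rep(1:5, each = 6)
  dam <- rep(1:10, each = 3)
  X <- cbind(1, rnorm(n), runif(n))
  y <- rnorm(n, 10, 2)
  for (theta in list(c(1.3, 0.7, 2.1), c(0, 0.5, 1), c(3, 0, 0.4))) {
    ll_dense <- dense_reml_oracle(nested_V(theta, sire, dam), y, X)
    expect_equal(reml_loglik(theta, y, X, sire, dam), ll_dense, tolerance = 1e-8)
  }
  expect_error(reml_loglik(c(0, 0, 0), y, X, sire, dam), "singular")
})

test_that("balanced nested ANOVA oracle reproduces a hand-worked fixture", {
  # 2 sires x 2 dams x 2 daughters; MS_within = 2, MS_dam = 26, MS_sire = 8
  y <- c(1, 3, 5, 7, 2, 4, 8, 10)
  sire <- rep(c("s1", "s2"), each = 4)
  dam <- rep(c("d1", "d2", "d3", "d4"), each = 2)
  vc <- anova_oracle_balanced(y, sire, dam)
  expect_equal(unname(vc$MS), c(8, 26, 2))
  expect_equal(vc$V_resid, 2)
  expect_equal(vc$V_dam, 12)
  expect_equal(vc$V_sire, -4.5)

  expect_equal(anova_oracle_balanced(rep(3, 8), sire, dam)$V_resid, 0)
  expect_equal(anova_oracle_balanced(rep(3, 8), sire, dam)$V_sire, 0)

  expect_error(anova_oracle_balanced(y[-1], sire[-1], dam[-1]), "balanced")
})

test_that("REML equals the ANOVA oracle on balanced designs with interior optimum", {
  d <- balanced_nested_data(12, 3, 4, vs = 4, vd = 2, ve = 1, seed = 53)
  vc <- anova_oracle_balanced(d$y, d$sire_id, d$dam_id)
  fit <- fit_nested_lmm(d, "y")
  expect_gt(min(vc$V_sire, vc$V_dam, vc$V_resid), 0) # interior
  expect_equal(fit$V_sire, vc$V_sire, tolerance = 1e-6)
  expect_equal(fit$V_dam, vc$V_dam, tolerance = 1e-6)
  expect_equal(fit$V_resid, vc$V_resid, tolerance = 1e-6)
})

test_that("REML fit agrees with lme4 on an unbalanced design with covariates", {
  skip_if_not_installed("lme4")
  sim <- simulate_dataset(sim_config(n_sires = 25, seed = 59))
  rec <- derive_traits(filter_analysis_subset(sim$phenotypes))
  fit <- fit_nested_lmm(rec, "longevity", fixed = c("lifetime_matings", "start_date"))
  lf <- lme4::lmer(longevity ~ lifetime_matings + start_date +
                     (1 | sire_id) + (1 | dam_id), data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- stats::setNames(vc$vcov, vc$grp)
  expect_equal(fit$V_sire, unname(ref["sire_id"]), tolerance = 1e-4)
  expect_equal(fit$V_dam, unname(ref["dam_id"]), tolerance = 1e-4)
  expect_equal(fit$V_resid, unname(ref["Residual"]), tolerance = 1e-5)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lf)), tolerance = 1e-7)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
})

test_that("estimates are invariant to record order and identifier relabeling", {
  d <- balanced_nested_data(8, 3, 3, vs = 3, vd = 1.5, ve = 1, seed = 61)
  fit1 <- fit_nested_lmm(d, "y")
  set.seed(62)
  perm <- sample(nrow(d))
  d2 <- d[perm, ]
  d2$sire_id <- paste0("SIRE_", d2$sire_id)
  d2$dam_id <- paste0("DAM_", d2$dam_id)
  fit2 <- fit_nested_lmm(d2, "y")
  expect_equal(fit1$V_sire, fit2$V_sire, tolerance = 1e-7)
  expect_equal(fit1$V_dam, fit2$V_dam, tolerance = 1e-7)
  expect_equal(fit1$reml_loglik, fit2$reml_loglik, tolerance = 1e-9)
})

test_that("a truly zero observational dam variance is reported on the boundary", {
  # note the dam component here is the observational one: data with
  # full-sib covariance equal to half-sib covariance (no extra dam term)
  d <- balanced_nested_data(100, 3, 4, vs = 3, vd = 0, ve = 10, seed = 67)
  fit <- fit_nested_lmm(d, "y")
  V_P <- fit$V_sire + fit$V_dam + fit$V_resid
  expect_lt(fit$V_dam, 0.05 * V_P)
  expect_true(fit$converged)
})

test_that("Wald test matches the squared z-statistic and validates its input", {
  d <- balanced_nested_data(10, 3, 3, vs = 2, vd = 1, ve = 1, seed = 71)
  set.seed(72)
  d$x <- rnorm(nrow(d))
  fit <- fit_nested_lmm(d, "y", fixed = "x")
  w <- wald_test(fit, "x")
  z2 <- (fit$beta["x"] / sqrt(fit$beta_cov["x", "x"]))^2
  expect_equal(w$statistic, unname(z2))
  expect_equal(w$df, 1)
  expect_equal(w$p_value, pchisq(unname(z2), 1, lower.tail = FALSE))
  expect_error(wald_test(fit, "nope"), "not in the fitted model")
})

test_that("likelihood-ratio test detects strong sire variance and stays valid", {
  d <- balanced_nested_data(30, 3, 4, vs = 6, vd = 1, ve = 2, seed = 73)
  full <- fit_nested_lmm(d, "y")
  red <- fit_nested_lmm(d, "y", random = "dam_only")
  lrt <- lrt_random_effect(full, red)
  expect_identical(lrt$term, "sire")
  expect_gte(lrt$statistic, 0)
  expect_lt(lrt$p_value, 0.001)

  lrt_b <- lrt_random_effect(full, red, boundary_correction = TRUE)
  expect_equal(lrt_b$p_value, lrt$p_value / 2)

  # non-nested pairs and mismatched fixed effects are rejected
  set.seed(74)
  d$x <- rnorm(nrow(d))
  other <- fit_nested_lmm(d, "y", fixed = "x")
  expect_error(lrt_random_effect(full, other), "not comparable")
  expect_error(lrt_random_effect(red, full), "exactly one")
})

test_that("boundary-null LRT of the sire component is conservative", {
  # true V_sire = 0: the plain chi-square(1) reference should reject at
  # most ~5% of the time (about half the nominal rate is expected)
  set.seed(79)
  rej <- 0
  n_rep <- 150
  for (i in seq_len(n_rep)) {
    d <- balanced_nested_data(15, 3, 3, vs = 0, vd = 1, ve = 2,
                              seed = 8000 + i)
    full <- fit_nested_lmm(d, "y")
    red <- fit_nested_lmm(d, "y", random = "dam_only")
    p <- lrt_random_effect(full, red)$p_value
    rej <- rej + (p < 0.05)
  }
  expect_lte(rej / n_rep, 0.07)
})

test_that("backward Wald selection keeps strong effects and drops null ones", {
  cfg <- sim_config(n_sires = 60, seed = 83, beta_lifetime_matings = 0.8)
  sim <- simulate_dataset(cfg)
  rec <- derive_traits(filter_analysis_subset(sim$phenotypes))
  sel <- select_minimal_model(rec, "longevity",
                              candidates = c("lifetime_matings", "body_size"))
  expect_true("lifetime_matings" %in% sel$kept)
  expect_false("body_size" %in% sel$kept)
  expect_identical(sort(sel$fit_minimal$fixed), sort(sel$kept))
  expect_s3_class(sel$tests, "tbl_df")
})

test_that("tidy and glance expose coefficients and components", {
  d <- balanced_nested_data(6, 3, 3, vs = 2, vd = 1, ve = 1, seed = 89)
  set.seed(90)
  d$x <- rnorm(nrow(d))
  fit <- fit_nested_lmm(d, "y", fixed = "x")
  td <- tidy(fit)
  expect_setequal(td$term[td$effect == "ran_pars"], c("V_sire", "V_dam", "V_resid"))
  expect_true(all(c("(Intercept)", "x") %in% td$term[td$effect == "fixed"]))
  gl <- glance(fit)
  expect_identical(gl$n_obs, nrow(d))
  expect_identical(gl$n_sires, 6L)
})
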