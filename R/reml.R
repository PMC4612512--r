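#' @importFrom generics tidy glance
NULL

# ---- internal workspace -----------------------------------------------------
#
# All REML computations for the nested sire/dam(sire) model work on sufficient
# statistics precomputed once per dataset. Writing V = V_e (I + g_s Z_s Z_s' +
# g_d Z_d Z_d') and applying the Woodbury identity reduces every likelihood
# evaluation to a Cholesky of a q x q matrix (q = number of sires + dams),
# independent of n.

reml_workspace <- function(y, X, sire, dam) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n) stop("X and y dimensions differ", call. = FALSE)
  if (qr(X)$rank < p) stop("fixed-effect design matrix is rank deficient", call. = FALSE)
  sire <- as.character(sire)
  dam <- as.character(dam)
  Zs <- stats::model.matrix(~ 0 + factor(sire))
  Zd <- stats::model.matrix(~ 0 + factor(dam))
  Z <- cbind(Zs, Zd)
  grp <- rep(c("sire", "dam"), c(ncol(Zs), ncol(Zd)))
  list(y = y, X = X, n = n, p = p, sire = sire, dam = dam,
       Z = Z, grp = grp,
       ZtZ = crossprod(Z), ZtX = crossprod(Z, X), Zty = crossprod(Z, y),
       XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       n_sires = ncol(Zs), n_dams = ncol(Zd))
}

# Core GLS pieces for V0 = I + sum_j gamma_j Z_j Z_j' at given variance ratios.
# `gamma` is named with component names ("sire", "dam"); components with
# gamma = 0 are dropped exactly.
v0_solve <- function(ws, gamma) {
  active <- names(gamma)[gamma > 0]
  if (length(active) == 0) {
    M <- ws$XtX
    return(list(logdetV0 = 0, XtViX = M, XtViy = ws$Xty, yViy = ws$yty))
  }
  cols <- ws$grp %in% active
  gvec <- gamma[ws$grp[cols]]
  W <- ws$ZtZ[cols, cols, drop = FALSE]
  diag(W) <- diag(W) + 1 / gvec
  cW <- chol(W)
  Tx <- backsolve(cW, ws$ZtX[cols, , drop = FALSE], transpose = TRUE)
  Ty <- backsolve(cW, ws$Zty[cols, , drop = FALSE], transpose = TRUE)
  list(logdetV0 = 2 * sum(log(diag(cW))) + sum(log(gvec)),
       XtViX = ws$XtX - crossprod(Tx),
       XtViy = ws$Xty - crossprod(Tx, Ty),
       yViy = ws$yty - sum(Ty^2))
}

# Profiled (over beta and V_e) negative restricted log-likelihood.
profiled_negll <- function(log_gamma, ws, active) {
  gamma <- stats::setNames(exp(log_gamma), active)
  sol <- v0_solve(ws, gamma)
  cM <- tryCatch(chol(sol$XtViX), error = function(e) NULL)
  if (is.null(cM)) return(1e10)
  beta <- backsolve(cM, backsolve(cM, sol$XtViy, transpose = TRUE))
  rss <- drop(sol$yViy - crossprod(sol$XtViy, beta))
  if (!is.finite(rss) || rss <= 0) return(1e10)
  df <- ws$n - ws$p
  0.5 * (df * log(rss / df) + sol$logdetV0 + 2 * sum(log(diag(cM))) +
           df * (1 + log(2 * pi)))
}

# Full restricted log-likelihood at explicit theta = (V_sire, V_dam, V_resid).
reml_loglik_ws <- function(theta, ws) {
  Vs <- theta[1]; Vd <- theta[2]; Ve <- theta[3]
  if (any(theta < 0)) stop("variance components must be non-negative", call. = FALSE)
  if (Ve <= 0) {
    # no Woodbury scaling possible; fall back to a dense factorization
    V <- Vs * tcrossprod(ws$Z[, ws$grp == "sire", drop = FALSE]) +
      Vd * tcrossprod(ws$Z[, ws$grp == "dam", drop = FALSE])
    ch <- tryCatch(chol(V), error = function(e)
      stop("covariance matrix is singular at the supplied components", call. = FALSE))
    u1 <- backsolve(ch, ws$y, transpose = TRUE)
    u2 <- backsolve(ch, ws$X, transpose = TRUE)
    M <- crossprod(u2)
    cM <- chol(M)
    beta <- backsolve(cM, backsolve(cM, crossprod(u2, u1), transpose = TRUE))
    yPy <- sum(u1^2) - drop(crossprod(crossprod(u2, u1), beta))
    return(drop(-0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cM))) + yPy +
                          (ws$n - ws$p) * log(2 * pi))))
  }
  gamma <- stats::setNames(c(Vs, Vd) / Ve, c("sire", "dam"))
  sol <- v0_solve(ws, gamma)
  cM <- chol(sol$XtViX)
  beta <- backsolve(cM, backsolve(cM, sol$XtViy, transpose = TRUE))
  yPy0 <- drop(sol$yViy - crossprod(sol$XtViy, beta))
  drop(-0.5 * ((ws$n - ws$p) * log(Ve) + sol$logdetV0 + 2 * sum(log(diag(cM))) +
                 yPy0 / Ve + (ws$n - ws$p) * log(2 * pi)))
}

#' Restricted log-likelihood of the nested sire/dam mixed model
#'
#' Evaluates the REML (restricted) log-likelihood of the Gaussian linear
#' mixed model with marginal covariance
#' `V = V_sire Z_s Z_s' + V_dam Z_d Z_d' + V_resid I` at the supplied
#' variance components, with fixed effects profiled out on error contrasts.
#'
#' @param theta Numeric vector `c(V_sire, V_dam, V_resid)`, all non-negative.
#' @param y Response vector.
#' @param X Fixed-effect design matrix (including intercept), full column rank.
#' @param sire_ids,dam_ids Grouping vectors, one entry per observation.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(theta, y, X, sire_ids, dam_ids) {
  ws <- reml_workspace(y, X, sire_ids, dam_ids)
  reml_loglik_ws(as.numeric(theta), ws)
}

# ---- fitting ----------------------------------------------------------------

#' Fit the nested sire/dam(sire) linear mixed model by REML
#'
#' Estimates sire, dam-within-sire and residual variance components of a
#' paternal half-sib design by restricted maximum likelihood, together with
#' fixed-effect coefficients and their covariance. Optimization is over
#' log variance ratios with the residual variance and coefficients profiled
#' out, multi-started, with exact handling of boundary (zero) components:
#' estimates below `1e-8` of the phenotypic variance are reported as exact 0.
#'
#' @param data Tibble of analysis records (see [derive_traits()]) with
#'   columns `sire_id`, `dam_id`, the response and any covariates.
#' @param response Name of the response column.
#' @param fixed Character vector of fixed covariate column names (an
#'   intercept is always included).
#' @param transform `"none"` or `"log1p"` (natural log(x+1) applied to the
#'   response before fitting).
#' @param random Random structure: `"sire_dam"` (default), or the reduced
#'   structures `"sire_only"` / `"dam_only"` used for likelihood-ratio tests.
#' @param starts Optional list of numeric start vectors for the log variance
#'   ratios (advanced).
#' @return Object of class `sib_fit` with components `V_sire`, `V_dam`,
#'   `V_resid`, `beta`, `beta_cov`, `reml_loglik`, `n_obs`, `n_sires`,
#'   `n_dams`, `converged`.
#' @seealso [reml_loglik()], [anova_oracle_balanced()], [wald_test()],
#'   [lrt_random_effect()]
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_sires = 20, seed = 3))
#' rec <- derive_traits(filter_analysis_subset(sim$phenotypes))
#' fit <- fit_nested_lmm(rec, "longevity", fixed = "lifetime_matings")
#' tidy(fit)
fit_nested_lmm <- function(data, response, fixed = character(),
                           transform = c("none", "log1p"),
                           random = c("sire_dam", "sire_only", "dam_only"),
                           starts = NULL) {
  transform <- match.arg(transform)
  random <- match.arg(random)
  stopifnot(all(c("sire_id", "dam_id", response, fixed) %in% names(data)))
  y <- as.numeric(data[[response]])
  if (transform == "log1p") y <- log1p_transform(y)
  X <- cbind(`(Intercept)` = 1, as.matrix(data[fixed]))
  ws <- reml_workspace(y, X, data$sire_id, data$dam_id)
  if (ws$n_sires < 2) stop("need at least 2 sire families", call. = FALSE)

  active <- switch(random,
                   sire_dam = c("sire", "dam"),
                   sire_only = "sire",
                   dam_only = "dam")
  k <- length(active)
  if (is.null(starts)) starts <- list(rep(log(0.25), k), rep(log(0.02), k))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, profiled_negll, ws = ws, active = active,
                        method = "L-BFGS-B", lower = -30, upper = 15,
                        control = list(factr = 1e5, maxit = 200))
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  gamma <- stats::setNames(exp(best$par), active)
  sol <- v0_solve(ws, gamma)
  cM <- chol(sol$XtViX)
  beta0 <- backsolve(cM, backsolve(cM, sol$XtViy, transpose = TRUE))
  rss <- drop(sol$yViy - crossprod(sol$XtViy, beta0))
  sigma2 <- rss / (ws$n - ws$p)

  V_sire <- if ("sire" %in% active) unname(gamma["sire"]) * sigma2 else 0
  V_dam <- if ("dam" %in% active) unname(gamma["dam"]) * sigma2 else 0
  V_resid <- sigma2
  V_P <- V_sire + V_dam + V_resid
  if (V_sire < 1e-8 * V_P) V_sire <- 0
  if (V_dam < 1e-8 * V_P) V_dam <- 0

  theta <- c(V_sire = V_sire, V_dam = V_dam, V_resid = V_resid)
  ll <- reml_loglik_ws(unname(theta), ws)
  # fixed-effect covariance from the inverse expected information (GLS form)
  gamma_fin <- stats::setNames(c(V_sire, V_dam) / V_resid, c("sire", "dam"))
  sol_fin <- v0_solve(ws, gamma_fin)
  beta_cov <- solve(sol_fin$XtViX) * V_resid
  beta <- stats::setNames(drop(solve(sol_fin$XtViX, sol_fin$XtViy)), colnames(X))
  dimnames(beta_cov) <- list(colnames(X), colnames(X))

  structure(list(
    response = response, fixed = fixed, transform = transform, random = random,
    V_sire = V_sire, V_dam = V_dam, V_resid = V_resid,
    beta = beta, beta_cov = beta_cov,
    reml_loglik = ll,
    n_obs = ws$n, n_sires = ws$n_sires, n_dams = ws$n_dams,
    converged = best$convergence == 0,
    y = y, X = X, data = data
  ), class = "sib_fit")
}

#' @export
print.sib_fit <- function(x, ...) {
  cat(sprintf("Nested sire/dam REML fit: %s%s\n", x$response,
              if (x$transform == "log1p") " (log1p scale)" else ""))
  cat(sprintf("  n = %d (%d sires, %d dams); REML logLik = %.4f%s\n",
              x$n_obs, x$n_sires, x$n_dams, x$reml_loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  V_sire = %.4g, V_dam = %.4g, V_resid = %.4g\n",
              x$V_sire, x$V_dam, x$V_resid))
  invisible(x)
}

#' @rdname fit_nested_lmm
#' @param x A `sib_fit` object.
#' @param effects Which terms to return: fixed effects, variance components,
#'   or both.
#' @param ... Unused.
#' @export
tidy.sib_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  out <- list()
  if ("fixed" %in% effects) {
    se <- sqrt(diag(x$beta_cov))
    out$fixed <- tibble::tibble(
      effect = "fixed", term = names(x$beta),
      estimate = unname(x$beta), std.error = unname(se),
      statistic = unname((x$beta / se)^2),
      p.value = stats::pchisq(unname((x$beta / se)^2), 1, lower.tail = FALSE))
  }
  if ("ran_pars" %in% effects) {
    out$ran <- tibble::tibble(
      effect = "ran_pars",
      term = c("V_sire", "V_dam", "V_resid"),
      estimate = c(x$V_sire, x$V_dam, x$V_resid),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
  }
  dplyr::bind_rows(out)
}

#' @rdname fit_nested_lmm
#' @export
glance.sib_fit <- function(x, ...) {
  tibble::tibble(n_obs = x$n_obs, n_sires = x$n_sires, n_dams = x$n_dams,
                 V_sire = x$V_sire, V_dam = x$V_dam, V_resid = x$V_resid,
                 logLik = x$reml_loglik, converged = x$converged)
}

# ---- independent moment estimator -------------------------------------------

#' Nested ANOVA variance components for a balanced design
#'
#' Method-of-moments (expected mean squares) estimator for a perfectly
#' balanced sire/dam(sire) design with no covariates: with `k` daughters per
#' dam and `d` dams per sire, `V_resid = MS_within`,
#' `V_dam = (MS_dam - MS_within)/k`, `V_sire = (MS_sire - MS_dam)/(k d)`.
#' Estimates may be negative; they are returned as computed. Serves as an
#' independent oracle for the REML fit, with which it coincides on balanced
#' designs whenever all estimates are positive.
#'
#' @param y Response vector.
#' @param sire_ids,dam_ids Balanced grouping vectors.
#' @return List with `V_sire`, `V_dam`, `V_resid`, the mean squares and
#'   degrees of freedom.
#' @export
anova_oracle_balanced <- function(y, sire_ids, dam_ids) {
  y <- as.numeric(y)
  sire <- as.character(sire_ids)
  dam <- as.character(dam_ids)
  dam_sizes <- table(dam)
  dams_per_sire <- table(vapply(split(dam, sire), function(d) length(unique(d)), integer(1)))
  if (length(unique(as.integer(dam_sizes))) != 1 || length(dams_per_sire) != 1)
    stop("design is not balanced; the expected-mean-squares oracle requires balance",
         call. = FALSE)
  k <- as.integer(dam_sizes[1])
  d <- as.integer(names(dams_per_sire))
  s <- length(unique(sire))
  n <- length(y)
  stopifnot(n == s * d * k)

  gm <- mean(y)
  dam_means <- tapply(y, dam, mean)
  sire_means <- tapply(y, sire, mean)
  dam_of <- tapply(sire, dam, function(x) x[1])

  ss_within <- sum((y - dam_means[dam])^2)
  ss_dam <- k * sum((dam_means - sire_means[dam_of])^2)
  ss_sire <- k * d * sum((sire_means - gm)^2)
  df_within <- n - s * d
  df_dam <- s * (d - 1)
  df_sire <- s - 1
  ms_within <- ss_within / df_within
  ms_dam <- ss_dam / df_dam
  ms_sire <- ss_sire / df_sire

  list(V_sire = (ms_sire - ms_dam) / (k * d),
       V_dam = (ms_dam - ms_within) / k,
       V_resid = ms_within,
       MS = c(sire = ms_sire, dam = ms_dam, within = ms_within),
       df = c(sire = df_sire, dam = df_dam, within = df_within))
}

# ---- tests on fits ----------------------------------------------------------

#' Wald chi-square test of a fixed effect
#'
#' Computes the Wald statistic `b' Cov(b)^{-1} b` for the coefficients of a
#' fitted fixed-effect term, with degrees of freedom equal to the number of
#' coefficients and the p-value from the upper tail of the chi-square
#' distribution.
#'
#' @param fit A [fit_nested_lmm()] object.
#' @param term Name of a fitted fixed-effect term.
#' @return One-row tibble: `kind`, `term`, `statistic`, `df`, `p_value`.
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "sib_fit"))
  idx <- which(names(fit$beta) == term)
  if (length(idx) == 0)
    stop("term '", term, "' is not in the fitted model", call. = FALSE)
  b <- fit$beta[idx]
  C <- fit$beta_cov[idx, idx, drop = FALSE]
  stat <- drop(crossprod(b, solve(C, b)))
  tibble::tibble(kind = "wald", term = term, statistic = stat,
                 df = length(idx),
                 p_value = stats::pchisq(stat, length(idx), lower.tail = FALSE))
}

#' Likelihood-ratio test of a random variance component
#'
#' Compares two nested REML fits differing by exactly one random component
#' (same response, transform and fixed effects). The statistic is twice the
#' log-likelihood difference, floored at zero, referred to a chi-square with
#' 1 df. Because the null places the variance on the boundary of its
#' parameter space, the plain chi-square reference is conservative; a 50:50
#' mixture correction halving the p-value is available via
#' `boundary_correction = TRUE` (off by default).
#'
#' @param fit_full,fit_reduced `sib_fit` objects; `fit_reduced` must drop one
#'   random component present in `fit_full`.
#' @param boundary_correction Use the 0.5*chi2_0 + 0.5*chi2_1 mixture null.
#' @return One-row tibble: `kind`, `term`, `statistic`, `df`, `p_value`.
#' @export
lrt_random_effect <- function(fit_full, fit_reduced, boundary_correction = FALSE) {
  stopifnot(inherits(fit_full, "sib_fit"), inherits(fit_reduced, "sib_fit"))
  if (fit_full$response != fit_reduced$response ||
      fit_full$transform != fit_reduced$transform ||
      !identical(sort(fit_full$fixed), sort(fit_reduced$fixed)))
    stop("fits are not comparable (different response, transform or fixed effects)",
         call. = FALSE)
  comps <- list(sire_dam = c("sire", "dam"), sire_only = "sire", dam_only = "dam")
  full_c <- comps[[fit_full$random]]
  red_c <- comps[[fit_reduced$random]]
  dropped <- setdiff(full_c, red_c)
  if (length(dropped) != 1 || !all(red_c %in% full_c))
    stop("reduced model must drop exactly one random component of the full model",
         call. = FALSE)
  stat <- max(0, 2 * (fit_full$reml_loglik - fit_reduced$reml_loglik))
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)
  if (boundary_correction) p <- if (stat == 0) 1 else 0.5 * p
  tibble::tibble(kind = "lrt", term = dropped, statistic = stat, df = 1,
                 p_value = p)
}

#' Backward-select significant fixed effects
#'
#' Fits the model with all candidate covariates, Wald-tests each, and
#' retains (in a single pass) only those with `p < alpha`; the intercept is
#' always kept. The returned minimal model is refitted on the retained
#' terms.
#'
#' @inheritParams fit_nested_lmm
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Retention threshold for the Wald p-value.
#' @return List of class `sib_selection`: `kept` (character), `tests`
#'   (tibble of Wald tests from the full model), `fit_full`, `fit_minimal`.
#' @export
select_minimal_model <- function(data, response, candidates, alpha = 0.05,
                                 transform = c("none", "log1p"),
                                 random = "sire_dam") {
  transform <- match.arg(transform)
  fit_full <- fit_nested_lmm(data, response, fixed = candidates,
                             transform = transform, random = random)
  tests <- purrr::map_dfr(candidates, function(tm) wald_test(fit_full, tm))
  kept <- tests$term[tests$p_value < alpha]
  fit_min <- fit_nested_lmm(data, response, fixed = kept,
                            transform = transform, random = random)
  structure(list(kept = kept, tests = tests, alpha = alpha,
                 fit_full = fit_full, fit_minimal = fit_min),
            class = "sib_selection")
}

#' @export
print.sib_selection <- function(x, ...) {
  cat("Backward Wald selection (alpha =", x$alpha, ")\n")
  print(x$tests)
  cat("retained:", if (length(x$kept)) paste(x$kept, collapse = ", ") else "(intercept only)", "\n")
  invisible(x)
}
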