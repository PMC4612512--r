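#' Additive genetic variance from the sire component
#'
#' Under a paternal half-sib design the between-sire variance equals one
#' quarter of the additive genetic variance, so `V_A = 4 V_sire`.
#'
#' @param V_sire Non-negative sire variance component.
#' @return `4 * V_sire`.
#' @export
#' @examples
#' additive_variance(12.602)
additive_variance <- function(V_sire) {
  if (any(V_sire < 0)) stop("V_sire must be non-negative", call. = FALSE)
  4 * V_sire
}

#' Total phenotypic variance as the sum of observational components
#'
#' @param vc A [fit_nested_lmm()] object, or a numeric vector
#'   `c(V_sire, V_dam, V_resid)`.
#' @return `V_sire + V_dam + V_resid`.
#' @export
phenotypic_variance <- function(vc) {
  if (inherits(vc, "sib_fit")) vc <- c(vc$V_sire, vc$V_dam, vc$V_resid)
  if (any(vc < 0)) stop("variance components must be non-negative", call. = FALSE)
  sum(vc)
}

#' Narrow-sense heritability
#'
#' @param V_A Additive genetic variance.
#' @param V_P Total phenotypic variance (must be positive).
#' @return `V_A / V_P`.
#' @export
heritability <- function(V_A, V_P) {
  if (any(V_P <= 0)) stop("V_P must be positive", call. = FALSE)
  V_A / V_P
}

#' Mean-standardized evolvability statistics
#'
#' Computes the coefficient of additive genetic variation
#' `CV_A = sqrt(V_A)/mean`, the coefficients of phenotypic and residual
#' variation `CV_P = sqrt(V_P)/mean` and `CV_R = sqrt(V_P - V_A)/mean`, and
#' the mean-squared-standardized evolvability `I_A = V_A/mean^2`. These
#' satisfy the identity `CV_A^2 + CV_R^2 = CV_P^2` exactly.
#'
#' @param V_A Additive genetic variance (`0 <= V_A <= V_P`).
#' @param V_P Total phenotypic variance.
#' @param mean Trait mean (positive).
#' @return Named list with `CV_A`, `CV_P`, `CV_R`, `I_A`.
#' @export
#' @examples
#' evolvability_stats(50.410, 96.393, 40.460)
evolvability_stats <- function(V_A, V_P, mean) {
  if (mean <= 0) stop("trait mean must be positive", call. = FALSE)
  if (V_A < 0 || V_P < 0) stop("variances must be non-negative", call. = FALSE)
  if (V_A > V_P)
    stop("V_A exceeds V_P; CV_R is undefined", call. = FALSE)
  list(CV_A = sqrt(V_A) / mean,
       CV_P = sqrt(V_P) / mean,
       CV_R = sqrt(V_P - V_A) / mean,
       I_A = V_A / mean^2)
}

# Parameter vector computed from a fitted model; shared by the point
# estimate and every jackknife replicate.
params_from_fit <- function(fit, mean_y) {
  V_A <- additive_variance(fit$V_sire)
  V_P <- phenotypic_variance(fit)
  ev <- evolvability_stats(min(V_A, V_P), V_P, mean_y)
  c(mean = mean_y, V_sire = fit$V_sire, V_dam = fit$V_dam,
    V_R = fit$V_resid, V_A = V_A, V_P = V_P,
    h2 = heritability(V_A, V_P),
    CV_A = ev$CV_A, CV_P = ev$CV_P, CV_R = ev$CV_R, I_A = ev$I_A)
}

#' Delete-one-group jackknife standard errors
#'
#' Applies `estimator` to the full data and to every leave-one-group-out
#' subset, and returns the jackknife standard error
#' `sqrt((n-1)/n * sum((theta_i - theta_bar)^2))` over the `n` groups for
#' every element of the estimator's result. No pseudovalue bias correction
#' is applied to the point estimate.
#'
#' @param data Tibble of records.
#' @param estimator Function taking a data subset and returning a named
#'   numeric vector.
#' @param group Name of the grouping column (default `"sire_id"`).
#' @return List with `estimate` (full-data result), `se`, `replicates`
#'   (matrix, one row per deleted group) and `n_groups`.
#' @export
#' @examples
#' d <- tibble::tibble(sire_id = rep(letters[1:5], each = 3), y = rnorm(15))
#' jackknife_se(d, function(x) c(mean = mean(x$y)))$se
jackknife_se <- function(data, estimator, group = "sire_id") {
  groups <- unique(data[[group]])
  n <- length(groups)
  if (n < 3) stop("jackknife requires at least 3 groups", call. = FALSE)
  full <- estimator(data)
  reps <- matrix(NA_real_, n, length(full),
                 dimnames = list(as.character(groups), names(full)))
  for (i in seq_len(n)) {
    sub <- data[data[[group]] != groups[i], , drop = FALSE]
    est <- tryCatch(estimator(sub), error = function(e)
      stop("estimator failed with group '", groups[i], "' deleted: ",
           conditionMessage(e), call. = FALSE))
    reps[i, ] <- est
  }
  center <- colMeans(reps)
  se <- sqrt((n - 1) / n * colSums((reps - rep(center, each = n))^2))
  list(estimate = full, se = se, replicates = reps, n_groups = n)
}

#' Quantitative-genetic parameters of a trait with jackknife standard errors
#'
#' High-level wrapper for one trait: optionally backward-selects significant
#' fixed effects by Wald tests (selection may be run on a transformed scale
#' while the genetic parameters are always extracted from the untransformed
#' fit, since mean-standardized evolvabilities are not comparable across
#' studies when computed on a transformed scale), fits the minimal nested
#' sire/dam REML model, converts its components to
#' `V_A = 4 V_sire`, `V_P`, `h2`, `CV_A`, `CV_P`, `CV_R`, `I_A`, and
#' attaches delete-one-sire-family jackknife standard errors, refitting the
#' full REML pipeline (with the selected terms held fixed) on every
#' leave-one-out subset. Likelihood-ratio tests of the sire and dam
#' components are reported alongside.
#'
#' @param data Analysis records (see [derive_traits()]).
#' @param response Trait column name.
#' @param candidates Candidate fixed covariates for selection. If
#'   `select = FALSE` they are all retained.
#' @param alpha Wald retention threshold.
#' @param select Run backward Wald selection (default `TRUE`).
#' @param select_transform Scale on which selection Wald tests are run
#'   (`"none"` or `"log1p"`); parameters always come from the untransformed
#'   fit.
#' @param jackknife Attach jackknife SEs (refits once per sire family).
#' @return Object of class `gparams`; use [tidy.gparams()] for a tibble.
#' @export
genetic_parameters <- function(data, response, candidates = character(),
                               alpha = 0.05, select = TRUE,
                               select_transform = "none",
                               jackknife = TRUE) {
  if (select && length(candidates)) {
    sel <- select_minimal_model(data, response, candidates, alpha = alpha,
                                transform = select_transform)
    kept <- sel$kept
  } else {
    sel <- NULL
    kept <- candidates
  }
  fit <- fit_nested_lmm(data, response, fixed = kept, transform = "none")
  est_fun <- function(d) {
    f <- fit_nested_lmm(d, response, fixed = kept, transform = "none")
    params_from_fit(f, mean(as.numeric(d[[response]])))
  }
  estimate <- params_from_fit(fit, mean(as.numeric(data[[response]])))
  mean_se <- stats::sd(as.numeric(data[[response]])) / sqrt(nrow(data))
  if (jackknife) {
    jk <- jackknife_se(data, est_fun, group = "sire_id")
    se <- jk$se
    n_jk <- jk$n_groups
  } else {
    se <- stats::setNames(rep(NA_real_, length(estimate)), names(estimate))
    n_jk <- 0L
  }
  se["mean"] <- mean_se

  lrt_sire <- lrt_random_effect(fit, fit_nested_lmm(data, response, fixed = kept,
                                                    random = "dam_only"))
  lrt_dam <- lrt_random_effect(fit, fit_nested_lmm(data, response, fixed = kept,
                                                   random = "sire_only"))

  structure(list(trait = response, estimate = estimate, se = se,
                 n_obs = fit$n_obs, n_sires = fit$n_sires, n_dams = fit$n_dams,
                 n_sires_jackknifed = n_jk,
                 fit = fit, selection = sel,
                 lrt = dplyr::bind_rows(lrt_sire, lrt_dam)),
            class = "gparams")
}

#' @rdname genetic_parameters
#' @param x A `gparams` object.
#' @param ... Unused.
#' @export
tidy.gparams <- function(x, ...) {
  tibble::tibble(trait = x$trait, parameter = names(x$estimate),
                 estimate = unname(x$estimate),
                 std.error = unname(x$se[names(x$estimate)]))
}

#' @rdname genetic_parameters
#' @export
glance.gparams <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_obs = x$n_obs, n_sires = x$n_sires,
                 n_dams = x$n_dams, h2 = unname(x$estimate["h2"]),
                 h2_se = unname(x$se["h2"]),
                 p_sire = x$lrt$p_value[x$lrt$term == "sire"],
                 p_dam = x$lrt$p_value[x$lrt$term == "dam"])
}

#' @export
print.gparams <- function(x, ...) {
  cat(sprintf("Quantitative-genetic parameters: %s (n = %d; %d sires, %d dams)\n",
              x$trait, x$n_obs, x$n_sires, x$n_dams))
  print(tidy(x), n = Inf)
  invisible(x)
}
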