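#' Simulation configuration for a nested full-sib/half-sib breeding design
#'
#' Describes the generative model for a paternal half-sib breeding design in
#' which each sire is mated to several dams and several daughters per dam are
#' assayed for longevity and lifetime mating behaviour. Two genetically
#' correlated traits are simulated under the infinitesimal model: longevity
#' (days) and a latent mating propensity expressed, per mating opportunity, as
#' a Bernoulli acceptance through the inverse-logit link.
#'
#' Defaults emulate a laboratory *Drosophila melanogaster* assay: 72 sires,
#' 3 dams per sire, 4 assayed daughters per dam, mating opportunities every
#' Monday/Wednesday/Friday (2-2-3 day gaps) from age 3 days until death,
#' mean longevity about 40 days with additive variance 50 days^2
#' (heritability about 0.5), a mean per-opportunity acceptance probability of
#' 0.35, a genetic correlation of -0.65 between longevity and mating
#' propensity, and 12% attrition from escapes/accidental deaths.
#'
#' @param n_sires Number of sire families.
#' @param n_dams_per_sire Dams mated to each sire.
#' @param n_daughters_per_dam Assayed daughters per dam family.
#' @param G 2x2 additive genetic covariance matrix; trait 1 is longevity
#'   (days^2), trait 2 the latent logit-scale mating propensity.
#' @param V_dam Length-2 vector of dam/common-environment variances per trait.
#' @param V_resid Length-2 vector of residual variances per trait.
#' @param trait_means Length-2 vector: mean longevity (days, must be positive)
#'   and mean latent propensity (logit scale).
#' @param beta_lifetime_matings Increment of longevity (days) per accepted
#'   mating, creating a positive phenotypic dependence of longevity on
#'   lifetime mating count.
#' @param beta_start_date Slope of longevity (days) per day of assay start
#'   offset (batch effect).
#' @param n_batches Number of distinct assay start dates; each dam family is
#'   assigned one uniformly at random.
#' @param opportunity_schedule Vector of inter-opportunity gaps in days,
#'   recycled; the default `c(2, 2, 3)` is the Mon/Wed/Fri cadence.
#' @param first_opportunity_day Age (days) at the first mating opportunity.
#' @param attrition_prob Probability that a female escapes or is accidentally
#'   killed (her record is flagged, not removed).
#' @param seed Integer seed used by [simulate_dataset()] unless overridden.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [sample_breeding_values()]
#' @export
#' @examples
#' cfg <- sim_config(n_sires = 10, seed = 42)
#' cfg$true_h2
sim_config <- function(n_sires = 72,
                       n_dams_per_sire = 3,
                       n_daughters_per_dam = 4,
                       G = matrix(c(50, -0.65 * sqrt(50 * 0.5),
                                    -0.65 * sqrt(50 * 0.5), 0.5), 2, 2),
                       V_dam = c(0, 0.1),
                       V_resid = c(46, 0.4),
                       trait_means = c(40.5, stats::qlogis(0.35)),
                       beta_lifetime_matings = 0.5,
                       beta_start_date = -0.2,
                       n_batches = 10,
                       opportunity_schedule = c(2, 2, 3),
                       first_opportunity_day = 3,
                       attrition_prob = 0.12,
                       seed = 1L) {
  G <- as.matrix(G)
  if (!isTRUE(all.equal(dim(G), c(2L, 2L))) || !isTRUE(all.equal(G[1, 2], G[2, 1])))
    stop("`G` must be a symmetric 2x2 matrix", call. = FALSE)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`G` must be positive semidefinite", call. = FALSE)
  if (length(V_dam) != 2 || any(V_dam < 0)) stop("`V_dam` must be 2 non-negative variances", call. = FALSE)
  if (length(V_resid) != 2 || any(V_resid < 0)) stop("`V_resid` must be 2 non-negative variances", call. = FALSE)
  if (n_sires < 1 || n_dams_per_sire < 1 || n_daughters_per_dam < 1)
    stop("design counts must be positive", call. = FALSE)
  if (trait_means[1] <= 0)
    stop("mean longevity must be positive", call. = FALSE)
  if (any(opportunity_schedule <= 0)) stop("opportunity gaps must be positive days", call. = FALSE)
  if (attrition_prob < 0 || attrition_prob > 1) stop("`attrition_prob` must be in [0, 1]", call. = FALSE)

  cfg <- list(
    n_sires = as.integer(n_sires),
    n_dams_per_sire = as.integer(n_dams_per_sire),
    n_daughters_per_dam = as.integer(n_daughters_per_dam),
    G = G, V_dam = as.numeric(V_dam), V_resid = as.numeric(V_resid),
    trait_means = as.numeric(trait_means),
    beta_lifetime_matings = beta_lifetime_matings,
    beta_start_date = beta_start_date,
    n_batches = as.integer(n_batches),
    opportunity_schedule = as.numeric(opportunity_schedule),
    first_opportunity_day = as.numeric(first_opportunity_day),
    attrition_prob = attrition_prob,
    seed = as.integer(seed)
  )
  cfg$true_h2 <- diag(G) / (diag(G) + cfg$V_dam + cfg$V_resid)
  cfg$true_r_g <- if (G[1, 1] > 0 && G[2, 2] > 0) G[1, 2] / sqrt(G[1, 1] * G[2, 2]) else 0
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Half-sib breeding design simulation configuration\n")
  cat(sprintf("  %d sires x %d dams x %d daughters = %d females\n",
              x$n_sires, x$n_dams_per_sire, x$n_daughters_per_dam,
              x$n_sires * x$n_dams_per_sire * x$n_daughters_per_dam))
  cat(sprintf("  true h2: longevity %.3f, mating propensity %.3f; true r_g %.3f\n",
              x$true_h2[1], x$true_h2[2], x$true_r_g))
  invisible(x)
}

# Draw from N(0, Sigma) via the symmetric eigenvalue square root; tolerates
# singular (PSD) Sigma, unlike a plain Cholesky.
mvn_sample <- function(n, Sigma) {
  e <- eigen(Sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(stats::rnorm(n * ncol(Sigma)), n, ncol(Sigma))
  z %*% (t(e$vectors) * sqrt(lam))
}

id_pad <- function(prefix, i) sprintf("%s%03d", prefix, i)

# Family structure shared by all generators: one row per daughter with ids.
design_frame <- function(cfg) {
  sire <- rep(seq_len(cfg$n_sires), each = cfg$n_dams_per_sire * cfg$n_daughters_per_dam)
  dam_within <- rep(rep(seq_len(cfg$n_dams_per_sire), each = cfg$n_daughters_per_dam),
                    times = cfg$n_sires)
  daughter <- rep(seq_len(cfg$n_daughters_per_dam),
                  times = cfg$n_sires * cfg$n_dams_per_sire)
  tibble::tibble(
    sire_id = id_pad("S", sire),
    dam_id = paste0(id_pad("S", sire), "_D", dam_within),
    female_id = paste0(id_pad("S", sire), "_D", dam_within, "_F", daughter),
    .sire = sire,
    .dam = (sire - 1L) * cfg$n_dams_per_sire + dam_within
  )
}

# Breeding values under the infinitesimal model: parental values ~ N(0, G),
# offspring a = a_sire/2 + a_dam/2 + Mendelian deviation ~ N(0, G/2).
sample_breeding_values_core <- function(cfg) {
  df <- design_frame(cfg)
  n_dams <- cfg$n_sires * cfg$n_dams_per_sire
  a_sire <- mvn_sample(cfg$n_sires, cfg$G)
  a_dam <- mvn_sample(n_dams, cfg$G)
  mend <- mvn_sample(nrow(df), cfg$G / 2)
  a <- 0.5 * a_sire[df$.sire, , drop = FALSE] +
    0.5 * a_dam[df$.dam, , drop = FALSE] + mend
  list(df = df, a = a, a_sire = a_sire, a_dam = a_dam)
}

#' Sample breeding values for a half-sib design
#'
#' Draws bivariate additive genetic (breeding) values for every daughter in
#' the design under the infinitesimal model: each parent's value is drawn
#' from N(0, G) and a daughter receives half of each parental value plus a
#' Mendelian-sampling deviation with covariance G/2. Across replicates the
#' breeding-value covariance per daughter is `G`, the covariance between
#' paternal half-sibs is `G/4` and between full sibs `G/2`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble with `sire_id`, `dam_id`, `female_id` and breeding values
#'   `a1` (longevity, days) and `a2` (latent mating propensity).
#' @export
sample_breeding_values <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  bv <- sample_breeding_values_core(config)
  dplyr::mutate(dplyr::select(bv$df, "sire_id", "dam_id", "female_id"),
                a1 = bv$a[, 1], a2 = bv$a[, 2])
}

# Days on which opportunities are offered, out to `horizon` days.
opportunity_days <- function(cfg, horizon) {
  gaps <- cfg$opportunity_schedule
  n_max <- ceiling((horizon - cfg$first_opportunity_day) / min(gaps)) + 2L
  cumsum(c(cfg$first_opportunity_day, rep_len(gaps, max(n_max, 1L))))
}

count_opportunities <- function(longevity, cfg) {
  days <- opportunity_days(cfg, max(longevity, 1))
  vapply(longevity, function(L) sum(days <= L), integer(1))
}

#' Simulate a full half-sib breeding-design dataset
#'
#' Generates a pedigree and one life-history record per daughter. Longevity
#' is the sum of its population mean, breeding value, dam effect, residual,
#' a batch (start-date) effect and a per-accepted-mating increment, rounded
#' to a positive integer day. Mating opportunities are offered on the
#' configured schedule until death; each is accepted with probability
#' `plogis(latent propensity)`, and each acceptance extends life by
#' `beta_lifetime_matings` days, generated sequentially so that the
#' opportunity count and longevity remain mutually consistent. Females are
#' independently flagged as escaped/accidentally killed with probability
#' `attrition_prob`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `sib_sim`: a list with
#'   \describe{
#'     \item{pedigree}{tibble `individual_id`, `sire_id`, `dam_id`
#'       (founders have `NA` parents, listed before descendants).}
#'     \item{phenotypes}{tibble of female life-history records with
#'       `longevity` (days), `mating_outcomes` (compact 0/1 string, one
#'       character per opportunity offered before death), `n_opportunities`,
#'       `start_date`, `body_size`, `death_cause`.}
#'     \item{truth}{the configuration echoed with the true heritabilities
#'       and genetic correlation implied by it.}
#'   }
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_sires = 6, seed = 7))
#' head(sim$phenotypes)
simulate_dataset <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  bv <- sample_breeding_values_core(cfg)
  df <- bv$df
  n <- nrow(df)
  n_dams <- cfg$n_sires * cfg$n_dams_per_sire

  d_eff <- cbind(stats::rnorm(n_dams, 0, sqrt(cfg$V_dam[1])),
                 stats::rnorm(n_dams, 0, sqrt(cfg$V_dam[2])))
  e_eff <- cbind(stats::rnorm(n, 0, sqrt(cfg$V_resid[1])),
                 stats::rnorm(n, 0, sqrt(cfg$V_resid[2])))
  start_date <- sample.int(cfg$n_batches, n_dams, replace = TRUE) - 1L
  body_size <- stats::rnorm(n_dams, 1, 0.05)

  latent <- cfg$trait_means[2] + bv$a[, 2] + d_eff[df$.dam, 2] + e_eff[, 2]
  p_mate <- stats::plogis(latent)
  base_long <- cfg$trait_means[1] + bv$a[, 1] + d_eff[df$.dam, 1] + e_eff[, 1] +
    cfg$beta_start_date * start_date[df$.dam]

  days <- opportunity_days(cfg, max(base_long, 1) +
                             abs(cfg$beta_lifetime_matings) * 100 + 10)
  outcomes <- character(n)
  longevity <- integer(n)
  for (i in seq_len(n)) {
    L <- base_long[i]
    out <- integer(0)
    k <- 1L
    while (k <= length(days) && days[k] <= L) {
      m <- stats::rbinom(1L, 1L, p_mate[i])
      out <- c(out, m)
      if (m == 1L) L <- L + cfg$beta_lifetime_matings
      k <- k + 1L
    }
    Li <- max(1L, as.integer(round(L)))
    # keep the opportunity count consistent with the rounded integer lifespan
    n_opp <- sum(days <= Li)
    while (length(out) < n_opp) out <- c(out, stats::rbinom(1L, 1L, p_mate[i]))
    out <- out[seq_len(n_opp)]
    outcomes[i] <- paste(out, collapse = "")
    longevity[i] <- Li
  }

  attr_flag <- stats::rbinom(n, 1L, cfg$attrition_prob) == 1L
  cause <- rep("natural", n)
  if (any(attr_flag))
    cause[attr_flag] <- sample(c("escaped", "accidental"), sum(attr_flag), replace = TRUE)

  phenotypes <- tibble::tibble(
    female_id = df$female_id,
    sire_id = df$sire_id,
    dam_id = df$dam_id,
    longevity = longevity,
    mating_outcomes = outcomes,
    n_opportunities = nchar(outcomes),
    start_date = start_date[df$.dam],
    body_size = body_size[df$.dam],
    death_cause = cause
  )

  sires <- unique(df$sire_id)
  dams <- unique(df$dam_id)
  pedigree <- tibble::tibble(
    individual_id = c(sires, dams, df$female_id),
    sire_id = c(rep(NA_character_, length(sires) + length(dams)), df$sire_id),
    dam_id = c(rep(NA_character_, length(sires) + length(dams)), df$dam_id)
  )

  structure(list(pedigree = pedigree, phenotypes = phenotypes,
                 truth = cfg, seed = as.integer(seed)),
            class = "sib_sim")
}

#' Simulate bivariate Gaussian traits on the half-sib pedigree
#'
#' Companion generator used for parameter-recovery studies of the bivariate
#' animal model: both traits are observed directly on the Gaussian scale
#' (trait value = mean + breeding value + dam effect + residual), so the
#' realized genetic correlation equals the configured
#' `G[1,2]/sqrt(G[1,1]*G[2,2])` exactly, without the attenuation introduced
#' by the per-opportunity Bernoulli measurement process of
#' [simulate_dataset()].
#'
#' @inheritParams simulate_dataset
#' @return Tibble with ids and Gaussian phenotypes `y1`, `y2`.
#' @export
simulate_gaussian_traits <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  bv <- sample_breeding_values_core(cfg)
  df <- bv$df
  n <- nrow(df)
  n_dams <- cfg$n_sires * cfg$n_dams_per_sire
  d_eff <- cbind(stats::rnorm(n_dams, 0, sqrt(cfg$V_dam[1])),
                 stats::rnorm(n_dams, 0, sqrt(cfg$V_dam[2])))
  e_eff <- cbind(stats::rnorm(n, 0, sqrt(cfg$V_resid[1])),
                 stats::rnorm(n, 0, sqrt(cfg$V_resid[2])))
  dplyr::mutate(dplyr::select(df, "sire_id", "dam_id", "female_id"),
                y1 = cfg$trait_means[1] + bv$a[, 1] + d_eff[df$.dam, 1] + e_eff[, 1],
                y2 = cfg$trait_means[2] + bv$a[, 2] + d_eff[df$.dam, 2] + e_eff[, 2])
}

#' Write a simulated dataset as delimited text
#'
#' Writes `phenotypes.csv`, `pedigree.csv` (comma-separated, header row,
#' UTF-8, missing values as empty fields, mating outcomes as a compact 0/1
#' string) and `truth.yml` (the configuration with its derived true
#' parameters) into `dir`.
#'
#' @param sim A `sib_sim` from [simulate_dataset()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sib_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$phenotypes, file.path(dir, "phenotypes.csv"), na = "")
  readr::write_csv(sim$pedigree, file.path(dir, "pedigree.csv"), na = "")
  tr <- sim$truth
  yaml::write_yaml(list(
    n_sires = tr$n_sires, n_dams_per_sire = tr$n_dams_per_sire,
    n_daughters_per_dam = tr$n_daughters_per_dam,
    G = as.vector(tr$G), V_dam = tr$V_dam, V_resid = tr$V_resid,
    trait_means = tr$trait_means,
    beta_lifetime_matings = tr$beta_lifetime_matings,
    beta_start_date = tr$beta_start_date, n_batches = tr$n_batches,
    opportunity_schedule = tr$opportunity_schedule,
    first_opportunity_day = tr$first_opportunity_day,
    attrition_prob = tr$attrition_prob, seed = sim$seed,
    true_h2 = as.numeric(tr$true_h2), true_r_g = tr$true_r_g
  ), file.path(dir, "truth.yml"))
  invisible(dir)
}

#' Read phenotype and pedigree tables written by [write_sim()]
#'
#' @param path Path to a CSV file.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path, call. = FALSE)
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(mating_outcomes = readr::col_character()))
}

#' @rdname read_phenotypes
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path, call. = FALSE)
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
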