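#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles either a simulation configuration or paths to phenotype/pedigree
#' CSV files with the model-selection and jackknife settings. Can also be
#' loaded from a YAML file with the same field names via `config_file`.
#'
#' @param simulation A [sim_config()] used when no input files are given.
#' @param phenotypes,pedigree Optional paths to CSV inputs (as written by
#'   [write_sim()]); when supplied, simulation is skipped.
#' @param alpha Wald retention threshold for fixed-effect selection.
#' @param jackknife Compute jackknife SEs (one REML refit per sire family).
#' @param seed Integer seed controlling all randomness.
#' @param config_file Optional YAML file; fields present in it override the
#'   arguments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = sim_config(), phenotypes = NULL,
                            pedigree = NULL, alpha = 0.05, jackknife = TRUE,
                            seed = 1L, config_file = NULL) {
  cfg <- list(simulation = simulation, phenotypes = phenotypes,
              pedigree = pedigree, alpha = alpha, jackknife = jackknife,
              seed = as.integer(seed))
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    y <- yaml::read_yaml(config_file)
    for (f in intersect(names(y), c("phenotypes", "pedigree", "alpha",
                                    "jackknife", "seed")))
      cfg[[f]] <- y[[f]]
    if (!is.null(y$simulation)) {
      sim_args <- y$simulation
      if (!is.null(sim_args$G)) sim_args$G <- matrix(unlist(sim_args$G), 2, 2)
      cfg$simulation <- do.call(sim_config, sim_args)
    }
    cfg$seed <- as.integer(cfg$seed)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full quantitative-genetic analysis pipeline
#'
#' Orchestrates simulate (or load) -> subset -> derive traits -> nested
#' sire/dam REML per trait with Wald-based fixed-effect selection and
#' likelihood-ratio tests -> genetic parameters with jackknife SEs ->
#' bivariate animal models for the genetic correlations between longevity
#' and early-life mating frequency and between early- and later-life mating
#' frequency. All randomness flows from `config$seed`; with a fixed seed
#' two runs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, writes `table1.tsv`,
#'   `tests.tsv`, `genetic_correlations.tsv` and `manifest.json` (plus the
#'   simulated CSVs when simulating).
#' @param quiet Suppress stage messages.
#' @return List with `data`, `records`, `params` (per-trait [genetic_parameters()]
#'   results), `tests`, `correlations`, `table1` (TSV text) and `manifest`,
#'   invisibly when `out_dir` is used.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[sibvar] ", sprintf(...))

  # stage 1: data
  if (!is.null(config$phenotypes)) {
    if (!file.exists(config$phenotypes))
      stop("pipeline stage 'data': phenotype file not found: ",
           config$phenotypes, call. = FALSE)
    phen <- read_phenotypes(config$phenotypes)
    ped <- if (!is.null(config$pedigree)) read_pedigree(config$pedigree) else NULL
    truth <- NULL
    say("loaded %d life-history records from %s", nrow(phen), config$phenotypes)
  } else {
    sim <- simulate_dataset(config$simulation, seed = config$seed)
    phen <- sim$phenotypes
    ped <- sim$pedigree
    truth <- sim$truth
    say("simulated %d females (%d sires x %d dams x %d daughters)",
        nrow(phen), truth$n_sires, truth$n_dams_per_sire, truth$n_daughters_per_dam)
  }

  # stage 2: subset and derive traits
  kept <- filter_analysis_subset(phen)
  say("analysis subset: %d -> %d females (>=6 opportunities, >=1 mating, natural death)",
      nrow(phen), nrow(kept))
  rec <- derive_traits(kept)

  # stage 3-4: per-trait models and genetic parameters
  say("fitting longevity model (selection on untransformed scale)")
  p_long <- genetic_parameters(
    rec, "longevity", candidates = c("lifetime_matings", "start_date", "body_size"),
    alpha = config$alpha, jackknife = config$jackknife)
  say("fitting early-life mating model (selection on log1p scale)")
  p_early <- genetic_parameters(
    rec, "early_life_matings", candidates = c("longevity", "start_date", "body_size"),
    alpha = config$alpha, select_transform = "log1p",
    jackknife = config$jackknife)
  params <- list(longevity = p_long, early_life_matings = p_early)

  tests <- dplyr::bind_rows(
    dplyr::mutate(p_long$selection$tests, trait = "longevity"),
    dplyr::mutate(p_long$lrt, trait = "longevity"),
    dplyr::mutate(p_early$selection$tests, trait = "early_life_matings"),
    dplyr::mutate(p_early$lrt, trait = "early_life_matings"))
  tests <- dplyr::select(tests, "trait", "kind", "term", "statistic", "df", "p_value")

  # stage 5: genetic correlations from bivariate animal models
  correlations <- NULL
  if (!is.null(ped)) {
    say("building relationship matrix and fitting bivariate animal models")
    A <- build_A_matrix(ped)
    biv1 <- fit_bivariate_animal_model(
      rec, c("longevity", "early_life_matings"), A,
      fixed1 = p_long$selection$kept, fixed2 = p_early$selection$kept)
    biv2 <- fit_bivariate_animal_model(
      rec, c("early_life_matings", "later_life_matings"), A,
      fixed1 = p_early$selection$kept, fixed2 = character())
    correlations <- tibble::tibble(
      trait1 = c("longevity", "early_life_matings"),
      trait2 = c("early_life_matings", "later_life_matings"),
      r_g = c(biv1$r_g, biv2$r_g),
      se_r_g = c(biv1$se_r_g, biv2$se_r_g),
      converged = c(biv1$converged, biv2$converged))
    say("r_g(longevity, early mating) = %.3f (SE %.3f)", biv1$r_g, biv1$se_r_g)
  }

  table1 <- render_table1(params)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sibvar")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    alpha = config$alpha,
    jackknife = config$jackknife,
    n_input = nrow(phen), n_analysis = nrow(rec),
    config_hash = rlang::hash(config))
  if (!is.null(truth)) {
    manifest$truth_vs_estimate <- list(
      h2_longevity = list(truth = unname(truth$true_h2[1]),
                          estimate = unname(p_long$estimate["h2"])),
      h2_early_mating = list(truth = unname(truth$true_h2[2]),
                             estimate = unname(p_early$estimate["h2"])),
      r_g = list(truth = truth$true_r_g,
                 estimate = if (!is.null(correlations)) correlations$r_g[1] else NA))
  }

  out <- list(data = phen, pedigree = ped, records = rec, params = params,
              tests = tests, correlations = correlations, table1 = table1,
              manifest = manifest, truth = truth)
  class(out) <- "sib_pipeline"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    writeLines(table1, file.path(out_dir, "table1.tsv"))
    readr::write_tsv(tests, file.path(out_dir, "tests.tsv"))
    if (!is.null(correlations))
      readr::write_tsv(correlations, file.path(out_dir, "genetic_correlations.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (is.null(config$phenotypes)) {
      readr::write_csv(phen, file.path(out_dir, "phenotypes.csv"), na = "")
      readr::write_csv(ped, file.path(out_dir, "pedigree.csv"), na = "")
    }
    say("outputs written to %s", out_dir)
    return(invisible(out))
  }
  out
}

#' @export
print.sib_pipeline <- function(x, ...) {
  cat(x$table1, sep = "\n")
  if (!is.null(x$correlations)) {
    cat("\nGenetic correlations (bivariate animal models):\n")
    print(x$correlations)
  }
  invisible(x)
}

fmt3 <- function(v) sprintf("%.3f", v)

fmt_se <- function(v, se) {
  ifelse(is.na(se), fmt3(v), sprintf("%s (%s)", fmt3(v), fmt3(se)))
}

fmt_p <- function(p) ifelse(p < 0.001, "<0.001*", fmt3(p))

#' Render a publication-shaped genetic-parameter table
#'
#' Formats per-trait parameter sets as a tab-separated table with
#' `value (SE)` cells rounded to 3 decimals: N, mean, family counts,
#' variance components, `V_A`, `V_P`, `V_R`, `h2`, `CV_A`, `CV_P`, `CV_R`,
#' `I_A` and likelihood-ratio p-values for the sire and dam components.
#'
#' @param params List of [genetic_parameters()] results.
#' @return Character vector of TSV lines (header + one row per trait).
#' @seealso [parse_table1()] for the inverse (up to 3-decimal rounding).
#' @export
render_table1 <- function(params) {
  header <- paste(c("trait", "N", "mean (SE)", "n_sires", "n_dams",
                    "V_Sire (SE)", "V_Dam (SE)", "V_A (SE)", "V_P (SE)",
                    "V_R (SE)", "h2 (SE)", "CV_A (SE)", "CV_P (SE)",
                    "CV_R (SE)", "I_A (SE)", "P_Sire", "P_Dam"),
                  collapse = "\t")
  rows <- vapply(params, function(p) {
    e <- p$estimate; s <- p$se
    cells <- c(p$trait, p$n_obs, fmt_se(e["mean"], s["mean"]),
               p$n_sires, p$n_dams,
               fmt_se(e["V_sire"], s["V_sire"]), fmt_se(e["V_dam"], s["V_dam"]),
               fmt_se(e["V_A"], s["V_A"]), fmt_se(e["V_P"], s["V_P"]),
               fmt_se(e["V_R"], s["V_R"]), fmt_se(e["h2"], s["h2"]),
               fmt_se(e["CV_A"], s["CV_A"]), fmt_se(e["CV_P"], s["CV_P"]),
               fmt_se(e["CV_R"], s["CV_R"]), fmt_se(e["I_A"], s["I_A"]),
               fmt_p(p$lrt$p_value[p$lrt$term == "sire"]),
               fmt_p(p$lrt$p_value[p$lrt$term == "dam"]))
    paste(cells, collapse = "\t")
  }, character(1))
  c(header, unname(rows))
}

#' Parse a rendered genetic-parameter table back to numbers
#'
#' Inverse of [render_table1()] up to the 3-decimal rounding used for
#' display: `parse_table1(render_table1(x))` recovers every estimate and SE
#' rounded to 3 decimals.
#'
#' @param lines Character vector as returned by [render_table1()].
#' @return Tibble in long format: `trait`, `cell`, `estimate`, `se`.
#' @export
parse_table1 <- function(lines) {
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  val_cols <- grep("\\(SE\\)", header)
  out <- purrr::map(rows, function(r) {
    m <- regmatches(r[val_cols], regexec("^(-?[0-9.]+)(?: \\((-?[0-9.]+)\\))?$",
                                         r[val_cols]))
    tibble::tibble(
      trait = r[1],
      cell = sub(" \\(SE\\)", "", header[val_cols]),
      estimate = vapply(m, function(x) as.numeric(x[2]), numeric(1)),
      se = vapply(m, function(x) if (length(x) < 3 || x[3] == "") NA_real_
                  else as.numeric(x[3]), numeric(1)))
  })
  dplyr::bind_rows(out)
}
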