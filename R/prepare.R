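#' Subset life-history records for genetic analysis
#'
#' Retains only females that (1) lived long enough to be offered at least
#' `min_opportunities` mating opportunities, (2) mated at least once, and
#' (3) died a natural death (neither escaped nor accidentally killed).
#' Record order is preserved and the input is not modified.
#'
#' @param records Tibble of life-history records as produced by
#'   [simulate_dataset()] (columns `mating_outcomes`, `death_cause`, ...).
#' @param min_opportunities Minimum number of opportunities offered
#'   (default 6, i.e. the female was alive at the sixth scheduled
#'   opportunity).
#' @param mated_scope Whether "mated at least once" counts matings anywhere
#'   in life (`"lifetime"`, default) or only within the first
#'   `min_opportunities` (`"early"`).
#' @return The retained rows, same columns, as a tibble.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_sires = 6, seed = 1))
#' nrow(sim$phenotypes); nrow(filter_analysis_subset(sim$phenotypes))
filter_analysis_subset <- function(records, min_opportunities = 6,
                                   mated_scope = c("lifetime", "early")) {
  mated_scope <- match.arg(mated_scope)
  stopifnot(all(c("mating_outcomes", "death_cause") %in% names(records)))
  out <- records$mating_outcomes
  n_opp <- nchar(out)
  n_mated <- if (mated_scope == "lifetime") {
    count_ones(out)
  } else {
    count_ones(substr(out, 1L, min_opportunities))
  }
  keep <- n_opp >= min_opportunities & n_mated >= 1L & records$death_cause == "natural"
  tibble::as_tibble(records[keep, , drop = FALSE])
}

count_ones <- function(s) {
  nchar(s) - nchar(gsub("1", "", s, fixed = TRUE))
}

#' Derive analysis traits from life-history records
#'
#' Splits each female's per-opportunity mating outcomes into early-life
#' mating frequency (matings accepted in opportunities 1-6), later-life
#' mating frequency (opportunities 7 to death) and lifetime mating count.
#' Every record must have been offered at least `n_early` opportunities —
#' run [filter_analysis_subset()] first.
#'
#' @param records Filtered life-history tibble.
#' @param n_early Number of opportunities defining early life (default 6).
#' @return Tibble with `female_id`, `sire_id`, `dam_id`, `longevity`,
#'   `early_life_matings`, `later_life_matings`, `lifetime_matings`,
#'   `start_date`, `body_size`.
#' @export
derive_traits <- function(records, n_early = 6) {
  out <- records$mating_outcomes
  if (any(nchar(out) < n_early))
    stop("all records must have at least ", n_early,
         " mating opportunities; run filter_analysis_subset() first",
         call. = FALSE)
  early <- count_ones(substr(out, 1L, n_early))
  lifetime <- count_ones(out)
  tibble::tibble(
    female_id = records$female_id,
    sire_id = records$sire_id,
    dam_id = records$dam_id,
    longevity = records$longevity,
    early_life_matings = early,
    later_life_matings = lifetime - early,
    lifetime_matings = lifetime,
    start_date = records$start_date,
    body_size = records$body_size
  )
}

#' Natural log(x + 1) transform for mating counts
#'
#' @param values Non-negative numeric vector.
#' @return `log(values + 1)`.
#' @export
#' @examples
#' log1p_transform(c(0, 1, exp(1) - 1))
log1p_transform <- function(values) {
  if (any(values < 0, na.rm = TRUE))
    stop("log(x + 1) transform requires non-negative values", call. = FALSE)
  log1p(values)
}
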