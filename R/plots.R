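#' Sire-family mean plot of a trait
#'
#' Dot-and-error-bar plot of sire-family means (+/- 1 SE), families ordered
#' by mean — the standard visual for between-family variance in a half-sib
#' design.
#'
#' @param data Analysis records with `sire_id` and the trait column.
#' @param trait Trait column name.
#' @return A ggplot object.
#' @export
plot_sire_family_means <- function(data, trait = "longevity") {
  fam <- dplyr::summarise(
    dplyr::group_by(data, .data$sire_id),
    mean = mean(.data[[trait]]),
    se = stats::sd(.data[[trait]]) / sqrt(dplyr::n()), .groups = "drop")
  fam <- dplyr::mutate(fam, sire_id = stats::reorder(.data$sire_id, .data$mean))
  ggplot2::ggplot(fam, ggplot2::aes(x = .data$sire_id, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             linewidth = 0.3, size = 0.3) +
    ggplot2::labs(x = "sire family (ordered by mean)", y = trait) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Sire-family trade-off plot: residual longevity vs early-life mating
#'
#' Residual longevity (from a linear regression of longevity on lifetime
#' mating count and start date) is averaged per sire family and plotted
#' against the family mean early-life mating frequency, with +/- 1 SE bars
#' on both axes. A negative trend across families is the family-level
#' signature of a genetic trade-off between early reproduction and
#' lifespan.
#'
#' @param data Analysis records (see [derive_traits()]).
#' @return A ggplot object.
#' @export
plot_genetic_tradeoff <- function(data) {
  res <- stats::resid(stats::lm(longevity ~ lifetime_matings + start_date,
                                data = data))
  d <- dplyr::mutate(data, .resid_longevity = res)
  fam <- dplyr::summarise(
    dplyr::group_by(d, .data$sire_id),
    x = mean(.data$early_life_matings),
    xse = stats::sd(.data$early_life_matings) / sqrt(dplyr::n()),
    y = mean(.data$.resid_longevity),
    yse = stats::sd(.data$.resid_longevity) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(fam, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$yse,
                                        ymax = .data$y + .data$yse),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$x - .data$xse,
                                         xmax = .data$x + .data$xse),
                            linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "sire-family mean early-life matings",
                  y = "sire-family mean residual longevity (days)") +
    ggplot2::theme_classic()
}

#' @rdname genetic_parameters
#' @param object A `gparams` object.
#' @export
autoplot.gparams <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$parameter %in% c("h2", "CV_A", "CV_P", "CV_R", "I_A"), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                          ymax = .data$estimate + .data$std.error)) +
    ggplot2::labs(title = object$trait, x = NULL,
                  y = "estimate (+/- jackknife SE)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL
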