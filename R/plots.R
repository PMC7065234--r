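#' Plot a mass spectrum
#'
#' @param object A [mass_spectrum()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.mass_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot dwell-time survival curves
#'
#' Step plot of S(t) per site on a log y scale; exponential dwells appear as
#' straight lines whose negative slope is k_off.
#'
#' @param object A `survival_curves` tibble from [survival_curve()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.survival_curves <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, .data$survival > 0),
    ggplot2::aes(x = .data$time_ns, y = .data$survival, colour = .data$site_id)
  ) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (ns)", y = "S(t)", colour = "site") +
    ggplot2::theme_minimal()
}

#' Plot a competition fit
#'
#' Observed bound fractions per lipid class across the detergent titration,
#' overlaid with the fitted displacement curves.
#'
#' @param object A `competition_fit` from [fit_competition()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.competition_fit <- function(object, ...) {
  dat <- object$data
  grid <- tidyr::expand_grid(
    lipid_class = object$fits$lipid_class,
    detergent_conc = seq(min(dat$detergent_conc), max(dat$detergent_conc),
                         length.out = 100)
  ) |>
    left_join(object$fits, by = "lipid_class") |>
    filter(!is.na(.data$K_L)) |>
    mutate(bound_fraction = purrr::pmap_dbl(
      list(.data$K_L, .data$K_D, .data$protected, .data$detergent_conc,
           .data$lipid_class),
      function(K_L, K_D, protected, D, cls) {
        L <- if (length(object$lipid_conc) == 1 && is.null(names(object$lipid_conc)))
          object$lipid_conc else object$lipid_conc[[cls]]
        occupancy(L, D, K_L, K_D = if (protected) Inf else K_D,
                  cmc = object$cmc, protected = protected)
      }
    ))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$detergent_conc,
                                    y = .data$bound_fraction,
                                    colour = .data$lipid_class)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::labs(x = "detergent (% w/v)", y = "bound fraction",
                  colour = "lipid") +
    ggplot2::theme_minimal()
}

#' Heatmap of per-state residue accessibility
#'
#' @param profile An `accessibility_profile` from [contact_frequency()].
#' @return A ggplot tile map of contact frequency by state and residue.
#' @export
plot_accessibility <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$residue, y = .data$state,
                                        fill = .data$contact_frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(fill = "contact\nfrequency") +
    ggplot2::theme_minimal()
}
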