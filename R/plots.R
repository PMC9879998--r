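#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a melting curve fit
#'
#' Data points with the fitted two-state curve and the extrapolated folded /
#' unfolded baselines.
#'
#' @param object A [fit_melt()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot melt_fit
#' @export
autoplot.melt_fit <- function(object, ...) {
  d <- augment(object)
  t_c <- d$temperature_C
  base <- tibble::tibble(
    temperature_C = rep(t_c, 2),
    mre = c(object$baselines$folded_intercept + object$baselines$folded_slope * t_c,
            object$baselines$unfolded_intercept + object$baselines$unfolded_slope * t_c),
    state = rep(c("folded", "unfolded"), each = length(t_c))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_C)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mre), size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "firebrick") +
    ggplot2::geom_line(
      data = base,
      ggplot2::aes(y = .data$mre, group = .data$state),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = expression("[" * theta * "]"[222] ~ "(deg" ~ cm^2 ~ dmol^-1 * ")"),
      title = sprintf("%s: T_m = %.1f °C, ΔH_m = %.0f kcal/mol",
                      object$state$name, kelvin_to_celsius(object$state$t_m_K),
                      object$state$dh_m)
    ) +
    ggplot2::theme_minimal()
}

#' Plot inhibition kinetics with fitted curves
#'
#' Initial rates versus substrate per inhibitor level with the fitted
#' competitive-inhibition model.
#'
#' @param object A [fit_ki()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ki_fit
#' @export
autoplot.ki_fit <- function(object, ...) {
  d <- object$data
  s_line <- seq(min(d$substrate_uM), max(d$substrate_uM), length.out = 120)
  pred <- tidyr::expand_grid(inhibitor_nM = unique(d$inhibitor_nM),
                             substrate_uM = s_line)
  ki <- if (object$no_inhibition) Inf else object$ki
  pred$rate <- object$v_max * pred$substrate_uM /
    (object$k_m * (1 + pred$inhibitor_nM / ki) + pred$substrate_uM)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate_uM, y = .data$rate,
                                  colour = factor(.data$inhibitor_nM))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred) +
    ggplot2::labs(x = "[S] (µM)", y = "initial rate",
                  colour = "[I] (nM)",
                  title = if (object$no_inhibition) "no inhibition detected"
                  else sprintf("K_I = %.3g nM", object$ki)) +
    ggplot2::theme_minimal()
}

#' Plot a fold template's contact map
#'
#' Contacts below the diagonal, burial classes along the diagonal.
#'
#' @param template A [fold_template()].
#' @return A ggplot.
#' @export
plot_contact_map <- function(template) {
  cc <- template$contacts
  pts <- tibble::tibble(i = c(cc$i, cc$j), j = c(cc$j, cc$i))
  diagd <- tibble::tibble(i = seq_len(template$length),
                          burial = template$burial)
  ggplot2::ggplot() +
    ggplot2::geom_tile(data = pts, ggplot2::aes(x = .data$i, y = .data$j),
                       fill = "grey30") +
    ggplot2::geom_tile(
      data = diagd,
      ggplot2::aes(x = .data$i, y = .data$i, fill = .data$burial)
    ) +
    ggplot2::scale_fill_manual(values = c(core = "firebrick",
                                          boundary = "goldenrod",
                                          surface = "steelblue")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue", fill = "burial",
                  title = sprintf("%s (%s)", template$name,
                                  template$topology_string)) +
    ggplot2::theme_minimal()
}

#' Plot three-state populations along a temperature range
#'
#' Populations of the long fold, embedded fold and unfolded state for fixed
#' free energies, across temperature.
#'
#' @param dg_long,dg_switch Free energies (kcal/mol) at the plotted
#'   temperatures (treated as temperature-independent over the range).
#' @param t_range Temperature range in deg C.
#' @return A ggplot.
#' @export
plot_populations <- function(dg_long, dg_switch, t_range = c(0, 100)) {
  t_grid <- seq(t_range[1], t_range[2], length.out = 200)
  pops <- purrr::map_dfr(t_grid,
                         ~ three_state_populations(dg_long, dg_switch, .x))
  long <- tidyr::pivot_longer(pops, c("f_S", "f_G", "f_U"),
                              names_to = "state", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$temperature_C,
                                     y = .data$fraction,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Temperature (°C)", y = "population",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the conflict landscape over embedding offsets
#'
#' Conflict count per candidate offset from a ranked embedding table,
#' highlighting the best alignment.
#'
#' @param ranks Output of [rank_embeddings()] or [rank_fold_pair()].
#' @return A ggplot.
#' @export
plot_embedding_ranks <- function(ranks) {
  ggplot2::ggplot(ranks, ggplot2::aes(x = .data$offset, y = .data$total_count)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$rank == 1), width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               guide = "none") +
    ggplot2::labs(x = "embedding offset", y = "catastrophic interactions") +
    ggplot2::theme_minimal()
}
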