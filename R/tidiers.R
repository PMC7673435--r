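#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fixed point
#'
#' @param x A `selfheal_fixed_point`.
#' @param ... Unused.
#' @return One-row tibble with `a_star`, `k_star`.
#' @method tidy selfheal_fixed_point
#' @export
tidy.selfheal_fixed_point <- function(x, ...) {
  tibble::tibble(a_star = x$a_star, k_star = x$k_star)
}

#' Tidy a stability report
#'
#' @param x A `selfheal_stability`.
#' @param ... Unused.
#' @return One-row tibble with `trace`, `determinant`, `stable`,
#'   `sufficient_D_lt_1`, `a_star`, `k_star`.
#' @method tidy selfheal_stability
#' @export
tidy.selfheal_stability <- function(x, ...) {
  tibble::tibble(trace = x$trace, determinant = x$determinant,
                 stable = x$stable, sufficient_D_lt_1 = x$sufficient_D_lt_1,
                 a_star = x$fixed_point$a_star, k_star = x$fixed_point$k_star)
}

#' Tidy a healing simulation
#'
#' @param x A `healing_sim`.
#' @param ... Unused.
#' @return The per-step series tibble.
#' @method tidy healing_sim
#' @export
tidy.healing_sim <- function(x, ...) x$series

#' One-row summary of a healing simulation
#'
#' @param x A `healing_sim`.
#' @param ... Unused.
#' @return One-row tibble: walk, agent count, steps, peak halo size and its
#'   step, resolution step, final injured-spring stiffness, final mean/sd of
#'   spring stiffness.
#' @method glance healing_sim
#' @export
glance.healing_sim <- function(x, ...) {
  s <- x$series
  tibble::tibble(
    walk = x$config$walk,
    n_agents = x$config$n_agents,
    n_steps = x$config$n_steps,
    peak_halo = max(s$halo_size),
    peak_halo_step = s$step[which.max(s$halo_size)],
    resolution_step = x$resolution_step,
    final_injured_k = s$injured_k[nrow(s)],
    final_mean_k = s$mean_k[nrow(s)],
    final_sd_k = s$sd_k[nrow(s)])
}

#' Tidy a healing ensemble
#'
#' @param x A `healing_ensemble`.
#' @param ... Unused.
#' @return The per-step ensemble summary tibble.
#' @method tidy healing_ensemble
#' @export
tidy.healing_ensemble <- function(x, ...) x$summary

#' One-row summary of a healing ensemble
#'
#' @param x A `healing_ensemble`.
#' @param ... Unused.
#' @return One-row tibble: walk, agents, replicates, median/IQR resolution
#'   step, peak of the mean-halo curve and its step.
#' @method glance healing_ensemble
#' @export
glance.healing_ensemble <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    walk = x$config$walk,
    n_agents = x$config$n_agents,
    n_reps = x$n_reps,
    median_resolution = stats::median(x$resolution_steps, na.rm = TRUE),
    iqr_resolution = stats::IQR(x$resolution_steps, na.rm = TRUE),
    unresolved = sum(is.na(x$resolution_steps)),
    peak_halo_mean = max(s$halo_mean),
    peak_halo_step = s$step[which.max(s$halo_mean)])
}

#' Plot a trajectory
#'
#' Activity and stiffness time courses in two facets, with the fixed point
#' drawn as a dashed reference line.
#'
#' @param object A `selfheal_trajectory` from [integrate_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot selfheal_trajectory
#' @export
autoplot.selfheal_trajectory <- function(object, ...) {
  fp <- fixed_point(attr(object, "params"))
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("a", "k"),
                              names_to = "variable", values_to = "value")
  ref <- tibble::tibble(variable = c("a", "k"),
                        value = c(fp$a_star, fp$k_star))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(a = "activity a", k = "stiffness k"))) +
    ggplot2::labs(x = "dimensionless time", y = NULL)
}

#' Plot a fixed-point sweep
#'
#' @param object A `selfheal_sweep` from [fixed_point_sweep()].
#' @param ... Unused.
#' @return A ggplot object (stiffness panel on log-log axes).
#' @method autoplot selfheal_sweep
#' @export
autoplot.selfheal_sweep <- function(object, ...) {
  ok <- dplyr::filter(tibble::as_tibble(object), .data$ok)
  long <- tidyr::pivot_longer(ok, c("a_star", "k_star"),
                              names_to = "variable", values_to = "fp")
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$fp)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = unique(object$param), y = "fixed point")
}

#' Plot a healing simulation
#'
#' Injured-spring stiffness, halo size, mean agent activity and mean spring
#' stiffness against time.
#'
#' @param object A `healing_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot healing_sim
#' @export
autoplot.healing_sim <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series,
                              c("injured_k", "halo_size", "mean_activity",
                                "mean_k"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = "dimensionless time", y = NULL)
}

#' Plot a healing ensemble
#'
#' Mean halo size with a +/- 1 SD ribbon.
#'
#' @param object A `healing_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot healing_ensemble
#' @export
autoplot.healing_ensemble <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$time, .data$halo_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$halo_mean - .data$halo_sd, 0),
      ymax = .data$halo_mean + .data$halo_sd), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dimensionless time", y = "halo size (springs)")
}

#' Plot a network
#'
#' Springs drawn as segments coloured by stiffness relative to the reference.
#'
#' @param object A `hex_network`.
#' @param positions Optional coordinate matrix (default stored positions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hex_network
#' @export
autoplot.hex_network <- function(object, positions = NULL, ...) {
  pos <- positions_of(object, positions)
  seg <- dplyr::mutate(object$springs,
                       x = pos[.data$from, 1L], y = pos[.data$from, 2L],
                       xend = pos[.data$to, 1L], yend = pos[.data$to, 2L],
                       rel = .data$stiffness / object$k_star_reference)
  ggplot2::ggplot(seg, ggplot2::aes(x = .data$x, y = .data$y,
                                    xend = .data$xend, yend = .data$yend,
                                    colour = .data$rel)) +
    ggplot2::geom_segment() +
    ggplot2::scale_colour_gradient2(midpoint = 1, low = "blue",
                                    mid = "grey70", high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "k / k*", x = NULL, y = NULL)
}
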