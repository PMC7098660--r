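#' Plot the trajectories of a simulation
#'
#' Paths of all swimmers, colored by individual, with the arena wall drawn
#' in bounded mode.
#'
#' @param object a `school_sim` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot school_sim
#' @export
autoplot.school_sim <- function(object, ...) {
  traj <- object$trajectories
  p <- ggplot2::ggplot(traj, ggplot2::aes(
    .data$x_m, .data$y_m,
    group = .data$agent_id, color = factor(.data$agent_id)
  )) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (m)", y = "y (m)", color = "agent",
      title = sprintf(
        "%s, %s k = %d", object$config$mode, object$config$strat$kind,
        resolve_strategy(object$config$strat, object$config$n_agents)$k
      )
    )
  if (object$config$mode == "bounded") {
    R <- object$config$params$arena_radius
    th <- seq(-pi, pi, length.out = 256)
    p <- p + ggplot2::annotate("path",
      x = R * cos(th), y = R * sin(th), linewidth = 0.4, color = "grey30"
    )
  }
  p
}

#' Plot ensemble mean cohesion and polarization over time
#'
#' @param object a `school_ensemble` object.
#' @param ... unused.
#' @return a ggplot with one facet per observable.
#' @method autoplot school_ensemble
#' @export
autoplot.school_ensemble <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$series[, c("time_s", "mean_C", "mean_P")],
    -"time_s",
    names_to = "observable", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Plot a cut-off sweep
#'
#' Steady-state cohesion against the attraction cut-off, with the escape
#' threshold and the estimated critical cut-off marked.
#'
#' @param object a `cutoff_sweep` object.
#' @param ... unused.
#' @method autoplot cutoff_sweep
#' @export
autoplot.cutoff_sweep <- function(object, ...) {
  ggplot2::ggplot(object$sweep, ggplot2::aes(.data$d_cut, .data$mean_C_ss)) +
    ggplot2::geom_hline(
      yintercept = object$escape_threshold,
      linetype = 2, color = "grey40"
    ) +
    ggplot2::geom_vline(
      xintercept = object$d_cut_critical,
      linetype = 3, color = "firebrick"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(d[cut] ~ "(m)"),
      y = "steady-state cohesion (m)"
    )
}

#' Plot an empirical PDF
#'
#' @param object a `school_pdf` object.
#' @param ... unused.
#' @method autoplot school_pdf
#' @export
autoplot.school_pdf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$mid, .data$mass)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = object$label, y = "probability mass")
}

#' Plot a cohesion-polarization density map
#'
#' @param map a tibble from [density_map()].
#' @return a ggplot tile map.
#' @export
plot_density_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(.data$c_mid, .data$p_mid,
    fill = .data$density
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "cohesion (m)", y = "polarization", fill = "density")
}
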