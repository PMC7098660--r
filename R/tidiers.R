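#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single simulation: its kick log
#'
#' @param x a `school_sim` object.
#' @param ... unused.
#' @return the kick-log tibble, with the neighbor list flattened to a
#'   semicolon-separated string.
#' @method tidy school_sim
#' @export
tidy.school_sim <- function(x, ...) {
  dplyr::mutate(
    x$kicks,
    neighbors = purrr::map_chr(.data$neighbors, paste, collapse = ";")
  )
}

#' One-row summary of a simulation
#'
#' @param x a `school_sim` object.
#' @param ... unused.
#' @return a one-row tibble: group size, strategy, kick count, duration,
#'   mean kick length and interval, and time-averaged cohesion and
#'   polarization.
#' @method glance school_sim
#' @export
glance.school_sim <- function(x, ...) {
  obs <- compute_observables(x)
  tibble::tibble(
    n_agents = x$config$n_agents,
    strategy = x$config$strat$kind,
    k = resolve_strategy(x$config$strat, x$config$n_agents)$k,
    mode = x$config$mode,
    n_kicks = nrow(x$kicks),
    duration_s = x$duration_s,
    mean_kick_length_m = mean(x$kicks$length_m),
    mean_kick_duration_s = mean(x$kicks$duration_s),
    mean_C = mean(obs$cohesion_m),
    mean_P = mean(obs$polarization, na.rm = TRUE)
  )
}

#' Tidy an ensemble: the per-time-bin mean series
#'
#' @param x a `school_ensemble` object.
#' @param ... unused.
#' @method tidy school_ensemble
#' @export
tidy.school_ensemble <- function(x, ...) x$series

#' One-row ensemble summary (steady state)
#'
#' @param x a `school_ensemble` object.
#' @param ... unused.
#' @method glance school_ensemble
#' @export
glance.school_ensemble <- function(x, ...) {
  tibble::tibble(
    n_runs = x$n_runs,
    total_kicks = x$config$total_kicks,
    strategy = x$config$strat$kind,
    k = resolve_strategy(x$config$strat, x$config$n_agents)$k,
    mode = x$config$mode,
    mean_C_ss = x$mean_C_ss,
    mean_P_ss = x$mean_P_ss
  )
}

#' Tidy a cut-off sweep
#'
#' @param x a `cutoff_sweep` object.
#' @param ... unused.
#' @method tidy cutoff_sweep
#' @export
tidy.cutoff_sweep <- function(x, ...) x$sweep

#' One-row cut-off sweep summary
#'
#' @param x a `cutoff_sweep` object.
#' @param ... unused.
#' @method glance cutoff_sweep
#' @export
glance.cutoff_sweep <- function(x, ...) {
  tibble::tibble(
    d_cut_critical = x$d_cut_critical,
    escape_threshold = x$escape_threshold,
    n_grid = nrow(x$sweep),
    n_runs = x$n_runs
  )
}

#' Tidy an empirical PDF
#'
#' @param x a `school_pdf` object.
#' @param ... unused.
#' @return a tibble with `mid`, `lower`, `upper`, `mass`.
#' @method tidy school_pdf
#' @export
tidy.school_pdf <- function(x, ...) {
  e <- x$edges
  tibble::tibble(
    mid = (e[-1] + e[-length(e)]) / 2,
    lower = e[-length(e)], upper = e[-1],
    mass = x$mass
  )
}
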