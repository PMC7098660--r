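#' Simulation configuration
#'
#' Bundles everything that determines a run: group size, model parameters,
#' neighbor-selection strategy, domain (bounded circular arena or unbounded
#' plane), kick budget and seed. A run is fully reproducible from its
#' configuration.
#'
#' @param n_agents number of swimmers (N >= 1; social terms need N >= 2).
#' @param params a [school_params()] object.
#' @param strat a [strategy()] object.
#' @param mode `"bounded"` (circular arena of radius `params$arena_radius`,
#'   wall repulsion active) or `"unbounded"` (no wall term, full-strength
#'   heading noise).
#' @param total_kicks kick budget summed over all agents.
#' @param seed integer seed; every random draw of the run derives from it.
#' @param frame_dt frame-sampling step for the output trajectories in
#'   seconds (default 0.04, the 25 Hz experimental clock). Set to `NA` to
#'   skip frame output.
#' @param init_radius radius of the disk in which initial positions are
#'   drawn uniformly. Defaults to the arena radius in bounded mode and to
#'   0.25 m (a compact start) in unbounded mode.
#' @param influence_truncated apply the attraction cut-off inside the
#'   influence ranking (default `FALSE`: the cut-off affects the summed
#'   turns only).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_agents = 5, params = school_params("model"),
                       strat = strategy("influential", 1),
                       mode = c("bounded", "unbounded"),
                       total_kicks = 10000, seed = 1L, frame_dt = 0.04,
                       init_radius = NULL, influence_truncated = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "school_params"), inherits(strat, "school_strategy"))
  if (total_kicks < 1) stop("total_kicks must be positive")
  resolve_strategy(strat, n_agents) # validates k <= N - 1
  if (is.null(init_radius)) {
    init_radius <- if (mode == "bounded") params$arena_radius else 0.25
  }
  structure(
    list(
      n_agents = as.integer(n_agents), params = params, strat = strat,
      mode = mode, total_kicks = as.integer(total_kicks),
      seed = as.integer(seed), frame_dt = frame_dt,
      init_radius = init_radius,
      influence_truncated = isTRUE(influence_truncated)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N = %d, %s %s, mode = %s, kicks = %d, seed = %d\n",
    x$n_agents, x$strat$kind,
    if (x$strat$kind %in% c("nearest", "random", "influential")) {
      paste0("k = ", x$strat$k)
    } else "",
    x$mode, x$total_kicks, x$seed
  ))
  invisible(x)
}

#' Draw one kick (length and duration)
#'
#' Kick lengths follow the configured bell-shaped law (gamma with mean
#' `mean_kick_length` and shape `kick_shape`, truncated to \eqn{(0,
#' 0.99\,v_0\tau_0)}; or a constant). The duration is the time an
#' exponentially decaying glide at peak speed \eqn{v_0} needs to cover the
#' length: \eqn{\tau = -\tau_0 \log(1 - l/(v_0\tau_0))} (or a sampled /
#' constant duration, depending on `tau_mode`).
#'
#' @param params a [school_params()] object.
#' @param n number of kicks to draw.
#' @return a tibble with columns `length` (m) and `duration` (s).
#' @export
sample_kick <- function(params, n = 1) {
  hi <- 0.99 * params$v0 * params$tau0
  len <- if (params$kick_law == "constant") {
    rep(params$mean_kick_length, n)
  } else {
    vapply(seq_len(n), function(i) {
      repeat {
        l <- stats::rgamma(1, shape = params$kick_shape,
                           scale = params$kick_scale)
        if (l > 0 && l < hi) return(l)
      }
    }, numeric(1))
  }
  dur <- switch(params$tau_mode,
    constant = rep(params$tau_mean, n),
    sampled = vapply(seq_len(n), function(i) {
      repeat {
        tau <- stats::rgamma(1, shape = params$kick_shape,
                             scale = params$tau_mean / params$kick_shape)
        if (tau > 1e-3) return(tau)
      }
    }, numeric(1)),
    from_length = kick_duration_from_length(len, params)
  )
  tibble::tibble(length = len, duration = dur)
}

#' Glide duration implied by a kick length
#'
#' @param length kick length(s) in meters (must be `< v0 * tau0`).
#' @param params a [school_params()] object.
#' @return duration(s) in seconds.
#' @export
kick_duration_from_length <- function(length, params) {
  if (any(length >= params$v0 * params$tau0)) {
    stop("kick length must be smaller than v0 * tau0")
  }
  -params$tau0 * log(1 - length / (params$v0 * params$tau0))
}

#' Position along a glide
#'
#' During a glide the swimmer moves along a straight segment of length
#' `kick_length` from its kick-start position, with traveled fraction
#' \eqn{f(\Delta t) = (1 - e^{-\Delta t/\tau_0}) / (1 - e^{-\tau/\tau_0})},
#' so that \eqn{f(0) = 0} and \eqn{f(\tau) = 1}.
#'
#' @param start length-2 kick start position (m).
#' @param heading kick heading (radians).
#' @param kick_length kick length (m).
#' @param kick_duration kick duration \eqn{\tau} (s).
#' @param dt time since kick onset, in `[0, kick_duration]`.
#' @param params a [school_params()] object (for \eqn{\tau_0}).
#' @return length-2 numeric position.
#' @export
glide_position <- function(start, heading, kick_length, kick_duration, dt,
                           params) {
  if (any(dt < -1e-12) || any(dt > kick_duration + 1e-12)) {
    stop("dt outside the kick interval [0, duration]")
  }
  f <- (1 - exp(-dt / params$tau0)) / (1 - exp(-kick_duration / params$tau0))
  f <- pmin(pmax(f, 0), 1)
  c(start[1] + f * kick_length * cos(heading),
    start[2] + f * kick_length * sin(heading))
}

# Initial state: uniform positions in a disk, uniform headings, a first kick
# per agent, and first kick-end times staggered inside [0, min tau) so that
# every agent kicks exactly once before any agent kicks twice.
# Returns a matrix with columns x, y, heading, len, tau, t_end.
init_school_state <- function(cfg) {
  n <- cfg$n_agents
  p <- cfg$params
  r <- cfg$init_radius * sqrt(stats::runif(n))
  a <- stats::runif(n, -pi, pi)
  x <- r * cos(a)
  y <- r * sin(a)
  heading <- stats::runif(n, -pi, pi)
  kk <- sample_kick(p, n)
  len <- kk$length
  tau <- kk$duration
  if (cfg$mode == "bounded") {
    R2 <- p$arena_radius^2
    for (i in seq_len(n)) {
      ok <- FALSE
      for (htry in 1:51) {
        if (htry > 1) heading[i] <- stats::runif(1, -pi, pi)
        for (ltry in 1:50) {
          ex <- x[i] + len[i] * cos(heading[i])
          ey <- y[i] + len[i] * sin(heading[i])
          if (ex^2 + ey^2 <= R2) {
            ok <- TRUE
            break
          }
          one <- sample_kick(p, 1)
          len[i] <- one$length
          tau[i] <- one$duration
        }
        if (ok) break
      }
      if (!ok) stop("could not place initial kick inside the arena")
    }
  }
  stagger <- min(tau) * (seq_len(n) - 1 + stats::runif(n)) / n
  cbind(x = x, y = y, heading = heading, len = len, tau = tau, t_end = stagger)
}

#' Run one burst-and-coast school simulation
#'
#' Event-driven simulation of the full configuration: kicks are processed
#' in time order; at each kick the focal swimmer selects its neighbors
#' (glide-interpolated to the kick time), turns by the summed wall, noise
#' and social contributions, and draws a new kick length and duration. In
#' bounded mode a kick whose straight endpoint would leave the arena is
#' re-drawn (up to 50 length resamples, then up to 50 noise redraws).
#'
#' @param cfg a [sim_config()] object.
#' @param init optional initial-state matrix (columns `x`, `y`, `heading`,
#'   `len`, `tau`, `t_end`), overriding the seeded initialization; used
#'   mainly for symmetry and reproducibility checks.
#' @return an object of class `school_sim`: a list with
#'   \describe{
#'     \item{trajectories}{tibble `time_s`, `agent_id`, `x_m`, `y_m`,
#'       `heading_rad`, frame-sampled at `cfg$frame_dt`.}
#'     \item{kicks}{tibble `time_s`, `agent_id`, `x_m`, `y_m`, `dphi_rad`,
#'       `heading_rad`, `length_m`, `duration_s`, `neighbors` (list column
#'       of selected indices).}
#'     \item{config}{the configuration.}
#'     \item{duration_s}{time of the last kick event.}
#'   }
#' @examples
#' cfg <- sim_config(n_agents = 5, total_kicks = 200, seed = 42)
#' sim <- run_simulation(cfg)
#' head(sim$kicks)
#' @export
run_simulation <- function(cfg, init = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  if (is.null(init)) init <- init_school_state(cfg)
  res <- resolve_strategy(cfg$strat, cfg$n_agents)
  raw <- .simulate_school_cpp(
    init, unclass(cfg$params), res$code, res$k,
    cfg$mode == "bounded", cfg$total_kicks,
    if (is.na(cfg$frame_dt)) -1 else cfg$frame_dt,
    TRUE, 1.0, cfg$influence_truncated
  )
  kicks <- tibble::tibble(
    time_s = raw$kicks[, 1],
    agent_id = as.integer(raw$kicks[, 2]),
    x_m = raw$kicks[, 3], y_m = raw$kicks[, 4],
    dphi_rad = raw$kicks[, 5], heading_rad = raw$kicks[, 6],
    length_m = raw$kicks[, 7], duration_s = raw$kicks[, 8],
    neighbors = raw$neighbors
  )
  traj <- tibble::tibble(
    time_s = raw$frame_time,
    agent_id = raw$frame_agent,
    x_m = raw$frame_x, y_m = raw$frame_y,
    heading_rad = raw$frame_heading
  )
  structure(
    list(
      trajectories = traj, kicks = kicks, config = cfg,
      duration_s = raw$duration
    ),
    class = "school_sim"
  )
}

#' @export
print.school_sim <- function(x, ...) {
  cat(sprintf(
    "<school_sim> N = %d, %s, %d kicks over %.1f s (%d frames)\n",
    x$config$n_agents, x$config$mode, nrow(x$kicks), x$duration_s,
    nrow(x$trajectories) / max(x$config$n_agents, 1)
  ))
  invisible(x)
}

# fast per-run summary used by ensembles: C(t), P(t) on the frame grid
# computed straight from the raw engine output (no tibble overhead)
frame_summary <- function(raw, n) {
  tt <- raw$frame_time
  nf <- length(tt) / n
  x <- matrix(raw$frame_x, nrow = n)
  y <- matrix(raw$frame_y, nrow = n)
  h <- matrix(raw$frame_heading, nrow = n)
  xb <- colMeans(x)
  yb <- colMeans(y)
  C <- colMeans(sqrt((x - rep(xb, each = n))^2 + (y - rep(yb, each = n))^2))
  P <- sqrt(colMeans(cos(h))^2 + colMeans(sin(h))^2)
  list(time = tt[seq(1, length(tt), by = n)], C = C, P = P)
}

#' Run an ensemble of independent simulations
#'
#' Repeats a configuration `n_runs` times with independent seeds derived
#' from the configuration seed, and aggregates group cohesion and
#' polarization: per-time-bin ensemble means \eqn{\langle C(t)\rangle},
#' \eqn{\langle C^2(t)\rangle}, \eqn{\langle P(t)\rangle} (over the time
#' span common to all runs) and steady-state summaries, defined as the
#' average over the time window holding the last 10% of each run's kicks,
#' then across runs.
#'
#' @param cfg a [sim_config()] object.
#' @param n_runs number of independent runs.
#' @param frame_dt frame step used for the ensemble observables (default
#'   0.4 s; ensemble means and steady-state time averages do not need the
#'   25 Hz resolution of single-run output).
#' @param steady_fraction fraction of each run (in kick count, from the
#'   end) averaged for the steady-state summaries (default 0.1).
#' @return an object of class `school_ensemble`: a list with `series` (a
#'   tibble `time_s`, `mean_C`, `mean_C2`, `mean_P`, `n_runs`), `steady` (a
#'   tibble with one row per run: `run`, `seed`, `C_ss`, `P_ss`), and the
#'   scalar summaries `mean_C_ss`, `mean_P_ss`.
#' @export
run_ensemble <- function(cfg, n_runs = 100, frame_dt = 0.4,
                         steady_fraction = 0.1) {
  stopifnot(inherits(cfg, "sim_config"), n_runs >= 1)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  res <- resolve_strategy(cfg$strat, cfg$n_agents)
  n <- cfg$n_agents
  runs <- vector("list", n_runs)
  steady <- matrix(NA_real_, n_runs, 2)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    init <- init_school_state(cfg)
    raw <- .simulate_school_cpp(
      init, unclass(cfg$params), res$code, res$k,
      cfg$mode == "bounded", cfg$total_kicks, frame_dt,
      FALSE, 1.0, cfg$influence_truncated
    )
    s <- frame_summary(raw, n)
    runs[[r]] <- s
    # steady state: time window of the last `steady_fraction` of kicks
    t_lo <- (1 - steady_fraction) * raw$duration
    w <- s$time >= t_lo
    steady[r, ] <- c(mean(s$C[w]), mean(s$P[w]))
  }
  n_common <- min(vapply(runs, function(s) length(s$time), integer(1)))
  Cm <- vapply(runs, function(s) s$C[seq_len(n_common)], numeric(n_common))
  Pm <- vapply(runs, function(s) s$P[seq_len(n_common)], numeric(n_common))
  series <- tibble::tibble(
    time_s = runs[[1]]$time[seq_len(n_common)],
    mean_C = rowMeans(Cm),
    mean_C2 = rowMeans(Cm^2),
    mean_P = rowMeans(Pm),
    n_runs = n_runs
  )
  structure(
    list(
      series = series,
      steady = tibble::tibble(
        run = seq_len(n_runs), seed = seeds,
        C_ss = steady[, 1], P_ss = steady[, 2]
      ),
      mean_C_ss = mean(steady[, 1]),
      mean_P_ss = mean(steady[, 2]),
      config = cfg, n_runs = n_runs
    ),
    class = "school_ensemble"
  )
}

#' @export
print.school_ensemble <- function(x, ...) {
  cat(sprintf(
    "<school_ensemble> %d runs x %d kicks (%s, %s k = %d)\n",
    x$n_runs, x$config$total_kicks, x$config$mode, x$config$strat$kind,
    resolve_strategy(x$config$strat, x$config$n_agents)$k
  ))
  cat(sprintf(
    "  steady state: <C> = %.4f m, <P> = %.4f\n", x$mean_C_ss, x$mean_P_ss
  ))
  invisible(x)
}

#' Critical attraction cut-off
#'
#' Sweeps the attraction cut-off distance `d_cut` over a grid: for each
#' value an ensemble is run and the steady-state mean cohesion recorded.
#' The critical cut-off \eqn{d^*_{cut}} is estimated as the smallest grid
#' value from which cohesion stays below the escape threshold for all
#' larger cut-offs (above \eqn{d^*_{cut}} the group is cohesive, below it
#' the swimmers diffuse).
#'
#' @param cfg a [sim_config()] object (its `params$d_cut` is overridden by
#'   the grid values).
#' @param cutoff_grid increasing vector of `d_cut` values (m).
#' @param n_runs ensemble size per grid value.
#' @param escape_threshold steady-state cohesion (m) above which the group
#'   is considered dispersed (default 0.5 m).
#' @param frame_dt frame step for ensemble observables (s).
#' @param statistic per-grid-point summary compared against the threshold:
#'   `"mean"` (ensemble mean, the classical choice) or `"median"` (the
#'   typical run). At moderate ensemble sizes the mean is dominated by
#'   rare group-fission events -- a single fissioned run contributes a
#'   steady-state cohesion of tens of meters -- so the median is the more
#'   faithful regime classifier for desk-scale sweeps.
#' @return an object of class `cutoff_sweep`: a list with `sweep` (tibble
#'   `d_cut`, `mean_C_ss`, `median_C_ss`, `mean_P_ss`, `escape_fraction`,
#'   `cohesive`) and `d_cut_critical` (boundary value with a warning if the
#'   grid does not bracket the transition).
#' @export
find_critical_cutoff <- function(cfg, cutoff_grid, n_runs = 100,
                                 escape_threshold = 0.5, frame_dt = 0.4,
                                 statistic = c("mean", "median")) {
  stopifnot(all(diff(cutoff_grid) > 0))
  statistic <- match.arg(statistic)
  rows <- purrr::map_dfr(seq_along(cutoff_grid), function(i) {
    d <- cutoff_grid[i]
    cfg_d <- cfg
    cfg_d$params$d_cut <- d
    cfg_d$seed <- cfg$seed + i # independent but reproducible per grid point
    ens <- run_ensemble(cfg_d, n_runs = n_runs, frame_dt = frame_dt)
    tibble::tibble(
      d_cut = d, mean_C_ss = ens$mean_C_ss,
      median_C_ss = stats::median(ens$steady$C_ss),
      mean_P_ss = ens$mean_P_ss,
      escape_fraction = mean(ens$steady$C_ss > escape_threshold)
    )
  })
  stat_col <- if (statistic == "mean") rows$mean_C_ss else rows$median_C_ss
  rows$cohesive <- stat_col < escape_threshold
  # smallest grid value from which all larger cut-offs are cohesive
  ok_from <- rev(cumprod(rev(rows$cohesive))) > 0
  if (all(ok_from)) {
    warning("entire grid is cohesive; returning the lower boundary")
    dstar <- cutoff_grid[1]
  } else if (!any(ok_from)) {
    warning("entire grid is diffusive; returning the upper boundary")
    dstar <- cutoff_grid[length(cutoff_grid)]
  } else {
    dstar <- cutoff_grid[which(ok_from)[1]]
  }
  structure(
    list(
      sweep = rows, d_cut_critical = dstar,
      escape_threshold = escape_threshold, statistic = statistic,
      config = cfg, n_runs = n_runs
    ),
    class = "cutoff_sweep"
  )
}

#' @export
print.cutoff_sweep <- function(x, ...) {
  cat(sprintf(
    "<cutoff_sweep> %d grid points, %d runs each; d*_cut = %.3g m (threshold %.2g m)\n",
    nrow(x$sweep), x$n_runs, x$d_cut_critical, x$escape_threshold
  ))
  invisible(x)
}
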