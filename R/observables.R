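#' Group cohesion
#'
#' Mean Euclidean distance of the swimmers to their barycenter -- the
#' effective radius of the group. An RMS variant (root mean squared
#' distance) is available for sensitivity checks.
#'
#' @param x,y coordinates of the N swimmers (m), N >= 2.
#' @param rms if `TRUE`, return the RMS distance instead of the mean.
#' @return cohesion in meters.
#' @examples
#' cohesion(c(0, 0.02, -0.02, 0, 0), c(0, 0, 0, 0.02, -0.02)) # 0.016
#' @export
cohesion <- function(x, y, rms = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- sqrt((x - mean(x))^2 + (y - mean(y))^2)
  if (rms) sqrt(mean(d^2)) else mean(d)
}

#' Group polarization
#'
#' Norm of the mean unit-heading vector: 1 for a perfectly aligned group,
#' of order \eqn{1/\sqrt{N}} for uncorrelated headings.
#'
#' @param headings headings of the N swimmers (radians).
#' @return polarization in `[0, 1]`.
#' @examples
#' polarization(c(0, 0, 0, 0, pi)) # 0.6
#' @export
polarization <- function(headings) {
  stopifnot(length(headings) >= 1)
  sqrt(mean(cos(headings))^2 + mean(sin(headings))^2)
}

#' Wall state of the group barycenter
#'
#' Distance of the barycenter to the wall, \eqn{r_{wB} = R - \|u_B\|}, and
#' relative angle of the barycenter heading to the wall,
#' \eqn{\theta_{wB} = \phi_B - \theta_B} (heading angle minus polar
#' position angle), so that \eqn{|\theta_{wB}| \approx \pi/2} when the
#' group swims parallel to the wall.
#'
#' @param x,y swimmer coordinates (m), tank-centered.
#' @param vx,vy swimmer velocity components (m/s).
#' @param arena_radius tank radius R (m).
#' @return a one-row tibble with `r_wb` (m) and `theta_wb` (radians; `NA`
#'   when the barycenter sits exactly at the origin or is at rest).
#' @export
barycenter_wall_state <- function(x, y, vx, vy, arena_radius) {
  xb <- mean(x)
  yb <- mean(y)
  vxb <- mean(vx)
  vyb <- mean(vy)
  r <- sqrt(xb^2 + yb^2)
  theta_wb <- if (r == 0 || (vxb == 0 && vyb == 0)) {
    NA_real_
  } else {
    wrap_angle(atan2(vyb, vxb) - atan2(yb, xb))
  }
  tibble::tibble(r_wb = arena_radius - r, theta_wb = theta_wb)
}

#' Rotation indices of the group
#'
#' `gamma` is the mean angular-momentum-like index of rotation of the
#' swimmers about the tank center, \eqn{\Gamma = \langle \sin(\phi_i -
#' \theta_i)\rangle}; `gamma_b` is the same quantity computed with
#' positions and velocities relative to the (translating) barycenter,
#' \eqn{\Gamma_B = \langle \sin(\bar\phi_i - \bar\theta_i)\rangle}.
#' Swimmers whose relative speed is below `eps` contribute 0 to
#' \eqn{\Gamma_B} (a purely translating group has \eqn{\Gamma_B = 0}).
#'
#' @param x,y positions (m), tank frame centered at the origin.
#' @param vx,vy velocities (m/s).
#' @param eps near-zero relative-speed guard (m/s).
#' @return a one-row tibble with `gamma` and `gamma_b`, both in `[-1, 1]`.
#' @export
rotation_indices <- function(x, y, vx, vy, eps = 1e-6) {
  stopifnot(length(x) >= 2)
  phi <- atan2(vy, vx)
  theta <- atan2(y, x)
  gamma <- mean(sin(phi - theta))
  xr <- x - mean(x)
  yr <- y - mean(y)
  vxr <- vx - mean(vx)
  vyr <- vy - mean(vy)
  sp <- sqrt(vxr^2 + vyr^2)
  contrib <- ifelse(sp < eps, 0, sin(atan2(vyr, vxr) - atan2(yr, xr)))
  tibble::tibble(gamma = gamma, gamma_b = mean(contrib))
}

#' Counter-milling index
#'
#' \eqn{Q = \Gamma_B \cdot \mathrm{sign}(\Gamma)}: negative when the
#' swimmers rotate about their barycenter in the direction opposite to the
#' group's rotation about the tank center (counter-milling), positive for
#' co-rotation (super-milling), 0 for pure translation or when
#' \eqn{\Gamma = 0}.
#'
#' @inheritParams rotation_indices
#' @return Q in `[-1, 1]`.
#' @export
counter_milling_index <- function(x, y, vx, vy, eps = 1e-6) {
  g <- rotation_indices(x, y, vx, vy, eps)
  g$gamma_b * sign(g$gamma)
}

#' Frame-wise collective observables of a trajectory set
#'
#' Computes, for every frame of a trajectory table, the five collective
#' observables: cohesion `C`, polarization `P`, barycenter wall distance
#' `r_wb` and wall angle `theta_wb` (bounded mode only), the rotation
#' indices and the counter-milling index `Q`. Velocities are estimated by
#' backward finite differences on the frame clock (the first frame is
#' dropped from velocity-based quantities). If a `heading_rad` column is
#' present it is used for the polarization; otherwise headings are taken
#' from the finite-difference velocities.
#'
#' @param traj a trajectory tibble with columns `time_s`, `agent_id`,
#'   `x_m`, `y_m` and optionally `heading_rad` (e.g.
#'   `run_simulation(cfg)$trajectories`), or a `school_sim` object.
#' @param arena_radius tank radius (m) for the wall observables; `NULL`
#'   (default) omits them -- use in unbounded mode.
#' @param eps near-zero relative-speed guard for the milling indices (m/s).
#' @param milling_frame frame for the barycenter rotation index
#'   \eqn{\Gamma_B}: `"translating"` (the literal formulas; a group
#'   circling the arena in rigid formation scores \eqn{Q = +1}) or
#'   `"co_rotating"` (the orbital rotation \eqn{\dot\phi_B\,\hat z \times
#'   \bar u_i} is subtracted from the relative velocities first, so a
#'   rigidly co-rotating group scores 0 and a formation of fixed
#'   orientation -- the window-cleaning motion -- scores \eqn{-1}).
#' @return a tibble with one row per frame: `time_s`, `cohesion_m`,
#'   `polarization`, `gamma`, `gamma_b`, `q`, and (if `arena_radius` is
#'   given) `r_wb_m`, `theta_wb_rad`.
#' @examples
#' sim <- run_simulation(sim_config(total_kicks = 300, seed = 7))
#' obs <- compute_observables(sim, arena_radius = 0.25)
#' dplyr::summarise(obs, mean(cohesion_m), mean(polarization))
#' @export
compute_observables <- function(traj, arena_radius = NULL, eps = 1e-6,
                                milling_frame = c("translating", "co_rotating")) {
  milling_frame <- match.arg(milling_frame)
  if (inherits(traj, "school_sim")) {
    if (is.null(arena_radius) && traj$config$mode == "bounded") {
      arena_radius <- traj$config$params$arena_radius
    }
    traj <- traj$trajectories
  }
  need <- c("time_s", "agent_id", "x_m", "y_m")
  if (!all(need %in% names(traj))) {
    stop("trajectory table must have columns ", paste(need, collapse = ", "))
  }
  traj <- dplyr::arrange(traj, .data$time_s, .data$agent_id)
  n <- length(unique(traj$agent_id))
  times <- unique(traj$time_s)
  nf <- length(times)
  if (nrow(traj) != n * nf) {
    stop("trajectory table is not on a common clock (missing frames)")
  }
  x <- matrix(traj$x_m, nrow = n)
  y <- matrix(traj$y_m, nrow = n)
  dt <- diff(times)
  vx <- cbind(NA_real_, (x[, -1, drop = FALSE] - x[, -nf, drop = FALSE]) /
    rep(dt, each = n))
  vy <- cbind(NA_real_, (y[, -1, drop = FALSE] - y[, -nf, drop = FALSE]) /
    rep(dt, each = n))
  h <- if ("heading_rad" %in% names(traj)) {
    matrix(traj$heading_rad, nrow = n)
  } else {
    atan2(vy, vx)
  }

  # all observables vectorized over frames (columns)
  xb <- colMeans(x)
  yb <- colMeans(y)
  C <- colMeans(sqrt((x - rep(xb, each = n))^2 + (y - rep(yb, each = n))^2))
  P <- sqrt(colMeans(cos(h))^2 + colMeans(sin(h))^2)
  phi <- atan2(vy, vx)
  theta <- atan2(y, x)
  gamma <- colMeans(sin(phi - theta))
  vxb <- colMeans(vx)
  vyb <- colMeans(vy)
  xr <- x - rep(xb, each = n)
  yr <- y - rep(yb, each = n)
  vxr <- vx - rep(vxb, each = n)
  vyr <- vy - rep(vyb, each = n)
  if (milling_frame == "co_rotating") {
    # subtract the orbital rotation rate of the barycenter heading
    phi_b <- atan2(vyb, vxb)
    dphi_b <- c(NA_real_, wrap_angle(diff(phi_b))) / c(NA_real_, dt)
    vxr <- vxr + rep(dphi_b, each = n) * yr
    vyr <- vyr - rep(dphi_b, each = n) * xr
  }
  contrib <- sin(atan2(vyr, vxr) - atan2(yr, xr))
  contrib[sqrt(vxr^2 + vyr^2) < eps] <- 0
  gamma_b <- colMeans(contrib)
  out <- tibble::tibble(
    time_s = times,
    cohesion_m = C,
    polarization = P,
    gamma = gamma,
    gamma_b = gamma_b,
    q = gamma_b * sign(gamma)
  )
  if (!is.null(arena_radius)) {
    rb <- sqrt(xb^2 + yb^2)
    theta_wb <- wrap_angle(atan2(vyb, vxb) - atan2(yb, xb))
    theta_wb[rb == 0 | (vxb == 0 & vyb == 0)] <- NA_real_
    out$r_wb_m <- arena_radius - rb
    out$theta_wb_rad <- theta_wb
  }
  out
}
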