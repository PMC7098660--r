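#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians (any real values).
#' @return angles wrapped to the half-open interval \eqn{(-\pi, \pi]},
#'   counter-clockwise positive.
#' @export
wrap_angle <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- pi
  w
}

#' Relative state of a neighbor as seen by a focal swimmer
#'
#' Computes the triplet that the pairwise interaction functions depend on:
#' the inter-individual distance \eqn{d_{ij}}, the viewing angle
#' \eqn{\psi_{ij}} (angle from the focal heading to the vector pointing at
#' the neighbor) and the heading difference \eqn{\phi_{ij} = \phi_j -
#' \phi_i}. The construction is asymmetric: \eqn{\psi_{ij} \neq \psi_{ji}}
#' in general.
#'
#' @param focal_position,neighbor_position numeric length-2 vectors (x, y)
#'   in meters.
#' @param focal_heading,neighbor_heading headings in radians.
#' @return a one-row tibble with columns `d_ij` (m), `psi_ij`, `phi_ij`
#'   (radians in \eqn{(-\pi, \pi]}) and `degenerate` (`TRUE` when the two
#'   positions coincide, in which case `psi_ij` is defined as 0).
#' @examples
#' relative_state(c(0, 0), 0, c(0, 1), pi / 2)
#' @export
relative_state <- function(focal_position, focal_heading,
                           neighbor_position, neighbor_heading) {
  stopifnot(
    length(focal_position) == 2, length(neighbor_position) == 2,
    all(is.finite(focal_position)), all(is.finite(neighbor_position))
  )
  dx <- neighbor_position[1] - focal_position[1]
  dy <- neighbor_position[2] - focal_position[2]
  d <- sqrt(dx^2 + dy^2)
  degenerate <- d == 0
  psi <- if (degenerate) 0 else wrap_angle(atan2(dy, dx) - focal_heading)
  tibble::tibble(
    d_ij = d,
    psi_ij = psi,
    phi_ij = wrap_angle(neighbor_heading - focal_heading),
    degenerate = degenerate
  )
}

#' Wall state of a swimmer in the circular arena
#'
#' @param position numeric length-2 (x, y) in tank-centered coordinates, m.
#' @param heading heading in radians.
#' @param arena_radius arena radius in meters.
#' @return a one-row tibble with `r_w` (distance to the nearest wall point,
#'   m) and `theta_w` (relative angle of the heading to the wall, radians;
#'   \eqn{\theta_w = \phi - \theta} with \eqn{\theta} the polar position
#'   angle, so \eqn{|\theta_w| = \pi/2} means motion parallel to the wall).
#' @export
wall_state <- function(position, heading, arena_radius) {
  stopifnot(length(position) == 2, all(is.finite(position)))
  r <- sqrt(sum(position^2))
  if (r > arena_radius) {
    warning("position lies outside the arena; r_w clamped at 0")
  }
  tibble::tibble(
    r_w = max(arena_radius - r, 0),
    theta_w = wrap_angle(heading - atan2(position[2], position[1]))
  )
}

#' Heading change induced by the wall
#'
#' The wall acts as a centripetal repulsion
#' \eqn{\delta\phi_w = F_w(r_w)\, O_w(\theta_w)} with a Gaussian radial
#' profile \eqn{F_w(r_w) = \gamma_w \exp[-(r_w/l_w)^2]} and the odd angular
#' modulation \eqn{O_w(\theta_w) = \beta_w \sin\theta_w (1 +
#' 0.7\cos 2\theta_w)}.
#'
#' @param r_w distance to the wall, m (vectorized).
#' @param theta_w relative angle of heading to the wall, radians.
#' @param params a [school_params()] object.
#' @return heading increment in radians.
#' @export
wall_turn <- function(r_w, theta_w, params) {
  params$gamma_w * exp(-(r_w / params$l_w)^2) *
    params$beta_w * sin(theta_w) * (1 + 0.7 * cos(2 * theta_w))
}

#' Spontaneous (noise) heading change
#'
#' The stochastic heading fluctuation at a kick is
#' \eqn{\gamma_R (1 - \alpha e^{-(r_w/l_w)^2})\, g} with `g` a standard
#' normal variate: fluctuations are damped near the wall and approach
#' \eqn{\gamma_R g} far from it. The variate is supplied by the caller so
#' the function stays deterministic. With `r_w = Inf` (unbounded domain)
#' the result is exactly \eqn{\gamma_R g}.
#'
#' @inheritParams wall_turn
#' @param g standard normal variate(s).
#' @return heading increment in radians.
#' @export
noise_turn <- function(r_w, g, params) {
  damp <- ifelse(is.infinite(r_w), 0, exp(-(r_w / params$l_w)^2))
  params$gamma_R * (1 - params$alpha * damp) * g
}

#' Pairwise attraction heading change
#'
#' \eqn{\delta\phi_{Att} = F_{Att}(d)\, O_{Att}(\psi)\, E_{Att}(\phi)} with
#' \deqn{F_{Att}(d) = \gamma_{Att} \frac{d/d_{Att} - 1}{1 + (d/l_{Att})^2},}
#' \eqn{O_{Att}(\psi) = \beta_{Att}\sin\psi\,(1 - 0.33\cos\psi)} and
#' \eqn{E_{Att}(\phi) = \lambda_{Att}(1 - 0.48\cos\phi - 0.31\cos 2\phi)}.
#' The interaction is repulsive below the balance distance \eqn{d_{Att}}
#' (sign flip) and is truncated to zero beyond the attraction cut-off
#' `params$d_cut` (the cut-off applies to the attraction only). A
#' degenerate pair at `d = 0` contributes zero.
#'
#' @param d_ij distance between the two swimmers, m (vectorized).
#' @param psi_ij viewing angle, radians.
#' @param phi_ij heading difference, radians.
#' @param params a [school_params()] object.
#' @return heading increment in radians.
#' @export
attraction_turn <- function(d_ij, psi_ij, phi_ij, params) {
  f <- params$gamma_Att * (d_ij / params$d_Att - 1) / (1 + (d_ij / params$l_Att)^2)
  o <- params$beta_Att * sin(psi_ij) * (1 - 0.33 * cos(psi_ij))
  e <- params$lambda_Att * (1 - 0.48 * cos(phi_ij) - 0.31 * cos(2 * phi_ij))
  out <- f * o * e
  out[d_ij > params$d_cut | d_ij == 0] <- 0
  out
}

#' Pairwise alignment heading change
#'
#' \eqn{\delta\phi_{Ali} = F_{Ali}(d)\, E_{Ali}(\psi)\, O_{Ali}(\phi)} with
#' \deqn{F_{Ali}(d) = \gamma_{Ali}\,(d/d_{Ali} + 1)\, e^{-(d/l_{Ali})^2},}
#' \eqn{E_{Ali}(\psi) = \beta_{Ali}(1 + 0.6\cos\psi - 0.32\cos 2\psi)} and
#' \eqn{O_{Ali}(\phi) = \lambda_{Ali}\sin\phi\,(1 + 0.3\cos 2\phi)}. The
#' attraction cut-off does **not** apply to the alignment.
#'
#' @inheritParams attraction_turn
#' @return heading increment in radians.
#' @export
alignment_turn <- function(d_ij, psi_ij, phi_ij, params) {
  f <- params$gamma_Ali * (d_ij / params$d_Ali + 1) * exp(-(d_ij / params$l_Ali)^2)
  e <- params$beta_Ali * (1 + 0.6 * cos(psi_ij) - 0.32 * cos(2 * psi_ij))
  o <- params$lambda_Ali * sin(phi_ij) * (1 + 0.3 * cos(2 * phi_ij))
  out <- f * e * o
  out[d_ij == 0] <- 0
  out
}

#' Influence of a neighbor on a focal swimmer
#'
#' The influence is the absolute pairwise contribution to the focal heading
#' change, \eqn{I_{ij} = |\delta\phi_{Att} + \delta\phi_{Ali}|}. It drives
#' the "most influential" neighbor-selection strategy. By default the
#' attraction entering the influence is *not* truncated at `d_cut`
#' (the cut-off is applied when summing turns, not when ranking neighbors),
#' so the ranking stays well defined beyond the cut-off.
#'
#' @inheritParams attraction_turn
#' @param truncated if `TRUE`, apply the attraction cut-off inside the
#'   influence as well.
#' @return non-negative influence value(s).
#' @export
pair_influence <- function(d_ij, psi_ij, phi_ij, params, truncated = FALSE) {
  p <- params
  if (!truncated) p$d_cut <- Inf
  abs(
    attraction_turn(d_ij, psi_ij, phi_ij, p) +
      alignment_turn(d_ij, psi_ij, phi_ij, p)
  )
}

#' Total heading increment at a kick
#'
#' Sums the wall, noise and selected social contributions:
#' \eqn{\delta\phi = \delta\phi_w + \delta\phi_R + \sum_{\langle j,i\rangle}
#' (\delta\phi_{Att} + \delta\phi_{Ali})}. `pairs` holds the relative state
#' of the neighbors *already selected* by the interaction strategy. In the
#' unbounded domain pass `r_w = Inf` (wall term omitted, full-strength
#' noise).
#'
#' @param r_w distance to the wall (m), or `Inf` for the unbounded domain.
#' @param theta_w relative angle of heading to the wall (ignored when
#'   `r_w = Inf`).
#' @param pairs a data frame with columns `d_ij`, `psi_ij`, `phi_ij` (one
#'   row per selected neighbor; zero rows allowed).
#' @param g standard normal variate for the noise term.
#' @param params a [school_params()] object.
#' @return the heading increment in radians (not yet wrapped).
#' @export
heading_increment <- function(r_w, theta_w, pairs, g, params) {
  wall <- if (is.infinite(r_w)) 0 else wall_turn(r_w, theta_w, params)
  social <- 0
  if (!is.null(pairs) && nrow(pairs) > 0) {
    social <- sum(
      attraction_turn(pairs$d_ij, pairs$psi_ij, pairs$phi_ij, params) +
        alignment_turn(pairs$d_ij, pairs$psi_ij, pairs$phi_ij, params)
    )
  }
  wall + noise_turn(r_w, g, params) + social
}
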