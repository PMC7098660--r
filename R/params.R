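#' Model parameters for a burst-and-coast school
#'
#' Builds the full parameter set of the pairwise interaction model: wall
#' repulsion, spontaneous heading noise, long-range attraction and alignment
#' between swimmers, and the kinematics of the kick-and-glide cycle. Two
#' named presets are shipped: `"model"` (parameters extracted from
#' rummy-nose tetra experiments and used for agent simulations) and
#' `"robots"` (the rescaled set used to drive small wheeled robots).
#'
#' All distances are in meters, times in seconds, angles in radians;
#' intensities (`gamma_*`) and angular normalization constants (`beta_*`,
#' `lambda_*`) are dimensionless. The angular functions of the model are
#' normalized so that the mean of their square over \eqn{(-\pi, \pi]} is 1;
#' the shipped constants are the published ones and are treated as
#' authoritative (see [angular_normalization()] to recompute them by
#' quadrature).
#'
#' @param preset `"model"` or `"robots"`, the base parameter set.
#' @param ... named overrides for any field, e.g. `gamma_w = 0` to disable
#'   the wall, or `d_cut = 0.5` to truncate the attraction at 0.5 m.
#'
#' @return An object of class `school_params`: a named list with fields
#'   `gamma_R`, `alpha`, `gamma_w`, `l_w`, `beta_w`, `gamma_Att`, `l_Att`,
#'   `d_Att`, `beta_Att`, `lambda_Att`, `gamma_Ali`, `l_Ali`, `d_Ali`,
#'   `beta_Ali`, `lambda_Ali`, `v0`, `tau0`, `mean_kick_length`,
#'   `arena_radius`, `d_cut`, plus the kick-law controls `kick_law`
#'   (`"gamma"` or `"constant"`), `kick_shape` (gamma shape of the
#'   kick-length law) and `tau_mode` / `tau_mean` (how kick durations are
#'   obtained; see Details).
#'
#' @details
#' Kick lengths are drawn from a bell-shaped law with mean
#' `mean_kick_length`; by default a gamma law with shape `kick_shape = 4`
#' truncated to \eqn{(0, 0.99\, v_0 \tau_0)}. Kick durations follow from the
#' exponentially decaying glide, \eqn{\tau = -\tau_0 \log(1 - l/(v_0
#' \tau_0))} (`tau_mode = "from_length"`). The robots preset instead uses a
#' constant kick length and a constant duration `tau_mean` (`tau_mode =
#' "constant"`), matching the robot controller; `tau_mode = "sampled"` draws
#' durations from a gamma law with mean `tau_mean` independently of length.
#'
#' @examples
#' p <- school_params("model")
#' p$gamma_Att
#' unbounded <- school_params("model", gamma_w = 0)
#' @export
school_params <- function(preset = c("model", "robots"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    model = list(
      gamma_R = 0.45, alpha = 2 / 3,
      gamma_w = 0.15, l_w = 0.06, beta_w = 1.9157,
      gamma_Att = 0.12, l_Att = 0.20, d_Att = 0.03,
      beta_Att = 1.395, lambda_Att = 0.9326,
      gamma_Ali = 0.09, l_Ali = 0.20, d_Ali = 0.06,
      beta_Ali = 0.9012, lambda_Ali = 1.6385,
      v0 = 0.14, tau0 = 0.8, mean_kick_length = 0.07,
      arena_radius = 0.25, d_cut = Inf,
      kick_law = "gamma", kick_shape = 4,
      tau_mode = "from_length", tau_mean = 0.5,
      noise_convention = "boundary", boundary_rejection = "length_first"
    ),
    robots = list(
      gamma_R = 0.1, alpha = 1,
      gamma_w = 0.79, l_w = 0.11, beta_w = 1.9157,
      gamma_Att = 0.18, l_Att = 0.37, d_Att = 0.18,
      beta_Att = 1.395, lambda_Att = 0.9326,
      gamma_Ali = 0.04, l_Ali = 0.37, d_Ali = 0.05,
      beta_Ali = 0.9012, lambda_Ali = 1.6385,
      v0 = 0.0375, tau0 = 0.9, mean_kick_length = 0.074,
      arena_radius = 0.42, d_cut = Inf,
      kick_law = "constant", kick_shape = 4,
      tau_mode = "constant", tau_mean = 1.3,
      noise_convention = "boundary", boundary_rejection = "length_first"
    )
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown) > 0) {
    stop("unknown school_params field(s): ", paste(unknown, collapse = ", "))
  }
  base[names(dots)] <- dots
  base$preset <- preset
  validate_school_params(structure(base, class = "school_params"))
}

validate_school_params <- function(p) {
  pos <- c(
    "l_w", "beta_w", "l_Att", "d_Att", "beta_Att", "lambda_Att", "l_Ali",
    "d_Ali", "beta_Ali", "lambda_Ali", "v0", "tau0", "mean_kick_length",
    "arena_radius", "tau_mean", "kick_shape"
  )
  for (f in pos) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("school_params field '", f, "' must be a single positive number")
    }
  }
  # intensities may be zero (a zero intensity switches the term off, as the
  # unbounded protocol does for the wall)
  for (f in c("gamma_R", "gamma_w", "gamma_Att", "gamma_Ali")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop("school_params field '", f, "' must be a single non-negative number")
    }
  }
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must lie in [0, 1]")
  if (!(is.numeric(p$d_cut) && length(p$d_cut) == 1 && p$d_cut > 0)) {
    stop("d_cut must be a positive number or Inf")
  }
  p$kick_law <- match.arg(p$kick_law, c("gamma", "constant"))
  p$tau_mode <- match.arg(p$tau_mode, c("from_length", "sampled", "constant"))
  p$noise_convention <- match.arg(p$noise_convention, c("boundary", "local"))
  p$boundary_rejection <- match.arg(p$boundary_rejection, c("length_first", "joint"))
  if (p$tau_mode == "from_length" && p$mean_kick_length >= p$v0 * p$tau0) {
    stop(
      "mean_kick_length must be smaller than v0 * tau0 when kick durations ",
      "are derived from the glide relation (tau_mode = \"from_length\")"
    )
  }
  p$kick_scale <- kick_length_scale(p)
  p
}

# Gamma-law scale calibrated so that the mean *after* truncation to
# (0, 0.99 v0 tau0) equals mean_kick_length: physically every kick is
# shorter than the maximal glide length v0*tau0, and the published mean
# refers to the realized (truncated) law.
kick_length_scale <- function(p) {
  if (p$kick_law != "gamma") {
    return(p$mean_kick_length / p$kick_shape)
  }
  hi <- 0.99 * p$v0 * p$tau0
  sh <- p$kick_shape
  trunc_mean <- function(s) {
    sh * s * stats::pgamma(hi, sh + 1, scale = s) /
      stats::pgamma(hi, sh, scale = s)
  }
  upper_lim <- hi * sh / (sh + 1) # truncated mean as scale -> Inf
  if (p$mean_kick_length >= upper_lim) {
    stop(
      "mean_kick_length too close to the maximal glide length ",
      "0.99 * v0 * tau0; the truncated kick-length law cannot reach it"
    )
  }
  naive <- p$mean_kick_length / sh
  if (trunc_mean(naive) >= p$mean_kick_length - 1e-12) {
    return(naive) # truncation negligible
  }
  stats::uniroot(
    function(s) trunc_mean(s) - p$mean_kick_length,
    c(naive, hi * 100), tol = 1e-12
  )$root
}

#' @export
print.school_params <- function(x, ...) {
  cat("<school_params> preset:", x$preset, "\n")
  cat(sprintf(
    "  noise      gamma_R = %.3g, alpha = %.3g\n", x$gamma_R, x$alpha
  ))
  cat(sprintf(
    "  wall       gamma_w = %.3g, l_w = %.3g m, beta_w = %.5g\n",
    x$gamma_w, x$l_w, x$beta_w
  ))
  cat(sprintf(
    "  attraction gamma_Att = %.3g, l_Att = %.3g m, d_Att = %.3g m, d_cut = %.3g m\n",
    x$gamma_Att, x$l_Att, x$d_Att, x$d_cut
  ))
  cat(sprintf(
    "  alignment  gamma_Ali = %.3g, l_Ali = %.3g m, d_Ali = %.3g m\n",
    x$gamma_Ali, x$l_Ali, x$d_Ali
  ))
  cat(sprintf(
    "  kicks      law = %s (mean %.3g m), v0 = %.3g m/s, tau0 = %.3g s, tau_mode = %s\n",
    x$kick_law, x$mean_kick_length, x$v0, x$tau0, x$tau_mode
  ))
  cat(sprintf("  arena      radius = %.3g m\n", x$arena_radius))
  invisible(x)
}

#' Read and write parameter sets as YAML
#'
#' Parameter presets are serialized as flat YAML maps whose keys are exactly
#' the `school_params` field names. `read_school_params()` validates the
#' result; unknown keys are an error.
#'
#' @param path file path.
#' @param params a `school_params` object (for writing).
#' @return `read_school_params()` returns a `school_params` object.
#' @export
read_school_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) stop("malformed parameter file")
  preset <- raw$preset %||% "model"
  raw$preset <- NULL
  raw$kick_scale <- NULL # derived at construction, not a free field
  if (!is.null(raw$d_cut) && identical(raw$d_cut, "infinite")) raw$d_cut <- Inf
  do.call(school_params, c(list(preset = preset), raw))
}

#' @rdname read_school_params
#' @export
write_school_params <- function(params, path) {
  stopifnot(inherits(params, "school_params"))
  out <- unclass(params)
  out$kick_scale <- NULL
  if (is.infinite(out$d_cut)) out$d_cut <- "infinite"
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' Recompute an angular normalization constant by quadrature
#'
#' Each angular interaction function is scaled so that the mean of its
#' square over \eqn{(-\pi, \pi]} equals 1. This helper recomputes the
#' implied constant \eqn{[\,(1/2\pi)\int f^2\,]^{-1/2}} for the published
#' angular series, as an independent check of the stored constants. Note
#' that the published attraction-evenness constant (`lambda_Att` = 0.9326)
#' is *not* consistent with its rounded series coefficients (quadrature
#' gives about 0.9272); the stored constant is kept authoritative.
#'
#' @param which one of `"wall_odd"` (\eqn{\sin\theta(1 + 0.7\cos 2\theta)}),
#'   `"att_odd"` (\eqn{\sin\psi(1 - 0.33\cos\psi)}), `"att_even"`
#'   (\eqn{1 - 0.48\cos\phi - 0.31\cos 2\phi}), `"ali_even"`
#'   (\eqn{1 + 0.6\cos\psi - 0.32\cos 2\psi}) or `"ali_odd"`
#'   (\eqn{\sin\phi(1 + 0.3\cos 2\phi)}).
#' @return the normalization constant (a single number).
#' @export
angular_normalization <- function(which = c(
                                    "wall_odd", "att_odd", "att_even",
                                    "ali_even", "ali_odd"
                                  )) {
  which <- match.arg(which)
  f <- switch(which,
    wall_odd = function(x) (sin(x) * (1 + 0.7 * cos(2 * x)))^2,
    att_odd = function(x) (sin(x) * (1 - 0.33 * cos(x)))^2,
    att_even = function(x) (1 - 0.48 * cos(x) - 0.31 * cos(2 * x))^2,
    ali_even = function(x) (1 + 0.6 * cos(x) - 0.32 * cos(2 * x))^2,
    ali_odd = function(x) (sin(x) * (1 + 0.3 * cos(2 * x)))^2
  )
  ms <- stats::integrate(f, -pi, pi, rel.tol = 1e-12)$value / (2 * pi)
  1 / sqrt(ms)
}
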