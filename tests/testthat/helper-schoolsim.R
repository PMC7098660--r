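# shared fixtures built in code

quick_cfg <- function(strat = strategy("influential", 1), mode = "unbounded",
                      kicks = 500, seed = 1L, n = 5, params = school_params("model"),
                      ...) {
  sim_config(
    n_agents = n, params = params, strat = strat, mode = mode,
    total_kicks = kicks, seed = seed, ...
  )
}

# straightforward independent recomputation of the frame observables,
# used as the brute-force oracle
brute_observables <- function(x, y, vx, vy, R = NULL, eps = 1e-6) {
  n <- length(x)
  xb <- mean(x)
  yb <- mean(y)
  C <- mean(sqrt((x - xb)^2 + (y - yb)^2))
  gam <- mean(sin(atan2(vy, vx) - atan2(y, x)))
  gb <- 0
  for (i in seq_len(n)) {
    vxr <- vx[i] - mean(vx)
    vyr <- vy[i] - mean(vy)
    if (sqrt(vxr^2 + vyr^2) >= eps) {
      gb <- gb + sin(atan2(vyr, vxr) - atan2(y[i] - yb, x[i] - xb)) / n
    }
  }
  out <- list(C = C, gamma = gam, gamma_b = gb, q = gb * sign(gam))
  if (!is.null(R)) {
    out$r_wb <- R - sqrt(xb^2 + yb^2)
    out$theta_wb <- schoolsim::wrap_angle(
      atan2(mean(vy), mean(vx)) - atan2(yb, xb)
    )
  }
  out
}
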