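p_model <- school_params("model")

test_that("kick durations follow the exponential-glide relation", {
  expect_equal(kick_duration_from_length(0.07, p_model),
    -0.8 * log(1 - 0.07 / (0.14 * 0.8)),
    tolerance = 1e-12
  )
  expect_equal(kick_duration_from_length(0.07, p_model), 0.7847, tolerance = 1e-4)
  # short-kick limit: tau -> l / v0
  expect_equal(kick_duration_from_length(1e-6, p_model), 1e-6 / 0.14,
    tolerance = 1e-5
  )
  expect_error(kick_duration_from_length(0.2, p_model), "v0")
})

test_that("sampled kick lengths keep the published mean within 1%", {
  set.seed(123)
  kk <- sample_kick(p_model, 1e5)
  expect_equal(mean(kk$length), 0.07, tolerance = 0.01)
  expect_true(all(kk$length > 0 & kk$length < 0.99 * 0.14 * 0.8))
  expect_equal(kk$duration, kick_duration_from_length(kk$length, p_model))
  # constant mode (robots)
  kr <- sample_kick(school_params("robots"), 10)
  expect_equal(kr$length, rep(0.074, 10))
  expect_equal(kr$duration, rep(1.3, 10))
})

test_that("glide interpolation hits its endpoints and the closed-form midpoint", {
  l <- 0.07
  tau <- kick_duration_from_length(l, p_model)
  expect_equal(glide_position(c(1, 2), 0, l, tau, 0, p_model), c(1, 2))
  expect_equal(glide_position(c(1, 2), 0, l, tau, tau, p_model), c(1 + l, 2))
  # frozen from the closed form f = (1 - e^(-dt/tau0)) / (1 - e^(-tau/tau0))
  f_half <- (1 - exp(-(tau / 2) / 0.8)) / (1 - exp(-tau / 0.8))
  mid <- glide_position(c(0, 0), 0, l, tau, tau / 2, p_model)
  expect_equal(mid[1], f_half * l, tolerance = 1e-12)
  expect_equal(mid[1], 0.043414, tolerance = 1e-4)
  expect_error(glide_position(c(0, 0), 0, l, tau, 2 * tau, p_model), "interval")
})

test_that("the engine reproduces the R-level model formulas kick by kick", {
  cfg <- sim_config(
    n_agents = 2, strat = strategy("influential", 1), mode = "unbounded",
    total_kicks = 12, seed = 31
  )
  sim <- run_simulation(cfg)

  # independent replay: same seed, pure R bookkeeping and model functions
  p <- cfg$params
  hi <- 0.99 * p$v0 * p$tau0
  set.seed(cfg$seed)
  init <- schoolsim:::init_school_state(cfg)
  st <- data.frame(
    x0 = init[, "x"], y0 = init[, "y"], h = init[, "heading"],
    len = init[, "len"], tau = init[, "tau"], t0 = 0, t_end = init[, "t_end"]
  )
  glide <- function(a, t) {
    dt <- t - st$t0[a]
    f <- (1 - exp(-dt / p$tau0)) / (1 - exp(-st$tau[a] / p$tau0))
    f <- min(max(f, 0), 1)
    c(st$x0[a] + f * st$len[a] * cos(st$h[a]),
      st$y0[a] + f * st$len[a] * sin(st$h[a]))
  }
  for (ev in seq_len(cfg$total_kicks)) {
    i <- which.min(st$t_end)
    t <- st$t_end[i]
    j <- 3 - i
    pos_i <- glide(i, t)
    pos_j <- glide(j, t)
    rs <- relative_state(pos_i, st$h[i], pos_j, st$h[j])
    social <- attraction_turn(rs$d_ij, rs$psi_ij, rs$phi_ij, p) +
      alignment_turn(rs$d_ij, rs$psi_ij, rs$phi_ij, p)
    g <- rnorm(1)
    # engine noise convention: damping factor held at its boundary value
    dphi <- p$gamma_R * (1 - p$alpha) * g + social
    newh <- wrap_angle(st$h[i] + dphi)
    repeat {
      l <- rgamma(1, shape = p$kick_shape, scale = p$kick_scale)
      if (l > 0 && l < hi) break
    }
    tau <- kick_duration_from_length(l, p)

    row <- sim$kicks[ev, ]
    expect_equal(row$agent_id, i)
    expect_equal(row$time_s, t, tolerance = 1e-12)
    expect_equal(c(row$x_m, row$y_m), pos_i, tolerance = 1e-12)
    expect_equal(row$dphi_rad, dphi, tolerance = 1e-12)
    expect_equal(row$heading_rad, newh, tolerance = 1e-12)
    expect_equal(row$length_m, l, tolerance = 1e-12)
    expect_equal(row$duration_s, tau, tolerance = 1e-12)
    expect_identical(row$neighbors[[1]], as.integer(j))

    st$x0[i] <- pos_i[1]
    st$y0[i] <- pos_i[2]
    st$h[i] <- newh
    st$len[i] <- l
    st$tau[i] <- tau
    st$t0[i] <- t
    st$t_end[i] <- t + tau
  }
})

test_that("kick budget and agenda bookkeeping are exact", {
  cfg <- quick_cfg(kicks = 400, seed = 2)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$kicks), 400)
  expect_true(all(diff(sim$kicks$time_s) >= 0)) # global time order
  for (a in 1:5) {
    ka <- sim$kicks[sim$kicks$agent_id == a, ]
    # onsets strictly increasing and separated by the previous duration
    expect_true(all(diff(ka$time_s) > 0))
    expect_equal(diff(ka$time_s), head(ka$duration_s, -1), tolerance = 1e-9)
  }
  # fair initial stagger: a budget of N kicks serves every agent exactly once
  sim1 <- run_simulation(quick_cfg(kicks = 5, seed = 9))
  expect_setequal(sim1$kicks$agent_id, 1:5)
})

test_that("all strategy kinds coincide at k = N - 1 (bit-identical logs)", {
  sims <- lapply(
    list(strategy("nearest", 4), strategy("random", 4),
         strategy("influential", 4), strategy("all")),
    function(s) run_simulation(quick_cfg(strat = s, kicks = 600, seed = 77))
  )
  for (i in 2:4) {
    expect_identical(
      sims[[1]]$kicks[, -9], sims[[i]]$kicks[, -9]
    )
    expect_identical(sims[[1]]$kicks$neighbors, sims[[i]]$kicks$neighbors)
    expect_identical(sims[[1]]$trajectories, sims[[i]]$trajectories)
  }
})

test_that("null dynamics: with all intensities zero every agent moves straight", {
  p0 <- school_params("model",
    gamma_R = 0, gamma_w = 0, gamma_Att = 0, gamma_Ali = 0
  )
  cfg <- quick_cfg(params = p0, kicks = 100, seed = 4)
  sim <- run_simulation(cfg)
  expect_true(all(abs(sim$kicks$dphi_rad) == 0))
  tr <- sim$trajectories
  for (a in 1:5) {
    ta <- tr[tr$agent_id == a, ]
    h0 <- ta$heading_rad[1]
    expect_true(all(ta$heading_rad == h0))
    # displacement always along the fixed heading
    dx <- diff(ta$x_m)
    dy <- diff(ta$y_m)
    expect_equal(dx * sin(h0), dy * cos(h0), tolerance = 1e-12)
  }
})

test_that("mirror symmetry: reflected initial conditions with negated noise", {
  cfg <- quick_cfg(strat = strategy("influential", 2), kicks = 300, seed = 12)
  set.seed(99)
  init <- schoolsim:::init_school_state(cfg)
  res <- schoolsim:::resolve_strategy(cfg$strat, cfg$n_agents)
  run_raw <- function(init, sign) {
    set.seed(555)
    schoolsim:::.simulate_school_cpp(
      init, unclass(cfg$params), res$code, res$k, FALSE,
      cfg$total_kicks, 0.2, TRUE, sign, FALSE
    )
  }
  a <- run_raw(init, 1.0)
  init_m <- init
  init_m[, "y"] <- -init_m[, "y"]
  init_m[, "heading"] <- wrap_angle(-init_m[, "heading"])
  b <- run_raw(init_m, -1.0)
  expect_equal(b$frame_x, a$frame_x, tolerance = 1e-10)
  expect_equal(b$frame_y, -a$frame_y, tolerance = 1e-10)
  expect_equal(b$kicks[, 5], -a$kicks[, 5], tolerance = 1e-10) # dphi negated
  expect_identical(b$neighbors, a$neighbors)
})

test_that("bounded mode keeps every frame inside the arena", {
  cfg <- sim_config(
    n_agents = 5, strat = strategy("nearest", 2), mode = "bounded",
    total_kicks = 4000, seed = 8, frame_dt = 0.04
  )
  sim <- run_simulation(cfg)
  r <- sqrt(sim$trajectories$x_m^2 + sim$trajectories$y_m^2)
  expect_true(all(r <= p_model$arena_radius + 1e-9))
})

test_that("a single-run ensemble equals the run it wraps", {
  cfg <- quick_cfg(kicks = 1000, seed = 3)
  ens <- run_ensemble(cfg, n_runs = 1, frame_dt = 0.5)
  set.seed(cfg$seed)
  seed1 <- sample.int(.Machine$integer.max - 1L, 1)
  cfg1 <- quick_cfg(kicks = 1000, seed = seed1, frame_dt = 0.5)
  sim <- run_simulation(cfg1)
  obs <- compute_observables(sim)
  m <- min(nrow(ens$series), nrow(obs))
  expect_equal(ens$series$mean_C[1:m], obs$cohesion_m[1:m], tolerance = 1e-9)
  expect_equal(ens$series$mean_P[1:m], obs$polarization[1:m], tolerance = 1e-9)
})

test_that("cut-off sweeps warn when the grid does not bracket the transition", {
  cfg <- quick_cfg(kicks = 1500, seed = 6)
  expect_warning(
    sw <- find_critical_cutoff(cfg, c(4, 5), n_runs = 3, statistic = "median"),
    "cohesive"
  )
  expect_equal(sw$d_cut_critical, 4)
  expect_warning(
    sw2 <- find_critical_cutoff(cfg, c(0.05, 0.1), n_runs = 3, statistic = "median"),
    "diffusive"
  )
  expect_equal(sw2$d_cut_critical, 0.1)
})
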