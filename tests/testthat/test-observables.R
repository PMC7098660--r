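test_that("cohesion is the mean distance to the barycenter", {
  expect_equal(cohesion(c(0, 0), c(0, 1)), 0.5) # two agents at distance 1
  expect_equal(cohesion(rep(0.3, 4), rep(-1, 4)), 0) # coincident
  # cross: barycenter at origin, four at 0.02, one at 0
  expect_equal(
    cohesion(c(0, 0.02, -0.02, 0, 0), c(0, 0, 0, 0.02, -0.02)),
    (0 + 4 * 0.02) / 5
  )
  expect_equal(
    cohesion(c(0, 0.02, -0.02, 0, 0), c(0, 0, 0, 0.02, -0.02), rms = TRUE),
    sqrt(4 * 0.02^2 / 5)
  )
})

test_that("polarization reproduces the worked heading configurations", {
  expect_equal(polarization(rep(1.234, 5)), 1)
  expect_equal(polarization(c(0, 0, 0, 0, pi)), 0.6)
  expect_equal(polarization(c(0, 0, 0, pi, pi)), 0.2)
  expect_equal(polarization(c(0, pi / 2, pi, -pi / 2)), 0, tolerance = 1e-12)
})

test_that("barycenter wall state follows the relative-angle convention", {
  # barycenter at origin
  b0 <- barycenter_wall_state(c(-0.1, 0.1), c(0, 0), c(1, 1), c(0, 0), 0.25)
  expect_equal(b0$r_wb, 0.25)
  # barycenter near the wall moving +y: parallel, CCW -> theta_wb = pi/2
  b <- barycenter_wall_state(0.25 - 0.07, 0, 0, 0.1, 0.25)
  expect_equal(b$r_wb, 0.07)
  expect_equal(b$theta_wb, pi / 2)
  # barycenter exactly at the origin with zero velocity: angle missing
  expect_true(is.na(barycenter_wall_state(c(-1, 1), c(0, 0), c(0, 0), c(0, 0), 0.25)$theta_wb))
})

test_that("rotation indices distinguish rigid rotation, translation and sign", {
  th <- seq(0, 2 * pi, length.out = 6)[-6]
  x <- 0.1 * cos(th) + 0.05 # offset center; gamma uses the tank frame
  y <- 0.1 * sin(th)
  # rigid CCW rotation about the ring center: v = omega x r (z cross)
  vx <- -(y - 0)
  vy <- (x - 0.05)
  g <- rotation_indices(x - 0.05, y, vx, vy) # centered at origin
  expect_equal(g$gamma, 1, tolerance = 1e-12)
  expect_equal(g$gamma_b, 1, tolerance = 1e-12)
  expect_equal(counter_milling_index(x - 0.05, y, vx, vy), 1)
  # CW rotation flips the sign
  gcw <- rotation_indices(x - 0.05, y, -vx, -vy)
  expect_equal(gcw$gamma, -1, tolerance = 1e-12)
  # pure translation: relative velocities vanish, gamma_b = 0, Q = 0
  gt <- rotation_indices(x, y, rep(0.3, 5), rep(0.1, 5))
  expect_equal(gt$gamma_b, 0)
  expect_equal(counter_milling_index(x, y, rep(0.3, 5), rep(0.1, 5)), 0)
})

test_that("counter-milling is negative when inner and outer rotations oppose", {
  # group barycenter circles the tank CW while individuals circle the
  # barycenter CCW
  th <- seq(0, 2 * pi, length.out = 6)[-6]
  bx <- 0.15
  by <- 0
  vbx <- 0
  vby <- -0.1 # CW about the tank center
  x <- bx + 0.03 * cos(th)
  y <- by + 0.03 * sin(th)
  vx <- vbx - (y - by)
  vy <- vby + (x - bx) # CCW about the barycenter
  q <- counter_milling_index(x, y, vx, vy)
  expect_lt(q, 0)
})

test_that("frame observables agree with a brute-force recomputation", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:7, 1)
    x <- runif(n, -0.2, 0.2)
    y <- runif(n, -0.2, 0.2)
    vx <- rnorm(n, 0, 0.1)
    vy <- rnorm(n, 0, 0.1)
    ref <- brute_observables(x, y, vx, vy, R = 0.25)
    g <- rotation_indices(x, y, vx, vy)
    expect_equal(g$gamma, ref$gamma, tolerance = 1e-12)
    expect_equal(g$gamma_b, ref$gamma_b, tolerance = 1e-12)
    expect_equal(cohesion(x, y), ref$C, tolerance = 1e-12)
    bw <- barycenter_wall_state(x, y, vx, vy, 0.25)
    expect_equal(bw$r_wb, ref$r_wb, tolerance = 1e-12)
    expect_equal(bw$theta_wb, ref$theta_wb, tolerance = 1e-12)
  }
})

test_that("observables respect their ranges and invariances", {
  sim <- run_simulation(quick_cfg(
    strat = strategy("influential", 2), mode = "bounded",
    kicks = 1500, seed = 21, frame_dt = 0.2
  ))
  obs <- compute_observables(sim)
  expect_true(all(obs$cohesion_m >= 0))
  expect_true(all(obs$polarization >= 0 & obs$polarization <= 1, na.rm = TRUE))
  expect_true(all(abs(obs$gamma) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(abs(obs$gamma_b) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(abs(obs$q) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(obs$r_wb_m >= -1e-9 & obs$r_wb_m <= 0.25 + 1e-9))

  # translation invariance of C, P, Q; rotation invariance of C, P, Q;
  # mirror: C, P, Q invariant, theta_wb negates
  tr <- sim$trajectories
  shift <- dplyr::mutate(tr, x_m = x_m + 0.4, y_m = y_m - 0.2)
  obs_s <- compute_observables(shift)
  expect_equal(obs_s$cohesion_m, obs$cohesion_m, tolerance = 1e-9)
  expect_equal(obs_s$polarization, obs$polarization, tolerance = 1e-9)

  a <- 0.7
  rot <- dplyr::mutate(tr,
    xr = cos(a) * x_m - sin(a) * y_m, yr = sin(a) * x_m + cos(a) * y_m,
    heading_rad = wrap_angle(heading_rad + a)
  )
  rot <- dplyr::transmute(rot, time_s, agent_id, x_m = xr, y_m = yr, heading_rad)
  obs_r <- compute_observables(rot, arena_radius = 0.25)
  expect_equal(obs_r$cohesion_m, obs$cohesion_m, tolerance = 1e-9)
  expect_equal(obs_r$polarization, obs$polarization, tolerance = 1e-9)
  expect_equal(obs_r$q, obs$q, tolerance = 1e-9)
  expect_equal(obs_r$r_wb_m, obs$r_wb_m, tolerance = 1e-9)

  mir <- dplyr::mutate(tr, y_m = -y_m, heading_rad = wrap_angle(-heading_rad))
  obs_m <- compute_observables(mir, arena_radius = 0.25)
  expect_equal(obs_m$cohesion_m, obs$cohesion_m, tolerance = 1e-9)
  expect_equal(obs_m$polarization, obs$polarization, tolerance = 1e-9)
  expect_equal(obs_m$q, obs$q, tolerance = 1e-9)
  expect_equal(obs_m$theta_wb_rad, -obs$theta_wb_rad, tolerance = 1e-9)
})

test_that("milling frames separate window-cleaning from vinyl-record motion", {
  dt <- 0.04
  tt <- seq(0, 8, by = dt)
  omega <- 0.5
  Rb <- 0.15
  offs <- 0.03 * cbind(cos(2 * pi * (1:5) / 5), sin(2 * pi * (1:5) / 5))
  mk <- function(rotating) {
    purrr::map_dfr(seq_along(tt), function(f) {
      a <- omega * tt[f]
      ox <- if (rotating) offs[, 1] * cos(a) - offs[, 2] * sin(a) else offs[, 1]
      oy <- if (rotating) offs[, 1] * sin(a) + offs[, 2] * cos(a) else offs[, 2]
      tibble::tibble(
        time_s = tt[f], agent_id = 1:5,
        x_m = Rb * cos(a) + ox, y_m = Rb * sin(a) + oy
      )
    })
  }
  # window-cleaning (formation of fixed orientation circling the tank):
  # literal formulas give ~0, the co-rotating frame calls it counter-milling
  win <- mk(rotating = FALSE)
  q_lit <- mean(compute_observables(win)$q, na.rm = TRUE)
  q_rot <- mean(compute_observables(win, milling_frame = "co_rotating")$q,
    na.rm = TRUE
  )
  expect_lt(abs(q_lit), 0.05)
  expect_lt(abs(q_rot - (-1)), 0.05)
  # vinyl record (rigid co-rotation): literal +1, co-rotating ~0
  vin <- mk(rotating = TRUE)
  q_lit2 <- mean(compute_observables(vin)$q, na.rm = TRUE)
  q_rot2 <- mean(compute_observables(vin, milling_frame = "co_rotating")$q,
    na.rm = TRUE
  )
  expect_lt(abs(q_lit2 - 1), 0.05)
  expect_lt(abs(q_rot2), 0.05)
})
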