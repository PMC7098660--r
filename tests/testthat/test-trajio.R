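test_that("pixel conversion is exact and invertible", {
  raw <- tibble::tibble(
    frame = c(1, 1, 2, 2), agent_id = c(1, 2, 1, 2),
    x_px = c(960, 1960, 960.5, 1959), y_px = c(540, 540, 541, 539)
  )
  tr <- pixels_to_meters(raw, origin_px = c(960, 540))
  expect_equal(tr$x_m[1], 0)
  expect_equal(tr$y_m[1], 0)
  expect_equal(tr$x_m[2], 1000 * 0.53e-3) # 1000 px -> 0.53 m
  expect_equal(tr$time_s, (raw$frame - 1) * 0.04)
  # round trip
  back <- tr$x_m / 0.53e-3 + 960
  expect_equal(back, raw$x_px, tolerance = 1e-9)
  expect_warning(
    pixels_to_meters(raw, origin_px = c(960, 540), arena_radius = 0.25),
    "outside"
  )
})

test_that("identity reassignment undoes label swaps and preserves positions", {
  # already-consistent labels are unchanged
  t0 <- tibble::tibble(
    time_s = rep(c(0, 0.04, 0.08), each = 2),
    agent_id = rep(1:2, 3),
    x_m = c(0, 1, 0.01, 1.01, 0.02, 1.02),
    y_m = 0
  )
  expect_equal(reassign_identities(t0), t0)

  # the documented 2x2 case: labels swapped at the second frame
  t1 <- tibble::tibble(
    time_s = rep(c(0, 0.04), each = 2),
    agent_id = rep(1:2, 2),
    x_m = c(0, 1, 1.05, 0.05), # observation for "1" jumped to 1.05
    y_m = 0
  )
  fixed <- reassign_identities(t1)
  expect_equal(fixed$x_m[fixed$time_s > 0 & fixed$agent_id == 1], 0.05)
  expect_equal(fixed$x_m[fixed$time_s > 0 & fixed$agent_id == 2], 1.05)

  # pure relabeling: per-frame position multisets are untouched
  set.seed(10)
  tr <- tibble::tibble(
    time_s = rep(seq(0, 0.4, by = 0.04), each = 4),
    agent_id = rep(1:4, 11),
    x_m = rnorm(44), y_m = rnorm(44)
  )
  out <- reassign_identities(tr)
  for (tt in unique(tr$time_s)) {
    expect_setequal(
      round(out$x_m[out$time_s == tt], 12),
      round(tr$x_m[tr$time_s == tt], 12)
    )
  }
  # greedy agrees with exact on well-separated tracks
  expect_equal(reassign_identities(t1, method = "greedy"), fixed)
})

test_that("rest filtering applies the published displacement threshold", {
  dt <- 0.04
  nf <- 200
  mk <- function(speed) {
    # one moving reference agent plus one at the probed speed
    tibble::tibble(
      time_s = rep((seq_len(nf) - 1) * dt, each = 2),
      agent_id = rep(1:2, nf),
      x_m = as.vector(rbind((seq_len(nf) - 1) * dt * 0.05,
        (seq_len(nf) - 1) * dt * speed)),
      y_m = 0
    )
  }
  still <- rest_filter(mk(0))
  expect_true(all(still$rest))
  # 10 mm/s exceeds the 6.6 mm/s rest threshold: nothing removed
  expect_false(any(rest_filter(mk(0.010))$rest))
  # 5 mm/s is below it: removed
  expect_true(all(rest_filter(mk(0.005))$rest))
  expect_warning(rest_filter(mk(0)[1:40, ]), "shorter")
})

test_that("sequence extraction keeps only long continuous runs", {
  dt <- 0.04
  mk_traj <- function(nf, rest_frames = integer(0)) {
    tr <- tibble::tibble(
      time_s = rep((seq_len(nf) - 1) * dt, each = 2),
      agent_id = rep(1:2, nf),
      x_m = rnorm(2 * nf), y_m = rnorm(2 * nf)
    )
    tr$rest <- rep(seq_len(nf) %in% rest_frames, each = 2)
    tr
  }
  # unbroken 60 s record -> one sequence
  expect_length(extract_sequences(mk_traj(1500)), 1)
  # 19 s -> none
  expect_length(extract_sequences(mk_traj(475)), 0)
  # 30 s, 2 s rest gap, 25 s -> two sequences
  nf <- 1425 # 57 s
  gap <- 751:800
  seqs <- extract_sequences(mk_traj(nf, gap))
  expect_length(seqs, 2)
  expect_gte(diff(range(seqs[[1]]$time_s)) + dt, 20)
  expect_gte(diff(range(seqs[[2]]$time_s)) + dt, 20)
})

test_that("kick detection finds speed minima with the 0.2 s window", {
  dt <- 0.04
  nf <- 250
  t <- (seq_len(nf) - 1) * dt
  # constant-speed agent -> no interior minima -> no kicks
  flat <- tibble::tibble(
    time_s = rep(t, each = 1), agent_id = 1, x_m = 0.05 * t, y_m = 0
  )
  expect_equal(nrow(detect_kicks(flat)), 0)

  # burst-and-coast speed profile: sharp rise at each onset (every 25
  # frames), exponential decay during the glide
  phase <- (seq_len(nf) - 1) %% 25
  speed <- 0.14 * exp(-phase * dt / 0.8)
  x <- cumsum(c(0, speed[-nf] * dt))
  saw <- tibble::tibble(time_s = t, agent_id = 1, x_m = x, y_m = 0)
  kk <- detect_kicks(saw)
  true_onsets <- t[which(phase == 0)]
  true_onsets <- true_onsets[true_onsets > 0.1 & true_onsets < max(t) - 0.1]
  expect_gte(nrow(kk), length(true_onsets))
  for (o in true_onsets) {
    expect_true(min(abs(kk$time_s - o)) <= dt + 1e-9)
  }
})

test_that("a clean fixture round-trips the engine trajectories exactly", {
  fx <- generate_fixture(
    duration_s = 20, noise_sd_m = 0, n_swaps = 0, n_rests = 0, seed = 3
  )
  tr <- pixels_to_meters(fx$raw, origin_px = fx$meta$origin_px)
  expect_equal(tr$x_m, fx$truth$trajectories$x_m, tolerance = 1e-9)
  expect_equal(tr$y_m, fx$truth$trajectories$y_m, tolerance = 1e-9)
})

test_that("fixture corruption is recoverable by the pipeline", {
  fx <- generate_fixture(duration_s = 50, n_swaps = 4, n_rests = 1, seed = 8)
  tr <- pixels_to_meters(fx$raw, origin_px = fx$meta$origin_px)
  fixed <- reassign_identities(tr)
  # after reassignment every track is frame-to-frame continuous
  step <- function(d) {
    x <- matrix(d$x_m, nrow = 5)
    y <- matrix(d$y_m, nrow = 5)
    sqrt(diff(t(x))^2 + diff(t(y))^2)
  }
  expect_lt(max(step(fixed)), 0.03) # no teleports remain
  # rest recovery
  rf <- rest_filter(fixed)
  truth_rest <- matrix(fx$truth$rest$rest, nrow = 5)
  frame_rest <- apply(truth_rest, 2, any)
  flagged <- matrix(rf$rest, nrow = 5)[1, ]
  recall <- sum(flagged & frame_rest) / sum(frame_rest)
  expect_gte(recall, 0.95)
})
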