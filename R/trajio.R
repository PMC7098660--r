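#' Convert raw pixel tracking output to metric, tank-centered trajectories
#'
#' Tracked video data arrive as one row per (frame, individual) with pixel
#' coordinates. This converts them to meters (default factor: 0.53 mm per
#' pixel), recenters on the tank center, and attaches the frame clock.
#'
#' @param raw a data frame with columns `frame`, `agent_id`, `x_px`,
#'   `y_px`.
#' @param factor meters per pixel.
#' @param origin_px length-2 pixel coordinates of the tank center.
#' @param dt frame period in seconds (default 0.04 s, i.e. 25 Hz).
#' @param arena_radius if given, warn when points fall outside the arena
#'   radius plus `tolerance`.
#' @param tolerance slack (m) for the outside-arena warning.
#' @return a trajectory tibble `time_s`, `agent_id`, `x_m`, `y_m` with
#'   attribute `frame_dt`.
#' @export
pixels_to_meters <- function(raw, factor = 0.53e-3, origin_px = c(0, 0),
                             dt = 0.04, arena_radius = NULL,
                             tolerance = 0.01) {
  stopifnot(all(c("frame", "agent_id", "x_px", "y_px") %in% names(raw)))
  out <- tibble::tibble(
    time_s = (raw$frame - min(raw$frame)) * dt,
    agent_id = raw$agent_id,
    x_m = (raw$x_px - origin_px[1]) * factor,
    y_m = (raw$y_px - origin_px[2]) * factor
  )
  if (!is.null(arena_radius)) {
    r <- sqrt(out$x_m^2 + out$y_m^2)
    n_out <- sum(r > arena_radius + tolerance)
    if (n_out > 0) {
      warning(n_out, " point(s) lie outside the arena radius + tolerance")
    }
  }
  attr(out, "frame_dt") <- dt
  out
}

# all permutations of 1..n (rows), lexicographic
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- matrix(c(seq_len(n))[-first][sub], nrow(sub), n - 1L)
    cbind(rep(first, nrow(sub)), rest)
  }))
}

#' Repair identity swaps by frame-to-frame assignment
#'
#' Multi-animal trackers frequently swap the labels of two crossing
#' individuals. This relabels each frame so that the total displacement of
#' all individuals from the previous frame is minimal: the N x N
#' assignment problem is solved exactly (by enumeration over permutations
#' -- globally optimal, and cheap for the small N of these experiments) or
#' greedily (`method = "greedy"`: closest pair first). The multiset of
#' positions in every frame is untouched; only labels move.
#'
#' @param traj a trajectory tibble (`time_s`, `agent_id`, `x_m`, `y_m`).
#' @param method `"optimal"` (exact, N <= 7) or `"greedy"`.
#' @return the relabeled trajectory tibble, same shape and ordering.
#' @export
reassign_identities <- function(traj, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  traj <- dplyr::arrange(traj, .data$time_s, .data$agent_id)
  ids <- sort(unique(traj$agent_id))
  n <- length(ids)
  times <- unique(traj$time_s)
  nf <- length(times)
  if (nrow(traj) != n * nf) stop("equal agent count required in every frame")
  if (method == "optimal" && n > 7) {
    stop("exact assignment supports N <= 7; use method = \"greedy\"")
  }
  x <- matrix(traj$x_m, nrow = n)
  y <- matrix(traj$y_m, nrow = n)
  perms <- if (method == "optimal") all_permutations(n) else NULL
  # assign[, f]: row r of frame f holds the observation given to identity r
  assign_idx <- matrix(seq_len(n), n, nf)
  px <- x[, 1]
  py <- y[, 1]
  for (f in 2:nf) {
    D <- outer(px, x[, f], function(a, b) (a - b)^2) +
      outer(py, y[, f], function(a, b) (a - b)^2)
    if (method == "optimal") {
      costs <- vapply(seq_len(nrow(perms)), function(pp) {
        sum(D[cbind(seq_len(n), perms[pp, ])])
      }, numeric(1))
      a <- perms[which.min(costs), ]
    } else {
      a <- integer(n)
      left_r <- seq_len(n)
      left_c <- seq_len(n)
      Dw <- D
      for (s in seq_len(n)) {
        ij <- which(Dw == min(Dw), arr.ind = TRUE)[1, ]
        a[left_r[ij[1]]] <- left_c[ij[2]]
        Dw <- Dw[-ij[1], -ij[2], drop = FALSE]
        left_r <- left_r[-ij[1]]
        left_c <- left_c[-ij[2]]
      }
    }
    assign_idx[, f] <- a
    px <- x[cbind(a, f)]
    py <- y[cbind(a, f)]
  }
  traj$x_m <- as.vector(x[cbind(as.vector(assign_idx), rep(seq_len(nf), each = n))])
  traj$y_m <- as.vector(y[cbind(as.vector(assign_idx), rep(seq_len(nf), each = n))])
  traj
}

#' Flag rest (freezing) periods
#'
#' A swimmer is considered at rest when its net displacement over a rolling
#' window of `window_frames` frames falls below `min_displacement_m`
#' (defaults: 60 frames and 15.9 mm, i.e. a mean speed under 6.6 mm/s for
#' at least 2.4 s at 25 Hz). All frames covered by such a window, for any
#' individual, are flagged; downstream analysis drops them.
#'
#' @param traj a trajectory tibble.
#' @param window_frames window length in frames.
#' @param min_displacement_m displacement threshold (m).
#' @return the trajectory tibble with an added logical `rest` column
#'   (frame-level: `TRUE` when any individual is at rest).
#' @export
rest_filter <- function(traj, window_frames = 60L,
                        min_displacement_m = 30 * 0.53e-3) {
  traj <- dplyr::arrange(traj, .data$time_s, .data$agent_id)
  ids <- sort(unique(traj$agent_id))
  n <- length(ids)
  times <- unique(traj$time_s)
  nf <- length(times)
  if (nrow(traj) != n * nf) stop("common clock required")
  if (nf < window_frames) {
    warning("sequence shorter than the rest window; nothing flagged")
    traj$rest <- FALSE
    return(traj)
  }
  x <- matrix(traj$x_m, nrow = n)
  y <- matrix(traj$y_m, nrow = n)
  flagged <- rep(FALSE, nf)
  w <- window_frames - 1L
  for (a in seq_len(n)) {
    disp <- sqrt((x[a, (1 + w):nf] - x[a, 1:(nf - w)])^2 +
      (y[a, (1 + w):nf] - y[a, 1:(nf - w)])^2)
    starts <- which(disp < min_displacement_m)
    for (s in starts) flagged[s:(s + w)] <- TRUE
  }
  traj$rest <- rep(flagged, each = n)
  traj
}

#' Extract continuous analysis sequences
#'
#' Splits a rest-filtered trajectory at flagged frames and clock gaps, and
#' keeps the maximal continuous runs lasting at least `min_duration_s`
#' (500 frames at 25 Hz for the default 20 s).
#'
#' @param traj a trajectory tibble, optionally with a `rest` column (from
#'   [rest_filter()]); missing `rest` means nothing is flagged.
#' @param min_duration_s minimum sequence duration (s).
#' @return a list of trajectory tibbles, one per retained sequence, each
#'   with a `sequence` id column.
#' @export
extract_sequences <- function(traj, min_duration_s = 20) {
  traj <- dplyr::arrange(traj, .data$time_s, .data$agent_id)
  if (!"rest" %in% names(traj)) traj$rest <- FALSE
  times <- unique(traj$time_s)
  nf <- length(times)
  n <- nrow(traj) / nf
  keep <- !matrix(traj$rest, nrow = n)[1, ]
  dt <- stats::median(diff(times))
  gap_after <- c(diff(times) > 1.5 * dt, FALSE)
  run_id <- cumsum(c(TRUE, (!keep[-nf] & keep[-1]) | gap_after[-nf])) # new run
  # runs only count kept frames; break runs at flagged frames or gaps
  grp <- ifelse(keep, run_id, NA_integer_)
  seqs <- list()
  for (g in unique(stats::na.omit(grp))) {
    idx <- which(!is.na(grp) & grp == g)
    if (length(idx) < 2) next
    span <- times[idx[length(idx)]] - times[idx[1]]
    if (span + dt >= min_duration_s) {
      sub <- traj[traj$time_s %in% times[idx], ]
      sub$sequence <- length(seqs) + 1L
      seqs[[length(seqs) + 1L]] <- sub
    }
  }
  seqs
}

#' Detect kick onsets from frame-wise speed minima
#'
#' Burst-and-coast kicks are located at the local minima of the speed
#' profile (backward finite differences on the frame clock), using a
#' centered detection window of `window_s` seconds (+-2 frames at 25 Hz
#' for the default 0.2 s). A minimum must be strictly smaller than every
#' earlier value and no larger than every later value in its window, so a
#' plateau yields its earliest frame. Because frame-to-frame tracking
#' noise enters the finite-difference speed at twice its own standard
#' deviation, the speed series is smoothed with a short centered moving
#' average (`smooth_frames`, default 3) before the minima search; set
#' `smooth_frames = 1` for raw speeds.
#'
#' @param traj a trajectory tibble on a common clock (one sequence).
#' @param window_s detection window (s).
#' @param smooth_frames odd width of the centered moving average applied
#'   to the speed series before the minima search.
#' @param min_burst_rise minimum frame-to-frame speed rise (m/s) right
#'   after a candidate minimum for it to count as a kick; bursts
#'   accelerate to about the peak speed within a frame or two, so the
#'   default 0.012 m/s separates them from noise wiggles on the glide
#'   (raising it improves precision on noisy data at some cost in recall).
#' @return a tibble of kick records: `agent_id`, `time_s` (onset),
#'   `x_m`, `y_m`, `heading_rad` (finite-difference heading at onset),
#'   `length_m` and `duration_s` to the next onset of the same individual
#'   (`NA` for its last kick).
#' @export
detect_kicks <- function(traj, window_s = 0.2, smooth_frames = 3L,
                         min_burst_rise = 0.012) {
  stopifnot(smooth_frames >= 1, smooth_frames %% 2 == 1)
  traj <- dplyr::arrange(traj, .data$time_s, .data$agent_id)
  ids <- sort(unique(traj$agent_id))
  n <- length(ids)
  times <- unique(traj$time_s)
  nf <- length(times)
  if (nrow(traj) != n * nf) stop("common clock required")
  dt <- stats::median(diff(times))
  half <- max(1L, floor(window_s / dt / 2))
  x <- matrix(traj$x_m, nrow = n)
  y <- matrix(traj$y_m, nrow = n)
  out <- purrr::map_dfr(seq_len(n), function(a) {
    vx <- c(NA, diff(x[a, ]) / dt)
    vy <- c(NA, diff(y[a, ]) / dt)
    sp_raw <- sqrt(vx^2 + vy^2)
    sp <- sp_raw
    if (smooth_frames > 1) {
      sm <- as.numeric(stats::filter(sp, rep(1 / smooth_frames, smooth_frames)))
      sp[!is.na(sm)] <- sm[!is.na(sm)]
    }
    # A kick terminates the glide with a sharp speed rise; the onset frame
    # sits at the speed minimum immediately before that rise. The rise is
    # the high-SNR feature under tracking noise, so onsets are located
    # where the frame-to-frame speed jump is the largest within the
    # centered detection window (plateaus resolve to the earliest frame)
    # and the rise over the following two frames reaches burst scale.
    jump <- c(sp_raw[-1] - sp_raw[-nf], NA)
    onsets <- integer(0)
    for (j in (half + 2):(nf - half - 1)) {
      w_lo <- jump[(j - half):(j - 1)]
      w_hi <- jump[(j + 1):(j + half)]
      if (!is.na(jump[j]) && all(jump[j] > w_lo, na.rm = TRUE) &&
          all(jump[j] >= w_hi, na.rm = TRUE)) {
        # burst-scale gate: speed rise over the two frames after the onset
        rise2 <- max(sp_raw[(j + 1):min(j + 2, nf)]) - sp_raw[j]
        if (is.finite(rise2) && rise2 >= min_burst_rise) {
          onsets <- c(onsets, j)
        }
      }
    }
    if (length(onsets) == 0) {
      return(tibble::tibble(
        agent_id = integer(0), time_s = numeric(0), x_m = numeric(0),
        y_m = numeric(0), heading_rad = numeric(0), length_m = numeric(0),
        duration_s = numeric(0)
      ))
    }
    nxt <- c(onsets[-1], NA)
    tibble::tibble(
      agent_id = ids[a],
      time_s = times[onsets],
      x_m = x[a, onsets],
      y_m = y[a, onsets],
      heading_rad = atan2(vy[onsets], vx[onsets]),
      length_m = ifelse(is.na(nxt), NA,
        sqrt((x[a, nxt] - x[a, onsets])^2 + (y[a, nxt] - y[a, onsets])^2)
      ),
      duration_s = times[nxt] - times[onsets]
    )
  })
  out
}

#' Generate a synthetic tracked-data fixture
#'
#' Emulates what a video tracker produces from a real school: a
#' burst-and-coast simulation is frame-sampled at 25 Hz, corrupted with
#' additive Gaussian position noise, persistent identity swaps (labels of
#' a random pair exchanged from a random frame onward, as trackers do
#' after a crossing), and rest episodes (the individual freezes in place
#' while its own clock pauses, so its path stays continuous), and finally
#' converted to pixel coordinates. Ground truth (clean trajectories, rest
#' masks, swap events, true kick onsets on the fixture clock) is returned
#' alongside for recovery benchmarking.
#'
#' @param duration_s fixture duration (s).
#' @param n_agents group size.
#' @param params,strat model parameters and neighbor strategy for the
#'   underlying simulation (defaults: model preset, most influential
#'   k = 2, bounded arena).
#' @param noise_sd_m tracking noise s.d. per coordinate (m); default half
#'   a pixel.
#' @param n_swaps number of injected identity-swap events.
#' @param n_rests number of injected rest episodes (each 3-6 s, one
#'   individual at a time).
#' @param seed integer seed.
#' @param factor,origin_px pixel conversion used for the raw table.
#' @return a list with `raw` (tibble `frame`, `agent_id`, `x_px`, `y_px`),
#'   `truth` (list: `trajectories` clean metric tibble with true labels,
#'   `rest` tibble `frame`, `agent_id`, flag, `swaps` tibble of events,
#'   `kicks` tibble of true onsets on the fixture clock), and `meta`
#'   (conversion factor, origin, dt, seed, config).
#' @export
generate_fixture <- function(duration_s = 60, n_agents = 5,
                             params = school_params("model"),
                             strat = strategy("influential", 2),
                             noise_sd_m = 0.5 * 0.53e-3,
                             n_swaps = 5, n_rests = 3, seed = 1L,
                             factor = 0.53e-3, origin_px = c(960, 540)) {
  dt <- 0.04
  set.seed(seed)
  total_kicks <- ceiling(duration_s * n_agents / 0.4) # generous kick budget
  cfg <- sim_config(
    n_agents = n_agents, params = params, strat = strat, mode = "bounded",
    total_kicks = total_kicks, seed = sample.int(2^30, 1), frame_dt = dt
  )
  sim <- run_simulation(cfg)
  if (sim$duration_s < duration_s + 1) stop("simulation shorter than fixture")
  n <- n_agents
  times_e <- unique(sim$trajectories$time_s)
  xe <- matrix(sim$trajectories$x_m, nrow = n)
  ye <- matrix(sim$trajectories$y_m, nrow = n)
  nf <- ceiling(duration_s / dt)

  # per-agent time warp: engine frame index advances except during rests
  resting <- matrix(FALSE, n, nf)
  rest_events <- list()
  if (n_rests > 0) {
    for (r in seq_len(n_rests)) {
      a <- sample.int(n, 1)
      len <- round(stats::runif(1, 3, 6) / dt)
      for (try in 1:50) {
        s0 <- sample.int(nf - len, 1)
        if (!any(resting[a, s0:(s0 + len - 1)])) break
      }
      resting[a, s0:(s0 + len - 1)] <- TRUE
      rest_events[[r]] <- tibble::tibble(
        agent_id = a, frame_start = s0, frame_end = s0 + len - 1L
      )
    }
  }
  eidx <- matrix(0L, n, nf)
  for (a in seq_len(n)) eidx[a, ] <- cumsum(!resting[a, ])
  if (max(eidx) > length(times_e)) stop("engine run too short for time warp")
  xt <- matrix(0, n, nf)
  yt <- matrix(0, n, nf)
  for (a in seq_len(n)) {
    xt[a, ] <- xe[a, eidx[a, ]]
    yt[a, ] <- ye[a, eidx[a, ]]
  }

  # true kick onsets mapped to the fixture clock
  truth_kicks <- dplyr::filter(sim$kicks, .data$time_s < max(times_e))
  fixture_time <- vapply(seq_len(nrow(truth_kicks)), function(i) {
    a <- truth_kicks$agent_id[i]
    ef <- findInterval(truth_kicks$time_s[i], times_e) + 1L # first engine frame >= onset
    j <- match(TRUE, eidx[a, ] >= ef)
    if (is.na(j)) NA_real_ else (j - 1) * dt
  }, numeric(1))
  truth_kicks <- tibble::tibble(
    agent_id = truth_kicks$agent_id,
    time_engine_s = truth_kicks$time_s,
    time_s = fixture_time
  )
  truth_kicks <- truth_kicks[!is.na(truth_kicks$time_s), ]

  # identity swaps: persistent label exchanges from a random frame onward
  labels <- matrix(rep(seq_len(n), nf), n, nf) # labels[slot, frame] = reported id
  swap_events <- list()
  if (n_swaps > 0) {
    sw_frames <- sort(sample(10:(nf - 10), n_swaps))
    for (s in seq_along(sw_frames)) {
      f <- sw_frames[s]
      pair <- sample.int(n, 2)
      sep <- sqrt((xt[pair[1], f] - xt[pair[2], f])^2 +
        (yt[pair[1], f] - yt[pair[2], f])^2)
      step <- max(
        sqrt((xt[pair, f] - xt[pair, f - 1])^2 +
          (yt[pair, f] - yt[pair, f - 1])^2)
      )
      labels[pair, f:nf] <- labels[rev(pair), f:nf]
      swap_events[[s]] <- tibble::tibble(
        frame = f, agent_a = pair[1], agent_b = pair[2],
        separation_m = sep, max_step_m = step
      )
    }
  }

  xn <- xt + stats::rnorm(n * nf, sd = noise_sd_m)
  yn <- yt + stats::rnorm(n * nf, sd = noise_sd_m)

  # raw table carries the *reported* (possibly swapped) labels
  raw <- tibble::tibble(
    frame = rep(seq_len(nf), each = n),
    agent_id = as.vector(labels),
    x_px = as.vector(xn) / factor + origin_px[1],
    y_px = as.vector(yn) / factor + origin_px[2]
  )
  raw <- dplyr::arrange(raw, .data$frame, .data$agent_id)

  truth_traj <- tibble::tibble(
    time_s = rep((seq_len(nf) - 1) * dt, each = n),
    agent_id = rep(seq_len(n), nf),
    x_m = as.vector(xt), y_m = as.vector(yt)
  )
  list(
    raw = raw,
    truth = list(
      trajectories = truth_traj,
      rest = tibble::tibble(
        frame = rep(seq_len(nf), each = n),
        agent_id = rep(seq_len(n), nf),
        rest = as.vector(resting)
      ),
      rest_events = dplyr::bind_rows(rest_events),
      swaps = dplyr::bind_rows(swap_events),
      kicks = truth_kicks
    ),
    meta = list(
      factor = factor, origin_px = origin_px, dt = dt, seed = seed,
      config = cfg, noise_sd_m = noise_sd_m
    )
  )
}
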