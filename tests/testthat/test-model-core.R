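p_model <- school_params("model")

test_that("relative_state computes distance, viewing angle and heading difference", {
  rs <- relative_state(c(0, 0), 0, c(1, 0), 0)
  expect_equal(c(rs$d_ij, rs$psi_ij, rs$phi_ij), c(1, 0, 0))

  rs <- relative_state(c(0, 0), 0, c(0, 1), pi / 2)
  expect_equal(c(rs$d_ij, rs$psi_ij, rs$phi_ij), c(1, pi / 2, pi / 2))

  rs <- relative_state(c(0, 0), pi / 2, c(1, 1), 0)
  expect_equal(c(rs$d_ij, rs$psi_ij, rs$phi_ij), c(sqrt(2), -pi / 4, -pi / 2))

  # asymmetric in general: psi_ij != psi_ji
  a <- relative_state(c(0, 0), 0.3, c(1, 2), -0.6)
  b <- relative_state(c(1, 2), -0.6, c(0, 0), 0.3)
  expect_false(isTRUE(all.equal(a$psi_ij, b$psi_ij)))
  expect_equal(a$d_ij, b$d_ij)

  # coincident positions flagged degenerate with psi defined as 0
  d <- relative_state(c(1, 1), 0.4, c(1, 1), 1.2)
  expect_true(d$degenerate)
  expect_equal(d$psi_ij, 0)
})

test_that("wall turn matches the published force and vanishes appropriately", {
  expect_equal(wall_turn(0.03, 0, p_model), 0) # sin(0)
  expect_lt(abs(wall_turn(10 * p_model$l_w, pi / 2, p_model)), 1e-43)
  # direct evaluation at the wall, heading parallel
  expect_equal(wall_turn(0, pi / 2, p_model),
    0.15 * 1.9157 * sin(pi / 2) * (1 + 0.7 * cos(pi)),
    tolerance = 1e-12
  )
  expect_equal(wall_turn(0, pi / 2, p_model), 0.0862, tolerance = 1e-3)
  # odd in theta_w
  th <- seq(-3, 3, by = 0.37)
  expect_equal(wall_turn(0.02, th, p_model), -wall_turn(0.02, -th, p_model))
})

test_that("noise turn is damped at the wall and full far from it", {
  expect_equal(noise_turn(0, 1, p_model), 0.45 * (1 - 2 / 3), tolerance = 1e-12)
  expect_equal(noise_turn(0, 1, p_model), 0.15, tolerance = 1e-12)
  expect_equal(noise_turn(0.5, 0, p_model), 0)
  expect_equal(noise_turn(100 * p_model$l_w, 1, p_model), 0.45, tolerance = 1e-12)
  expect_equal(noise_turn(Inf, 1, p_model), 0.45)
})

test_that("attraction turn matches direct evaluation, balance point and cut-off", {
  expect_equal(attraction_turn(p_model$d_Att, 1.1, 0.3, p_model), 0)
  expect_equal(attraction_turn(0.15, 0, 0.7, p_model), 0) # odd in psi
  val <- attraction_turn(0.06, pi / 2, 0, p_model)
  f <- 0.12 * (0.06 / 0.03 - 1) / (1 + (0.06 / 0.2)^2)
  o <- 1.395 * sin(pi / 2) * (1 - 0.33 * cos(pi / 2))
  e <- 0.9326 * (1 - 0.48 - 0.31)
  expect_equal(val, f * o * e, tolerance = 1e-12)
  expect_equal(val, 0.0301, tolerance = 1e-3)
  # repulsive below the balance distance
  expect_lt(attraction_turn(0.01, pi / 2, 0, p_model), 0)
  # hard truncation beyond the attraction cut-off
  p_cut <- school_params("model", d_cut = 0.05)
  expect_equal(attraction_turn(0.06, pi / 2, 0, p_cut), 0)
  expect_gt(abs(attraction_turn(0.04, pi / 2, 0, p_cut)), 0)
  # alignment is NOT subject to the cut-off
  expect_equal(
    alignment_turn(0.06, 0, pi / 2, p_cut),
    alignment_turn(0.06, 0, pi / 2, p_model)
  )
})

test_that("alignment turn matches direct evaluation and decays with distance", {
  expect_equal(alignment_turn(0.1, 0.8, 0, p_model), 0) # odd in phi
  expect_lt(abs(alignment_turn(10 * p_model$l_Ali, 0, pi / 2, p_model)), 1e-40)
  val <- alignment_turn(0.06, 0, pi / 2, p_model)
  f <- 0.09 * (0.06 / 0.06 + 1) * exp(-(0.06 / 0.2)^2)
  e <- 0.9012 * (1 + 0.6 - 0.32)
  o <- 1.6385 * sin(pi / 2) * (1 + 0.3 * cos(pi))
  expect_equal(val, f * e * o, tolerance = 1e-12)
  expect_equal(val, 0.2177, tolerance = 1e-3)
})

test_that("influence equals the absolute summed social turn on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    d <- runif(1, 0, 1.5)
    psi <- runif(1, -pi, pi)
    phi <- runif(1, -pi, pi)
    expect_equal(
      pair_influence(d, psi, phi, p_model),
      abs(attraction_turn(d, psi, phi, p_model) +
        alignment_turn(d, psi, phi, p_model)),
      tolerance = 1e-12
    )
  }
  # both odd factors vanish at psi = phi = 0
  expect_equal(pair_influence(0.2, 0, 0, p_model), 0)
})

test_that("left/right mirror symmetry of the social turns", {
  set.seed(7)
  for (i in 1:100) {
    d <- runif(1, 0.01, 1)
    psi <- runif(1, -pi, pi)
    phi <- runif(1, -pi, pi)
    expect_equal(
      attraction_turn(d, psi, phi, p_model),
      -attraction_turn(d, -psi, -phi, p_model),
      tolerance = 1e-12
    )
    expect_equal(
      alignment_turn(d, psi, phi, p_model),
      -alignment_turn(d, -psi, -phi, p_model),
      tolerance = 1e-12
    )
  }
})

test_that("heading increment sums wall, noise and social terms additively", {
  # no stimuli
  expect_equal(heading_increment(Inf, 0, NULL, 0, p_model), 0)
  # k = 0 reduces to wall + noise
  expect_equal(
    heading_increment(0.04, 0.9, NULL, 1.3, p_model),
    wall_turn(0.04, 0.9, p_model) + noise_turn(0.04, 1.3, p_model)
  )
  # additivity over pairs and permutation invariance
  pairs <- tibble::tibble(
    d_ij = c(0.1, 0.34), psi_ij = c(0.5, -1.2), phi_ij = c(-0.3, 2.1)
  )
  one <- function(i) heading_increment(0.1, 0.2, pairs[i, ], 0.7, p_model)
  base <- wall_turn(0.1, 0.2, p_model) + noise_turn(0.1, 0.7, p_model)
  expect_equal(
    heading_increment(0.1, 0.2, pairs, 0.7, p_model),
    one(1) + one(2) - base,
    tolerance = 1e-12
  )
  expect_equal(
    heading_increment(0.1, 0.2, pairs, 0.7, p_model),
    heading_increment(0.1, 0.2, pairs[2:1, ], 0.7, p_model),
    tolerance = 1e-15
  )
})

test_that("wrap_angle maps to (-pi, pi]", {
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  x <- seq(-20, 20, by = 0.13)
  w <- wrap_angle(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
})
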