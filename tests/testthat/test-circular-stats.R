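test_that("polar transform maps cells to compass angles about the centre", {
  v <- matrix(0, 9, 9)
  v[5, 8] <- 2   # due east of centre (x0 = 5, z0 = 5): row z, col x
  s <- polar_transform(xz_matrix(v, center = c(5, 5)), exclusion_radius_px = 1)
  expect_equal(s$angles, 0)
  expect_equal(s$weights, 2)

  # cell at the exact centre is excluded, not given an undefined angle
  v[5, 5] <- 10
  s2 <- polar_transform(xz_matrix(v, center = c(5, 5)))
  expect_equal(length(s2$angles), 1)

  v2 <- matrix(0, 9, 9)
  v2[5, 8] <- 1; v2[8, 5] <- 1; v2[5, 2] <- 1; v2[2, 5] <- 1  # E N W S
  s4 <- polar_transform(xz_matrix(v2, center = c(5, 5)))
  expect_setequal(round(s4$angles, 12),
                  round(c(0, pi / 2, pi, 3 * pi / 2), 12))
  expect_equal(s4$weights, rep(1, 4))

  v3 <- matrix(0, 3, 3); v3[2, 2] <- 1
  expect_error(polar_transform(xz_matrix(v3, center = c(2, 2))),
               "degenerate")
})

test_that("mean resultant length matches hand values and the expansion oracle", {
  expect_equal(mean_resultant_length(weighted_angles(pi / 3, 5)), 1.0)
  expect_lt(mean_resultant_length(
    weighted_angles(c(0, pi / 2, pi, 3 * pi / 2))), 1e-12)
  expect_equal(mean_resultant_length(weighted_angles(c(0, pi), c(3, 1))),
               0.5, tolerance = 1e-12)
  expect_error(mean_resultant_length(weighted_angles(c(0, 1), c(0, 0))),
               "degenerate")
})

test_that("the Rayleigh test follows the corrected exponential formula", {
  u <- weighted_angles(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(rayleigh_test(u), 1.0)

  # n = 100, Rbar = 0.3: evaluate the correction series independently
  th <- c(rep(0, 1), seq(0, 2 * pi, length.out = 7)[-7])
  s <- weighted_angles(0, 1)  # placeholder; construct directly below
  n <- 100; rbar <- 0.3; z <- n * rbar^2
  p_expected <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  # build a weighted set with exactly that Rbar and n_eff:
  # k at angle 0 and n-k split evenly on a symmetric pair gives
  # Rbar = (k + (n-k)cos(a)) ... simpler: two antipodal masses
  # w1 at 0, w2 at pi with w1 + w2 = 100, (w1-w2)/100 = 0.3
  s <- weighted_angles(c(0, pi), c(65, 35))
  expect_equal(mean_resultant_length(s), 0.3, tolerance = 1e-12)
  expect_equal(rayleigh_test(s), p_expected, tolerance = 1e-12)

  # p decreases monotonically in Rbar at fixed n
  ps <- vapply(seq(55, 95, by = 5), function(w1)
    rayleigh_test(weighted_angles(c(0, pi), c(w1, 100 - w1))), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(rayleigh_test(weighted_angles(0, 1)), "insufficient")
})

test_that("Watson's U2 matches analytic values and censored p bounds", {
  n <- 4
  th <- 2 * pi * (2 * seq_len(n) - 1) / (2 * n)   # perfectly spaced
  expect_equal(watson_u2(weighted_angles(th)), 1 / 48, tolerance = 1e-12)
  expect_equal(watson_p(1 / 48)$label, ">0.10")

  s <- weighted_angles(rep(0.7, 1), 100)   # all mass at one angle
  u2 <- watson_u2(s)
  expect_gt(u2, 1)
  expect_equal(watson_p(u2)$label, "<0.01")
  expect_equal(watson_p(u2)$p_upper, 0.01)
  expect_equal(watson_p(0.2)$label, "0.025-0.05")
})

test_that("weighted circular statistics equal brute-force expansion", {
  withr::local_seed(31)
  for (k in 1:30) {
    s <- random_weight_set(200, 4)
    expanded <- rep(s$angles, times = s$weights)
    expect_equal(mean_resultant_length(s), rbar_oracle(expanded),
                 tolerance = 1e-12)
    if (mean_resultant_length(s) > 1e-8)
      expect_equal(mean_direction(s), dir_oracle(expanded),
                   tolerance = 1e-12)
    expect_equal(watson_u2(s), u2_oracle(expanded), tolerance = 1e-9)
  }
})

test_that("rotation shifts the mean direction and leaves Rbar and U2 fixed", {
  withr::local_seed(43)
  for (k in 1:15) {
    s <- random_weight_set(100, 3)
    delta <- runif(1, 0, 2 * pi)
    rot <- weighted_angles(s$angles + delta, s$weights)
    expect_equal(mean_resultant_length(rot), mean_resultant_length(s),
                 tolerance = 1e-12)
    expect_equal(watson_u2(rot), watson_u2(s), tolerance = 1e-9)
    expect_equal((mean_direction(rot) - mean_direction(s)) %% (2 * pi),
                 delta %% (2 * pi), tolerance = 1e-9)
  }
})

test_that("mean direction handles symmetry and degeneracy", {
  expect_equal(mean_direction(weighted_angles(c(0, pi / 2))), pi / 4)
  expect_equal(mean_direction(weighted_angles(3 * pi / 2, 2)), 3 * pi / 2)
  expect_error(mean_direction(weighted_angles(c(0, pi / 2, pi, 3 * pi / 2))),
               "undefined")
})

test_that("windrose binning conserves weight with half-open sectors", {
  s <- weighted_angles(c(0, pi / 2), c(1, 1))
  wr <- windrose(s, 4)
  expect_equal(wr$sector_weights, c(1, 1, 0, 0))
  expect_equal(wr$sector_centers_rad, c(0, pi / 2, pi, 3 * pi / 2))

  # boundary angle pi/4 with K = 4 belongs to the higher sector
  wb <- windrose(weighted_angles(pi / 4), 4)
  expect_equal(wb$sector_weights, c(0, 1, 0, 0))

  withr::local_seed(5)
  s2 <- random_weight_set(300, 5)
  wr2 <- windrose(s2, 16)
  expect_equal(sum(wr2$sector_weights), sum(s2$weights))
  expect_error(windrose(s2, 1), "n_sectors")
})

test_that("the combined circular summary is coherent", {
  withr::local_seed(77)
  s <- weighted_angles(rnorm(400, pi / 3, 0.4) %% (2 * pi))
  cs <- circular_stats(s)
  expect_gt(cs$rayleigh_rbar, 0.8)
  expect_lt(cs$rayleigh_p, 1e-6)
  expect_equal(cs$watson_p, "<0.01")
  expect_equal(cs$mean_direction_rad, pi / 3, tolerance = 0.1)
  expect_equal(cs$n_eff, 400)
})
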