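test_that("simulation is deterministic and parameters are validated", {
  p <- sim_params(seed = 42)
  s1 <- simulate_root_system(p, 26)
  s2 <- simulate_root_system(p, 26)
  expect_identical(s1$polylines, s2$polylines)

  expect_error(sim_params(lateral_emergence_span = 0), "lateral_emergence_span")
  expect_error(sim_params(box_depth_mm = -1), "box_depth_mm")
  expect_error(sim_params(n_laterals = -2), "n_laterals")
  expect_error(sim_params(step_mm = 0), "step_mm")
  expect_error(simulate_root_system(p, 13), "day")
})

test_that("a lateral-free system is a single primary root", {
  p <- sim_params(n_laterals = 0, seed = 5)
  s <- simulate_root_system(p, 26)
  expect_length(s$polylines, 1)
  expect_identical(s$polylines[[1]]$order, 1L)
})

test_that("the primary root descends monotonically and stops at the gel bottom", {
  p <- sim_params(step_mm = 1, seed = 9)
  tips <- vapply(p$growth_days, function(d) {
    v <- simulate_root_system(p, d)$polylines[[1]]$vertices
    max(v[, 2])
  }, numeric(1))
  expect_true(all(diff(tips) >= 0))
  expect_equal(tips[length(tips)], 33.0)   # clamped at depth = 33 mm
  # within one system, primary depth is nondecreasing along the path
  v <- simulate_root_system(p, 26)$polylines[[1]]$vertices
  expect_true(all(diff(v[, 2]) >= -1e-9))
})

test_that("laterals emerge only within the configured span of the primary", {
  p <- sim_params(seed = 3, lateral_emergence_span = 1 / 3)
  s <- simulate_root_system(p, 26)
  prim <- s$polylines[[1]]$vertices
  span_depth <- max(prim[, 2]) / 3 + p$step_mm  # one step of slack
  for (pl in s$polylines) {
    if (pl$order == 2L)
      expect_lt(pl$vertices[1, 2], span_depth)
  }
})

test_that("rasterization maps vertices to the expected voxels", {
  sys <- structure(list(polylines = list(
    list(order = 1L, vertices = matrix(c(10.5, 5.5, 10.5), 1, 3))),
    origin = c(10, 10), box_width_mm = 20, box_depth_mm = 20),
    class = "root_system3d")
  v <- rasterize(sys, 1)
  expect_equal(sum(v$occupancy > 0), 1)
  expect_equal(v$occupancy[11, 6, 11], 1)  # 0-based (10, 5, 10)

  # straight vertical 10 mm segment, 1 mm voxels: oracle = unique floors of
  # a dense sampling of the segment
  seg <- structure(list(polylines = list(
    list(order = 1L, vertices = matrix(c(5.5, 2.3, 5.5,  5.5, 12.3, 5.5),
                                       2, 3, byrow = TRUE))),
    origin = c(5, 5), box_width_mm = 20, box_depth_mm = 20),
    class = "root_system3d")
  v2 <- rasterize(seg, 1)
  ys <- seq(2.3, 12.3, by = 0.01)
  oracle_n <- length(unique(floor(ys)))
  occ_col <- which(v2$occupancy > 0, arr.ind = TRUE)
  expect_equal(nrow(occ_col), oracle_n)
  expect_true(oracle_n %in% 10:11)
  expect_true(all(occ_col[, 1] == 6) && all(occ_col[, 3] == 6))

  empty <- structure(list(polylines = list(), origin = c(5, 5),
                          box_width_mm = 20, box_depth_mm = 20),
                     class = "root_system3d")
  expect_equal(sum(rasterize(empty, 1)$occupancy), 0)

  outside <- structure(list(polylines = list(
    list(order = 1L, vertices = matrix(c(25, 5, 5), 1, 3))),
    origin = c(5, 5), box_width_mm = 20, box_depth_mm = 20),
    class = "root_system3d")
  expect_error(rasterize(outside, 1), "geometry")
})

test_that("projection follows the four-camera mirror geometry", {
  sys <- structure(list(polylines = list(
    list(order = 1L, vertices = matrix(c(3.5, 5.5, 7.5), 1, 3))),
    origin = c(5, 5), box_width_mm = 10, box_depth_mm = 10),
    class = "root_system3d")
  v <- rasterize(sys, 1)   # occupies 0-based voxel (3, 5, 7) in a 10^3 grid
  a <- project_view(v, "A")$mask
  expect_equal(sum(a), 1)
  expect_equal(a[6, 4], 1)                  # (row 5, col 3) 0-based
  cc <- project_view(v, "C")$mask
  expect_equal(cc[6, 10 - 1 - 3 + 1], 1)    # col mirrored: 10-1-3 = 6
  b <- project_view(v, "B")$mask
  expect_equal(b[6, 8], 1)                  # col indexes z
  d <- project_view(v, "D")$mask
  expect_equal(d[6, 10 - 1 - 7 + 1], 1)

  # occlusion: two voxels differing only in z give one side-A pixel
  sys2 <- structure(list(polylines = list(
    list(order = 1L, vertices = matrix(c(3.5, 5.5, 2.5), 1, 3)),
    list(order = 1L, vertices = matrix(c(3.5, 5.5, 7.5), 1, 3))),
    origin = c(5, 5), box_width_mm = 10, box_depth_mm = 10),
    class = "root_system3d")
  expect_equal(sum(project_view(rasterize(sys2, 1), "A")$mask), 1)
})

test_that("projections agree with a brute-force ray check", {
  v <- quick_system(seed = 2, day = 19)$voxels
  occ <- v$occupancy > 0
  n_occ <- sum(occ)
  for (side in c("A", "B", "C", "D")) {
    m <- project_view(v, side)$mask
    expect_lte(sum(m), n_occ)
  }
  brute_a <- t(apply(occ, c(1, 2), any)) * 1
  expect_equal(project_view(v, "A")$mask, brute_a)
  expect_equal(project_view(v, "C")$mask,
               brute_a[, rev(seq_len(ncol(brute_a)))])
})

test_that("fluorescence rendering is exact, artifact-aware and reproducible", {
  sk <- project_view(quick_system(seed = 4, day = 19)$voxels, "A")
  img0 <- render_fluorescence(sk, psf_sigma = 0, noise_sd = 0,
                              n_artifacts = 0, seed = 1)
  expect_equal((img0$pixels > 0) * 1, sk$mask)   # support = skeleton exactly

  img3 <- render_fluorescence(sk, psf_sigma = 0, noise_sd = 0,
                              n_artifacts = 3, seed = 1)
  extra <- (img3$pixels > 0) * 1 - sk$mask
  expect_equal(flood_fill_n_components(extra), 3)
  # artifacts are disjoint from the root (no overlap, no adjacency)
  expect_equal(sum(extra * sk$mask), 0)

  imgn1 <- render_fluorescence(sk, psf_sigma = 0.5, noise_sd = 0.02,
                               n_artifacts = 2, seed = 7)
  imgn2 <- render_fluorescence(sk, psf_sigma = 0.5, noise_sd = 0.02,
                               n_artifacts = 2, seed = 7)
  expect_identical(imgn1$pixels, imgn2$pixels)
  expect_error(render_fluorescence(sk, psf_sigma = -1), "psf_sigma")
})

test_that("ground-truth profile conserves occupancy and spans the gel depth", {
  occ <- array(0, dim = c(3, 3, 3))
  occ[1, 1, 1] <- 1; occ[2, 1, 2] <- 2; occ[3, 1, 3] <- 1  # layer 0: 4
  occ[1, 3, 1] <- 1                                        # layer 2: 1
  v <- structure(list(occupancy = occ, voxel_size_mm = 1,
                      dims = c(nx = 3, ny = 3, nz = 3),
                      box_width_mm = 3, box_depth_mm = 3),
                 class = "voxel_grid")
  expect_equal(ground_truth_vertical_profile(v)$counts, c(4, 0, 1))

  g <- quick_system(seed = 6)$voxels
  prof <- ground_truth_vertical_profile(g)
  expect_equal(sum(prof$counts), sum(g$occupancy))
  expect_lte(length(prof$counts), ceiling(33 / g$voxel_size_mm))
  empty <- structure(list(occupancy = array(0, c(2, 2, 2)), voxel_size_mm = 1,
                          dims = c(nx = 2, ny = 2, nz = 2),
                          box_width_mm = 2, box_depth_mm = 2),
                     class = "voxel_grid")
  expect_equal(ground_truth_vertical_profile(empty)$counts, c(0, 0))
})

test_that("ground-truth angles follow the compass convention", {
  occ <- array(0, dim = c(9, 1, 9))
  occ[8, 1, 5] <- 2   # due east of centre (5, 5)
  v <- structure(list(occupancy = occ, voxel_size_mm = 1,
                      dims = c(nx = 9, ny = 1, nz = 9),
                      box_width_mm = 9, box_depth_mm = 1),
                 class = "voxel_grid")
  s <- ground_truth_angles(v, c(5, 5))
  expect_equal(s$angles, 0)
  expect_equal(s$weights, 2)

  occ[, , ] <- 0
  occ[8, 1, 5] <- 1; occ[5, 1, 8] <- 1; occ[2, 1, 5] <- 1; occ[5, 1, 2] <- 1
  v$occupancy <- occ
  expect_lt(mean_resultant_length(ground_truth_angles(v, c(5, 5))), 1e-12)

  # centre voxel excluded, not given an undefined angle
  occ[5, 1, 5] <- 10
  v$occupancy <- occ
  expect_length(ground_truth_angles(v, c(5, 5))$angles, 4)

  # ring of voxels: mean resultant length near zero
  nn <- 41
  occ2 <- array(0, dim = c(nn, 1, nn))
  th <- seq(0, 2 * pi, length.out = 241)[-241]
  ix <- pmin(pmax(round(21 + 15 * cos(th)), 1), nn)
  iz <- pmin(pmax(round(21 + 15 * sin(th)), 1), nn)
  for (k in seq_along(ix)) occ2[ix[k], 1, iz[k]] <- 1
  v2 <- structure(list(occupancy = occ2, voxel_size_mm = 1,
                       dims = c(nx = nn, ny = 1, nz = nn),
                       box_width_mm = nn, box_depth_mm = 1),
                  class = "voxel_grid")
  expect_lt(mean_resultant_length(ground_truth_angles(v2, c(21, 21))), 0.05)
})
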