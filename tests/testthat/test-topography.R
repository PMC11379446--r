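test_that("maps carry envelope frames onto the lattice with NA holes", {
  lay <- default_grid_layout()
  env <- structure(list(values = matrix(1, 128, 7), t = (1:7 - 0.5) / 10,
                        frame_rate = 10), class = "envelope_series")
  maps <- maps_from_envelope(env, lay)
  expect_length(maps$maps, 7)
  m <- maps$maps[[1]]
  expect_equal(sum(is.na(m)), 2)              # the two absent corners
  expect_true(all(is.na(m[cbind(c(1, 14), c(5, 5))])))
  expect_equal(range(m, na.rm = TRUE), c(1, 1))

  # extra bad channels become additional holes
  maps2 <- maps_from_envelope(env, lay, bad = rbind(c(3, 2)))
  expect_equal(sum(is.na(maps2$maps[[1]])), 3)
})

test_that("RoA handles singleton, uniform and hand-computed maps", {
  lay <- grid_layout(3, 3, ied_fp = 8, ied_ft = 8)

  m <- matrix(0, 3, 3); m[2, 3] <- 1
  expect_equal(roa(m, lay), c(ft = 16, fp = 8))

  u <- matrix(5, 3, 3)
  expect_equal(roa(u, lay), c(ft = 8, fp = 8))

  # three cells above threshold: weighted centroid by hand
  h <- matrix(0.1, 3, 3)
  h[1, 1] <- 1.0; h[1, 2] <- 0.8; h[2, 1] <- 0.9
  expect_equal(roa(h, lay), c(ft = 0.8 * 8 / 2.7, fp = 0.9 * 8 / 2.7),
               tolerance = 1e-12)

  expect_error(roa(matrix(NA_real_, 2, 2), grid_layout(2, 2)), "no defined")
})

test_that("RoA agrees with the cell-enumeration oracle on random maps", {
  set.seed(10)
  for (i in 1:40) {
    nr <- sample(2:26, 1); nc <- sample(2:5, 1)
    lay <- grid_layout(nr, nc, ied_fp = 8, ied_ft = 8)
    m <- rand_map(lay)
    thr <- sample(c(0, 0.5, 0.7, 1), 1)
    expect_equal(roa(m, lay, thr), oracle_roa(m, lay, thr), tolerance = 1e-9)
  }
})

test_that("CoG equals zero-threshold RoA and both are scale invariant", {
  set.seed(11)
  lay <- grid_layout(6, 4)
  m <- rand_map(lay)
  expect_identical(cog(m, lay), roa(m, lay, threshold_fraction = 0))
  expect_equal(roa(5.5 * m, lay), roa(m, lay))

  # centroid lies inside the bounding box of defined cells
  cells <- which(!is.na(m), arr.ind = TRUE)
  ctr <- cog(m, lay)
  expect_true(ctr["ft"] >= (min(cells[, 2]) - 1) * 8 &&
              ctr["ft"] <= (max(cells[, 2]) - 1) * 8)
  expect_true(ctr["fp"] >= (min(cells[, 1]) - 1) * 8 &&
              ctr["fp"] <= (max(cells[, 1]) - 1) * 8)
})

test_that("trajectory of uniform maps sits at the grid centre; NA frames kept", {
  lay <- grid_layout(5, 5)
  env <- structure(list(values = matrix(1, 25, 10), t = (1:10 - 0.5) / 10,
                        frame_rate = 10), class = "envelope_series")
  traj <- roa_trajectory(maps_from_envelope(env, lay))
  expect_equal(traj$ft, rep(16, 10))
  expect_equal(traj$fp, rep(16, 10))
  expect_equal(attr(traj, "kind"), "RoA")

  env$values[, 4] <- NA
  traj2 <- roa_trajectory(maps_from_envelope(env, lay))
  expect_true(is.na(traj2$ft[4]) && all(!is.na(traj2$ft[-4])))
})

test_that("mean RoA moves monotonically with the kernel centre position", {
  lay <- grid_layout(13, 5, 8, 8)
  map_grid <- channel_map(lay)
  positions <- seq(24, 72, by = 12)
  mean_fp <- vapply(positions, function(p) {
    # noiseless synthetic envelope: Gaussian kernel sampled on the lattice
    amp <- exp(-((map_grid$ft - 16)^2 / (2 * 8^2) +
                 (map_grid$fp - p)^2 / (2 * 12^2)))
    env <- structure(list(values = matrix(amp, ncol = 3, nrow = length(amp)),
                          t = (1:3 - 0.5) / 10, frame_rate = 10),
                     class = "envelope_series")
    mean(roa_trajectory(maps_from_envelope(env, lay))$fp)
  }, numeric(1))
  expect_equal(cor(positions, mean_fp, method = "spearman"), 1)
})

test_that("RoA tracks a static simulated source to within half an electrode", {
  cfg <- quick_cfg(21, duration_s = 20, failure_time_s = 17,
                   center_path = rbind(c(0, 16, 48)), center_jitter_mm = 0)
  sub <- simulate_subject(cfg)
  recf <- filter_emg(sub$rec)
  env <- rms_envelope(recf)
  traj <- roa_trajectory(maps_from_envelope(env, cfg$layout))
  hold <- traj$t > 7 & traj$t < 15
  expect_lt(sd(traj$ft[hold]), 4)
  expect_lt(sd(traj$fp[hold]), 4)
  expect_lt(abs(mean(traj$ft[hold]) - 16), 4)
  expect_lt(abs(mean(traj$fp[hold]) - 48), 4)
})

test_that("hole interpolation averages defined neighbours, for display only", {
  m <- matrix(c(9, 2, 9, 1, NA, 3, 9, 4, 9), 3, 3, byrow = TRUE)
  out <- interpolate_bad(m)
  expect_equal(out[2, 2], 2.5)

  full <- matrix(1:9, 3, 3)
  expect_identical(interpolate_bad(full), full)

  corner <- matrix(c(NA, 2, 4, 9), 2, 2)
  expect_equal(interpolate_bad(corner)[1, 1], 3)

  # an isolated hole with no defined neighbour stays undefined
  expect_true(is.na(interpolate_bad(matrix(NA_real_, 1, 1))[1, 1]))
})
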