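# Generators: determinism, ground-truth consistency, noise calibration.

test_that("confocal phantom handles the no-site and flat-field cases", {
  ph <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(8, 24, 24), n_sites = 0, noise_model = "none"
  ))
  expect_equal(nrow(ph$truth$sites), 0)
  expect_true(all(ph$stack$channels$rna == 100))

  ph2 <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(8, 24, 24), n_sites = 4, noise_model = "none",
    enrichment_amplitude = 1
  ))
  expect_equal(max(abs(ph2$stack$channels$mark - 100)), 0, tolerance = 1e-12)
})

test_that("generators are pure functions of their config", {
  a <- gen_confocal_phantom(confocal_config(shape_voxels = c(10, 48, 48),
                                            n_sites = 10, seed = 7))
  b <- gen_confocal_phantom(confocal_config(shape_voxels = c(10, 48, 48),
                                            n_sites = 10, seed = 7))
  expect_identical(a$stack$channels$rna, b$stack$channels$rna)
  expect_identical(a$truth$sites, b$truth$sites)

  t1 <- gen_trajectories(trajectory_config(n_larvae = 3, seed = 5))
  t2 <- gen_trajectories(trajectory_config(n_larvae = 3, seed = 5))
  expect_identical(t1$table, t2$table)

  i1 <- gen_ion_phantom(ion_config(grid_shape = c(64, 64), groups = c(g = 3),
                                   channels = default_lipid_channels()[1:5, ],
                                   seed = 3))
  i2 <- gen_ion_phantom(ion_config(grid_shape = c(64, 64), groups = c(g = 3),
                                   channels = default_lipid_channels()[1:5, ],
                                   seed = 3))
  expect_identical(i1$stack$planes, i2$stack$planes)

  c1 <- gen_cuticle_phantom(10, seed = 2)
  c2 <- gen_cuticle_phantom(10, seed = 2)
  expect_identical(c1$image$data, c2$image$data)

  g1 <- gen_track_pair(50, 100, track_spec(noise_sd = 1),
                       track_spec(noise_sd = 1), seed = 4)
  g2 <- gen_track_pair(50, 100, track_spec(noise_sd = 1),
                       track_spec(noise_sd = 1), seed = 4)
  expect_identical(g1$signal$values, g2$signal$values)
})

test_that("flat-region noise SD matches the configured level within 5%", {
  ph <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(50, 50, 50), n_sites = 0, background_sd = 10, seed = 2
  ))
  expect_gt(length(ph$stack$channels$rna), 1e5)
  expect_equal(sd(ph$stack$channels$rna), 10, tolerance = 0.05)
})

test_that("site placement respects separation and errors when infeasible", {
  cfg <- confocal_config(shape_voxels = c(10, 64, 64), n_sites = 20,
                         noise_model = "none", seed = 3)
  ph <- gen_confocal_phantom(cfg)
  s <- ph$truth$sites
  d <- as.matrix(dist(cbind(s$z_um, s$y_um, s$x_um)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_separation_um)

  expect_error(
    gen_confocal_phantom(confocal_config(
      shape_voxels = c(10, 24, 24), n_sites = 500, seed = 1
    )),
    "could not place"
  )
})

test_that("ion phantom recovers configured structure exactly at zero noise", {
  ph <- gen_ion_phantom(ion_config(grid_shape = c(64, 64), groups = c(g = 0),
                                   channels = default_lipid_channels()[1:3, ],
                                   noise_sd = 0))
  expect_true(all(ph$stack$planes == 0))

  ph2 <- gen_ion_phantom(ion_config(grid_shape = c(96, 96), groups = c(g = 5),
                                    larva_axes_px = c(8, 3), noise_sd = 0,
                                    channels = default_lipid_channels()[1:4, ],
                                    group_effects = list(), seed = 7))
  lab <- ph2$truth$label_mask
  expect_equal(sort(unique(as.vector(lab))), 0:5)
  for (i in 1:5) {
    for (ch in 1:4) {
      px <- ph2$stack$planes[, , ch][lab == i]
      expect_true(all(px == ph2$truth$abundance[i, ch]))
    }
  }
})

test_that("ion phantom with 10 larvae yields 10 ground-truth components", {
  ph <- gen_ion_phantom(ion_config(grid_shape = c(128, 128), groups = c(g = 10),
                                   channels = default_lipid_channels()[1:5, ],
                                   seed = 7))
  # oracle: connected components of the truth mask, 4-connectivity
  lab <- ph$truth$label_mask
  n_cc <- max(EBImage::bwlabel(EBImage::Image(t(lab > 0) * 1)))
  expect_equal(n_cc, 10)
  expect_equal(max(lab), 10)
})

test_that("deterministic trajectory configs yield straight constant paths", {
  tj <- gen_trajectories(trajectory_config(
    n_larvae = 1, still_fraction = 0, turn_sd_deg = 0, speed_sd_mm_s = 0,
    head_cast_rate_per_min = 0, duration_s = 10
  ))
  d <- tj$table
  steps <- sqrt(diff(d$x_mm)^2 + diff(d$y_mm)^2)
  expect_equal(max(abs(steps - steps[1])), 0, tolerance = 1e-12)
  # collinear: cross products of consecutive displacements vanish
  dx <- diff(d$x_mm); dy <- diff(d$y_mm)
  cross <- head(dx, -1) * tail(dy, -1) - head(dy, -1) * tail(dx, -1)
  expect_equal(max(abs(cross)), 0, tolerance = 1e-12)
})

test_that("injected head-cast counts follow the configured Poisson mean", {
  counts <- vapply(1:40, function(s) {
    tj <- gen_trajectories(trajectory_config(
      n_larvae = 5, still_fraction = 0, head_cast_rate_per_min = 1.5,
      seed = s
    ))
    nrow(tj$truth$events)
  }, 0L)
  # 200 movers at Poisson mean 3: mean count within 4 SE
  expect_equal(mean(counts) / 5, 3, tolerance = 4 * sqrt(3 / 200) / 3)
})

test_that("track pair fixtures honour their specs", {
  tp <- gen_track_pair(30, 100, track_spec(baseline = 2),
                       track_spec(baseline = 2))
  expect_identical(tp$signal$values, tp$control$values)

  imp <- gen_track_pair(30, 100, track_spec(
    peaks = data.frame(center = 10, height = 5, width_bins = 0)
  ), track_spec())
  expect_equal(sum(imp$signal$values != 0), 1)
  expect_equal(imp$signal$values[10], 5)
})

test_that("cuticle phantom places the requested spots at the spacing", {
  blank <- gen_cuticle_phantom(0, seed = 1)
  expect_equal(nrow(blank$truth), 0)

  ph <- gen_cuticle_phantom(25, spacing_px = 4, seed = 3)
  expect_equal(nrow(ph$truth), 25)
  d <- as.matrix(dist(ph$truth))
  diag(d) <- Inf
  expect_gte(min(d), 4)
  expect_error(gen_cuticle_phantom(500, roi = c(32, 32), spacing_px = 6),
               "could not place")
})
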