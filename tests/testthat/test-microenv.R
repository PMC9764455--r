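# Site detection and microenvironment statistics.

test_that("empty or flat channels give an empty SiteSet, unknown channels error", {
  vs <- volume_stack(list(rna = array(0, c(6, 16, 16))), c(0.2, 0.1, 0.1))
  det <- detect_sites(vs, "rna")
  expect_equal(nrow(det$sites), 0)
  expect_error(detect_sites(vs, "nope"), "unknown channel")
})

test_that("noiseless phantom sites are detected exactly at ground truth", {
  ph <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(16, 64, 64), n_sites = 20, site_peak_snr = 10,
    noise_model = "none", channels = "rna", seed = 2
  ))
  det <- detect_sites(ph$stack, "rna")
  expect_equal(nrow(det$sites), 20)
  sc <- match_sites(det$sites, ph$truth$sites, radius_vox = 1)
  expect_equal(sc$f1, 1)
})

test_that("raising the detection threshold never yields more sites", {
  ph <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(16, 64, 64), n_sites = 25, seed = 3, channels = "rna"
  ))
  n <- vapply(c(2, 3, 4, 5, 6), function(k) {
    nrow(detect_sites(ph$stack, "rna", threshold_k = k)$sites)
  }, 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("site intensities recover a single-voxel impulse and symmetry", {
  a <- array(0, c(7, 9, 9))
  a[4, 5, 5] <- 100
  a[4, 5, 2] <- 100
  vs <- volume_stack(list(rna = a), c(0.1, 0.1, 0.1))
  ss <- site_set_from_coords(data.frame(z = c(3, 3), y = c(4, 4),
                                        x = c(4, 1)), vs)
  si <- site_intensities(vs, "rna", ss, r_int_um = 0.05)
  expect_equal(si$peak_intensity, c(100, 100))
  expect_equal(si$integrated_intensity, c(100, 100))
  expect_equal(si$n_voxels, c(1, 1))
})

test_that("integrated intensities track ground-truth amplitudes (noiseless)", {
  ph <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(20, 80, 80), n_sites = 25, site_amp_sdlog = 0.5,
    noise_model = "none", channels = "rna", seed = 4
  ))
  ss <- site_set_from_coords(ph$truth$sites, ph$stack)
  si <- site_intensities(ph$stack, "rna", ss, r_int_um = 0.3)
  expect_gte(cor(si$integrated_intensity, ph$truth$sites$peak), 0.99)
})

test_that("flat-field radial profile is identically 1 with zero variance", {
  vs <- volume_stack(list(mark = array(7.5, c(16, 48, 48))), c(0.2, 0.1, 0.1))
  ss <- site_set_from_coords(data.frame(z = 8, y = 24, x = 24), vs)
  rp <- radial_profile(vs, "mark", ss)
  expect_equal(unname(rp$mean_intensity), rep(1, length(rp$mean_intensity)),
               tolerance = 1e-12)
  expect_true(all(rp$variance < 1e-20))
})

test_that("injected Gaussian enrichment is recovered against the blur oracle", {
  cfg <- confocal_config(shape_voxels = c(40, 160, 160), n_sites = 25,
                         noise_model = "none", min_separation_um = 2.5,
                         margin_um = 1, seed = 1)
  ph <- gen_confocal_phantom(cfg)
  ss <- site_set_from_coords(ph$truth$sites, ph$stack)
  rp <- radial_profile(ph$stack, "mark", ss)
  # oracle: amplitude shrinkage from PSF convolution, exact at r = 0
  peak_oracle <- 1 + (cfg$enrichment_amplitude - 1) *
    prod(cfg$enrichment_sigma_um /
           sqrt(cfg$enrichment_sigma_um^2 + cfg$psf_sigma_um^2))
  expect_equal(unname(rp$mean_intensity[1]), peak_oracle, tolerance = 0.02)
  # and within 10% of the injected amplitude
  expect_equal(unname(rp$mean_intensity[1]), 2, tolerance = 0.1)
  # non-increasing out to 2 sigma
  within_2s <- which(rp$bin_edges_um[-1] <= 2 * cfg$enrichment_sigma_um)
  expect_true(all(diff(rp$mean_intensity[within_2s]) <= 1e-9))
})

test_that("radial profile depends on physical, not voxel, distances", {
  # sample the same continuous enrichment field at two z spacings
  field <- function(nz, dz) {
    a <- array(0, c(nz, 81, 81))
    cz <- (nz + 1) / 2
    for (z in 1:nz) {
      r2z <- ((z - cz) * dz)^2
      dy2 <- (((1:81) - 41) * 0.1)^2
      a[z, , ] <- 1 + exp(-(outer(dy2, dy2, "+") + r2z) / (2 * 0.5^2))
    }
    a
  }
  vs1 <- volume_stack(list(m = field(41, 0.2)), c(0.2, 0.1, 0.1))
  vs2 <- volume_stack(list(m = field(21, 0.4)), c(0.4, 0.1, 0.1))
  rp1 <- radial_profile(vs1, "m",
                        site_set_from_coords(data.frame(z = 20, y = 40, x = 40),
                                             vs1))
  rp2 <- radial_profile(vs2, "m",
                        site_set_from_coords(data.frame(z = 10, y = 40, x = 40),
                                             vs2))
  expect_equal(rp1$mean_intensity, rp2$mean_intensity, tolerance = 0.02)
})

test_that("site_density equals the brute-force count/area oracle", {
  vs <- volume_stack(list(rna = array(0, c(4, 50, 50))), c(0.2, 0.1, 0.1))
  for (s in 1:25) {
    set.seed(s)
    n <- sample(0:30, 1)
    coords <- data.frame(z = sample(0:3, n, TRUE), y = sample(0:49, n, TRUE),
                         x = sample(0:49, n, TRUE))
    ss <- site_set_from_coords(coords, vs)
    mask <- matrix(runif(2500) < 0.3, 50, 50)
    if (!any(mask)) mask[1, 1] <- TRUE
    res <- site_density(ss, mask)
    oracle <- if (n > 0) {
      sum(vapply(seq_len(n), function(i) mask[coords$y[i] + 1, coords$x[i] + 1],
                 TRUE))
    } else {
      0L
    }
    expect_identical(res$n_sites, as.integer(oracle))
    expect_equal(res$density_per_px, oracle / sum(mask))
  }
  expect_error(site_density(site_set_from_coords(data.frame(z = 0, y = 0, x = 0),
                                                 vs),
                            matrix(FALSE, 50, 50)), "empty")
})

test_that("enrichment_at_sites separates carriers from non-carriers", {
  vs <- volume_stack(list(ubx = array(3, c(8, 20, 20))), c(0.2, 0.1, 0.1))
  ss <- site_set_from_coords(data.frame(z = 4, y = 10, x = 10), vs)
  expect_equal(enrichment_at_sites(vs, "ubx", ss)$mean_intensity, 3)

  ph <- gen_confocal_phantom(confocal_config(
    shape_voxels = c(40, 160, 160), n_sites = 20, noise_model = "none",
    enrichment_fraction = 0.5, min_separation_um = 2.5, margin_um = 1,
    seed = 5
  ))
  ss2 <- site_set_from_coords(ph$truth$sites, ph$stack)
  en <- enrichment_at_sites(ph$stack, "mark", ss2, r_sample_um = 0.2)
  flag <- ph$truth$sites$enriched
  ratio <- mean(en$mean_intensity[flag]) / mean(en$mean_intensity[!flag])
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("region_cell_intensities recovers per-label means", {
  a <- array(0, c(4, 30, 30))
  lab <- matrix(0L, 30, 30)
  lab[1:10, 1:10] <- 1L
  lab[15:24, 5:14] <- 2L
  for (z in 1:4) {
    plane <- matrix(0, 30, 30)
    plane[lab == 1] <- 10
    plane[lab == 2] <- 20
    a[z, , ] <- plane
  }
  vs <- volume_stack(list(h3k4 = a), c(0.2, 0.1, 0.1))
  rc <- region_cell_intensities(vs, "h3k4", lab)
  expect_equal(rc$mean_intensity, c(10, 20))
})
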