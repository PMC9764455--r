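# Single-larva MALDI deconvolution and lipidomics statistics.

small_channels <- function(n = 6) default_lipid_channels()[seq_len(n), ]

test_that("segmentation recovers noiseless larvae exactly", {
  ph <- gen_ion_phantom(ion_config(grid_shape = c(128, 128), groups = c(g = 10),
                                   noise_sd = 0, group_effects = list(),
                                   channels = small_channels(), seed = 1))
  mask <- segment_larvae(ph$stack)
  expect_equal(mask$n_larvae, 10)
  mm <- match_labels(mask$labels, ph$truth$label_mask)
  ious <- vapply(seq_len(10), function(i) {
    label_iou(mask$labels, ph$truth$label_mask, i, mm[i])
  }, 0)
  expect_true(all(ious >= 0.95))
})

test_that("blank stacks and one-pixel gaps are handled per the contract", {
  blank <- structure(
    list(planes = array(0, c(20, 20, 2)),
         channels = small_channels(2), pixel_size_um = 100),
    class = "IonImageStack"
  )
  expect_equal(segment_larvae(blank)$n_larvae, 0)

  # two blobs separated by a single background column stay distinct
  plane <- matrix(0, 20, 41)
  plane[5:15, 5:19] <- 100
  plane[5:15, 21:35] <- 100
  two <- structure(
    list(planes = array(plane, c(20, 41, 1)),
         channels = small_channels(1), pixel_size_um = 100),
    class = "IonImageStack"
  )
  expect_equal(segment_larvae(two, min_area_px = 5)$n_larvae, 2)
})

test_that("label count matches truth across seeds at moderate noise", {
  for (s in 1:20) {
    ph <- gen_ion_phantom(ion_config(
      grid_shape = c(96, 96), groups = c(g = 6), larva_axes_px = c(8, 3),
      channels = small_channels(), group_effects = list(),
      noise_sd = 10, seed = s
    ))
    mask <- segment_larvae(ph$stack)
    expect_equal(mask$n_larvae, 6)
  }
})

test_that("noiseless abundance recovery is exact; noisy recovery correlates", {
  ph <- gen_ion_phantom(ion_config(grid_shape = c(128, 128), groups = c(g = 10),
                                   noise_sd = 0, group_effects = list(),
                                   channels = small_channels(), seed = 2))
  mask <- segment_larvae(ph$stack)
  am <- per_larva_abundance(ph$stack, mask)
  mm <- match_labels(mask$labels, ph$truth$label_mask)
  expect_equal(unname(am$values), unname(ph$truth$abundance[mm, ]),
               tolerance = 1e-12)

  # uniform plane inside one larva, mean aggregation returns the value
  expect_true(all(abs(am$values[1, ] - ph$truth$abundance[mm[1], ]) == 0))

  phn <- gen_ion_phantom(ion_config(grid_shape = c(128, 128), groups = c(g = 10),
                                    noise_sd = 10, group_effects = list(),
                                    channels = small_channels(), seed = 2))
  maskn <- segment_larvae(phn$stack)
  amn <- per_larva_abundance(phn$stack, maskn)
  mmn <- match_labels(maskn$labels, phn$truth$label_mask)
  for (ch in seq_len(ncol(amn$values))) {
    expect_gte(cor(amn$values[, ch], phn$truth$abundance[mmn, ch]), 0.95)
  }
})

test_that("batch adjustment equalizes batches and is idempotent", {
  set.seed(4)
  v <- matrix(rnorm(80, 100, 5), 20, 4)
  meta <- data.frame(larva_id = 1:20, group = "g", batch = rep(1:2, each = 10))
  chans <- small_channels(4)

  # single batch: passthrough
  am1 <- abundance_matrix(v, transform(meta, batch = 1L), chans)
  expect_equal(batch_adjust(am1)$values, v, tolerance = 1e-9)

  # location shift
  vs <- v; vs[11:20, ] <- vs[11:20, ] + 10
  ams <- abundance_matrix(vs, meta, chans)
  adj <- batch_adjust(ams)
  for (ch in 1:4) {
    m <- tapply(adj$values[, ch], meta$batch, mean)
    expect_lt(abs(diff(m)), 1e-9)
  }

  # scale effect
  vm <- v; vm[11:20, ] <- vm[11:20, ] * 3
  amm <- abundance_matrix(vm, meta, chans)
  adjm <- batch_adjust(amm)
  for (ch in 1:4) {
    s <- tapply(adjm$values[, ch], meta$batch, sd)
    expect_lt(abs(diff(s)), 1e-9)
  }

  # idempotence
  again <- batch_adjust(adjm)
  expect_lt(max(abs(again$values - adjm$values)), 1e-9)
})

test_that("PCA follows the eigen oracle and its conventions", {
  meta <- function(n) data.frame(larva_id = seq_len(n), group = "g", batch = 1L)

  # identical rows: zero variance everywhere -> constant columns dropped
  am0 <- abundance_matrix(matrix(5, 4, 3), meta(4), small_channels(3))
  expect_error(suppressWarnings(pca_profiles(am0)), "fewer varying channels")

  set.seed(9)
  x <- rnorm(200)
  v <- cbind(x + rnorm(200, 0, 0.1), -x + rnorm(200, 0, 0.1))
  am <- abundance_matrix(v, meta(200), small_channels(2))
  p <- pca_profiles(am, 2)
  # eigen oracle on the standardized covariance
  ev <- eigen(cor(v))$vectors[, 1]
  ev <- ev * sign(ev[which.max(abs(ev))])
  expect_equal(abs(sum(p$loadings[, 1] * ev)), 1, tolerance = 1e-6)
  # sign convention: largest-magnitude loading positive
  expect_gt(p$loadings[which.max(abs(p$loadings[, 1])), 1], 0)
  # variance fractions: complete, non-increasing, sum to 1
  expect_equal(sum(pca_profiles(am, 2)$variance_fraction), 1,
               tolerance = 1e-9)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))

  # row-permutation invariance (scores permute along)
  perm <- sample(200)
  amp <- abundance_matrix(v[perm, ], meta(200), small_channels(2))
  pp <- pca_profiles(amp, 2)
  expect_equal(unname(pp$scores[order(perm), 1]), unname(p$scores[, 1]),
               tolerance = 1e-8)
})

test_that("class enrichment ranks a constructed fold-change signature", {
  set.seed(11)
  chans <- default_lipid_channels()[c(1:8, 31:38, 61:64), ]  # 8 TG, 8 GPL, 4 other
  n <- 12
  base <- matrix(rexp(2 * n * nrow(chans), 1 / 100), 2 * n, nrow(chans))
  fold <- ifelse(chans$lipid_class == "triglyceride", 2, 1)
  v <- base
  v[(n + 1):(2 * n), ] <- t(t(v[(n + 1):(2 * n), ]) * fold)
  am <- abundance_matrix(v, data.frame(larva_id = 1:(2 * n),
                                       group = rep(c("A", "B"), each = n),
                                       batch = 1L), chans)
  ce <- class_enrichment(am, reference = "A")
  expect_equal(ce$class[1], "triglyceride")
  expect_gt(ce$median_log2fc[ce$class == "triglyceride"], 0)

  # identical groups: flat fold changes, p ~ 1
  am2 <- abundance_matrix(rbind(base[1:n, ], base[1:n, ]),
                          data.frame(larva_id = 1:(2 * n),
                                     group = rep(c("A", "B"), each = n),
                                     batch = 1L), chans)
  ce2 <- class_enrichment(am2, reference = "A")
  expect_true(all(ce2$p_value > 0.99))
  expect_true(all(abs(ce2$median_log2fc) < 1e-12))
})

test_that("the configured TG-up / glycerophospholipid-down signature is recovered", {
  ph <- gen_ion_phantom(ion_config(seed = 6))
  mask <- segment_larvae(ph$stack)
  mm <- match_labels(mask$labels, ph$truth$label_mask)
  am <- per_larva_abundance(
    ph$stack, mask,
    meta = data.frame(larva_id = seq_len(mask$n_larvae),
                      group = ph$truth$larvae$group[mm], batch = 1L)
  )
  ce <- class_enrichment(am, reference = "TrrWT")
  expect_gt(ce$median_log2fc[ce$class == "triglyceride"], 0)
  expect_lt(ce$median_log2fc[ce$class == "glycerophospholipid"], 0)
  expect_lt(ce$p_value[ce$class == "triglyceride"], 0.05)
})

test_that("ion-image stacks round-trip through the TIFF directory format", {
  ph <- gen_ion_phantom(ion_config(grid_shape = c(48, 48), groups = c(g = 2),
                                   larva_axes_px = c(6, 3),
                                   channels = small_channels(3), seed = 5))
  d <- file.path(tempdir(), "ion_rt")
  write_ion_dir(ph$stack, d)
  st2 <- read_ion_dir(d)
  expect_equal(st2$planes, ph$stack$planes, tolerance = 1e-6)
  expect_equal(st2$channels$mz, ph$stack$channels$mz)
  expect_equal(st2$pixel_size_um, 100)
})
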