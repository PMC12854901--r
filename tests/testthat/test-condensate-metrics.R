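mask_seg <- function(mask, nucleus = NULL) {
  structure(
    list(
      nucleus_mask = nucleus %||% array(TRUE, dim = dim(mask)),
      condensate_mask = mask,
      nucleus_threshold = 0, condensate_threshold = 1,
      empty = FALSE, fit = NULL
    ),
    class = "compartment_seg"
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("constructed cubes are counted with exact voxel volumes", {
  m <- array(FALSE, dim = c(12, 12, 8))
  m[2:4, 2:4, 2:4] <- TRUE
  m[8:10, 8:10, 5:7] <- TRUE
  vs <- c(0.3, 0.1, 0.1)
  obj <- label_condensates(mask_seg(m), min_size = 1, voxel_size = vs)
  expect_equal(nrow(obj), 2)
  expect_equal(obj$voxel_count, c(27L, 27L))
  expect_equal(obj$volume, rep(27 * prod(vs), 2))
  expect_equal(nrow(label_condensates(mask_seg(m), min_size = 28,
                                      voxel_size = vs)), 0)
})

test_that("labelling matches an exhaustive flood-fill oracle exactly", {
  set.seed(91)
  for (rep in 1:5) {
    m <- array(runif(14 * 14 * 7) < 0.18, dim = c(14, 14, 7))
    lab_pkg <- condensr:::cpp_label_components(m, 26L)
    lab_ref <- flood_fill_labels(m, 26)
    expect_equal(max(lab_pkg), max(lab_ref))
    expect_equal(sort(tabulate(lab_pkg[lab_pkg > 0])),
                 sort(tabulate(lab_ref[lab_ref > 0])))
    # voxel-level agreement up to label permutation
    pos <- lab_ref > 0
    expect_equal(length(unique(paste(lab_pkg[pos], lab_ref[pos]))), max(lab_ref))
  }
})

test_that("26-connectivity joins corner neighbours; 6-connectivity does not", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE # corner-adjacent
  expect_equal(max(condensr:::cpp_label_components(m, 26L)), 1)
  expect_equal(max(condensr:::cpp_label_components(m, 6L)), 2)
  obj <- label_condensates(mask_seg(m), min_size = 1, voxel_size = c(1, 1, 1))
  expect_equal(nrow(obj), 1)
})

test_that("placed spheres are recovered with analytic volumes", {
  p <- clean_scene_params(
    grid_shape = c(30, 110, 110), voxel_size = c(0.15, 0.06, 0.06),
    nucleus_axes = c(2, 3.1, 3.1), n_condensates = 12, volume_fraction = 0.1,
    condensate_radius_mean = 0.5, condensate_radius_sd = 0.05, rng_seed = 8
  )
  sc <- generate_scene(p)
  obj <- label_condensates(mask_seg(sc$truth$condensate_mask), min_size = 1,
                           voxel_size = p$voxel_size)
  expect_equal(nrow(obj), 12)
  tr <- sc$truth$per_object_volumes
  # voxelised volume within one voxel-shell of the analytic sphere volume
  for (i in seq_len(nrow(tr))) {
    r <- tr$radius[i]
    shell <- 4 * pi * r^2 * max(p$voxel_size)
    expect_lt(abs(tr$volume[i] - 4 / 3 * pi * r^3), shell)
  }
  expect_equal(sort(obj$voxel_count), sort(tr$voxel_count))
})

test_that("sub-min_size speckles do not change the condensate count", {
  m <- array(FALSE, dim = c(14, 14, 7))
  m[3:6, 3:6, 2:5] <- TRUE
  base <- label_condensates(mask_seg(m), min_size = 4, voxel_size = c(1, 1, 1))
  set.seed(5)
  speck <- m
  speck[12, 12, 6] <- TRUE
  speck[1, 13, 2] <- TRUE
  with_speck <- label_condensates(mask_seg(speck), min_size = 4,
                                  voxel_size = c(1, 1, 1))
  expect_equal(nrow(with_speck), nrow(base))
  expect_equal(with_speck$voxel_count, base$voxel_count)
})

test_that("phase metrics recover a noiseless scene and obey the mixture identity", {
  sc <- generate_scene(clean_scene_params(background_level = 10, noise_model = "gaussian",
                                       noise_sd = 3, rng_seed = 3))
  h <- weighted_intensity_histogram(sc$image, n_bins = 64)
  seg <- segment_compartments(sc$image, fit_gaussian_sum(h, 3))
  pm <- compute_phase_metrics(sc$image, seg)
  expect_rel_equal(pm$c_dil, 10 + sc$truth$true_c_dil, 0.05)
  expect_rel_equal(pm$c_den, 10 + sc$truth$true_c_den, 0.05)
  expect_rel_equal(pm$volume_fraction, sc$truth$true_volume_fraction, 0.05)
  # identity: c_tot is the phi-weighted mean of the phases by construction
  mix <- pm$volume_fraction * pm$c_den + (1 - pm$volume_fraction) * pm$c_dil
  expect_rel_equal(pm$c_tot, mix, 1e-6)
})

test_that("degenerate segmentations produce flagged metrics", {
  a <- array(5, dim = c(8, 8, 4))
  img <- volumetric_image(a, voxel_size = c(0.2, 0.1, 0.1))
  none <- mask_seg(array(FALSE, dim = dim(a)))
  pm <- compute_phase_metrics(img, none)
  expect_equal(pm$volume_fraction, 0)
  expect_true(is.na(pm$c_den))
  expect_equal(pm$c_tot, pm$c_dil)
  expect_equal(pm$n_condensates, 0L)
  all_cond <- mask_seg(array(TRUE, dim = dim(a)))
  pm2 <- compute_phase_metrics(img, all_cond)
  expect_equal(pm2$volume_fraction, 1)
  expect_true(is.na(pm2$c_dil))
})

test_that("volumes scale with voxel size while intensity statistics do not", {
  sc <- generate_scene(tiny_scene_params(noise_model = "gaussian", noise_sd = 3, rng_seed = 12))
  h <- weighted_intensity_histogram(sc$image, n_bins = 64)
  seg <- segment_compartments(sc$image, fit_gaussian_sum(h, 3))
  pm1 <- compute_phase_metrics(sc$image, seg)
  scaled <- sc$image
  s <- c(2, 3, 1.5)
  scaled$voxel_size <- scaled$voxel_size * s
  pm2 <- compute_phase_metrics(scaled, seg)
  expect_equal(pm2$nucleus_volume, pm1$nucleus_volume * prod(s))
  expect_equal(pm2$mean_condensate_volume,
               pm1$mean_condensate_volume * prod(s))
  expect_equal(pm2$c_tot, pm1$c_tot)
  expect_equal(pm2$c_den, pm1$c_den)
  expect_equal(pm2$volume_fraction, pm1$volume_fraction)
})
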