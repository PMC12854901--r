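test_that("FRAP normalisation maps the trace onto [0, 1] exactly", {
  tr <- normalize_frap(c(10, 10, 10, 10, 10, 2, 4, 6, 8), n_prebleach = 5)
  expect_equal(tr$normalised, c(1, 1, 1, 1, 1, 0, 0.25, 0.5, 0.75))
  expect_equal(min(tr$normalised), 0)
  expect_equal(max(tr$normalised), 1)
  expect_true(attr(tr, "included")) # 80% drop passes the 50% rule
})

test_that("a shallow bleach is flagged for exclusion", {
  tr <- normalize_frap(c(10, 10, 10, 10, 10, 7, 7.5, 8), n_prebleach = 5)
  expect_false(attr(tr, "included"))
  expect_equal(attr(tr, "bleach_drop"), 0.3)
})

test_that("FRAP normalisation recovers the generator's mobile fraction", {
  raw <- generate_frap_series(mobile_fraction = 0.6, recovery_rate = 0.2,
                              noise_sd = 0.5, rng_seed = 7)
  tr <- normalize_frap(raw)
  plateau <- mean(tr$normalised[tr$frame > 60])
  expect_lt(abs(plateau - 0.6), 0.05)
})

test_that("FRAP normalisation is idempotent and rejects flat traces", {
  tr <- normalize_frap(c(5, 5, 5, 5, 5, 1, 2, 3), n_prebleach = 5)
  again <- normalize_frap(tibble::tibble(intensity = tr$normalised),
                          n_prebleach = 5)
  expect_equal(again$normalised, tr$normalised)
  expect_error(normalize_frap(rep(3, 10)), "Flat")
  expect_error(normalize_frap(c(1, 2), n_prebleach = 5), "too short")
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("Pearson colocalisation is exact under affine identity", {
  sc <- generate_scene(tiny_scene_params(noise_model = "gaussian", noise_sd = 2,
                                         rng_seed = 3))
  ch1 <- sc$image
  ch2 <- ch1
  ch2$data <- 2 * ch1$data + 5
  res <- pearson_colocalization(ch1, ch2, mask = "whole-image")
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
  expect_equal(res$n_voxels, length(ch1$data))
})

test_that("independent channels decorrelate and partial channels hit rho", {
  p <- scene_params(
    grid_shape = c(20, 80, 80), voxel_size = c(0.2, 0.1, 0.1),
    nucleus_axes = c(1.6, 3, 3), n_condensates = 0, volume_fraction = 0,
    c_tot = 0, background_level = 50, noise_sd = 10, background_sd = 0,
    texture_cv = 0, rng_seed = 19
  )
  two <- generate_two_channel_scene(p, "independent")
  res <- pearson_colocalization(two$ch1, two$ch2, mask = "whole-image")
  expect_gte(res$n_voxels, 1e5)
  expect_lt(abs(res$pearson_r), 0.1)
  two2 <- generate_two_channel_scene(tiny_scene_params(noise_model = "gaussian",
                                                       noise_sd = 3,
                                                       rng_seed = 5),
                                     "partial", rho = 0.8)
  res2 <- pearson_colocalization(two2$ch1, two2$ch2, mask = "whole-image")
  expect_lt(abs(res2$pearson_r - 0.8), 0.05)
})

test_that("colocalisation masks and degenerate inputs are handled", {
  sc <- generate_scene(tiny_scene_params(rng_seed = 4))
  flat <- sc$image
  flat$data <- array(1, dim = dim(flat$data))
  expect_error(pearson_colocalization(sc$image, flat, mask = "whole-image"),
               "variance")
  m <- array(FALSE, dim = dim(sc$image$data))
  m[1:2, 1, 1] <- TRUE
  expect_error(pearson_colocalization(sc$image, sc$image, mask = m),
               "fewer than 10")
  two <- generate_two_channel_scene(tiny_scene_params(noise_model = "gaussian",
                                                      noise_sd = 3,
                                                      rng_seed = 6),
                                    "identical")
  res <- pearson_colocalization(two$ch1, two$ch2)
  expect_equal(res$mask_used, "otsu")
  expect_lt(res$n_voxels, length(two$ch1$data))
  expect_equal(res$pearson_r, 1, tolerance = 1e-12)
})

test_that("transects sample deterministically along the segment", {
  a <- array(4, dim = c(12, 12, 3))
  img <- volumetric_image(a, voxel_size = c(0.3, 0.1, 0.1))
  prof <- transect_profile(img, from = c(2, 2), to = c(2, 11), z = 2)
  expect_equal(nrow(prof), 10)
  expect_true(all(prof[[img$channel]] == 4))
  expect_equal(prof$distance[2] - prof$distance[1], 0.1)
  expect_error(transect_profile(img, from = c(3, 3), to = c(3, 3)), "Zero-length")
  expect_error(transect_profile(img, from = c(0, 2), to = c(5, 5)), "inside")
})

test_that("both channels of an identical scene peak at the same transect sample", {
  p <- tiny_scene_params(n_condensates = 1, volume_fraction = 0.06,
                         rng_seed = 10)
  two <- generate_two_channel_scene(p, "identical")
  obj <- two$truth$per_object_volumes
  lab <- two$truth$condensate_labels
  w <- which(lab == 1, arr.ind = TRUE)
  zc <- round(mean(w[, 3]))
  yc <- round(mean(w[w[, 3] == zc, 1]))
  prof <- transect_profile(two$ch1, two$ch2,
                           from = c(yc, 1), to = c(yc, dim(lab)[2]), z = zc)
  ch_names <- setdiff(names(prof), c("step", "y", "x", "distance"))
  expect_equal(which.max(prof[[ch_names[1]]]), which.max(prof[[ch_names[2]]]))
  expect_s3_class(plot_transect(prof), "ggplot")
})

test_that("integrated intensity is zero for uniform images and linear in brightness", {
  a <- array(5, dim = c(20, 20, 4))
  img <- volumetric_image(a, voxel_size = c(0.3, 0.1, 0.1))
  res <- suppressWarnings(integrated_intensity(img))
  expect_equal(res$integrated_intensity_per_slice, 0)
  sc1 <- generate_scene(tiny_scene_params(rng_seed = 14, background_level = 2))
  sc2 <- sc1
  sc2$image$data <- sc1$image$data * 2
  r1 <- integrated_intensity(sc1$image, background_roi = c(1, 1))
  r2 <- integrated_intensity(sc2$image, background_roi = c(1, 1))
  expect_rel_equal(r2$integrated_intensity_per_slice /
                     r1$integrated_intensity_per_slice, 2, 0.05)
})

test_that("per-slice normalisation makes duplicated stacks equivalent", {
  sc <- generate_scene(tiny_scene_params(rng_seed = 15, background_level = 2))
  a <- sc$image$data
  doubled <- volumetric_image(array(c(a, a), dim = c(dim(a)[1:2], 2 * dim(a)[3])),
                              voxel_size = sc$image$voxel_size)
  r1 <- integrated_intensity(sc$image, background_roi = c(1, 1))
  r2 <- integrated_intensity(doubled, background_roi = c(1, 1))
  expect_equal(r2$integrated_intensity_per_slice,
               r1$integrated_intensity_per_slice, tolerance = 1e-9)
  expect_equal(r2$n_slices, 2 * r1$n_slices)
})

test_that("integrated intensity is additive over disjoint regions", {
  set.seed(16)
  a <- array(runif(24 * 24 * 3, 10, 20), dim = c(24, 24, 3))
  a[, 1:12, ] <- a[, 1:12, ] + 30
  img <- volumetric_image(a, voxel_size = c(0.3, 0.1, 0.1))
  proj <- apply(a, c(1, 2), sum)
  roi_mean <- mean(proj[1:10, 13:22])
  manual <- sum(pmax(proj - roi_mean, 0)) / 3
  res <- suppressWarnings(integrated_intensity(img, background_roi = c(1, 13)))
  expect_equal(res$integrated_intensity_per_slice, manual, tolerance = 1e-9)
  left <- sum(pmax(proj[, 1:12] - roi_mean, 0)) / 3
  right <- sum(pmax(proj[, 13:24] - roi_mean, 0)) / 3
  expect_equal(res$integrated_intensity_per_slice, left + right,
               tolerance = 1e-9)
})

test_that("Mann-Whitney comparison matches exhaustive enumeration", {
  res <- compare_groups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$u, 0)
  # all 3 ranks below: exact two-sided p = 2 / choose(6, 3)
  expect_equal(res$p_value, 2 / choose(6, 3))
  expect_equal(res$stars, "n.s.")
  same <- compare_groups(c(5, 6, 7, 8), c(5, 6, 7, 8))
  expect_gt(same$p_value, 0.9)
  expect_equal(same$stars, "n.s.")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("star thresholds follow the usual convention", {
  set.seed(17)
  a <- rnorm(40, 0, 1)
  b <- rnorm(40, 3, 1)
  res <- compare_groups(a, b)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$stars, "***")
})
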