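test_that("mass balance fixes the phase concentrations in closed form", {
  # phi = 0.1, pc = 5, c_tot = 100 => C_dil = 100 / (0.1*5 + 0.9), C_den = 5 C_dil
  p <- clean_scene_params(
    volume_fraction = 0.1, partition_coefficient = 5, c_tot = 100,
    background_level = 0, rng_seed = 42
  )
  sc <- generate_scene(p)
  phi <- sc$truth$true_volume_fraction
  expect_equal(sc$truth$true_c_dil, 100 / (phi * 5 + (1 - phi)), tolerance = 1e-12)
  expect_equal(sc$truth$true_c_den, 5 * sc$truth$true_c_dil, tolerance = 1e-12)
  # the requested phi is achieved up to voxel discretisation
  expect_rel_equal(phi, 0.1, 0.05)
  expect_rel_equal(sc$truth$true_c_dil, 100 / (0.1 * 5 + 0.9), 0.02)
  # voxel-averaging the noiseless image over the nucleus returns c_tot
  expect_rel_equal(mean(sc$image$data[sc$truth$nucleus_mask]), 100, 0.01)
})

test_that("a condensate-free noiseless scene has exactly two intensity values", {
  p <- clean_scene_params(n_condensates = 0, volume_fraction = 0,
                          background_level = 7, rng_seed = 1)
  sc <- generate_scene(p)
  vals <- sort(unique(as.numeric(sc$image$data)))
  expect_length(vals, 2)
  expect_equal(vals[1], 7)
  expect_equal(vals[2], 7 + sc$truth$true_c_dil)
})

test_that("identical parameters and seed give bit-identical scenes", {
  p <- scene_params(rng_seed = 7, grid_shape = c(10, 32, 32),
                    voxel_size = c(0.2, 0.12, 0.12),
                    nucleus_axes = c(0.9, 1.7, 1.7),
                    condensate_radius_mean = 0.45, n_condensates = 2)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$condensate_labels, b$truth$condensate_labels)
  p2 <- p
  p2$rng_seed <- 8L
  expect_false(identical(generate_scene(p2)$image$data, a$image$data))
})

test_that("raising the partition coefficient raises C_den and lowers C_dil", {
  cdil <- cden <- numeric(0)
  for (pc in c(2, 5, 10)) {
    sc <- generate_scene(tiny_scene_params(partition_coefficient = pc, rng_seed = 5))
    cdil <- c(cdil, sc$truth$true_c_dil)
    cden <- c(cden, sc$truth$true_c_den)
  }
  expect_true(all(diff(cdil) < 0))
  expect_true(all(diff(cden) > 0))
})

test_that("ground-truth masks are geometrically consistent", {
  sc <- generate_scene(tiny_scene_params(rng_seed = 3))
  tr <- sc$truth
  expect_true(all(tr$nucleus_mask[tr$condensate_mask]))
  expect_equal(max(tr$condensate_labels), nrow(tr$per_object_volumes))
  expect_equal(sum(tr$condensate_mask) / sum(tr$nucleus_mask),
               tr$true_volume_fraction)
  expect_equal(sum(tr$per_object_volumes$voxel_count), sum(tr$condensate_mask))
})

test_that("impossible condensate packing fails with an informative error", {
  p <- tiny_scene_params(volume_fraction = 0.5, n_condensates = 40,
                         condensate_radius_sd = 0, rng_seed = 1)
  expect_error(generate_scene(p), "placed|crowded|radius")
})

test_that("parameter validation rejects unphysical scenes", {
  expect_error(scene_params(partition_coefficient = 0.5), "partition_coefficient")
  expect_error(scene_params(volume_fraction = 0.7), "volume_fraction")
  expect_error(scene_params(nucleus_axes = c(10, 10, 10)), "grid")
})

test_that("binary-mode series pins the dilute phase at saturation", {
  spec <- thermo_series_spec(
    n_images = 8, mode = "binary",
    scene = tiny_scene_params(), rng_seed = 2
  )
  ser <- generate_series(spec)
  expect_equal(nrow(ser), 8)
  expect_true(all(diff(ser$c_tot_nominal) > 0))
  expect_true(all(ser$true_c_dil == spec$c_sat))
  expect_true(all(ser$true_c_den == spec$c_den_binary))
})

test_that("sub-saturation binary images carry all signal in the dilute phase", {
  spec <- thermo_series_spec(
    n_images = 6, mode = "binary", c_tot_range = c(20, 70), c_sat = 40,
    scene = tiny_scene_params(), rng_seed = 2
  )
  ser <- generate_series(spec)
  below <- ser$c_tot_nominal < 40
  expect_true(any(below))
  expect_true(all(ser$true_volume_fraction[below] == 0))
  expect_true(all(ser$true_c_dil[below] == ser$c_tot_nominal[below]))
  # phi follows the lever rule, clipped at zero
  phi_law <- pmax((ser$c_tot_nominal - 40) / (spec$c_den_binary - 40), 0)
  expect_equal(ser$law_phi, phi_law, tolerance = 1e-12)
})

test_that("multicomponent-mode phase concentrations rise linearly with c_tot", {
  spec <- thermo_series_spec(
    n_images = 10, mode = "multicomponent",
    scene = tiny_scene_params(), rng_seed = 4
  )
  ser <- generate_series(spec)
  expect_true(all(diff(ser$true_c_dil) > 0))
  expect_true(all(diff(ser$true_c_den) > 0))
  expect_equal(cor(ser$c_tot_nominal, ser$true_c_dil), 1, tolerance = 1e-12)
})

test_that("series generation rejects a degenerate concentration range", {
  expect_error(thermo_series_spec(c_tot_range = c(100, 100)), "min < max")
  expect_error(thermo_series_spec(n_images = 1), "n_images")
})

test_that("identical-mode channels are perfectly correlated", {
  two <- generate_two_channel_scene(tiny_scene_params(rng_seed = 9), "identical")
  expect_equal(cor(as.numeric(two$ch1$data), as.numeric(two$ch2$data)), 1)
})

test_that("independent noise-dominated channels are uncorrelated", {
  p <- scene_params(
    grid_shape = c(20, 80, 80), voxel_size = c(0.2, 0.1, 0.1),
    nucleus_axes = c(1.6, 3, 3), n_condensates = 0, volume_fraction = 0,
    c_tot = 0, background_level = 50, noise_sd = 10, background_sd = 0,
    texture_cv = 0, rng_seed = 11
  )
  two <- generate_two_channel_scene(p, "independent")
  expect_gte(length(two$ch1$data), 1e5)
  r <- cor(as.numeric(two$ch1$data), as.numeric(two$ch2$data))
  expect_lt(abs(r), 0.1)
})

test_that("partial colocalisation hits the requested correlation", {
  for (rho in c(0.5, 0.8)) {
    two <- generate_two_channel_scene(tiny_scene_params(noise_model = "gaussian",
                                                        noise_sd = 3,
                                                        rng_seed = 13),
                                      "partial", rho = rho)
    r <- cor(as.numeric(two$ch1$data), as.numeric(two$ch2$data))
    expect_lt(abs(r - rho), 0.05)
  }
  expect_error(
    generate_two_channel_scene(tiny_scene_params(), "partial", rho = 1.2),
    "rho"
  )
})

test_that("FRAP traces follow the closed-form recovery model", {
  # full recovery limit
  tr <- generate_frap_series(recovery_rate = 50, mobile_fraction = 1,
                             noise_sd = 0, rng_seed = 1)
  expect_equal(tail(tr$intensity, 1), 100, tolerance = 1e-6)
  # immobile: flat at the bleach floor
  tr0 <- generate_frap_series(recovery_rate = 0.2, mobile_fraction = 0,
                              bleach_depth = 0.8, noise_sd = 0)
  post <- tr0$intensity[tr0$phase == "post"]
  expect_true(all(abs(post - 20) < 1e-9))
  # analytic exponential at every frame
  tr2 <- generate_frap_series(
    n_timepoints = 75, pre_bleach_level = 100, bleach_depth = 0.8,
    recovery_rate = 0.1, mobile_fraction = 0.7, noise_sd = 0
  )
  t_post <- 0:69
  expected <- 100 * (0.2 + 0.7 * 0.8 * (1 - exp(-0.1 * t_post)))
  expect_equal(tr2$intensity[tr2$phase == "post"], expected, tolerance = 1e-9)
  expect_error(generate_frap_series(recovery_rate = -1), "recovery_rate")
  expect_error(generate_frap_series(mobile_fraction = 2), "mobile_fraction")
})

test_that("TIFF round-trip preserves intensities to quantisation accuracy", {
  sc <- generate_scene(tiny_scene_params(rng_seed = 6))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volumetric_tiff(sc$image, path, bits = 12)
  back <- read_volumetric_tiff(path)
  expect_equal(back$voxel_size, sc$image$voxel_size)
  expect_equal(back$channel, sc$image$channel)
  tol <- max(sc$image$data) / (2^12 - 1)
  expect_lt(max(abs(back$data - sc$image$data)), tol)
})

test_that("unreadable TIFF input fails cleanly", {
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("this is not a tiff", bad)
  expect_error(read_volumetric_tiff(bad, voxel_size = c(0.2, 0.1, 0.1)),
               "Failed to read TIFF")
  expect_error(read_volumetric_tiff("/nonexistent/file.tif"), "not found")
})
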