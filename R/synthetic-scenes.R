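#' Parameters of a synthetic condensate scene
#'
#' Describes one simulated nucleus: an ellipsoidal compartment of elevated
#' scaffold fluorescence inside a darker field, containing spherical
#' condensates (the dense phase). Given the total scaffold concentration
#' `c_tot`, the partition coefficient `pc = C_den / C_dil` and the achieved
#' condensate volume fraction `phi`, the two phase concentrations follow from
#' mass balance:
#' \deqn{C_{tot} = \phi C_{den} + (1-\phi) C_{dil}, \qquad C_{den} = pc \cdot C_{dil}.}
#' The detector offset `background_level` is added everywhere, so that
#' mode-based background subtraction recovers scaffold signal without bias.
#'
#' `condensate_radius_mean`/`_sd` set the *relative* spread of condensate
#' radii; absolute radii are rescaled so the total analytic sphere volume
#' matches `volume_fraction` times the analytic nucleus volume.
#'
#' @param grid_shape Integer voxels `(z, y, x)`.
#' @param voxel_size Micrometres per voxel `(z, y, x)`.
#' @param nucleus_axes Ellipsoid semi-axes in micrometres `(z, y, x)`.
#' @param c_tot Mean scaffold fluorescence over the nucleus (a.u.).
#' @param partition_coefficient `C_den / C_dil`, must be >= 1.
#' @param volume_fraction Target fraction of nucleus volume occupied by
#'   condensates, in `[0, 0.5]`.
#' @param n_condensates Number of condensates to place.
#' @param condensate_radius_mean,condensate_radius_sd Radius distribution
#'   shape (micrometres, before volume rescaling).
#' @param background_level Detector offset (a.u.).
#' @param psf_sigma Isotropic Gaussian blur in micrometres; 0 disables.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param poisson_gain Intensity units per detected photon for Poisson noise.
#' @param texture_cv Coefficient of variation of the smooth multiplicative
#'   intra-phase texture field (chromatin-like heterogeneity within each
#'   phase); 0 renders perfectly uniform phases.
#' @param texture_scale Correlation length of the texture field in
#'   micrometres. Texture coarser than the median kernel survives filtering,
#'   which is what gives each compartment a finite-width intensity peak in
#'   real stacks.
#' @param background_sd Scale of the smooth, strictly nonnegative
#'   half-normal background structure field (extranuclear autofluorescence,
#'   e.g. chloroplasts in leaf tissue), a.u.; added on top of
#'   `background_level` everywhere. 0 disables.
#' @param c_dil,c_den Optional explicit phase concentrations; when supplied
#'   they override the `c_tot`/`partition_coefficient` mass balance and
#'   `c_tot` is recomputed from the achieved volume fraction.
#' @param rng_seed Integer seed; identical parameters and seed give
#'   bit-identical scenes.
#' @return A `scene_params` list.
#' @export
scene_params <- function(grid_shape = c(26, 96, 96),
                         voxel_size = c(0.15, 0.08, 0.08),
                         nucleus_axes = c(1.7, 3.0, 3.0),
                         c_tot = 100,
                         partition_coefficient = 5,
                         volume_fraction = 0.08,
                         n_condensates = 4,
                         condensate_radius_mean = 0.7,
                         condensate_radius_sd = 0.1,
                         background_level = 50,
                         psf_sigma = 0,
                         noise_model = c("gaussian", "none", "poisson"),
                         noise_sd = 4,
                         poisson_gain = 1,
                         texture_cv = 0.07,
                         texture_scale = 0.2,
                         background_sd = 8,
                         c_dil = NULL,
                         c_den = NULL,
                         rng_seed = 1L) {
  noise_model <- match.arg(noise_model)
  p <- list(
    grid_shape = setNames(as.integer(grid_shape), c("z", "y", "x")),
    voxel_size = setNames(as.numeric(voxel_size), c("z", "y", "x")),
    nucleus_axes = setNames(as.numeric(nucleus_axes), c("z", "y", "x")),
    c_tot = c_tot,
    partition_coefficient = partition_coefficient,
    volume_fraction = volume_fraction,
    n_condensates = as.integer(n_condensates),
    condensate_radius_mean = condensate_radius_mean,
    condensate_radius_sd = condensate_radius_sd,
    background_level = background_level,
    psf_sigma = psf_sigma,
    noise_model = noise_model,
    noise_sd = noise_sd,
    poisson_gain = poisson_gain,
    texture_cv = texture_cv,
    texture_scale = texture_scale,
    background_sd = background_sd,
    c_dil = c_dil,
    c_den = c_den,
    rng_seed = as.integer(rng_seed)
  )
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  if (is.null(p$c_dil) && p$partition_coefficient < 1) {
    abort("`partition_coefficient` must be >= 1.")
  }
  if (p$volume_fraction < 0 || p$volume_fraction > 0.5) {
    abort("`volume_fraction` must lie in [0, 0.5].")
  }
  if (p$n_condensates < 0) abort("`n_condensates` must be >= 0.")
  if (p$background_level < 0) abort("`background_level` must be >= 0.")
  half_extent <- p$grid_shape * p$voxel_size / 2
  if (any(p$nucleus_axes >= half_extent)) {
    abort("Nucleus does not fit in the grid; enlarge `grid_shape`.")
  }
  invisible(p)
}

# Voxel-centre coordinate vectors (micrometres) for each axis of the internal
# (y, x, z) array.
grid_coords <- function(p) {
  gs <- p$grid_shape
  vs <- p$voxel_size
  list(
    y = (seq_len(gs["y"]) - 0.5) * vs["y"],
    x = (seq_len(gs["x"]) - 0.5) * vs["x"],
    z = (seq_len(gs["z"]) - 0.5) * vs["z"]
  )
}

ellipsoid_mask <- function(coords, centre, axes) {
  qy <- ((coords$y - centre["y"]) / axes["y"])^2
  qx <- ((coords$x - centre["x"]) / axes["x"])^2
  qz <- ((coords$z - centre["z"]) / axes["z"])^2
  ny <- length(qy)
  nx <- length(qx)
  nz <- length(qz)
  q <- outer(outer(qy, qx, `+`), qz, `+`)
  array(q <= 1, dim = c(ny, nx, nz))
}

# Rejection-sample non-overlapping sphere centres fully inside the nucleus.
# A bounded total attempt budget keeps crowded requests from looping forever.
place_condensates <- function(p, centre, max_attempts = 1e4) {
  n <- p$n_condensates
  if (n == 0 || p$volume_fraction == 0) {
    return(list(centres = matrix(numeric(0), ncol = 3), radii = numeric(0)))
  }
  radii <- rnorm(n, p$condensate_radius_mean, p$condensate_radius_sd)
  radii <- pmax(radii, 0.2 * p$condensate_radius_mean)
  v_nuc <- 4 / 3 * pi * prod(p$nucleus_axes)
  target <- p$volume_fraction * v_nuc
  radii <- radii * (target / sum(4 / 3 * pi * radii^3))^(1 / 3)
  radii <- sort(radii, decreasing = TRUE) # place big ones first
  if (max(radii) >= min(p$nucleus_axes)) {
    abort("Condensate radius exceeds nucleus semi-axis; reduce `volume_fraction` or increase `n_condensates`.")
  }
  centres <- matrix(NA_real_, nrow = n, ncol = 3,
                    dimnames = list(NULL, c("z", "y", "x")))
  placed <- 0L
  attempts <- 0L
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    r <- radii[placed + 1L]
    # uniform in the shrunken ellipsoid that keeps the sphere inside
    ax <- p$nucleus_axes - r
    u <- runif(3, -1, 1)
    if (sum(u^2) > 1) next
    cand <- centre + u * ax[c("z", "y", "x")]
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt(colSums((t(centres[seq_len(placed), , drop = FALSE]) - cand)^2))
      ok <- all(d > radii[seq_len(placed)] + r + 0.01)
    }
    if (ok) {
      placed <- placed + 1L
      centres[placed, ] <- cand
    }
  }
  if (placed < n) {
    abort(sprintf(
      "Condensate placement failed: placed %d of %d after %d attempts; the nucleus is too crowded.",
      placed, n, attempts
    ))
  }
  list(centres = centres, radii = radii)
}

voxelise_condensates <- function(p, coords, placement) {
  gs <- p$grid_shape
  labels <- array(0L, dim = c(gs["y"], gs["x"], gs["z"]))
  n <- length(placement$radii)
  for (i in seq_len(n)) {
    c_i <- placement$centres[i, ]
    r <- placement$radii[i]
    iy <- which(abs(coords$y - c_i["y"]) <= r)
    ix <- which(abs(coords$x - c_i["x"]) <= r)
    iz <- which(abs(coords$z - c_i["z"]) <= r)
    if (!length(iy) || !length(ix) || !length(iz)) next
    qy <- ((coords$y[iy] - c_i["y"]) / r)^2
    qx <- ((coords$x[ix] - c_i["x"]) / r)^2
    qz <- ((coords$z[iz] - c_i["z"]) / r)^2
    q <- outer(outer(qy, qx, `+`), qz, `+`)
    sub <- labels[iy, ix, iz, drop = FALSE]
    sub[q <= 1] <- i
    labels[iy, ix, iz] <- sub
  }
  labels
}

apply_noise <- function(x, p) {
  switch(p$noise_model,
    none = x,
    gaussian = x + rnorm(length(x), 0, p$noise_sd),
    poisson = {
      g <- p$poisson_gain
      rpois(length(x), pmax(x, 0) / g) * g
    }
  )
}

#' Generate a synthetic condensate scene with ground truth
#'
#' Renders the scene described by [scene_params()]: voxel intensities are
#' `background_level` plus `C_dil` in the nucleoplasm and `C_den` inside
#' condensates, then optional Gaussian point-spread blur and detector noise
#' (negative values clamped to zero). The returned ground truth refers to
#' the pre-blur geometry and uses the volume fraction actually achieved after
#' voxel discretisation, so the mass balance holds exactly on the noiseless
#' rendered scene.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `image` (a [volumetric_image()]) and `truth`
#'   (class `scene_truth`: masks, label volume, true concentrations,
#'   per-object volumes).
#' @export
generate_scene <- function(params) {
  validate_scene_params(params)
  withr::with_seed(params$rng_seed, generate_scene_impl(params))
}

generate_scene_impl <- function(p) {
  coords <- grid_coords(p)
  centre <- setNames(p$grid_shape * p$voxel_size / 2, c("z", "y", "x"))
  nucleus <- ellipsoid_mask(coords, centre, p$nucleus_axes)
  placement <- place_condensates(p, centre)
  labels <- voxelise_condensates(p, coords, placement)
  cond <- labels > 0L
  # voxelised condensates are built inside the analytic nucleus, but guard
  # against discretisation leaking a voxel outside the nucleus mask
  cond <- cond & nucleus
  labels[!cond] <- 0L
  phi <- sum(cond) / sum(nucleus)

  if (!is.null(p$c_dil)) {
    c_dil <- p$c_dil
    c_den <- if (!is.null(p$c_den)) p$c_den else p$c_dil
    c_tot <- phi * c_den + (1 - phi) * c_dil
  } else if (phi == 0) {
    c_dil <- p$c_tot
    c_den <- NA_real_
    c_tot <- p$c_tot
  } else {
    pc <- p$partition_coefficient
    c_dil <- p$c_tot / (phi * pc + (1 - phi))
    c_den <- pc * c_dil
    c_tot <- p$c_tot
  }

  signal <- array(0, dim = dim(nucleus))
  signal[nucleus] <- c_dil
  if (!is.na(c_den)) signal[cond] <- c_den

  # smooth intra-phase texture and background variability: spatial structure
  # coarser than the median kernel, so compartment intensity peaks keep a
  # finite width after filtering (as in real stacks)
  if (p$texture_cv > 0 || p$background_sd > 0) {
    s_tex <- p$texture_scale / p$voxel_size # voxels (z, y, x)
    smooth_field <- function() {
      f <- array(rnorm(length(signal)), dim = dim(signal))
      f <- cpp_gaussian_blur(f, s_tex["y"], s_tex["x"], s_tex["z"])
      (f - mean(f)) / sd(f)
    }
    if (p$texture_cv > 0) {
      signal <- signal * (1 + p$texture_cv * smooth_field())
    }
    # structured stray fluorescence (e.g. chloroplast autofluorescence):
    # discrete bright patches on a flat dark floor, so a large share of
    # background voxels sit exactly at `background_level` and the image mode
    # identifies the detector floor; excluded from the nucleus
    bg_field <- 0
    if (p$background_sd > 0) {
      bg_field <- p$background_sd * pmax(abs(smooth_field()) - 0.5, 0)
      bg_field[nucleus] <- 0
    }
    img <- pmax(signal, 0) + p$background_level + bg_field
  } else {
    img <- signal + p$background_level
  }
  img <- array(img, dim = dim(nucleus))

  if (p$psf_sigma > 0) {
    s_vox <- p$psf_sigma / p$voxel_size # (z, y, x)
    img <- cpp_gaussian_blur(img, s_vox["y"], s_vox["x"], s_vox["z"])
  }
  img <- apply_noise(img, p)
  img <- array(pmax(img, 0), dim = dim(nucleus))

  vv <- voxel_volume(p$voxel_size)
  counts <- tabulate(labels[labels > 0L], nbins = max(labels, 0L))
  per_object <- tibble::tibble(
    label = seq_along(counts),
    voxel_count = as.integer(counts),
    volume = counts * vv,
    radius = placement$radii[seq_along(counts)]
  )
  truth <- structure(
    list(
      nucleus_mask = nucleus,
      condensate_mask = cond,
      condensate_labels = labels,
      true_c_dil = c_dil,
      true_c_den = c_den,
      true_c_tot = c_tot,
      true_volume_fraction = phi,
      background_level = p$background_level,
      per_object_volumes = per_object,
      params = p
    ),
    class = "scene_truth"
  )
  list(
    image = volumetric_image(img, voxel_size = p$voxel_size, channel = "mClover3"),
    truth = truth
  )
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> C_dil=%.4g C_den=%.4g C_tot=%.4g phi=%.4g, %d condensates\n",
    x$true_c_dil, x$true_c_den, x$true_c_tot, x$true_volume_fraction,
    nrow(x$per_object_volumes)
  ))
  invisible(x)
}

#' Reduced-size scene template for large simulation studies
#'
#' The default [scene_params()] geometry is sized for accurate per-image
#' quantification. Simulation studies that analyse thousands of images
#' (e.g. replicated series discrimination) use this smaller grid; the
#' segmentation biases grow somewhat at this resolution but cross-image
#' correlation structure is preserved.
#'
#' @param ... Overrides passed to [scene_params()].
#' @return A `scene_params` object.
#' @export
scene_params_reduced <- function(...) {
  scene_params(
    grid_shape = c(12, 40, 40),
    voxel_size = c(0.2, 0.12, 0.12),
    nucleus_axes = c(1.1, 1.9, 1.9),
    condensate_radius_mean = 0.5,
    condensate_radius_sd = 0.07,
    ...
  )
}

#' Specification of a concentration-dependence image series
#'
#' Defines a set of simulated nuclei spanning a range of total scaffold
#' concentrations under one of two thermodynamic regimes. In `"binary"` mode
#' the system behaves as a simple two-phase separator: above the saturation
#' concentration `c_sat` the dilute phase is pinned at `c_sat` and the dense
#' phase at `c_den_binary`, and only the condensate volume fraction grows
#' with `c_tot`. In `"multicomponent"` mode both phase concentrations climb
#' linearly with `c_tot` (`c_dil = dil_intercept + dil_slope * c_tot`,
#' `c_den = den_intercept + den_slope * c_tot`), as observed for condensates
#' whose composition involves heterotypic partners.
#'
#' @param n_images Number of images (>= 2), evenly spaced over `c_tot_range`.
#' @param c_tot_range `(min, max)` total concentration in a.u.
#' @param mode `"multicomponent"` or `"binary"`.
#' @param c_sat,c_den_binary Binary-mode phase concentrations (a.u.).
#' @param dil_intercept,dil_slope,den_intercept,den_slope Multicomponent
#'   linear laws (a.u. and dimensionless slope).
#' @param scene Template [scene_params()] providing geometry, optics and
#'   noise; per-image concentration fields are overridden.
#' @param rng_seed Integer seed; per-image seeds are derived from it.
#' @return A `thermo_series_spec` list.
#' @export
thermo_series_spec <- function(n_images = 40,
                               c_tot_range = c(50, 130),
                               mode = c("multicomponent", "binary"),
                               c_sat = 40,
                               c_den_binary = 400,
                               dil_intercept = 20, dil_slope = 0.3,
                               den_intercept = 200, den_slope = 2,
                               scene = scene_params(),
                               rng_seed = 1L) {
  mode <- match.arg(mode)
  if (n_images < 2) abort("`n_images` must be >= 2.")
  if (c_tot_range[1] >= c_tot_range[2]) {
    abort("`c_tot_range` must satisfy min < max.")
  }
  structure(
    list(
      n_images = as.integer(n_images), c_tot_range = as.numeric(c_tot_range),
      mode = mode, c_sat = c_sat, c_den_binary = c_den_binary,
      dil_intercept = dil_intercept, dil_slope = dil_slope,
      den_intercept = den_intercept, den_slope = den_slope,
      scene = scene, rng_seed = as.integer(rng_seed)
    ),
    class = "thermo_series_spec"
  )
}

series_law <- function(spec, c_tot) {
  if (spec$mode == "binary") {
    phi <- pmax((c_tot - spec$c_sat) / (spec$c_den_binary - spec$c_sat), 0)
    c_dil <- ifelse(phi > 0, spec$c_sat, c_tot)
    c_den <- ifelse(phi > 0, spec$c_den_binary, NA_real_)
  } else {
    c_dil <- spec$dil_intercept + spec$dil_slope * c_tot
    c_den <- spec$den_intercept + spec$den_slope * c_tot
    phi <- pmax((c_tot - c_dil) / (c_den - c_dil), 0)
    c_den[phi == 0] <- NA_real_
    c_dil[phi == 0] <- c_tot[phi == 0]
  }
  tibble::tibble(c_tot_nominal = c_tot, law_c_dil = c_dil,
                 law_c_den = c_den, law_phi = phi)
}

#' Generate a concentration-dependence series of synthetic scenes
#'
#' @param spec A [thermo_series_spec()].
#' @return A tibble with one row per image, ordered by increasing nominal
#'   `c_tot`: image id, the thermodynamic law values, achieved ground-truth
#'   values and list-columns `image` and `truth`.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "thermo_series_spec"))
  c_tot <- seq(spec$c_tot_range[1], spec$c_tot_range[2],
               length.out = spec$n_images)
  law <- series_law(spec, c_tot)
  seeds <- withr::with_seed(
    spec$rng_seed,
    sample.int(.Machine$integer.max, spec$n_images)
  )
  rows <- purrr::pmap(
    list(law$c_tot_nominal, law$law_c_dil, law$law_c_den, law$law_phi, seeds),
    function(ct, cd, cn, phi, seed) {
      p <- spec$scene
      p$volume_fraction <- min(phi, 0.5)
      # droplet size distribution is held fixed across the series; the
      # condensate *number* carries the volume-fraction dependence
      v_drop <- 4 / 3 * pi *
        (p$condensate_radius_mean^3 + 3 * p$condensate_radius_mean * p$condensate_radius_sd^2)
      v_nuc <- 4 / 3 * pi * prod(p$nucleus_axes)
      p$n_condensates <- if (phi > 0) {
        max(1L, as.integer(round(phi * v_nuc / v_drop)))
      } else {
        0L
      }
      p$c_dil <- cd
      p$c_den <- if (is.na(cn)) NULL else cn
      p$c_tot <- ct
      p$rng_seed <- as.integer(seed %% .Machine$integer.max)
      generate_scene(p)
    }
  )
  out <- dplyr::bind_cols(
    tibble::tibble(image_id = sprintf("img%03d", seq_along(rows))),
    law,
    tibble::tibble(
      true_c_dil = purrr::map_dbl(rows, ~ .x$truth$true_c_dil),
      true_c_den = purrr::map_dbl(rows, ~ .x$truth$true_c_den),
      true_c_tot = purrr::map_dbl(rows, ~ .x$truth$true_c_tot),
      true_volume_fraction = purrr::map_dbl(rows, ~ .x$truth$true_volume_fraction),
      image = purrr::map(rows, "image"),
      truth = purrr::map(rows, "truth")
    )
  )
  out
}

#' Generate a two-channel scene for co-localisation analysis
#'
#' The first channel is a standard scene. The second is either an exact copy
#' (`"identical"`), an independently seeded realisation (`"independent"`), or
#' a statistical mixture (`"partial"`) constructed so that the voxelwise
#' Pearson correlation between the channels across the grid is approximately
#' `rho`. The partial construction mixes the standardised first channel with
#' an independent smoothed Gaussian field and is intended for validating
#' correlation estimation, not as a physical second fluorophore.
#'
#' @param params A [scene_params()] for channel 1.
#' @param coloc_mode `"identical"`, `"independent"` or `"partial"`.
#' @param rho Target correlation for `"partial"`, in (-1, 1).
#' @return List with `ch1`, `ch2` ([volumetric_image()]s) and `truth` of the
#'   first channel's scene.
#' @export
generate_two_channel_scene <- function(params,
                                       coloc_mode = c("identical", "independent", "partial"),
                                       rho = 0.8) {
  coloc_mode <- match.arg(coloc_mode)
  scene <- generate_scene(params)
  ch1 <- scene$image
  ch1$channel <- "ch1"
  if (coloc_mode == "identical") {
    ch2 <- ch1
    ch2$channel <- "ch2"
  } else if (coloc_mode == "independent") {
    p2 <- params
    p2$rng_seed <- withr::with_seed(
      params$rng_seed + 1L,
      sample.int(.Machine$integer.max, 1)
    )
    ch2 <- generate_scene(p2)$image
    ch2$channel <- "ch2"
  } else {
    if (abs(rho) >= 1) abort("`rho` must lie strictly inside (-1, 1).")
    x <- as.numeric(ch1$data)
    z1 <- (x - mean(x)) / sd(x)
    e <- withr::with_seed(params$rng_seed + 2L, {
      f <- array(rnorm(length(x)), dim = dim(ch1$data))
      if (params$psf_sigma > 0) {
        s_vox <- params$psf_sigma / params$voxel_size
        f <- cpp_gaussian_blur(f, s_vox["y"], s_vox["x"], s_vox["z"])
      }
      as.numeric(f)
    })
    e <- (e - mean(e)) / sd(e)
    mix <- rho * z1 + sqrt(1 - rho^2) * e
    # offset keeps the rendered channel nonnegative without clipping the mix
    y <- mean(x) + 4 * sd(x) + sd(x) * mix
    ch2 <- volumetric_image(array(y, dim = dim(ch1$data)),
                            voxel_size = params$voxel_size, channel = "ch2")
  }
  list(ch1 = ch1, ch2 = ch2, truth = scene$truth)
}

#' Generate a synthetic FRAP intensity trace
#'
#' Pre-bleach frames sit at `pre_bleach_level`; the bleach event drops the
#' signal to `pre_bleach_level * (1 - bleach_depth)`; recovery is a single
#' exponential toward the mobile-fraction plateau
#' `pre * (floor + mobile_fraction * (1 - floor))` with `floor = 1 - bleach_depth`:
#' \deqn{I(t) = I_0 \left( f + m (1-f)(1 - e^{-k t}) \right)}
#' for post-bleach frame index `t = 0, 1, ...`.
#'
#' @param n_timepoints Total frames (pre + post); default 75 = 5 + 70.
#' @param pre_bleach_level Plateau before bleaching (a.u.).
#' @param bleach_depth Fractional drop at the bleach event, in (0, 1].
#' @param recovery_rate Exponential rate per frame (>= 0).
#' @param mobile_fraction Fraction of signal that recovers, in [0, 1].
#' @param noise_sd Additive Gaussian noise (a.u.).
#' @param n_prebleach Number of pre-bleach frames.
#' @param rng_seed Integer seed.
#' @return Tibble with `frame`, `phase` (`"pre"`/`"post"`) and `intensity`.
#' @export
generate_frap_series <- function(n_timepoints = 75,
                                 pre_bleach_level = 100,
                                 bleach_depth = 0.8,
                                 recovery_rate = 0.15,
                                 mobile_fraction = 0.7,
                                 noise_sd = 1,
                                 n_prebleach = 5,
                                 rng_seed = 1L) {
  if (recovery_rate < 0) abort("`recovery_rate` must be >= 0.")
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    abort("`mobile_fraction` must lie in [0, 1].")
  }
  if (bleach_depth <= 0 || bleach_depth > 1) {
    abort("`bleach_depth` must lie in (0, 1].")
  }
  n_post <- n_timepoints - n_prebleach
  if (n_post < 1) abort("`n_timepoints` must exceed `n_prebleach`.")
  floor_frac <- 1 - bleach_depth
  t_post <- seq_len(n_post) - 1
  mean_trace <- c(
    rep(pre_bleach_level, n_prebleach),
    pre_bleach_level *
      (floor_frac + mobile_fraction * (1 - floor_frac) *
         (1 - exp(-recovery_rate * t_post)))
  )
  noise <- if (noise_sd > 0) {
    withr::with_seed(rng_seed, rnorm(n_timepoints, 0, noise_sd))
  } else {
    rep(0, n_timepoints)
  }
  tibble::tibble(
    frame = seq_len(n_timepoints),
    phase = rep(c("pre", "post"), c(n_prebleach, n_post)),
    intensity = mean_trace + noise
  )
}
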