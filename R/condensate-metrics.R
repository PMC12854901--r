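#' Label individual condensates in a segmentation
#'
#' 26-connected components of the condensate mask, discarding objects below
#' `min_size` voxels (speckle rejection; the threshold is exposed because
#' object-detection cutoffs are image-quality dependent). Physical volumes
#' use the anisotropic voxel size.
#'
#' @param seg A [segment_compartments()] result (or a logical mask array,
#'   in which case `voxel_size` must be supplied).
#' @param img Optional [volumetric_image()] for per-object intensity stats.
#' @param min_size Minimum object size in voxels.
#' @param voxel_size `(z, y, x)` voxel size when `seg` is a bare mask.
#' @return A tibble of objects sorted by descending volume: `label`,
#'   `voxel_count`, `volume` (\eqn{\mu m^3}), centroid coordinates
#'   (micrometres), and mean/max intensity when `img` is given.
#' @export
label_condensates <- function(seg, img = NULL, min_size = 4, voxel_size = NULL) {
  if (inherits(seg, "compartment_seg")) {
    mask <- seg$condensate_mask
    if (is.null(voxel_size) && !is.null(img)) voxel_size <- img$voxel_size
  } else {
    mask <- seg
  }
  if (is.null(voxel_size)) {
    if (is.null(img)) abort("Supply `img` or `voxel_size` for physical volumes.")
    voxel_size <- img$voxel_size
  }
  voxel_size <- setNames(as.numeric(voxel_size), c("z", "y", "x"))
  vv <- prod(voxel_size)
  lab <- cpp_label_components(array(as.logical(mask), dim = dim(mask)), 26L)
  n_lab <- max(lab)
  empty <- tibble::tibble(
    label = integer(0), voxel_count = integer(0), volume = numeric(0),
    centroid_z = numeric(0), centroid_y = numeric(0), centroid_x = numeric(0),
    mean_intensity = numeric(0), max_intensity = numeric(0)
  )
  if (n_lab == 0L) {
    return(empty)
  }
  counts <- tabulate(lab[lab > 0L], nbins = n_lab)
  keep <- which(counts >= min_size)
  if (length(keep) == 0L) {
    return(empty)
  }
  idx <- which(lab > 0L)
  li <- lab[idx]
  sel <- li %in% keep
  idx <- idx[sel]
  li <- li[sel]
  d <- dim(mask)
  yy <- (idx - 1) %% d[1] + 1
  xx <- ((idx - 1) %/% d[1]) %% d[2] + 1
  zz <- (idx - 1) %/% (d[1] * d[2]) + 1
  grp <- factor(li, levels = keep)
  cen <- function(v, vs) as.numeric(tapply((v - 0.5) * vs, grp, mean))
  out <- tibble::tibble(
    label = keep,
    voxel_count = counts[keep],
    volume = counts[keep] * vv,
    centroid_z = cen(zz, voxel_size["z"]),
    centroid_y = cen(yy, voxel_size["y"]),
    centroid_x = cen(xx, voxel_size["x"]),
    mean_intensity = NA_real_,
    max_intensity = NA_real_
  )
  if (!is.null(img)) {
    vals <- img$data[idx]
    out$mean_intensity <- as.numeric(tapply(vals, grp, mean))
    out$max_intensity <- as.numeric(tapply(vals, grp, max))
  }
  dplyr::arrange(out, dplyr::desc(.data$volume), .data$label)
}

#' Per-image phase metrics
#'
#' Compartment concentrations are mean voxel intensities: `c_tot` over the
#' whole nucleus, `c_dil` over the nucleoplasm (nucleus minus condensates),
#' `c_den` over the pooled condensate voxels (`NA` when there are none).
#' Volumes come from segmented voxel counts times the physical voxel volume,
#' and the volume fraction is condensate voxels over nucleus voxels, so the
#' mixture identity `c_tot = phi * c_den + (1 - phi) * c_dil` holds by
#' construction.
#'
#' @param img The (filtered, background-subtracted) [volumetric_image()].
#' @param seg A [segment_compartments()] result.
#' @param objects Optional [label_condensates()] tibble; computed with the
#'   default `min_size` when absent. Condensate counts and mean volumes are
#'   reported from this table.
#' @return A one-row tibble: `c_tot`, `c_dil`, `c_den`, `volume_fraction`,
#'   `n_condensates`, `mean_condensate_volume`, `nucleus_volume`.
#' @export
compute_phase_metrics <- function(img, seg, objects = NULL) {
  stopifnot(is_volumetric_image(img), inherits(seg, "compartment_seg"))
  nuc <- seg$nucleus_mask
  if (!any(nuc)) abort("Empty nucleus mask; no compartment to quantify.")
  cond <- seg$condensate_mask
  dil <- nuc & !cond
  n_nuc <- sum(nuc)
  n_cond <- sum(cond)
  if (is.null(objects)) objects <- label_condensates(seg, img = img)
  vv <- voxel_volume(img)
  tibble::tibble(
    c_tot = mean(img$data[nuc]),
    c_dil = if (any(dil)) mean(img$data[dil]) else NA_real_,
    c_den = if (n_cond > 0) mean(img$data[cond]) else NA_real_,
    volume_fraction = n_cond / n_nuc,
    n_condensates = nrow(objects),
    mean_condensate_volume = if (nrow(objects)) mean(objects$volume) else NA_real_,
    nucleus_volume = n_nuc * vv
  )
}
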