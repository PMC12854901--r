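#' Segment nucleus and condensates from a fitted intensity model
#'
#' Thresholds follow the mean + 3 SD rule: the nucleus (or cell) compartment
#' is every voxel brighter than `mu_1 + 3 sigma_1` of the first (background)
#' Gaussian component, and the dense phase is every nucleus voxel brighter
#' than `mu_2 + 3 sigma_2` of the second (nucleoplasm) component. When four
#' components were fitted, components 3 and 4 jointly describe the dense
#' phase and the condensate threshold still comes from component 2.
#'
#' The nucleus mask is post-processed to the largest 26-connected component
#' with internal holes filled, so bright debris outside the nucleus cannot
#' join it and condensate voxels darker than the nucleus threshold cannot
#' punch holes through it.
#'
#' @param img The (filtered, background-subtracted) [volumetric_image()] the
#'   histogram was computed from.
#' @param fit A converged [fit_gaussian_sum()] with >= 2 components.
#' @return An object of class `compartment_seg`: logical `nucleus_mask` and
#'   `condensate_mask` arrays, the two thresholds, an `empty` flag and the
#'   fit that produced them.
#' @export
segment_compartments <- function(img, fit) {
  stopifnot(is_volumetric_image(img), inherits(fit, "gmm_fit"))
  if (nrow(fit$components) < 2 || anyNA(fit$components$mean)) {
    abort("Segmentation needs a fit with at least two components.")
  }
  comp <- fit$components
  thr_nucleus <- comp$mean[1] + 3 * comp$sd[1]
  thr_condensate <- comp$mean[2] + 3 * comp$sd[2]
  if (thr_condensate <= thr_nucleus) {
    abort(sprintf(
      paste0(
        "Inverted thresholds: condensate threshold %.4g <= nucleus threshold ",
        "%.4g; the first two fitted components overlap."
      ),
      thr_condensate, thr_nucleus
    ))
  }
  above <- img$data > thr_nucleus
  empty <- !any(above)
  if (empty) {
    nucleus <- above
  } else {
    lab <- cpp_label_components(above, 26L)
    counts <- tabulate(lab[lab > 0L])
    keep <- which.max(counts)
    nucleus <- array(lab == keep, dim = dim(above))
    nucleus <- fill_holes_3d(nucleus)
  }
  condensate <- nucleus & (img$data > thr_condensate)
  structure(
    list(
      nucleus_threshold = thr_nucleus,
      condensate_threshold = thr_condensate,
      nucleus_mask = nucleus,
      condensate_mask = condensate,
      empty = empty,
      fit = fit
    ),
    class = "compartment_seg"
  )
}

# Fill cavities: background components (6-connected) that do not touch the
# array border are interior holes.
fill_holes_3d <- function(mask) {
  bg <- !mask
  lab <- cpp_label_components(bg, 6L)
  d <- dim(mask)
  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]
  ))
  border_labels <- border_labels[border_labels > 0L]
  hole <- bg & !array(lab %in% border_labels, dim = d)
  mask | hole
}

#' @export
print.compartment_seg <- function(x, ...) {
  cat(sprintf(
    "<compartment_seg> nucleus > %.4g (%d voxels), condensates > %.4g (%d voxels)%s\n",
    x$nucleus_threshold, sum(x$nucleus_mask),
    x$condensate_threshold, sum(x$condensate_mask),
    if (x$empty) " [EMPTY]" else ""
  ))
  invisible(x)
}
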