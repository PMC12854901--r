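#' Normalise a FRAP recovery curve
#'
#' Affine rescaling of a fluorescence-recovery trace so that its maximum is
#' exactly 1 and its minimum exactly 0, allowing recovery curves from
#' different structures to be compared. The function also applies the usual
#' inclusion rule that the bleach must have removed at least half the signal:
#' a trace whose first post-bleach value exceeds 50 percent of the pre-bleach
#' mean is flagged as excluded (but still returned).
#'
#' @param raw_trace Numeric intensity trace, or a tibble with an `intensity`
#'   column such as [generate_frap_series()] output.
#' @param n_prebleach Number of pre-bleach frames at the start of the trace.
#' @return A tibble of class `frap_trace`: `frame`, `phase`, `raw`,
#'   `normalised`, with attributes `included` (logical), `bleach_drop`
#'   (fractional signal loss at the bleach frame) and `n_prebleach`.
#' @export
normalize_frap <- function(raw_trace, n_prebleach = 5) {
  if (is.data.frame(raw_trace)) {
    if (!"intensity" %in% names(raw_trace)) {
      abort("Trace data frame needs an `intensity` column.")
    }
    raw <- raw_trace$intensity
  } else {
    raw <- as.numeric(raw_trace)
  }
  n <- length(raw)
  if (n <= n_prebleach + 1) abort("Trace too short for the given `n_prebleach`.")
  rng <- range(raw)
  if (rng[1] == rng[2]) abort("Flat trace; normalisation undefined.")
  normalised <- (raw - rng[1]) / (rng[2] - rng[1])
  pre_mean <- mean(raw[seq_len(n_prebleach)])
  first_post <- raw[n_prebleach + 1]
  bleach_drop <- 1 - first_post / pre_mean
  included <- bleach_drop >= 0.5
  out <- tibble::tibble(
    frame = seq_len(n),
    phase = rep(c("pre", "post"), c(n_prebleach, n - n_prebleach)),
    raw = raw,
    normalised = normalised
  )
  attr(out, "included") <- included
  attr(out, "bleach_drop") <- bleach_drop
  attr(out, "n_prebleach") <- n_prebleach
  class(out) <- c("frap_trace", class(out))
  out
}

#' Voxelwise Pearson co-localisation of two channels
#'
#' Pearson correlation (with two-sided p-value) between two channels over a
#' stated voxel mask. Whole-image correlations are inflated by the shared
#' dark background, so the default mask is the union of per-channel Otsu
#' foregrounds.
#'
#' @param ch1,ch2 [volumetric_image()]s on identical grids.
#' @param mask `"otsu"` (default), `"whole-image"`, or a logical array.
#' @return One-row tibble: `pearson_r`, `p_value`, `n_voxels`, `mask_used`.
#' @export
pearson_colocalization <- function(ch1, ch2, mask = "otsu") {
  stopifnot(is_volumetric_image(ch1), is_volumetric_image(ch2))
  assert_same_grid(ch1, ch2)
  if (is.character(mask)) {
    mask_used <- match.arg(mask, c("otsu", "whole-image"))
    m <- if (mask_used == "whole-image") {
      array(TRUE, dim = dim(ch1$data))
    } else {
      (ch1$data > otsu_threshold(ch1$data)) |
        (ch2$data > otsu_threshold(ch2$data))
    }
  } else {
    mask_used <- "custom"
    m <- mask
    if (!identical(dim(m), dim(ch1$data))) abort("Mask grid mismatch.")
  }
  a <- ch1$data[m]
  b <- ch2$data[m]
  if (length(a) < 10) abort("Mask selects fewer than 10 voxels.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Zero variance in one channel inside the mask.")
  }
  ct <- cor.test(a, b, method = "pearson")
  tibble::tibble(
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    n_voxels = length(a),
    mask_used = mask_used
  )
}

# Otsu's between-class variance threshold on a 256-bin histogram.
otsu_threshold <- function(x, n_bins = 256) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    return(rng[1])
  }
  width <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((x - rng[1]) / width), n_bins - 1) + 1
  h <- tabulate(as.integer(idx), nbins = n_bins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[n_bins]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  centers[which.max(between)] + width / 2
}

#' Paired intensity profile along a line transect
#'
#' Samples one z-plane of one or two channels along the discretised segment
#' between two in-plane endpoints using nearest-voxel stepping (one sample
#' per unit step along the longer axis), the standard way to display
#' co-localisation across a condensate.
#'
#' @param ch1 A [volumetric_image()].
#' @param ch2 Optional second channel on the same grid.
#' @param from,to Endpoints `c(y, x)` in voxel coordinates.
#' @param z z-slice index.
#' @return Tibble with `step`, `y`, `x`, `distance` (micrometres along the
#'   transect) and one intensity column per channel.
#' @export
transect_profile <- function(ch1, ch2 = NULL, from, to, z = 1) {
  stopifnot(is_volumetric_image(ch1))
  d <- dim(ch1$data)
  pts <- rbind(from, to)
  if (any(pts[, 1] < 1 | pts[, 1] > d[1] | pts[, 2] < 1 | pts[, 2] > d[2]) ||
      z < 1 || z > d[3]) {
    abort("Transect endpoints must lie inside the grid.")
  }
  n_steps <- max(abs(to - from)) + 1
  if (n_steps == 1 && all(from == to)) abort("Zero-length transect.")
  yy <- round(seq(from[1], to[1], length.out = n_steps))
  xx <- round(seq(from[2], to[2], length.out = n_steps))
  step_um <- sqrt(
    ((to[1] - from[1]) * ch1$voxel_size["y"])^2 +
      ((to[2] - from[2]) * ch1$voxel_size["x"])^2
  ) / (n_steps - 1)
  out <- tibble::tibble(
    step = seq_len(n_steps),
    y = yy, x = xx,
    distance = (seq_len(n_steps) - 1) * step_um,
    ch1 = ch1$data[cbind(yy, xx, z)]
  )
  names(out)[names(out) == "ch1"] <- ch1$channel
  if (!is.null(ch2)) {
    assert_same_grid(ch1, ch2)
    out[[ch2$channel]] <- ch2$data[cbind(yy, xx, z)]
  }
  out
}

#' Semi-quantitative protein level from a sum projection
#'
#' Sums the stack along z, estimates the background as the mean of a square
#' region of interest on the projection, subtracts it from every projected
#' pixel (clamping at zero) and reports the total remaining intensity divided
#' by the number of z-slices - a per-slice integrated intensity comparable
#' across images acquired with identical settings.
#'
#' @param img A [volumetric_image()].
#' @param background_roi `c(y, x)` corner of the ROI on the projection;
#'   `NULL` picks the image corner with the lowest mean.
#' @param roi_size ROI edge length in pixels.
#' @return One-row tibble: `integrated_intensity_per_slice`,
#'   `background_roi_mean`, `n_slices`, `channel`, `roi_y`, `roi_x`.
#' @export
integrated_intensity <- function(img, background_roi = NULL, roi_size = 10) {
  stopifnot(is_volumetric_image(img))
  d <- dim(img$data)
  if (roi_size > min(d[1], d[2])) abort("`roi_size` exceeds the image plane.")
  proj <- apply(img$data, c(1, 2), sum)
  if (is.null(background_roi)) {
    corners <- rbind(
      c(1, 1), c(1, d[2] - roi_size + 1),
      c(d[1] - roi_size + 1, 1), c(d[1] - roi_size + 1, d[2] - roi_size + 1)
    )
    means <- apply(corners, 1, function(cc) {
      mean(proj[cc[1]:(cc[1] + roi_size - 1), cc[2]:(cc[2] + roi_size - 1)])
    })
    background_roi <- corners[which.min(means), ]
  }
  ry <- background_roi[1]:(background_roi[1] + roi_size - 1)
  rx <- background_roi[2]:(background_roi[2] + roi_size - 1)
  if (max(ry) > d[1] || max(rx) > d[2] || min(ry) < 1 || min(rx) < 1) {
    abort("Background ROI falls outside the image.")
  }
  roi_mean <- mean(proj[ry, rx])
  fg <- proj > otsu_threshold(proj)
  if (any(fg[ry, rx])) {
    warn("Background ROI overlaps detected signal; the estimate may be inflated.")
  }
  corrected <- pmax(proj - roi_mean, 0)
  tibble::tibble(
    integrated_intensity_per_slice = sum(corrected) / d[3],
    background_roi_mean = roi_mean,
    n_slices = d[3],
    channel = img$channel,
    roi_y = background_roi[1],
    roi_x = background_roi[2]
  )
}

#' Compare two groups with a Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test with the usual star
#' convention: `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05,
#' `n.s.` otherwise. Exact p-values are used for small tie-free samples and
#' the tie-corrected normal approximation otherwise.
#'
#' @param values_a,values_b Numeric group samples (each n >= 3).
#' @return One-row tibble: `u` (the U statistic of group A), `p_value`,
#'   `stars`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 3 || length(b) < 3) {
    abort("Each group needs at least 3 observations.")
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided",
                                     correct = TRUE))
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = p,
    stars = stars,
    n_a = length(a),
    n_b = length(b)
  )
}
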