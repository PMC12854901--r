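#' Construct a volumetric fluorescence image
#'
#' A `volumetric_image` wraps a 3D grid of nonnegative intensities together
#' with the physical voxel dimensions and a channel label. Internally the
#' array is stored with dimensions `(y, x, z)` so that each `[, , k]` slice is
#' one confocal plane; constructors and metadata use the acquisition order
#' `(z, y, x)` common in stack sidecars.
#'
#' @param data Numeric 3D array. Either `(y, x, z)` (default) or `(z, y, x)`
#'   when `order = "zyx"`.
#' @param voxel_size Numeric length-3, micrometres per voxel in `(z, y, x)`
#'   order.
#' @param channel Channel label, e.g. `"mClover3"`.
#' @param order Dimension order of `data`.
#' @return An object of class `volumetric_image`.
#' @export
volumetric_image <- function(data, voxel_size, channel = "ch1",
                             order = c("yxz", "zyx")) {
  order <- match.arg(order)
  if (length(dim(data)) != 3L) {
    abort("`data` must be a 3D array.")
  }
  if (order == "zyx") {
    data <- aperm(data, c(2L, 3L, 1L))
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be three positive values (z, y, x) in µm.")
  }
  structure(
    list(
      data = data,
      voxel_size = setNames(voxel_size, c("z", "y", "x")),
      channel = as.character(channel)
    ),
    class = "volumetric_image"
  )
}

#' @export
print.volumetric_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volumetric_image> %s: %d x %d x %d voxels (y, x, z), voxel %.3g x %.3g x %.3g um (z, y, x)\n",
    x$channel, d[1], d[2], d[3],
    x$voxel_size["z"], x$voxel_size["y"], x$voxel_size["x"]
  ))
  cat(sprintf(
    "  intensity range [%.4g, %.4g], mean %.4g\n",
    min(x$data), max(x$data), mean(x$data)
  ))
  invisible(x)
}

#' @export
as.array.volumetric_image <- function(x, ...) x$data

#' Physical volume of one voxel in cubic micrometres
#' @param img A `volumetric_image` or a voxel-size vector.
#' @return Scalar volume in \eqn{\mu m^3}.
#' @export
voxel_volume <- function(img) {
  vs <- if (inherits(img, "volumetric_image")) img$voxel_size else as.numeric(img)
  prod(vs)
}

is_volumetric_image <- function(x) inherits(x, "volumetric_image")

assert_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    abort("Channel grids have different dimensions.")
  }
  invisible(TRUE)
}

#' Write a stack as multi-page TIFF plus a JSON sidecar
#'
#' One TIFF page per z-slice. Intensities are quantised to `bits` grey levels
#' spanning `[0, max(intensity)]`; the quantisation scale is recorded in the
#' sidecar (`<path>.json`) along with the voxel size in `(z, y, x)` order and
#' the channel label, so [read_volumetric_tiff()] restores physical units.
#'
#' @param img A `volumetric_image`.
#' @param path Output TIFF path.
#' @param bits Grey-level resolution at export, 8 or 12 (stored in 8- or
#'   16-bit containers respectively).
#' @return `path`, invisibly.
#' @export
write_volumetric_tiff <- function(img, path, bits = c(12, 8)) {
  bits <- match.arg(as.character(bits[1]), c("12", "8"))
  bits <- as.integer(bits)
  n_levels <- 2^bits - 1L
  mx <- max(img$data)
  scale <- if (mx > 0) mx / n_levels else 1
  q <- round(img$data / scale)
  container <- if (bits == 8L) 8L else 16L
  pages <- lapply(seq_len(dim(q)[3]), function(z) q[, , z] / n_levels)
  tiff::writeTIFF(pages, path, bits.per.sample = container)
  sidecar <- list(
    voxel_size_um = as.numeric(img$voxel_size),
    channel = img$channel,
    bits = bits,
    intensity_scale = scale
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a stack written by [write_volumetric_tiff()]
#'
#' @param path TIFF path; the sidecar is expected at `<path>.json`. A plain
#'   TIFF without sidecar is accepted if `voxel_size` is supplied.
#' @param voxel_size Optional `(z, y, x)` voxel size override in micrometres.
#' @return A `volumetric_image`.
#' @export
read_volumetric_tiff <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("TIFF not found: %s", path))
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) {
      abort(sprintf("Failed to read TIFF '%s': %s", path, conditionMessage(e)))
    }
  )
  if (!is.list(pages)) pages <- list(pages)
  sidecar_path <- paste0(path, ".json")
  channel <- "ch1"
  quantised <- FALSE
  scale <- 1
  n_levels <- 1
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- sc$voxel_size_um
    if (!is.null(sc$channel)) channel <- sc$channel
    if (!is.null(sc$intensity_scale)) {
      quantised <- TRUE
      scale <- sc$intensity_scale
      n_levels <- 2^(sc$bits %||% 12) - 1
    }
  } else if (is.null(voxel_size)) {
    abort(sprintf("No sidecar at '%s'; supply `voxel_size`.", sidecar_path))
  }
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1] # drop extra samples
    arr[, , z] <- if (quantised) round(pg * n_levels) * scale else pg
  }
  volumetric_image(arr, voxel_size = voxel_size, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
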