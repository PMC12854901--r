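#' Pipeline configuration
#'
#' Collects every tunable of the image-analysis pipeline with its default.
#' Configurations serialise losslessly to YAML/JSON via [write_run_config()]
#' and [read_run_config()].
#'
#' @param median_kernel Median filter size `(y, x, z)`.
#' @param n_bins Histogram bins.
#' @param histogram_weighting `"intensity"` or `"count"`.
#' @param k_candidates Component counts to try, subset of `c(2, 3, 4)`.
#' @param n_starts Multi-start count for each fit.
#' @param parsimony_tol Model-selection tie margin, see [select_model()].
#' @param min_size Minimum condensate size in voxels.
#' @param p_threshold,r_null Verdict-rule thresholds, see
#'   [correlate_metrics()].
#' @param profile_bins Bins for [binned_profile()].
#' @param voxel_size Optional `(z, y, x)` voxel-size override for inputs
#'   lacking a sidecar.
#' @param keep_masks Keep segmentation masks in per-image reports.
#' @param rng_seed Seed for any stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(median_kernel = c(5, 5, 3),
                       n_bins = 64,
                       histogram_weighting = "intensity",
                       k_candidates = c(2, 3, 4),
                       n_starts = 4,
                       parsimony_tol = 0.004,
                       min_size = 4,
                       p_threshold = 0.05,
                       r_null = 0.2,
                       profile_bins = 4,
                       voxel_size = NULL,
                       keep_masks = FALSE,
                       rng_seed = 1L) {
  structure(
    list(
      median_kernel = as.integer(median_kernel),
      n_bins = as.integer(n_bins),
      histogram_weighting = histogram_weighting,
      k_candidates = as.integer(k_candidates),
      n_starts = as.integer(n_starts),
      parsimony_tol = parsimony_tol,
      min_size = as.integer(min_size),
      p_threshold = p_threshold,
      r_null = r_null,
      profile_bins = as.integer(profile_bins),
      voxel_size = if (is.null(voxel_size)) NULL else as.numeric(voxel_size),
      keep_masks = isTRUE(keep_masks),
      rng_seed = as.integer(rng_seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lst, path, auto_unbox = FALSE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, lst[!vapply(lst, is.null, logical(1))])
}

#' Characterise a single image
#'
#' The per-image workflow: median filter, mode background subtraction,
#' intensity-weighted histogram, 2/3/4-component Gaussian-sum fits with
#' adjusted-R-squared model selection, mean + 3 SD segmentation, condensate
#' labelling and phase metrics.
#'
#' @param input A [volumetric_image()] or a TIFF path readable by
#'   [read_volumetric_tiff()].
#' @param config A [run_config()].
#' @return An object of class `image_report`: `metrics` (one-row tibble with
#'   `k_selected`, `adj_r_square`, `mode_value` and candidate adjusted
#'   R-squareds appended), `objects`, `fit`, `candidates` (a [glance()]
#'   tibble per candidate k), and masks when `keep_masks`.
#' @export
run_image <- function(input, config = run_config()) {
  img <- if (is_volumetric_image(input)) {
    input
  } else {
    read_volumetric_tiff(input, voxel_size = config$voxel_size)
  }
  filtered <- median_filter_3d(img, kernel = config$median_kernel)
  bg <- subtract_mode_background(filtered)
  hist <- weighted_intensity_histogram(
    bg$image,
    n_bins = config$n_bins, weighting = config$histogram_weighting
  )
  models <- fit_histogram_models(
    hist,
    k_candidates = config$k_candidates,
    parsimony_tol = config$parsimony_tol,
    n_starts = config$n_starts
  )
  fit <- models$selected
  seg <- segment_compartments(bg$image, fit)
  if (seg$empty || !any(seg$nucleus_mask)) {
    abort("Image has no voxels above the nucleus threshold.")
  }
  objects <- label_condensates(seg, img = bg$image, min_size = config$min_size)
  metrics <- compute_phase_metrics(bg$image, seg, objects)
  candidates <- tibble::tibble(
    k = vapply(models$fits, function(f) f$k, integer(1)),
    adjusted_r_square = vapply(models$fits, function(f) f$adjusted_r_square, numeric(1)),
    rss = vapply(models$fits, function(f) f$rss, numeric(1)),
    converged = vapply(models$fits, function(f) f$converged, logical(1))
  )
  metrics$k_selected <- fit$k
  metrics$adj_r_square <- fit$adjusted_r_square
  metrics$mode_value <- bg$mode_value
  metrics$nucleus_threshold <- seg$nucleus_threshold
  metrics$condensate_threshold <- seg$condensate_threshold
  structure(
    list(
      metrics = metrics,
      objects = objects,
      fit = fit,
      candidates = candidates,
      segmentation = if (config$keep_masks) seg else NULL,
      image = if (config$keep_masks) bg$image else NULL
    ),
    class = "image_report"
  )
}

#' @export
print.image_report <- function(x, ...) {
  cat("<image_report>\n")
  print(x$metrics)
  invisible(x)
}

#' Analyse a concentration-dependence image series
#'
#' Runs [run_image()] on every input, collecting per-image phase metrics
#' into a series table, then performs the cross-image correlation analysis
#' and binned mean/SEM profiles. Individual image failures are logged and
#' tolerated as long as at least three images succeed.
#'
#' @param inputs A list of [volumetric_image()]s, a character vector of TIFF
#'   paths, a directory containing TIFFs, or a [generate_series()] tibble.
#' @param config A [run_config()].
#' @return An object of class `series_report`: `table` (one metrics row per
#'   analysed image), `verdict` (a [correlate_metrics()] result), `profiles`
#'   (named list of [binned_profile()] tibbles), `failures`.
#' @export
run_series <- function(inputs, config = run_config()) {
  if (is.data.frame(inputs) && "image" %in% names(inputs)) {
    ids <- inputs$image_id %||% sprintf("img%03d", seq_len(nrow(inputs)))
    inputs <- setNames(inputs$image, ids)
  } else if (is.character(inputs) && length(inputs) == 1 && dir.exists(inputs)) {
    paths <- sort(list.files(inputs, pattern = "\\.tiff?$", full.names = TRUE))
    inputs <- setNames(as.list(paths), basename(paths))
  } else if (is.character(inputs)) {
    inputs <- setNames(as.list(inputs), basename(inputs))
  } else if (is.null(names(inputs))) {
    names(inputs) <- sprintf("img%03d", seq_along(inputs))
  }
  results <- purrr::imap(inputs, function(inp, id) {
    tryCatch(
      list(ok = TRUE, id = id, report = run_image(inp, config)),
      error = function(e) list(ok = FALSE, id = id, message = conditionMessage(e))
    )
  })
  ok <- purrr::keep(results, "ok")
  failures <- purrr::map_dfr(
    purrr::discard(results, "ok"),
    ~ tibble::tibble(image_id = .x$id, message = .x$message)
  )
  if (length(ok) < 3) {
    abort(sprintf(
      "Only %d of %d images analysable; at least 3 required.",
      length(ok), length(results)
    ))
  }
  table <- purrr::map_dfr(ok, function(r) {
    dplyr::bind_cols(tibble::tibble(image_id = r$id), r$report$metrics)
  })
  verdict <- correlate_metrics(
    table,
    p_threshold = config$p_threshold, r_null = config$r_null
  )
  metrics <- c("volume_fraction", "mean_condensate_volume", "c_den", "c_dil")
  profiles <- lapply(
    setNames(metrics, metrics),
    function(m) binned_profile(table, m, n_bins = config$profile_bins)
  )
  structure(
    list(
      table = table, verdict = verdict, profiles = profiles,
      failures = failures, reports = ok
    ),
    class = "series_report"
  )
}

#' @export
print.series_report <- function(x, ...) {
  cat(sprintf(
    "<series_report> %d images analysed, %d failed\n",
    nrow(x$table), nrow(x$failures)
  ))
  print(x$verdict)
  invisible(x)
}

#' Write the tabular outputs of a series analysis
#'
#' Emits `metrics.csv` (one row per image), `objects.csv` (all condensates),
#' `verdict.json` and one `profile_<metric>.csv` per profiled metric.
#'
#' @param report A [run_series()] result.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_series_report <- function(report, out_dir) {
  stopifnot(inherits(report, "series_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$table, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  objects <- purrr::map_dfr(report$reports, function(r) {
    dplyr::bind_cols(tibble::tibble(image_id = r$id), r$report$objects)
  })
  utils::write.csv(objects, file.path(out_dir, "objects.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(
      list(verdict = report$verdict$verdict,
           criteria_trace = report$verdict$criteria_trace),
      split(
        report$verdict$correlations[c("n", "r", "p")],
        report$verdict$correlations$metric
      )
    ),
    file.path(out_dir, "verdict.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  for (m in names(report$profiles)) {
    utils::write.csv(report$profiles[[m]],
                     file.path(out_dir, sprintf("profile_%s.csv", m)),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
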