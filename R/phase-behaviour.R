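#' Correlate per-image metrics with total concentration
#'
#' The concentration-dependence test for liquid-liquid phase separation:
#' across a series of images spanning a range of total scaffold
#' concentrations, Pearson correlations of condensate volume fraction, mean
#' condensate volume, dense-phase and dilute-phase concentration against
#' `c_tot` are computed with two-sided p-values. The verdict rule
#' operationalises the thermodynamic argument:
#' * `multicomponent-like` - both `c_dil` and `c_den` rise significantly
#'   with `c_tot` (`r > 0`, `p < p_threshold`): the phase concentrations are
#'   not pinned at a saturation value.
#' * `binary-like` - `c_dil` and `c_den` are flat (`|r| < r_null`,
#'   `p >= p_threshold`) while the volume fraction still grows significantly
#'   with `c_tot`, as expected when only the amount of dense phase responds
#'   to expression level.
#' * `indeterminate` - anything else.
#'
#' @param table A tibble with one row per image carrying columns `c_tot`,
#'   `volume_fraction`, `mean_condensate_volume`, `c_den`, `c_dil` (e.g. the
#'   output of [run_series()] or row-bound [compute_phase_metrics()]).
#' @param p_threshold Significance level for the verdict rule.
#' @param r_null Magnitude below which a correlation counts as "flat".
#' @return An object of class `behaviour_verdict` with `correlations` (a
#'   tibble of `metric`, `n`, `r`, `p`), `verdict` and a human-readable
#'   `criteria_trace`.
#' @export
correlate_metrics <- function(table, p_threshold = 0.05, r_null = 0.2) {
  metrics <- c("volume_fraction", "mean_condensate_volume", "c_den", "c_dil")
  missing_cols <- setdiff(c("c_tot", metrics), names(table))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  rows <- purrr::map(metrics, function(m) {
    ok <- stats::complete.cases(table$c_tot, table[[m]])
    x <- table$c_tot[ok]
    y <- table[[m]][ok]
    if (length(x) < 3) {
      abort(sprintf("Metric '%s' has %d valid pairs; need at least 3.", m, length(x)))
    }
    if (sd(x) == 0 || sd(y) == 0) {
      abort(sprintf("Metric '%s' (or c_tot) has zero variance; correlation undefined.", m))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(metric = m, n = length(x), r = unname(ct$estimate), p = ct$p.value)
  })
  cors <- dplyr::bind_rows(rows)
  r_of <- function(m) cors$r[cors$metric == m]
  p_of <- function(m) cors$p[cors$metric == m]
  rising <- function(m) r_of(m) > 0 && p_of(m) < p_threshold
  flat <- function(m) abs(r_of(m)) < r_null && p_of(m) >= p_threshold
  verdict <- if (rising("c_dil") && rising("c_den")) {
    "multicomponent-like"
  } else if (flat("c_dil") && flat("c_den") && rising("volume_fraction")) {
    "binary-like"
  } else {
    "indeterminate"
  }
  trace <- sprintf(
    paste0(
      "r(c_dil)=%.3f (p=%.3g), r(c_den)=%.3f (p=%.3g), ",
      "r(volume_fraction)=%.3f (p=%.3g); rule: multicomponent-like if both ",
      "phase concentrations rise (r>0, p<%.3g); binary-like if both are flat ",
      "(|r|<%.2f, p>=%.3g) while volume fraction rises."
    ),
    r_of("c_dil"), p_of("c_dil"), r_of("c_den"), p_of("c_den"),
    r_of("volume_fraction"), p_of("volume_fraction"),
    p_threshold, r_null, p_threshold
  )
  structure(
    list(
      correlations = cors, verdict = verdict, criteria_trace = trace,
      p_threshold = p_threshold, r_null = r_null
    ),
    class = "behaviour_verdict"
  )
}

#' @export
print.behaviour_verdict <- function(x, ...) {
  cat(sprintf("<behaviour_verdict> %s\n", x$verdict))
  print(x$correlations)
  invisible(x)
}

#' @method tidy behaviour_verdict
#' @export
tidy.behaviour_verdict <- function(x, ...) x$correlations

#' @method glance behaviour_verdict
#' @export
glance.behaviour_verdict <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$correlations,
    names_from = "metric", values_from = c("r", "p"), id_cols = NULL,
    names_glue = "{.value}_{metric}"
  )
  dplyr::bind_cols(tibble::tibble(verdict = x$verdict), wide)
}

#' Binned mean/SEM profile of a metric against total concentration
#'
#' Images are grouped into equal-width bins of `c_tot`; per bin the mean and
#' standard error of the metric are reported, the standard summary used to
#' draw concentration-dependence profiles with an SEM ribbon. A bin holding
#' a single image gets `sem = 0` and `single_point = TRUE` so profiles stay
#' plottable while the degenerate error estimate remains visible.
#'
#' @param table As in [correlate_metrics()].
#' @param metric Column name to profile.
#' @param n_bins Number of equal-width `c_tot` bins (>= 2).
#' @return Tibble with `bin`, `bin_center`, `n`, `mean`, `sem`,
#'   `single_point`; empty bins are absent.
#' @export
binned_profile <- function(table, metric, n_bins = 4) {
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  if (!metric %in% names(table)) abort(sprintf("No column '%s'.", metric))
  ok <- stats::complete.cases(table$c_tot, table[[metric]])
  x <- table$c_tot[ok]
  y <- table[[metric]][ok]
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  if (length(unique(bin)) == 1L) {
    warn("All images fall into a single c_tot bin; profile is degenerate.")
  }
  out <- tibble::tibble(bin = bin, y = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$y),
      sem = ifelse(dplyr::n() > 1, sd(.data$y) / sqrt(dplyr::n()), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_center = (edges[.data$bin] + edges[.data$bin + 1]) / 2,
      single_point = .data$n == 1L,
      .after = "bin"
    )
  out
}
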