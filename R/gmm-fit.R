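#' Fit a k-component sum of Gaussians to a weighted histogram
#'
#' Least-squares fit of
#' \deqn{f(x) = \sum_{i=1}^{k} A_i \exp\left(-\frac{(x-\mu_i)^2}{2\sigma_i^2}\right)}
#' to the normalised histogram weights, by Levenberg-Marquardt with analytic
#' gradients and box constraints. This is a curve fit to the intensity
#' distribution (the quantity the adjusted R-squared model selection is
#' defined on), not an EM mixture fit over voxels.
#'
#' Bounds are constrained so that components remain identifiable intensity
#' populations: means within the observed range, standard deviations in
#' `[bin_width/2, range/6]`, amplitudes in `[0, 1.5 * max(weight)]`, and
#' adjacent component means at least `min_separation` apart (means are
#' fitted as a base plus positive increments). Because the objective is
#' multimodal the fit is restarted from `n_starts` deterministic initial
#' placements (weighted quantiles, an even spread, and a low-anchored
#' variant, each at a narrow and a wide starting width); the best residual
#' sum of squares wins. The same histogram always yields the same fit.
#'
#' @param hist A [weighted_intensity_histogram()].
#' @param k Number of components (2, 3 or 4).
#' @param bounds Optional list with elements `amplitude`, `mean`, `sd`, each
#'   a `(lo, hi)` pair overriding the defaults.
#' @param n_starts Number of multi-start initialisations.
#' @param min_separation Minimum distance between adjacent component means
#'   (a.u.); defaults to 4 bin widths. Keeps components identifiable as
#'   distinct intensity populations.
#' @param extra_starts Optional list of additional flat start vectors
#'   `c(amplitudes, means, sds)`, e.g. forward-initialisations from a
#'   smaller model.
#' @return An object of class `gmm_fit`: components sorted by ascending mean,
#'   `rss`, `tss`, `adjusted_r_square`, `converged`, and the histogram used.
#' @export
fit_gaussian_sum <- function(hist, k, bounds = NULL, n_starts = 4,
                             min_separation = NULL, extra_starts = NULL) {
  stopifnot(inherits(hist, "weighted_histogram"))
  k <- as.integer(k)
  if (!k %in% 2:4) abort("`k` must be 2, 3 or 4.")
  x <- hist$data$bin_center
  y <- hist$data$weight
  n_occ <- sum(y > 0)
  if (3L * k > n_occ) {
    abort(sprintf("Histogram has %d occupied bins; too few for k = %d.", n_occ, k))
  }
  rng <- range(x)
  span <- diff(rng)
  def_bounds <- list(
    amplitude = c(0, 1.5 * max(y)),
    mean = rng,
    # sd floor of half a bin width lets a component match a population
    # narrower than the binning; the minimum-separation constraint (below)
    # is what prevents component collapse, and the ceiling well below the
    # span stops a near-flat "blanket" component
    sd = c(hist$bin_width / 2, span / 6)
  )
  if (!is.null(bounds)) def_bounds <- modifyList(def_bounds, bounds)
  b <- def_bounds
  if (any(vapply(b, function(v) v[1] >= v[2], logical(1)))) {
    abort("Fit bounds must satisfy lo < hi for every parameter.")
  }
  if (is.null(min_separation)) min_separation <- 4 * hist$bin_width
  # means are fitted as a base plus positive increments, so components stay
  # ordered and at least `min_separation` apart: two components can never
  # collapse onto (or split) a single population
  lower <- c(rep(b$amplitude[1], k), b$mean[1],
             rep(min_separation, k - 1), rep(b$sd[1], k))
  upper <- c(rep(b$amplitude[2], k), b$mean[2],
             rep(span, k - 1), rep(b$sd[2], k))

  starts <- gmm_starts(x, y, k, b, n_starts, min_separation)
  if (!is.null(extra_starts)) {
    starts <- c(
      starts,
      lapply(extra_starts, flat_to_inc, k = k, min_separation = min_separation)
    )
  }
  best <- NULL
  best_rss <- Inf
  best_converged <- FALSE
  for (par0 in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = par0,
        lower = lower, upper = upper,
        fn = gmm_residuals_inc, jac = gmm_jacobian_inc,
        x = x, y = y, k = k,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-7, ptol = 1e-7)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    conv <- fit$info %in% 1:4
    rss <- fit$deviance
    better <- (conv && !best_converged) ||
      (conv == best_converged && rss < best_rss)
    if (is.null(best) || better) {
      best <- fit
      best_rss <- rss
      best_converged <- conv
    }
  }
  if (is.null(best)) {
    return(new_gmm_fit(NULL, k, hist, converged = FALSE))
  }
  new_gmm_fit(inc_to_flat(best$par, k), k, hist, converged = best_converged)
}

# increment parameterisation <-> flat (A, mu, sd) parameter vector
inc_to_flat <- function(par, k) {
  mu <- cumsum(par[k + seq_len(k)])
  c(par[seq_len(k)], mu, par[2 * k + seq_len(k)])
}

flat_to_inc <- function(par, k, min_separation) {
  ord <- order(par[k + seq_len(k)])
  mu <- par[k + seq_len(k)][ord]
  d <- pmax(diff(mu), min_separation)
  c(par[seq_len(k)][ord], mu[1], d, par[2 * k + seq_len(k)][ord])
}

gmm_residuals_inc <- function(par, x, y, k) {
  cpp_gmm_residuals_inc(par, x, y, k)
}

gmm_jacobian_inc <- function(par, x, y, k) {
  cpp_gmm_jacobian_inc(par, x, y, k)
}

gmm_model <- function(par, x, k) {
  a <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  s <- par[2 * k + seq_len(k)]
  f <- numeric(length(x))
  for (i in seq_len(k)) {
    f <- f + a[i] * exp(-(x - mu[i])^2 / (2 * s[i]^2))
  }
  f
}

gmm_residuals <- function(par, x, y, k) gmm_model(par, x, k) - y

gmm_jacobian <- function(par, x, y, k) {
  a <- par[seq_len(k)]
  mu <- par[k + seq_len(k)]
  s <- par[2 * k + seq_len(k)]
  J <- matrix(0, nrow = length(x), ncol = 3 * k)
  for (i in seq_len(k)) {
    d <- x - mu[i]
    e <- exp(-d^2 / (2 * s[i]^2))
    J[, i] <- e
    J[, k + i] <- a[i] * e * d / s[i]^2
    J[, 2 * k + i] <- a[i] * e * d^2 / s[i]^3
  }
  J
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[ord][which(cw >= p)[1]], numeric(1))
}

gmm_starts <- function(x, y, k, b, n_starts, min_separation) {
  rng <- range(x)
  span <- diff(rng)
  # narrow starts lock onto sharp populations, wide ones onto broad humps
  sd_narrow <- b$sd[1]
  sd_wide <- max(span / (6 * k), b$sd[1])
  amp_at <- function(mu) {
    pmax(y[pmin(pmax(findInterval(mu, x), 1), length(x))], 0.05 * max(y))
  }
  mk <- function(mu, sd0) {
    mu <- pmin(pmax(mu, b$mean[1]), b$mean[2])
    c(amp_at(mu), mu, rep(sd0, k))
  }
  mu_q <- weighted_quantile(x, y, (seq_len(k) - 0.5) / k)
  mu_e <- rng[1] + span * (seq_len(k) - 0.5) / k
  # low-anchored: one component at the histogram origin (the residual
  # background after mode subtraction), the rest on the weighted quantiles
  mu_a <- c(rng[1] + b$sd[1], weighted_quantile(x, y, (seq_len(k - 1) - 0.5) / (k - 1)))
  bases <- list(mu_a, mu_q, mu_e)
  # ordered so that truncation keeps the anchored/quantile pairs first
  grid <- list(
    list(mu_a, sd_narrow), list(mu_q, sd_narrow),
    list(mu_a, sd_wide), list(mu_q, sd_wide),
    list(mu_e, sd_narrow), list(mu_e, sd_wide)
  )
  starts <- lapply(grid, function(g) mk(g[[1]], g[[2]]))
  n_extra <- max(0L, n_starts - length(starts))
  if (n_extra > 0) {
    jit <- withr::with_seed(
      1903L, # fixed: restarts are part of the deterministic fit procedure
      matrix(rnorm(n_extra * k, 0, span / 10), nrow = n_extra)
    )
    for (j in seq_len(n_extra)) {
      starts <- c(starts, list(mk(bases[[(j - 1L) %% 3L + 1L]] + jit[j, ], sd_narrow)))
    }
  }
  starts <- starts[seq_len(min(length(starts), n_starts))]
  lapply(starts, flat_to_inc, k = k, min_separation = min_separation)
}

new_gmm_fit <- function(par, k, hist, converged) {
  y <- hist$data$weight
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (is.null(par)) {
    comps <- tibble::tibble(
      weight = rep(NA_real_, k), mean = NA_real_, sd = NA_real_
    )
    rss <- NA_real_
    adj <- -Inf
  } else {
    ord <- order(par[k + seq_len(k)])
    comps <- tibble::tibble(
      weight = par[seq_len(k)][ord],
      mean = par[k + seq_len(k)][ord],
      sd = par[2 * k + seq_len(k)][ord]
    )
    rss <- sum(gmm_residuals(par, hist$data$bin_center, y, k)^2)
    adj <- adjusted_r_square(rss, tss, n, 3L * k)
  }
  structure(
    list(
      components = comps, k = k, rss = rss, tss = tss,
      n_bins = n, adjusted_r_square = adj, converged = converged,
      hist = hist
    ),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf(
    "<gmm_fit> k = %d, adjusted R^2 = %.5f, %s\n",
    x$k, x$adjusted_r_square,
    if (x$converged) "converged" else "NOT converged"
  ))
  print(x$components)
  invisible(x)
}

#' Predicted histogram curve of a fitted Gaussian sum
#' @param object A `gmm_fit`.
#' @param newdata Optional intensity values; defaults to the fitted bins.
#' @param ... Unused.
#' @method predict gmm_fit
#' @export
predict.gmm_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$hist$data$bin_center
  par <- with(object$components, c(weight, mean, sd))
  gmm_model(par, x, object$k)
}

#' @method tidy gmm_fit
#' @export
tidy.gmm_fit <- function(x, ...) {
  dplyr::mutate(x$components,
    component = dplyr::row_number(), k = x$k, .before = 1
  )
}

#' @method glance gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, adjusted_r_square = x$adjusted_r_square,
    rss = x$rss, tss = x$tss, n_bins = x$n_bins, converged = x$converged
  )
}

#' Adjusted coefficient of determination
#'
#' \deqn{\bar R^2 = 1 - \frac{RSS/(n-p-1)}{TSS/(n-1)}}
#' used to compare Gaussian-sum fits with different numbers of components
#' (`p = 3k` free parameters).
#'
#' @param rss Residual sum of squares.
#' @param tss Total sum of squares (> 0).
#' @param n_bins Number of fitted points `n`.
#' @param n_params Number of free parameters `p`.
#' @return The adjusted R-squared (<= 1).
#' @export
adjusted_r_square <- function(rss, tss, n_bins, n_params) {
  if (!is.finite(tss) || tss <= 0) {
    abort("`tss` must be positive; the histogram is degenerate.")
  }
  if (n_bins <= n_params + 1) {
    abort("`n_bins` must exceed `n_params` + 1.")
  }
  1 - (rss / (n_bins - n_params - 1)) / (tss / (n_bins - 1))
}

#' Select the best Gaussian-sum fit by adjusted R-squared
#'
#' Non-converged fits are skipped; among converged fits the highest adjusted
#' R-squared wins, with ties broken toward the smaller, more parsimonious
#' model. A tie is any difference within `parsimony_tol`: adjusted-R-squared
#' differences at that scale are within the fit statistic's replicate-to-
#' replicate variability on images of the same scene, so a larger model is
#' only accepted when it improves the fit by more than that noise floor
#' (the usual one-standard-error selection logic). Set `parsimony_tol = 0`
#' for the strict arg-max rule.
#'
#' @param fits List of [fit_gaussian_sum()] results.
#' @param parsimony_tol Adjusted-R-squared margin treated as a tie.
#' @return The selected `gmm_fit`.
#' @export
select_model <- function(fits, parsimony_tol = 0.004) {
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0) {
    abort("No converged Gaussian-sum fit; cannot segment this image.")
  }
  ks <- vapply(fits, function(f) f$k, integer(1))
  fits <- fits[order(ks)]
  adj <- vapply(fits, function(f) f$adjusted_r_square, numeric(1))
  fits[[which(adj >= max(adj) - parsimony_tol)[1]]]
}

#' Fit candidate component counts and select one
#'
#' @param hist A [weighted_intensity_histogram()].
#' @param k_candidates Subset of `c(2, 3, 4)`.
#' @param parsimony_tol Tie margin for [select_model()].
#' @param ... Passed to [fit_gaussian_sum()].
#' @return List with `fits` (one per candidate `k`) and `selected`.
#' @export
fit_histogram_models <- function(hist, k_candidates = c(2, 3, 4),
                                 parsimony_tol = 0.004, ...) {
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (!all(k_candidates %in% 2:4)) abort("`k_candidates` must be within {2, 3, 4}.")
  fits <- list()
  prev <- NULL
  for (k in k_candidates) {
    extra <- NULL
    if (!is.null(prev) && isTRUE(prev$converged) && prev$k == k - 1L) {
      extra <- forward_starts(prev, hist)
    }
    fit <- fit_gaussian_sum(hist, k, extra_starts = extra, ...)
    fits[[paste0("k", k)]] <- fit
    prev <- fit
  }
  list(fits = fits, selected = select_model(fits, parsimony_tol))
}

# Forward initialisation: the (k-1)-component solution plus one component
# placed on its largest positive residual, so a well-fitted sub-model is
# never lost when a component is added. Two placements are proposed: the
# largest residual anywhere, and the largest residual away from the existing
# components (a population the sub-model missed entirely, e.g. the residual
# background bump).
forward_starts <- function(prev, hist) {
  x <- hist$data$bin_center
  y <- hist$data$weight
  res <- y - predict(prev)
  comps <- prev$components
  mk <- function(i) {
    c(
      comps$weight, max(res[i], 0.02 * max(y)),
      comps$mean, x[i],
      comps$sd, 2 * hist$bin_width
    )
  }
  sep <- 4 * hist$bin_width
  far <- res
  for (j in seq_len(nrow(comps))) {
    far[abs(x - comps$mean[j]) < max(sep, 2 * comps$sd[j])] <- -Inf
  }
  out <- list(mk(which.max(res)))
  if (any(is.finite(far)) && max(far) > 0) {
    out <- c(out, list(mk(which.max(far))))
  }
  out
}
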