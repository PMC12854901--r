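# Small, fast scene configurations used across the test files.

# clean scene: no noise, no optics, no heterogeneity; useful wherever an
# exact geometric or mass-balance oracle is asserted. Explicit arguments
# override the clean defaults.
clean_defaults <- list(
  noise_model = "none", noise_sd = 0, psf_sigma = 0,
  texture_cv = 0, background_sd = 0
)

clean_scene_params <- function(...) {
  do.call(scene_params, utils::modifyList(clean_defaults, list(...)))
}

tiny_grid <- list(
  grid_shape = c(10, 32, 32),
  voxel_size = c(0.2, 0.12, 0.12),
  nucleus_axes = c(0.9, 1.7, 1.7),
  condensate_radius_mean = 0.45,
  condensate_radius_sd = 0.05,
  n_condensates = 2
)

tiny_scene_params <- function(...) {
  do.call(scene_params,
          utils::modifyList(utils::modifyList(clean_defaults, tiny_grid),
                            list(...)))
}

# independent pure-R flood-fill labelling oracle (stack-based DFS), used to
# cross-check the compiled connected-component labelling
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  nbrs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  nbrs <- nbrs[!(nbrs$dy == 0 & nbrs$dx == 0 & nbrs$dz == 0), ]
  if (connectivity == 6) {
    nbrs <- nbrs[abs(nbrs$dy) + abs(nbrs$dx) + abs(nbrs$dz) == 1, ]
  }
  nxt <- 0L
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    if (!mask[y, x, z] || lab[y, x, z] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(y, x, z))
    lab[y, x, z] <- nxt
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(nbrs))) {
        yy <- v[1] + nbrs$dy[i]; xx <- v[2] + nbrs$dx[i]; zz <- v[3] + nbrs$dz[i]
        if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3]) next
        if (mask[yy, xx, zz] && lab[yy, xx, zz] == 0L) {
          lab[yy, xx, zz] <- nxt
          stack[[length(stack) + 1L]] <- c(yy, xx, zz)
        }
      }
    }
  }
  lab
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
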