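# shared fixtures and independent oracles, built in code at test time

# isotropic template with voxel centers symmetric about the origin
grid_template <- function(dims = c(11, 11, 11), spacing = 3) {
  origin <- -(dims - 1) * spacing / 2
  aff <- rbind(cbind(diag(3) * spacing, origin), c(0, 0, 0, 1))
  vol3d(array(0, dims), aff)
}

all_ones_mask <- function(template) {
  brain_mask(array(1, dim(template$data)), template$affine)
}

# independent sphere oracle: exhaustive distance check over every voxel
# center of the full grid (no bounding-box shortcut), plus the voxel
# containing each coordinate
sphere_oracle <- function(coords_mm, radius_mm, template) {
  if (is.null(dim(coords_mm))) coords_mm <- matrix(coords_mm, ncol = 3)
  d <- dim(template$data)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  centers <- t(template$affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
  out <- array(0, d)
  for (r in seq_len(nrow(coords_mm))) {
    hit <- sqrt(rowSums(sweep(centers, 2, coords_mm[r, ])^2)) <=
      radius_mm + 1e-9
    out[idx[hit, , drop = FALSE] + 1] <- 1
    home <- round(drop(solve(template$affine, c(coords_mm[r, ], 1))[1:3]))
    if (all(home >= 0) && all(home <= d - 1))
      out[matrix(home + 1, ncol = 3)] <- 1
  }
  out
}

# independent Benjamini-Hochberg step-up oracle: largest k with
# p_(k) <= k q / m is found by direct enumeration; rejects p <= p_(k)
bh_reject_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  if (!is.finite(k)) return(rep(FALSE, m))
  p <= ps[k]
}

# toy 4D volume from a T x V matrix laid out on a small grid
toy_vol4d <- function(Y, dims, spacing = 3, tr = 2) {
  stopifnot(ncol(Y) == prod(dims))
  tmpl <- grid_template(dims, spacing)
  vol4d(array(t(Y), c(dims, nrow(Y))), tmpl$affine, tr_seconds = tr)
}

zero_motion <- function(tlen) motion_trace(matrix(0, tlen, 3),
                                           matrix(0, tlen, 3))

table1_path <- function() {
  system.file("extdata", "extraversion_studies.csv", package = "fcnmapper")
}

# small-but-real synthetic cohort for pipeline-level tests
tiny_cohort_spec <- function(rng_seed = 42, n_subjects = 6, n_volumes = 60,
                             networks = list(planted_network(
                               component_centers = rbind(c(-9, -9, 0),
                                                         c(9, 9, 0)),
                               component_radius_mm = 7))) {
  cohort_spec(n_subjects = n_subjects, n_volumes = n_volumes,
              grid_shape = c(14, 16, 14), networks = networks,
              rng_seed = rng_seed)
}
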