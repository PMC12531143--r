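#' Specifications for synthetic data
#'
#' `planted_network()` describes one spatially coherent network: spherical
#' components whose voxels share a band-limited latent time series with
#' loading `loading_w` plus i.i.d. Gaussian noise of standard deviation
#' `noise_sd`. The expected correlation between two voxels of the same
#' network is `w^2 / (w^2 + sd^2)`.
#'
#' `cohort_spec()` describes a normative resting-state cohort on a common
#' grid. The defaults are the package's reference setting: a 20 x 24 x 20
#' grid at 3 mm, 20 subjects, 120 volumes at TR 2 s, and one planted network
#' of three 9-mm components with loading 1 against unit noise.
#'
#' `study_spec()` describes a synthetic literature: studies x contrasts x
#' foci, with a fraction of foci drawn from the planted network (with mm
#' jitter) and the rest uniform in gray matter. Defaults: 8 studies, one
#' contrast each, 2 foci per contrast, all in-network, 3 mm jitter.
#'
#' @param component_centers n x 3 matrix (or list of 3-vectors) of component
#'   centers, mm.
#' @param component_radius_mm component sphere radius, mm.
#' @param loading_w latent-signal loading, >= 0.
#' @param noise_sd voxel noise standard deviation, > 0.
#' @return spec lists used by the `simulate_*` generators.
#' @export
planted_network <- function(component_centers = rbind(c(-12, -18, 0),
                                                      c(15, 9, 6),
                                                      c(0, 18, -9)),
                            component_radius_mm = 9,
                            loading_w = 1, noise_sd = 1) {
  if (is.list(component_centers))
    component_centers <- do.call(rbind, component_centers)
  stopifnot(loading_w >= 0, noise_sd > 0, component_radius_mm > 0)
  list(component_centers = .as_coord_matrix(component_centers),
       component_radius_mm = component_radius_mm,
       loading_w = loading_w, noise_sd = noise_sd)
}

#' @rdname planted_network
#' @param n_subjects cohort size (>= 2).
#' @param n_volumes time points per scan (>= 30).
#' @param tr_seconds repetition time, s.
#' @param grid_shape 3-vector of grid dimensions.
#' @param spacing_mm isotropic voxel size, mm.
#' @param networks list of `planted_network()` specs (possibly empty for a
#'   null cohort).
#' @param gm_axis_fraction semi-axes of the ellipsoidal gray-matter envelope
#'   as a fraction of the half-extent of the grid.
#' @param latent_band latent-signal frequency band, Hz (kept inside the
#'   0.01–0.1 Hz analysis band so bandpass filtering preserves the signal).
#' @param global_amplitude amplitude of a brain-wide shared fluctuation added
#'   to every gray-matter voxel (0 = none). A nonzero value emulates the
#'   global physiological/scanner component that global signal regression
#'   exists to remove; with it at 0 the cohort's only shared variance is the
#'   planted network itself, so GSR would remove the planted signal — run
#'   such cohorts with `gsr = FALSE`.
#' @param motion_sd per-frame random-walk sd of the simulated motion, mm.
#' @param spike_prob probability that a subject's trace carries one injected
#'   motion spike.
#' @param rng_seed integer seed; generators are pure functions of spec + seed.
#' @export
cohort_spec <- function(n_subjects = 20, n_volumes = 120, tr_seconds = 2,
                        grid_shape = c(20, 24, 20), spacing_mm = 3,
                        networks = list(planted_network()),
                        gm_axis_fraction = 0.92,
                        latent_band = c(0.01, 0.08),
                        global_amplitude = 0,
                        motion_sd = 0.02, spike_prob = 0.2,
                        rng_seed = 1) {
  stopifnot(n_subjects >= 2, n_volumes >= 30, tr_seconds > 0,
            length(grid_shape) == 3, spacing_mm > 0, global_amplitude >= 0)
  list(n_subjects = as.integer(n_subjects), n_volumes = as.integer(n_volumes),
       tr_seconds = tr_seconds, grid_shape = as.integer(grid_shape),
       spacing_mm = spacing_mm, networks = networks,
       gm_axis_fraction = gm_axis_fraction, latent_band = latent_band,
       global_amplitude = global_amplitude,
       motion_sd = motion_sd, spike_prob = spike_prob,
       rng_seed = as.integer(rng_seed))
}

#' @rdname planted_network
#' @param n_studies,contrasts_per_study,foci_per_contrast synthetic
#'   literature dimensions (all >= 1).
#' @param in_network_fraction fraction of foci sampled from the planted
#'   network (the rest are uniform in gray matter), in \[0, 1\].
#' @param jitter_sd_mm isotropic Gaussian jitter of in-network foci, mm.
#' @param n_range,age_range ranges the per-study sample sizes and mean ages
#'   are drawn from (defaults span the included-literature ranges, 30–364
#'   participants and mean ages 20–72 years).
#' @export
study_spec <- function(n_studies = 8, contrasts_per_study = 1,
                       foci_per_contrast = 2, in_network_fraction = 1,
                       jitter_sd_mm = 3, n_range = c(30, 364),
                       age_range = c(20, 72), rng_seed = 1) {
  stopifnot(n_studies >= 1, contrasts_per_study >= 1, foci_per_contrast >= 1,
            in_network_fraction >= 0, in_network_fraction <= 1,
            jitter_sd_mm >= 0)
  list(n_studies = as.integer(n_studies),
       contrasts_per_study = as.integer(contrasts_per_study),
       foci_per_contrast = as.integer(foci_per_contrast),
       in_network_fraction = in_network_fraction,
       jitter_sd_mm = jitter_sd_mm, n_range = n_range,
       age_range = age_range, rng_seed = as.integer(rng_seed))
}

# centered RAS affine for an isotropic grid
.centered_affine <- function(grid_shape, spacing_mm) {
  origin <- -(grid_shape - 1) * spacing_mm / 2
  rbind(cbind(diag(3) * spacing_mm, origin), c(0, 0, 0, 1))
}

# band-limited unit-variance latent series
.bandlimited_series <- function(tlen, tr, band) {
  w <- stats::rnorm(tlen)
  s <- bandpass(w, band[1], band[2], tr_seconds = tr)
  s / stats::sd(s)
}

#' Simulate a normative resting-state cohort with planted networks
#'
#' Every voxel of a planted network carries `w * s(t) + noise`, where `s(t)`
#' is a per-subject band-limited latent series shared across that network's
#' voxels; background gray-matter voxels are pure noise. The gray-matter
#' mask is an ellipsoidal envelope inscribed in the grid. Each subject also
#' gets a simulated motion trace and white-matter/CSF nuisance series.
#' Deterministic given `spec$rng_seed`.
#'
#' @param spec a [cohort_spec()].
#' @return list: `subjects` (each with `bold` (`vol4d`), `motion`
#'   ([motion_trace()]), `wm`, `csf`, `subject_id`), `gm_mask`
#'   (`brain_mask`), `truth_masks` (list of `brain_mask`, one per planted
#'   network), `template` (`vol3d`), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$rng_seed)
  d <- spec$grid_shape
  aff <- .centered_affine(d, spec$spacing_mm)
  template <- vol3d(array(0, d), aff)

  centers <- .all_voxel_centers_mm(template)
  semi <- (d - 1) * spec$spacing_mm / 2 * spec$gm_axis_fraction
  inside <- rowSums(sweep(centers, 2, rep(0, 3))^2 /
                      matrix(semi^2, nrow(centers), 3, byrow = TRUE)) <= 1
  gm <- brain_mask(array(as.numeric(inside), d), aff)

  truth_masks <- lapply(spec$networks, function(nw) {
    m <- make_sphere_seed(nw$component_centers, nw$component_radius_mm,
                          template)
    m$data <- m$data * gm$data
    if (sum(m$data) == 0) stop("planted network lies outside the grid/GM")
    m
  })

  gm_idx <- which(gm$data == 1)
  net_idx <- lapply(truth_masks, function(m) which(m$data == 1))
  tlen <- spec$n_volumes
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    arr <- array(0, c(d, tlen))
    flat <- matrix(0, prod(d), tlen)
    for (nn in seq_along(spec$networks)) {
      nw <- spec$networks[[nn]]
      lat <- .bandlimited_series(tlen, spec$tr_seconds, spec$latent_band)
      flat[net_idx[[nn]], ] <- flat[net_idx[[nn]], , drop = FALSE] +
        matrix(lat, length(net_idx[[nn]]), tlen, byrow = TRUE) * nw$loading_w
    }
    amp <- spec$global_amplitude %||% 0
    if (amp > 0) {
      glob <- .bandlimited_series(tlen, spec$tr_seconds, spec$latent_band)
      flat[gm_idx, ] <- flat[gm_idx, , drop = FALSE] +
        matrix(glob, length(gm_idx), tlen, byrow = TRUE) * amp
    }
    noise_sd <- if (length(spec$networks)) spec$networks[[1]]$noise_sd else 1
    flat[gm_idx, ] <- flat[gm_idx, , drop = FALSE] +
      matrix(stats::rnorm(length(gm_idx) * tlen, sd = noise_sd),
             length(gm_idx), tlen)
    arr <- array(flat, c(d, tlen))
    spike_frames <- if (stats::runif(1) < spec$spike_prob)
      sample(15:(tlen - 5), 1) else integer(0)
    subjects[[s]] <- list(
      subject_id = sprintf("sub-%02d", s),
      bold = vol4d(arr, aff, tr_seconds = spec$tr_seconds),
      motion = simulate_motion(tlen, spike_frames = spike_frames,
                               base_sd = spec$motion_sd),
      wm = as.numeric(stats::rnorm(tlen, sd = 1)),
      csf = as.numeric(stats::rnorm(tlen, sd = 1)))
  }
  list(subjects = subjects, gm_mask = gm, truth_masks = truth_masks,
       template = template, spec = spec)
}

#' Simulate a realignment motion trace
#'
#' Smooth low-amplitude random-walk drift on all six parameters, plus
#' sustained 1-mm translation steps injected at `spike_frames` — each step
#' produces exactly one volume with framewise displacement above the 0.5-mm
#' spike threshold.
#'
#' @param n_volumes trace length.
#' @param spike_frames integer frames (2..T) receiving an injected step.
#' @param base_sd per-frame random-walk standard deviation, mm (rotations use
#'   `base_sd / 100` radians).
#' @param step_mm injected displacement size, mm.
#' @return a [motion_trace()].
#' @export
simulate_motion <- function(n_volumes, spike_frames = integer(0),
                            base_sd = 0.02, step_mm = 1) {
  stopifnot(all(spike_frames >= 2), all(spike_frames <= n_volumes))
  trans <- apply(matrix(stats::rnorm(n_volumes * 3, sd = base_sd),
                        n_volumes, 3), 2, cumsum)
  rot <- apply(matrix(stats::rnorm(n_volumes * 3, sd = base_sd / 100),
                      n_volumes, 3), 2, cumsum)
  if (n_volumes == 1) { trans <- matrix(trans, 1); rot <- matrix(rot, 1) }
  for (f in spike_frames)
    trans[f:n_volumes, 1] <- trans[f:n_volumes, 1] + step_mm
  motion_trace(trans, rot)
}

#' Simulate a study/foci table around a planted network
#'
#' Emits the study-table schema consumed by [build_contrast_seeds()]: per
#' contrast, a fraction `in_network_fraction` of foci are sampled from
#' truth-mask voxel centers with isotropic Gaussian jitter, the remainder
#' uniformly from gray-matter voxel centers. Per-study sample sizes, sex
#' splits and mean ages are drawn from the spec's ranges. All coordinates are
#' emitted in MNI space. Synthetic data: study identities carry a `synth_`
#' prefix.
#'
#' @param truth_mask planted-network `brain_mask` (may be `NULL` when
#'   `in_network_fraction = 0`).
#' @param spec a [study_spec()].
#' @param gm_mask gray-matter `brain_mask`.
#' @return foci tibble in the [load_study_table()] schema.
#' @export
simulate_study_foci <- function(truth_mask, spec = study_spec(), gm_mask) {
  set.seed(spec$rng_seed)
  if (sum(gm_mask$data) == 0) stop("empty gray-matter mask")
  gm_centers <- .all_voxel_centers_mm(gm_mask)[gm_mask$data == 1, ,
                                               drop = FALSE]
  if (spec$in_network_fraction > 0) {
    if (is.null(truth_mask) || sum(truth_mask$data) == 0)
      stop("nonempty truth mask required when in_network_fraction > 0")
    net_centers <- .all_voxel_centers_mm(truth_mask)[truth_mask$data == 1, ,
                                                     drop = FALSE]
  }
  rows <- list()
  for (s in seq_len(spec$n_studies)) {
    n <- sample(spec$n_range[1]:spec$n_range[2], 1)
    n_f <- stats::rbinom(1, n, stats::runif(1, 0.3, 0.7))
    age <- round(stats::runif(1, spec$age_range[1], spec$age_range[2]), 1)
    for (cc in seq_len(spec$contrasts_per_study)) {
      for (ff in seq_len(spec$foci_per_contrast)) {
        if (stats::runif(1) < spec$in_network_fraction) {
          xyz <- net_centers[sample(nrow(net_centers), 1), ] +
            stats::rnorm(3, sd = spec$jitter_sd_mm)
        } else {
          xyz <- gm_centers[sample(nrow(gm_centers), 1), ]
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          study_id = sprintf("synth_study_%02d", s),
          n = n, n_female = n_f, n_male = n - n_f,
          mean_age = age, sd_age = round(stats::runif(1, 1, 10), 2),
          scale = "synthetic", space = "MNI",
          contrast_id = sprintf("contrast_%d", cc),
          x = xyz[1], y = xyz[2], z = xyz[3],
          sign = sample(c("positive", "negative"), 1))
      }
    }
  }
  dplyr::bind_rows(rows)
}

# empirical calibration: mixing weight on normal scores -> achieved Spearman
.calibrate_mixing <- function(rho_target, P, n_reps = 50) {
  if (rho_target == 0) return(0)
  grid <- seq(0.02, 0.999, length.out = 40)
  xs <- stats::qnorm((seq_len(P) - 0.5) / P)   # fixed normal scores
  achieved <- vapply(grid, function(w) {
    mean(vapply(seq_len(n_reps), function(i) {
      y <- w * xs + sqrt(1 - w^2) * stats::rnorm(P)
      stats::cor(xs, y, method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  stats::approx(achieved, grid, xout = abs(rho_target), rule = 2)$y *
    sign(rho_target)
}

#' Simulate receptor parcel maps with target Spearman correlation
#'
#' Each tracer's parcel vector is built by mixing the normal scores of the
#' network vector's ranks with independent Gaussian noise,
#' `y = w * scores(x) + sqrt(1 - w^2) * eps`. The mixing weight `w` achieving
#' a requested Spearman rho is found by brute-force Monte-Carlo calibration
#' (rank correlations of mixed Gaussians have no convenient closed form).
#' Deterministic given `rng_seed`.
#'
#' @param network_parcels parcel tibble (`parcel_id`, `value`) or numeric
#'   vector — the map the tracers should correlate with.
#' @param rhos named numeric vector of target Spearman correlations in
#'   (-1, 1), one per tracer.
#' @param rng_seed integer seed.
#' @param calibration_reps Monte-Carlo replicates per calibration grid point.
#' @return wide parcel tibble: `parcel_id` plus one column per tracer.
#' @export
simulate_receptor_maps <- function(network_parcels, rhos, rng_seed = 1,
                                   calibration_reps = 50) {
  if (is.null(names(rhos)) || any(!nzchar(names(rhos))))
    names(rhos) <- paste0("tracer_", seq_along(rhos))
  if (any(abs(rhos) > 1)) stop("|rho| must be <= 1")
  tb <- if (is.numeric(network_parcels))
    tibble::tibble(parcel_id = seq_along(network_parcels),
                   value = as.numeric(network_parcels))
  else network_parcels
  P <- nrow(tb)
  set.seed(rng_seed)
  xs <- stats::qnorm((rank(tb$value, ties.method = "average") - 0.5) / P)
  out <- tibble::tibble(parcel_id = tb$parcel_id)
  for (tr in names(rhos)) {
    rho <- rhos[[tr]]
    if (abs(rho) >= 1) {
      out[[tr]] <- if (rho > 0) xs else -xs
      next
    }
    w <- .calibrate_mixing(rho, P, calibration_reps)
    out[[tr]] <- w * xs + sqrt(1 - w^2) * stats::rnorm(P)
  }
  out
}

#' Simulate a label atlas by Voronoi partition
#'
#' Labels every in-mask voxel by its nearest of `n_labels` randomly chosen
#' in-mask voxel centers, guaranteeing every label occurs. Used both for the
#' canonical-network atlas (8 labels with the conventional names) and for
#' finer parcel atlases.
#'
#' @param mask `brain_mask` defining the labelled territory.
#' @param n_labels number of labels.
#' @param names character vector of label names (defaults to the eight
#'   canonical network names when `n_labels` is 8, else `parcel_<i>`).
#' @param rng_seed integer seed.
#' @return an [atlas_label_map()].
#' @export
simulate_label_atlas <- function(mask, n_labels = 8, names = NULL,
                                 rng_seed = 1) {
  set.seed(rng_seed)
  idx <- which(mask$data == 1)
  stopifnot(length(idx) >= n_labels)
  centers_all <- .all_voxel_centers_mm(mask)
  seeds <- sample(idx, n_labels)
  seed_mm <- centers_all[seeds, , drop = FALSE]
  in_mm <- centers_all[idx, , drop = FALSE]
  d2 <- vapply(seq_len(n_labels), function(l)
    rowSums(sweep(in_mm, 2, seed_mm[l, ])^2), numeric(length(idx)))
  lab_vals <- max.col(-d2, ties.method = "first")
  arr <- array(0, dim(mask$data))
  arr[idx] <- lab_vals
  if (is.null(names)) {
    names <- if (n_labels == 8)
      c("visual", "somatomotor", "dorsal attention", "ventral attention",
        "limbic", "frontoparietal", "default mode", "subcortical")
    else sprintf("parcel_%03d", seq_len(n_labels))
  }
  atlas_label_map(vol3d(arr, mask$affine, mask$space),
                  stats::setNames(names, seq_len(n_labels)))
}
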