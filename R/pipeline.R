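#' Pipeline configuration
#'
#' Validated bag of tunable parameters for [run_fcnm()]. Defaults are the
#' conventional FCNM settings: 4-mm seed spheres (1 and 7 mm for sensitivity
#' analyses), voxel-level FDR at q = 0.05 restricted to positive
#' connectivity, a 50% overlap-probability network threshold, a 20%
#' canonical-network involvement rule, 5000 permutations for receptor-map
#' correlations, 10 discarded initial volumes, FD spike threshold 0.5 mm,
#' motion limits 2 mm / 2 degrees, 0.01–0.1 Hz bandpass, and global signal
#' regression on.
#'
#' @param radius_mm seed sphere radius, mm.
#' @param fdr_q voxel-level FDR level.
#' @param prob_threshold overlap-probability threshold (fraction of contrast
#'   seeds).
#' @param involvement_pct canonical-network involvement threshold, percent.
#' @param n_perm permutations per receptor map.
#' @param gsr include global signal regression.
#' @param n_discard initial volumes discarded.
#' @param fd_spike_mm FD threshold for spike regressors, mm.
#' @param head_radius_mm head radius for FD, mm.
#' @param band bandpass edges, Hz.
#' @param max_trans_mm,max_rot_deg motion QC limits.
#' @param smooth_fwhm_mm optional spatial smoothing of the BOLD data before
#'   connectivity (0 = none; upstream-normalized cohorts typically arrive
#'   already smoothed).
#' @param seed_agg seed time-series aggregation (`"mean"` or `"pc1"`).
#' @param correlation_method receptor-map correlation (`"spearman"` or
#'   `"pearson"`).
#' @param network_input map entering the receptor-map correlation: the
#'   unthresholded overlap-probability map (`"prob"`, default, the richest
#'   gradation), the binary network mask (`"mask"`), or the mean group-t map
#'   (`"tmean"`).
#' @param rng_seed integer seed for every stochastic step.
#' @return list of class `fcnm_config`.
#' @export
fcnm_config <- function(radius_mm = 4, fdr_q = 0.05, prob_threshold = 0.5,
                        involvement_pct = 20, n_perm = 5000, gsr = TRUE,
                        n_discard = 10, fd_spike_mm = 0.5,
                        head_radius_mm = 50, band = c(0.01, 0.1),
                        max_trans_mm = 2, max_rot_deg = 2,
                        smooth_fwhm_mm = 0,
                        seed_agg = c("mean", "pc1"),
                        correlation_method = c("spearman", "pearson"),
                        network_input = c("prob", "mask", "tmean"),
                        rng_seed = 1) {
  stopifnot(radius_mm > 0, fdr_q > 0, fdr_q < 1,
            prob_threshold > 0, prob_threshold <= 1,
            involvement_pct >= 0, involvement_pct <= 100,
            n_perm >= 1, n_discard >= 0, fd_spike_mm > 0,
            head_radius_mm > 0, length(band) == 2, band[1] >= 0,
            band[2] > band[1], smooth_fwhm_mm >= 0)
  structure(list(radius_mm = radius_mm, fdr_q = fdr_q,
                 prob_threshold = prob_threshold,
                 involvement_pct = involvement_pct, n_perm = n_perm,
                 gsr = gsr, n_discard = n_discard,
                 fd_spike_mm = fd_spike_mm, head_radius_mm = head_radius_mm,
                 band = band, max_trans_mm = max_trans_mm,
                 max_rot_deg = max_rot_deg, smooth_fwhm_mm = smooth_fwhm_mm,
                 seed_agg = match.arg(seed_agg),
                 correlation_method = match.arg(correlation_method),
                 network_input = match.arg(network_input),
                 rng_seed = as.integer(rng_seed)),
            class = "fcnm_config")
}

# temporal preprocessing of one subject; returns in-mask T x V matrix or NULL
# if motion QC fails
.preprocess_subject <- function(subj, gm_mask, config) {
  bold <- discard_initial_volumes(subj$bold, config$n_discard)
  motion <- discard_motion(subj$motion, config$n_discard)
  qc <- motion_qc(motion, config$max_trans_mm, config$max_rot_deg)
  if (!qc$pass) return(NULL)
  if (config$smooth_fwhm_mm > 0)
    bold <- smooth_gaussian(bold, config$smooth_fwhm_mm)
  tlen <- dim(bold$data)[4]
  keep <- (config$n_discard + 1):(config$n_discard + tlen)
  d <- dim(bold$data)
  idx <- which(gm_mask$data == 1)
  Y <- t(matrix(bold$data, prod(d[1:3]), d[4])[idx, , drop = FALSE])
  global_sig <- rowMeans(Y)
  fd <- framewise_displacement(motion, config$head_radius_mm)
  design <- build_nuisance_design(
    motion, fd = fd, global_sig = global_sig,
    wm_sig = if (!is.null(subj$wm)) subj$wm[keep] else NULL,
    csf_sig = if (!is.null(subj$csf)) subj$csf[keep] else NULL,
    include_gsr = config$gsr, spike_threshold_mm = config$fd_spike_mm)
  R <- .ols_residuals(design$matrix, Y)
  .fft_bandpass(R, bold$tr_seconds, config$band[1], config$band[2])
}

# group binary map for one contrast from preprocessed in-mask series
.contrast_binary_map <- function(pre_list, seed_mask, gm_mask, config) {
  idx <- which(gm_mask$data == 1)
  seed_rows <- match(which(seed_mask$data == 1), idx)
  if (anyNA(seed_rows)) stop("seed extends outside the analysis mask")
  n <- length(pre_list)
  Z <- matrix(0, length(idx), n)
  for (s in seq_len(n)) {
    Y <- pre_list[[s]]
    sser <- if (config$seed_agg == "mean" || length(seed_rows) == 1L) {
      rowMeans(Y[, seed_rows, drop = FALSE])
    } else {
      S <- Y[, seed_rows, drop = FALSE]
      pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)$x[, 1]
      ms <- rowMeans(S)
      if (stats::sd(ms) > 0 && stats::cor(pc, ms) < 0) pc <- -pc
      pc
    }
    sds <- sqrt(colSums((Y - rep(colMeans(Y), each = nrow(Y)))^2))
    r <- rep(0, length(idx))
    ok <- sds > 0
    if (stats::sd(sser) == 0) stop("zero-variance seed time series")
    if (any(ok)) r[ok] <- drop(stats::cor(sser, Y[, ok, drop = FALSE]))
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z <- atanh(r)
    z[!ok] <- 0
    Z[, s] <- z
  }
  m <- rowMeans(Z)
  sdv <- sqrt(rowSums((Z - m)^2) / (n - 1))
  tval <- ifelse(sdv > 0, m / (sdv / sqrt(n)),
                 ifelse(m != 0, sign(m) * Inf, 0))
  p <- 2 * stats::pt(-abs(tval), n - 1)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj <= config$fdr_q & tval > 0
  out <- array(0, dim(gm_mask$data))
  out[idx[sig]] <- 1
  brain_mask(out, gm_mask$affine, gm_mask$space)
}

#' Run the full FCNM pipeline
#'
#' Orchestrates: foci -> contrast seeds -> per-subject temporal preprocessing
#' (volume discard, motion QC gate, Friston-24 + spike + WM/CSF (+ global)
#' regression, 0.01–0.1 Hz bandpass) -> per-contrast seed FC and voxelwise
#' one-sample t-tests -> voxel-level FDR binarization restricted to positive
#' connectivity -> overlap-probability map -> 50% network threshold ->
#' canonical-atlas overlap report -> receptor-map neurochemical profile.
#' Identical config + seed gives identical outputs.
#'
#' @param cohort a [simulate_cohort()] bundle or an equivalently shaped list
#'   (`subjects` with `bold`/`motion`/`wm`/`csf`, and `gm_mask`).
#' @param foci foci tibble ([load_study_table()] / [simulate_study_foci()]).
#' @param canonical_atlas optional [atlas_label_map()] for the overlap
#'   report.
#' @param parcel_atlas optional parcel [atlas_label_map()] for the
#'   neurochemical profile.
#' @param receptor_maps optional receptor maps (see [neurochem_profile()]).
#' @param config an [fcnm_config()].
#' @return object of class `fcnm_result`: `network` (`network_mask`),
#'   `prob_map`, `binary_maps`, `seeds` (tibble), `overlap` (tibble or
#'   `NULL`), `neurochem` (tibble or `NULL`), `manifest` (list).
#' @export
run_fcnm <- function(cohort, foci, canonical_atlas = NULL,
                     parcel_atlas = NULL, receptor_maps = NULL,
                     config = fcnm_config()) {
  t0 <- Sys.time()
  gm <- cohort$gm_mask
  for (obj in list(canonical_atlas, parcel_atlas)) {
    if (!is.null(obj) && !same_geometry(gm, obj$labels))
      .stop_geometry(gm, obj$labels, "gray-matter mask and atlas")
  }
  if (!same_geometry(gm, cohort$subjects[[1]]$bold))
    .stop_geometry(gm, cohort$subjects[[1]]$bold, "gray-matter mask and cohort")
  set.seed(config$rng_seed)
  seeds <- build_contrast_seeds(foci, gm, config$radius_mm)
  pre <- .preprocess_cohort(cohort, config)
  res <- .fcnm_from_preprocessed(pre, seeds, cohort, canonical_atlas,
                                 parcel_atlas, receptor_maps, config)
  res$manifest$started <- format(t0, "%Y-%m-%dT%H:%M:%S%z")
  res$manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
}

.preprocess_cohort <- function(cohort, config) {
  pre <- list(); used <- character(); excluded <- character()
  for (subj in cohort$subjects) {
    Y <- .preprocess_subject(subj, cohort$gm_mask, config)
    if (is.null(Y)) {
      excluded <- c(excluded, subj$subject_id)
    } else {
      pre[[length(pre) + 1]] <- Y
      used <- c(used, subj$subject_id)
    }
  }
  if (length(pre) < 2)
    stop("fewer than 2 subjects survive motion QC")
  list(series = pre, subjects_used = used, subjects_excluded = excluded)
}

.fcnm_from_preprocessed <- function(pre, seeds, cohort, canonical_atlas,
                                    parcel_atlas, receptor_maps, config) {
  gm <- cohort$gm_mask
  binary_maps <- lapply(seeds, function(cs)
    .contrast_binary_map(pre$series, cs$seed, gm, config))
  prob_map <- overlap_probability(binary_maps)
  network <- threshold_network(prob_map, config$prob_threshold)

  overlap <- NULL
  if (!is.null(canonical_atlas)) {
    overlap <- overlap_proportions(network, canonical_atlas) |>
      classify_involvement(config$involvement_pct)
  }
  neurochem <- NULL
  if (!is.null(parcel_atlas) && !is.null(receptor_maps)) {
    net_in <- switch(config$network_input,
      prob = { v <- prob_map$prob; v$data <- v$data * gm$data; v },
      mask = { v <- vol3d(network$data, network$affine, network$space); v },
      tmean = stop("tmean network input requires cached t-maps; use 'prob' or 'mask'"))
    neurochem <- neurochem_profile(net_in, receptor_maps, parcel_atlas,
                                   method = config$correlation_method,
                                   n_perm = config$n_perm, q = config$fdr_q,
                                   seed = config$rng_seed, mask = gm)
  }
  seeds_tb <- dplyr::bind_rows(lapply(seeds, function(cs)
    tibble::tibble(contrast_id = cs$contrast_id,
                   n_foci_used = cs$n_foci_used,
                   n_foci_dropped = cs$n_foci_dropped,
                   seed_voxels = sum(cs$seed$data))))
  manifest <- list(
    config = unclass(config),
    k_contrasts = length(seeds),
    subjects_used = pre$subjects_used,
    subjects_excluded = pre$subjects_excluded,
    n_subjects_used = length(pre$series),
    gm_voxels = sum(gm$data),
    voxel_counts = list(
      per_contrast_significant = vapply(binary_maps, function(m)
        sum(m$data), numeric(1)),
      network = sum(network$data)),
    package_version = as.character(utils::packageVersion("fcnmapper")))
  structure(list(network = network, prob_map = prob_map,
                 binary_maps = binary_maps, seeds = seeds_tb,
                 overlap = overlap, neurochem = neurochem,
                 manifest = manifest),
            class = "fcnm_result")
}

#' @export
print.fcnm_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<fcnm_result> K = %d contrasts, %d subjects, ",
                     "network = %d voxels (of %d GM)\n"),
              m$k_contrasts, m$n_subjects_used,
              m$voxel_counts$network, m$gm_voxels))
  if (!is.null(x$overlap)) {
    inv <- x$overlap$network[x$overlap$involved]
    cat("involved canonical networks: ",
        if (length(inv)) paste(inv, collapse = ", ") else "none", "\n")
  }
  if (!is.null(x$neurochem)) {
    sig <- x$neurochem$tracer[x$neurochem$significant]
    cat("FDR-significant tracers: ",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Seed-radius sensitivity analysis
#'
#' Repeats the FCNM run for each seed radius, reusing the (radius-independent)
#' preprocessed time series across runs, and reports the pairwise Dice
#' similarity of the resulting network masks — topographic similarity across
#' radii indicates the network is not an artifact of seed size.
#'
#' @param cohort,foci,canonical_atlas,config as in [run_fcnm()].
#' @param radii numeric vector of sphere radii, mm (default 1, 4, 7).
#' @return list: `results` (named list of `fcnm_result`), `dice_table`
#'   (tibble of pairwise Dice between network masks).
#' @export
run_sensitivity <- function(cohort, foci, radii = c(1, 4, 7),
                            canonical_atlas = NULL, config = fcnm_config()) {
  stopifnot(length(radii) >= 1, all(radii > 0))
  pre <- .preprocess_cohort(cohort, config)
  results <- list()
  for (r in radii) {
    cfg <- config
    cfg$radius_mm <- r
    set.seed(cfg$rng_seed)
    seeds <- build_contrast_seeds(foci, cohort$gm_mask, r)
    results[[paste0("r", r)]] <-
      .fcnm_from_preprocessed(pre, seeds, cohort, canonical_atlas, NULL,
                              NULL, cfg)
  }
  pairs <- expand.grid(i = seq_along(radii), j = seq_along(radii))
  dice_table <- dplyr::bind_rows(apply(pairs, 1, function(pr) {
    tibble::tibble(radius_a = radii[pr[1]], radius_b = radii[pr[2]],
                   dice = dice(results[[pr[1]]]$network,
                               results[[pr[2]]]$network))
  }))
  list(results = results, dice_table = tibble::as_tibble(dice_table))
}

#' Write pipeline artifacts to a directory
#'
#' Network and probability maps as NIfTI, per-contrast binary maps, the
#' overlap and neurochemical tables as CSV, and a JSON run manifest
#' (provenance: config echo, contrast count, subjects, per-stage voxel
#' counts, package version).
#'
#' @param result an `fcnm_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fcnm_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(result$prob_map$prob, file.path(dir, "network_probability.nii.gz"))
  write_volume(result$network, file.path(dir, "network_mask.nii.gz"))
  for (i in seq_along(result$binary_maps))
    write_volume(result$binary_maps[[i]],
                 file.path(dir, sprintf("contrast_%02d_binary.nii.gz", i)))
  readr::write_csv(result$seeds, file.path(dir, "contrast_seeds.csv"))
  if (!is.null(result$overlap))
    readr::write_csv(result$overlap, file.path(dir, "atlas_overlap.csv"))
  if (!is.null(result$neurochem))
    readr::write_csv(result$neurochem, file.path(dir, "neurochem_profile.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
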