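#' Load a study/foci table
#'
#' Reads the delimited study table that carries, per row, the sample
#' characteristics of one included VBM study and (optionally) one reported
#' coordinate. Study-level columns are repeated across the foci rows of a
#' study. Rows whose `x`, `y`, `z` are all present become foci; rows without
#' coordinates contribute the study record only, so a characteristics-only
#' transcription (no published coordinates) is a valid input.
#'
#' Required columns: `study_id`, `n`, `n_female`, `n_male`, `mean_age`,
#' `scale`, `space`. Optional: `sd_age`, `contrast_id`, `x`, `y`, `z`,
#' `sign`. `space` must be `"MNI"` or `"Talairach"` per row; `sign`
#' (direction of the gray-matter association) defaults to `"positive"`.
#'
#' @param path path to a CSV/TSV file (delimiter sniffed by extension:
#'   `.tsv` reads as tab-separated, anything else as comma-separated).
#' @return list with tibbles `studies` (one row per study) and `foci`
#'   (one row per coordinate, possibly empty).
#' @export
load_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  tab <- suppressWarnings(reader(path, show_col_types = FALSE,
                                 progress = FALSE))
  if (nrow(tab) == 0) stop("no records in study table: ", path)
  required <- c("study_id", "n", "n_female", "n_male", "mean_age", "scale",
                "space")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  for (opt in c("sd_age", "contrast_id", "x", "y", "z", "sign"))
    if (!opt %in% names(tab)) tab[[opt]] <- NA
  bad_space <- which(!tab$space %in% c("MNI", "Talairach"))
  if (length(bad_space))
    stop("rows with unknown coordinate space (must be MNI or Talairach): ",
         paste(utils::head(bad_space, 5), collapse = ", "))

  studies <- tab |>
    dplyr::distinct(.data$study_id, .keep_all = TRUE) |>
    dplyr::transmute(
      study_id = as.character(.data$study_id),
      n = as.integer(.data$n),
      n_female = as.integer(.data$n_female),
      n_male = as.integer(.data$n_male),
      mean_age = as.numeric(.data$mean_age),
      sd_age = as.numeric(.data$sd_age),
      scale = as.character(.data$scale),
      space = as.character(.data$space))

  bad <- studies$study_id[!is.na(studies$n_female) & !is.na(studies$n_male) &
                          studies$n_female + studies$n_male != studies$n]
  if (length(bad))
    stop("n_female + n_male != n for study: ", paste(bad, collapse = ", "))
  if (any(!is.na(studies$mean_age) & studies$mean_age <= 0))
    stop("mean_age must be positive")

  foci <- tab |>
    dplyr::filter(!is.na(.data$x) & !is.na(.data$y) & !is.na(.data$z)) |>
    dplyr::transmute(
      study_id = as.character(.data$study_id),
      contrast_id = dplyr::coalesce(as.character(.data$contrast_id),
                                    as.character(.data$study_id)),
      x = as.numeric(.data$x), y = as.numeric(.data$y),
      z = as.numeric(.data$z),
      space = as.character(.data$space),
      sign = dplyr::coalesce(as.character(.data$sign), "positive"))
  if (nrow(foci)) {
    dup <- duplicated(foci[, c("study_id", "contrast_id", "x", "y", "z")])
    if (any(dup)) {
      warning(sum(dup), " duplicate focus row(s) removed")
      foci <- foci[!dup, , drop = FALSE]
    }
    bad_sign <- which(!foci$sign %in% c("positive", "negative"))
    if (length(bad_sign))
      stop("sign must be 'positive' or 'negative' (focus rows: ",
           paste(utils::head(bad_sign, 5), collapse = ", "), ")")
  }
  list(studies = studies, foci = tibble::as_tibble(foci))
}

#' Summarize sample characteristics across studies
#'
#' Totals and the sample-size-weighted mean of study-level mean ages,
#' `sum(n_i * age_i) / sum(n_i)`, reported at two decimals as is conventional
#' for pooled demographics.
#'
#' @param studies tibble of study records (`load_study_table()$studies`).
#' @return one-row tibble: `n_studies`, `total_n`, `total_female`,
#'   `total_male`, `weighted_mean_age`, `min_n`, `max_n`.
#' @export
summarize_sample <- function(studies) {
  stopifnot(nrow(studies) >= 1)
  tibble::tibble(
    n_studies = nrow(studies),
    total_n = sum(studies$n),
    total_female = sum(studies$n_female),
    total_male = sum(studies$n_male),
    weighted_mean_age = round(sum(studies$n * studies$mean_age) /
                                sum(studies$n), 2),
    min_n = min(studies$n),
    max_n = max(studies$n))
}

# ---- Talairach -> MNI -------------------------------------------------------

.tal_registry_env <- new.env(parent = emptyenv())

#' Registered Talairach/MNI affines
#'
#' Named 4x4 matrices shipped as a JSON config
#' (`inst/extdata/talairach_mni_affines.json`), stored in the MNI-to-Talairach
#' direction. The default `"lancaster"` entry is the pooled-average
#' Lancaster-style matrix; conversion Talairach-to-MNI applies its inverse.
#' Because the matrix is configuration, not code, a different convention can
#' be supplied either by editing the JSON or by passing a 4x4 matrix straight
#' to [tal_to_mni()].
#'
#' @return named list of 4x4 matrices (MNI -> Talairach direction).
#' @export
tal_mni_transforms <- function() {
  if (is.null(.tal_registry_env$mats)) {
    path <- system.file("extdata", "talairach_mni_affines.json",
                        package = "fcnmapper", mustWork = TRUE)
    cfg <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
    .tal_registry_env$mats <- lapply(cfg$mni_to_tal, function(m) {
      m <- as.matrix(m); .check_affine(m); m
    })
  }
  .tal_registry_env$mats
}

#' Convert Talairach coordinates to MNI
#'
#' Applies the inverse of a registered (or user-supplied) MNI-to-Talairach
#' affine. With `transform = "identity"` coordinates pass through unchanged,
#' which is also how MNI-space foci are handled upstream.
#'
#' @param coords numeric 3-vector or n x 3 matrix of Talairach mm coordinates.
#' @param transform name of a registered affine (see [tal_mni_transforms()]),
#'   or a 4x4 matrix in the Talairach-to-MNI direction.
#' @return matrix of MNI mm coordinates (same shape as input rows).
#' @export
tal_to_mni <- function(coords, transform = "lancaster") {
  coords <- .as_coord_matrix(coords)
  if (is.character(transform)) {
    mats <- tal_mni_transforms()
    if (!transform %in% names(mats))
      stop("unknown Talairach transform: ", transform,
           " (registered: ", paste(names(mats), collapse = ", "), ")")
    mat <- solve(mats[[transform]])
  } else {
    mat <- as.matrix(transform)
    .check_affine(mat)
  }
  unname(t(mat %*% t(cbind(coords, 1)))[, 1:3, drop = FALSE])
}

# ---- contrast seeds ---------------------------------------------------------

#' Build per-contrast sphere-seed masks from foci
#'
#' For each study contrast: converts Talairach foci to MNI, drops foci whose
#' nearest voxel lies outside the gray-matter mask (counted, mirroring the
#' exclusion of coordinates outside the GM mask), and voxelizes the union of
#' spheres around the survivors. Contrasts left with no usable focus are
#' excluded with a message; if no contrast survives at all, that is an error.
#'
#' @param foci tibble of foci (`load_study_table()$foci` or
#'   [simulate_study_foci()]).
#' @param gm_mask gray-matter `brain_mask` on the analysis grid.
#' @param radius_mm sphere radius in mm (FCNM default 4; 1 and 7 for
#'   sensitivity analyses).
#' @param template volume supplying the analysis grid (defaults to the mask).
#' @param tal_transform passed to [tal_to_mni()] for Talairach rows.
#' @return list of contrast seeds; each element has `contrast_id`,
#'   `seed` (`brain_mask`), `n_foci_used`, `n_foci_dropped`.
#' @export
build_contrast_seeds <- function(foci, gm_mask, radius_mm = 4,
                                 template = gm_mask,
                                 tal_transform = "lancaster") {
  stopifnot(nrow(foci) >= 1)
  if (!same_geometry(gm_mask, template)) .stop_geometry(gm_mask, template)
  key <- paste(foci$study_id, foci$contrast_id, sep = "::")
  seeds <- list()
  for (k in unique(key)) {
    rows <- foci[key == k, , drop = FALSE]
    xyz <- as.matrix(rows[, c("x", "y", "z")])
    tal <- rows$space == "Talairach"
    if (any(tal)) xyz[tal, ] <- tal_to_mni(xyz[tal, , drop = FALSE],
                                           tal_transform)
    part <- filter_coords_in_mask(xyz, gm_mask)
    n_used <- nrow(part$retained)
    if (n_used == 0) {
      message("contrast ", k, " excluded: all ", nrow(rows),
              " foci outside the gray-matter mask")
      next
    }
    sphere <- make_sphere_seed(part$retained, radius_mm, template)
    # restrict to gray matter so downstream FC uses in-mask voxels only;
    # nonempty by construction (each retained focus rounds to a GM voxel)
    sphere$data <- sphere$data * gm_mask$data
    seeds[[k]] <- list(
      contrast_id = k,
      seed = sphere,
      n_foci_used = n_used,
      n_foci_dropped = nrow(rows) - n_used)
  }
  if (!length(seeds))
    stop("no contrast has any focus inside the gray-matter mask")
  seeds
}
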