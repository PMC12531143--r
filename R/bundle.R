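#' Write a pipeline-ready synthetic bundle
#'
#' Serializes everything [run_fcnm()] needs into one directory: per-subject
#' BOLD NIfTI + 6-column motion text + WM/CSF nuisance series, the
#' gray-matter mask and planted-truth masks, the foci CSV, optional atlases
#' (NIfTI + JSON names), optional receptor parcel CSV, and a JSON spec echo
#' from which the bundle can be regenerated.
#'
#' @param dir output directory.
#' @param cohort a [simulate_cohort()] result.
#' @param foci foci tibble.
#' @param canonical_atlas,parcel_atlas optional [atlas_label_map()]s.
#' @param receptor_maps optional wide parcel tibble
#'   ([simulate_receptor_maps()]).
#' @return `dir`, invisibly.
#' @export
write_synthetic_bundle <- function(dir, cohort, foci,
                                   canonical_atlas = NULL,
                                   parcel_atlas = NULL,
                                   receptor_maps = NULL) {
  dir.create(file.path(dir, "cohort"), showWarnings = FALSE, recursive = TRUE)
  for (subj in cohort$subjects) {
    base <- file.path(dir, "cohort", subj$subject_id)
    write_volume(subj$bold, paste0(base, "_bold.nii.gz"))
    write_motion(subj$motion, paste0(base, "_motion.txt"))
    utils::write.table(cbind(wm = subj$wm, csf = subj$csf),
                       paste0(base, "_nuisance.txt"), row.names = FALSE)
  }
  write_volume(cohort$gm_mask, file.path(dir, "gm_mask.nii.gz"))
  for (i in seq_along(cohort$truth_masks))
    write_volume(cohort$truth_masks[[i]],
                 file.path(dir, sprintf("truth_network_%d.nii.gz", i)))
  readr::write_csv(foci, file.path(dir, "foci.csv"))
  if (!is.null(canonical_atlas))
    write_atlas(canonical_atlas, file.path(dir, "canonical_atlas.nii.gz"),
                file.path(dir, "canonical_atlas_names.json"))
  if (!is.null(parcel_atlas))
    write_atlas(parcel_atlas, file.path(dir, "parcel_atlas.nii.gz"),
                file.path(dir, "parcel_atlas_names.json"))
  if (!is.null(receptor_maps))
    readr::write_csv(receptor_maps, file.path(dir, "receptor_parcels.csv"))
  jsonlite::write_json(cohort$spec, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pipeline bundle from disk
#'
#' Inverse of [write_synthetic_bundle()] (truth masks and spec are optional —
#' a bundle of real data need not have them).
#'
#' @param dir bundle directory.
#' @return list shaped like a [simulate_cohort()] result plus `foci`,
#'   `canonical_atlas`, `parcel_atlas`, `receptor_maps` (NULL when absent).
#' @export
read_bundle <- function(dir) {
  gm <- read_volume(file.path(dir, "gm_mask.nii.gz"))
  gm <- brain_mask(round(gm$data), gm$affine, gm$space)
  bold_files <- sort(list.files(file.path(dir, "cohort"),
                                pattern = "_bold\\.nii(\\.gz)?$",
                                full.names = TRUE))
  if (!length(bold_files)) stop("no BOLD volumes under ", dir, "/cohort")
  subjects <- lapply(bold_files, function(f) {
    id <- sub("_bold\\.nii(\\.gz)?$", "", basename(f))
    base <- file.path(dir, "cohort", id)
    nuis <- utils::read.table(paste0(base, "_nuisance.txt"), header = TRUE)
    list(subject_id = id,
         bold = read_volume(f),
         motion = read_motion(paste0(base, "_motion.txt")),
         wm = nuis$wm, csf = nuis$csf)
  })
  truth_files <- sort(list.files(dir, pattern = "^truth_network_.*\\.nii",
                                 full.names = TRUE))
  truth_masks <- lapply(truth_files, function(f) {
    v <- read_volume(f); brain_mask(round(v$data), v$affine, v$space)
  })
  read_if <- function(nii, js)
    if (file.exists(file.path(dir, nii)))
      read_atlas(file.path(dir, nii), file.path(dir, js)) else NULL
  rc <- if (file.exists(file.path(dir, "receptor_parcels.csv")))
    readr::read_csv(file.path(dir, "receptor_parcels.csv"),
                    show_col_types = FALSE, progress = FALSE) else NULL
  list(subjects = subjects, gm_mask = gm, truth_masks = truth_masks,
       foci = readr::read_csv(file.path(dir, "foci.csv"),
                              show_col_types = FALSE, progress = FALSE),
       canonical_atlas = read_if("canonical_atlas.nii.gz",
                                 "canonical_atlas_names.json"),
       parcel_atlas = read_if("parcel_atlas.nii.gz",
                              "parcel_atlas_names.json"),
       receptor_maps = rc)
}
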