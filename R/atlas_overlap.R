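#' Canonical network label atlas
#'
#' An integer label volume plus a label-to-name table. Label 0 is reserved
#' for background; every named label must occur in the grid.
#'
#' @param labels `vol3d` of nonnegative integers (or an integer array plus
#'   `affine`).
#' @param names named character vector or list mapping label integers
#'   (as names) to network names, e.g. `c("1" = "visual", ...)`.
#' @param affine required when `labels` is a bare array.
#' @return object of class `atlas_label_map`.
#' @export
atlas_label_map <- function(labels, names, affine = NULL) {
  if (!inherits(labels, "vol3d")) labels <- vol3d(labels, affine)
  vals <- labels$data
  if (any(vals < 0) || any(vals != round(vals)))
    stop("atlas labels must be nonnegative integers")
  names <- unlist(names)
  ids <- as.integer(base::names(names))
  if (any(is.na(ids)) || any(ids == 0))
    stop("label names must be keyed by nonzero integer labels")
  missing_lab <- ids[!ids %in% unique(as.vector(vals))]
  if (length(missing_lab))
    stop("named label(s) absent from the grid: ",
         paste(missing_lab, collapse = ", "))
  structure(list(labels = labels,
                 names = stats::setNames(as.character(names), ids)),
            class = "atlas_label_map")
}

#' @export
print.atlas_label_map <- function(x, ...) {
  cat(sprintf("<atlas_label_map> %d named labels on a %s grid\n",
              length(x$names), paste(dim(x$labels$data), collapse = " x ")))
  invisible(x)
}

#' Read an atlas from NIfTI + JSON name table
#'
#' @param nifti_path integer label NIfTI.
#' @param names_path JSON file holding an object mapping label integers to
#'   names.
#' @return an [atlas_label_map()].
#' @export
read_atlas <- function(nifti_path, names_path) {
  vol <- read_volume(nifti_path)
  vol$data <- array(round(vol$data), dim(vol$data))
  nm <- jsonlite::fromJSON(names_path)
  atlas_label_map(vol, unlist(nm))
}

#' Write an atlas as NIfTI + JSON name table
#'
#' @param atlas an [atlas_label_map()].
#' @param nifti_path,names_path output paths.
#' @export
write_atlas <- function(atlas, nifti_path, names_path) {
  write_volume(atlas$labels, nifti_path)
  jsonlite::write_json(as.list(atlas$names), names_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(nifti_path)
}

#' Overlap proportions with canonical networks
#'
#' For each named atlas label L, the percentage of L's voxels covered by the
#' network mask: `100 * |network ∩ L| / |L|`. The denominator is the
#' canonical network's own voxel count. A complementary diagnostic column,
#' `network_fraction_pct` (share of the network mask falling inside L), is
#' emitted as well but plays no part in the involvement rule.
#'
#' @param network a network `brain_mask`.
#' @param atlas an [atlas_label_map()] on the same grid.
#' @return tibble with one row per named label: `network`, `label`,
#'   `network_voxels`, `overlap_voxels`, `proportion_pct`,
#'   `network_fraction_pct`.
#' @export
overlap_proportions <- function(network, atlas) {
  if (!same_geometry(network, atlas$labels))
    .stop_geometry(network, atlas$labels, "network and atlas")
  lab <- as.vector(atlas$labels$data)
  net <- as.vector(network$data) == 1
  mask_size <- sum(net)
  ids <- as.integer(names(atlas$names))
  rows <- lapply(ids, function(id) {
    in_lab <- lab == id
    n_lab <- sum(in_lab)
    if (n_lab == 0)
      stop("atlas label ", id, " has zero voxels")
    ov <- sum(in_lab & net)
    tibble::tibble(
      network = unname(atlas$names[as.character(id)]),
      label = id,
      network_voxels = n_lab,
      overlap_voxels = ov,
      proportion_pct = 100 * ov / n_lab,
      network_fraction_pct = if (mask_size > 0) 100 * ov / mask_size else 0)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("overlap_report", class(out))
  out
}

#' Classify canonical-network involvement
#'
#' A canonical network is called involved iff its overlap proportion is at
#' least `threshold_pct` percent — inclusive, so exactly 20% counts with the
#' default rule.
#'
#' @param report an [overlap_proportions()] tibble.
#' @param threshold_pct involvement threshold in percent (default 20).
#' @return the report with an `involved` logical column (class
#'   `overlap_report`).
#' @export
classify_involvement <- function(report, threshold_pct = 20) {
  out <- dplyr::mutate(report,
                       involved = .data$proportion_pct >= threshold_pct)
  attr(out, "threshold_pct") <- threshold_pct
  if (!inherits(out, "overlap_report"))
    class(out) <- c("overlap_report", class(out))
  out
}
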