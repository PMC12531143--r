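#' Volumetric containers
#'
#' `vol3d()` wraps a 3D scalar grid together with its 4x4 voxel-to-mm affine
#' (NIfTI RAS+ convention, 0-based voxel indices). `vol4d()` adds a time axis
#' and a repetition time. `brain_mask()` is a `vol3d` whose values are
#' restricted to \{0, 1\}.
#'
#' These are the carriers for every map in the FCNM pipeline: seed masks,
#' gray-matter masks, t-maps, overlap-probability maps and atlases all share
#' a grid and an affine, and geometry is checked whenever two volumes meet.
#'
#' @param data numeric array (3D for `vol3d`/`brain_mask`, 4D for `vol4d`).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param space text label for the coordinate space (e.g. `"MNI152"`).
#' @param tr_seconds repetition time in seconds (4D only), > 0.
#' @return An object of class `vol3d`, `vol4d` or `brain_mask`.
#' @export
vol3d <- function(data, affine, space = "MNI152") {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L)
  .check_affine(affine)
  if (any(dim(data) < 1L)) stop("grid dimensions must be >= 1 on each axis")
  structure(list(data = data, affine = unname(affine), space = space),
            class = "vol3d")
}

#' @rdname vol3d
#' @export
vol4d <- function(data, affine, tr_seconds, space = "MNI152") {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 4L)
  .check_affine(affine)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  structure(list(data = data, affine = unname(affine), space = space,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "vol4d")
}

#' @rdname vol3d
#' @export
brain_mask <- function(data, affine, space = "MNI152") {
  v <- vol3d(data, affine, space)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop("brain_mask values must be restricted to {0, 1}")
  v$data <- array(as.numeric(v$data != 0), dim(v$data))
  class(v) <- c("brain_mask", "vol3d")
  v
}

.check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)) ||
      !all(is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  d <- det(affine)
  if (!is.finite(d) || abs(d) < 1e-12) stop("affine must be invertible")
  invisible(TRUE)
}

#' @export
print.vol3d <- function(x, ...) {
  cat(sprintf("<%s> %s grid, space %s, spacing %s mm\n",
              class(x)[1], paste(dim(x$data), collapse = " x "), x$space,
              paste(signif(voxel_spacing(x), 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.vol4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol4d> %s grid x %d volumes, TR %.3g s, space %s\n",
              paste(d[1:3], collapse = " x "), d[4], x$tr_seconds, x$space))
  invisible(x)
}

#' Voxel spacing in mm
#'
#' Column norms of the 3x3 part of the affine: the physical size of one voxel
#' step along each grid axis.
#'
#' @param vol a `vol3d`/`vol4d`, or a 4x4 affine matrix.
#' @return numeric length-3 vector of mm per voxel.
#' @export
voxel_spacing <- function(vol) {
  aff <- if (is.matrix(vol)) vol else vol$affine
  sqrt(colSums(aff[1:3, 1:3]^2))
}

#' Geometry equality between volumes
#'
#' @param a,b volumes (`vol3d`/`vol4d`).
#' @param tol absolute tolerance on affine entries.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-4) {
  da <- dim(a$data)[1:3]; db <- dim(b$data)[1:3]
  all(da == db) && max(abs(a$affine - b$affine)) <= tol
}

.stop_geometry <- function(a, b, what = "volumes") {
  stop(sprintf("geometry mismatch between %s: grid %s vs %s", what,
               paste(dim(a$data)[1:3], collapse = "x"),
               paste(dim(b$data)[1:3], collapse = "x")), call. = FALSE)
}

# ---- NIfTI I/O --------------------------------------------------------------

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a `vol3d` (3D image) or `vol4d` (4D image,
#' with the repetition time taken from the header's fourth pixdim).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `vol3d` or `vol4d`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (all(is.na(arr))) stop("NaN-filled image: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  nd <- length(dim(arr))
  if (nd == 3L) {
    vol3d(arr, aff)
  } else if (nd == 4L) {
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) tr <- 1
    vol4d(arr, aff, tr_seconds = tr)
  } else {
    stop("unsupported NIfTI dimensionality: ", nd)
  }
}

#' Write a volume to NIfTI
#'
#' The affine is written exactly as held (as sform/qform); for 4D volumes the
#' repetition time is stored in the header.
#'
#' @param vol `vol3d` or `vol4d`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  sp <- voxel_spacing(vol)
  RNifti::pixdim(img) <- if (inherits(vol, "vol4d"))
    c(sp, vol$tr_seconds) else sp
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- coordinate geometry ----------------------------------------------------

#' Convert between mm coordinates and voxel indices
#'
#' `mm_to_voxel()` maps world (mm) coordinates to continuous 0-based voxel
#' indices through the inverse affine; `voxel_to_mm()` is its inverse.
#'
#' @param affine 4x4 voxel-to-mm matrix, or a volume carrying one.
#' @param coords numeric 3-vector or n x 3 matrix.
#' @return numeric matrix (n x 3); a single coordinate yields a 1 x 3 matrix
#'   which drops cleanly with `drop()`.
#' @export
mm_to_voxel <- function(affine, coords) {
  if (!is.matrix(affine)) affine <- affine$affine
  .check_affine(affine)
  coords <- .as_coord_matrix(coords)
  h <- cbind(coords, 1)
  out <- t(solve(affine, t(h)))[, 1:3, drop = FALSE]
  unname(out)
}

#' @rdname mm_to_voxel
#' @export
voxel_to_mm <- function(affine, coords) {
  if (!is.matrix(affine)) affine <- affine$affine
  coords <- .as_coord_matrix(coords)
  unname(t(affine %*% t(cbind(coords, 1)))[, 1:3, drop = FALSE])
}

.as_coord_matrix <- function(coords) {
  if (is.null(dim(coords))) {
    stopifnot(length(coords) == 3L)
    coords <- matrix(coords, ncol = 3L)
  }
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3L, all(is.finite(coords)))
  coords
}

# mm coordinates of every voxel center, as an n_voxel x 3 matrix in array order
.all_voxel_centers_mm <- function(vol) {
  d <- dim(vol$data)[1:3]
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  voxel_to_mm(vol$affine, idx)
}

# ---- sphere seeds -----------------------------------------------------------

#' Build a sphere-union seed mask
#'
#' Voxelizes the union of closed balls of radius `radius_mm` centered at each
#' coordinate: a voxel belongs to the seed if its center lies within
#' `radius_mm` of at least one coordinate, or if it is the voxel containing a
#' coordinate (so a sphere smaller than half the voxel size still marks the
#' voxel it falls in, and any in-grid coordinate yields a nonempty seed, as
#' sphere tools conventionally guarantee). This is the contrast-seed
#' construction of FCNM (default radius 4 mm; 1 and 7 mm are used for
#' sensitivity analyses).
#'
#' @param coords_mm numeric 3-vector or n x 3 matrix of mm coordinates.
#' @param radius_mm sphere radius in mm, > 0.
#' @param template a `vol3d`/`brain_mask` supplying grid and affine.
#' @return a `brain_mask` on the template grid.
#' @export
make_sphere_seed <- function(coords_mm, radius_mm, template) {
  stopifnot(is.numeric(radius_mm), length(radius_mm) == 1L, radius_mm > 0)
  coords <- .as_coord_matrix(coords_mm)
  d <- dim(template$data)[1:3]
  sp <- voxel_spacing(template)
  out <- array(0, d)
  for (r in seq_len(nrow(coords))) {
    c_vox <- drop(mm_to_voxel(template$affine, coords[r, ]))
    home <- round(c_vox)
    if (all(home >= 0) && all(home <= d - 1L))
      out[matrix(home + 1L, ncol = 3)] <- 1
    lo <- pmax(0L, floor(c_vox - radius_mm / sp - 1))
    hi <- pmin(d - 1L, ceiling(c_vox + radius_mm / sp + 1))
    if (any(lo > hi)) next
    box <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                 k = lo[3]:hi[3]))
    ctr <- voxel_to_mm(template$affine, box)
    dist <- sqrt(rowSums(sweep(ctr, 2, coords[r, ])^2))
    inside <- box[dist <= radius_mm + 1e-9, , drop = FALSE] + 1L
    if (nrow(inside)) out[inside] <- 1
  }
  if (sum(out) == 0)
    stop("empty seed: no coordinate falls within the grid at this radius")
  brain_mask(out, template$affine, template$space)
}

# ---- Gaussian smoothing -----------------------------------------------------

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian convolution with kernel width given as full width at
#' half maximum in mm (sigma = fwhm / (2 sqrt(2 ln 2)) per axis, converted to
#' voxel units through the voxel spacing). Boundaries are handled by
#' reflective (symmetric) padding, which conserves total image mass for
#' interior-supported structures. For 4D input each time point is smoothed
#' independently in space.
#'
#' @param vol `vol3d` or `vol4d`.
#' @param fwhm_mm full width at half maximum in mm, >= 0 (0 is the identity).
#' @return same class as `vol`.
#' @export
smooth_gaussian <- function(vol, fwhm_mm) {
  stopifnot(is.numeric(fwhm_mm), length(fwhm_mm) == 1L)
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(vol)
  sp <- voxel_spacing(vol)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / sp
  arr <- vol$data
  for (ax in 1:3) arr <- .conv_axis(arr, ax, sigma_vox[ax])
  out <- vol
  out$data <- arr
  out
}

# 1D Gaussian convolution along axis `ax` with symmetric (reflective) padding
.conv_axis <- function(arr, ax, sigma) {
  if (sigma <= 0) return(arr)
  n <- dim(arr)[ax]
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  # convolution matrix with symmetric padding folded into the boundary rows
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- (i - half):(i + half)
    src_ref <- .reflect_index(src, n)
    for (j in seq_along(src)) M[i, src_ref[j]] <- M[i, src_ref[j]] + k[j]
  }
  nd <- length(dim(arr))
  perm <- c(ax, setdiff(seq_len(nd), ax))
  a <- aperm(arr, perm)
  dp <- dim(a)
  a <- M %*% matrix(a, nrow = n)
  dim(a) <- dp
  aperm(a, order(perm))
}

# symmetric reflection of 1-based indices into 1..n (edge included once)
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  i <- ((i - 1L) %% p + p) %% p
  ifelse(i >= n, p - i, i) + 1L
}

# ---- coordinate filtering ---------------------------------------------------

#' Partition coordinates by mask membership
#'
#' A coordinate is retained iff its nearest voxel (continuous index rounded to
#' nearest) lies inside the grid and has mask value 1. Order is preserved;
#' an empty retained set is a legal outcome.
#'
#' @param coords_mm numeric 3-vector or n x 3 matrix of mm coordinates.
#' @param mask a `brain_mask`.
#' @return list with `retained` and `dropped` (n x 3 matrices) and
#'   `retained_idx` (positions of retained rows in the input).
#' @export
filter_coords_in_mask <- function(coords_mm, mask) {
  coords <- .as_coord_matrix(coords_mm)
  d <- dim(mask$data)
  vox <- round(mm_to_voxel(mask$affine, coords))
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] &
            vox[, 2] >= 0 & vox[, 2] < d[2] &
            vox[, 3] >= 0 & vox[, 3] < d[3]
  keep <- logical(nrow(coords))
  if (any(inside))
    keep[inside] <- mask$data[vox[inside, , drop = FALSE] + 1L] == 1
  list(retained = coords[keep, , drop = FALSE],
       dropped = coords[!keep, , drop = FALSE],
       retained_idx = which(keep))
}

#' Dice similarity coefficient between binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; two empty masks are defined as identical
#' (Dice 1).
#'
#' @param a,b `brain_mask` objects on the same grid.
#' @return numeric scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!same_geometry(a, b)) .stop_geometry(a, b, "masks")
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(a$data * b$data) / (sa + sb)
}
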