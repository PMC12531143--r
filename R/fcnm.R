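#' Seed time series
#'
#' Aggregates the time series of all seed voxels. The default (and the
#' convention adopted here) is the unweighted mean; `"pc1"` gives the first
#' principal component of the seed voxel series, sign-aligned with the mean
#' series.
#'
#' @param data `vol4d`.
#' @param seed nonempty `brain_mask` on the same grid.
#' @param method `"mean"` (default) or `"pc1"`.
#' @return numeric vector of length T.
#' @export
seed_timeseries <- function(data, seed, method = c("mean", "pc1")) {
  method <- match.arg(method)
  if (!same_geometry(data, seed)) .stop_geometry(data, seed, "data and seed")
  idx <- which(seed$data == 1)
  if (!length(idx)) stop("empty seed mask")
  d <- dim(data$data)
  Y <- matrix(data$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  if (method == "mean" || nrow(Y) == 1L) return(colMeans(Y))
  Yc <- t(Y) - colMeans(t(Y))
  pc <- stats::prcomp(Yc, center = FALSE, scale. = FALSE)$x[, 1]
  m <- colMeans(Y)
  if (stats::sd(m) > 0 && stats::cor(pc, m) < 0) pc <- -pc
  pc
}

#' Fisher z-transformation
#'
#' `z = atanh(r)`, variance-stabilizing for correlation coefficients; odd in
#' `r`. Inputs must satisfy `|r| < 1` — callers clip sample correlations
#' upstream (see [seed_fc_map()]).
#'
#' @param r numeric vector of correlations with `|r| < 1`.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires finite |r| < 1; clip correlations upstream")
  atanh(r)
}

#' Per-subject seed-to-voxel functional connectivity map
#'
#' Pearson correlation between the seed time series and every voxel series
#' inside the analysis mask, clipped to `|r| <= 1 - 1e-7`, then Fisher
#' z-transformed. Voxels with zero temporal variance get z = 0 and are
#' flagged; out-of-mask voxels are 0.
#'
#' @param data `vol4d` with at least 3 time points.
#' @param seed nonempty `brain_mask` (should lie inside the analysis mask).
#' @param analysis_mask `brain_mask` defining the in-brain voxel family.
#' @param method seed aggregation, see [seed_timeseries()].
#' @param subject_id,contrast_id optional labels carried on the result.
#' @return object of class `fc_map`: list with `z` (`vol3d`),
#'   `n_flagged_voxels`, `subject_id`, `contrast_id`.
#' @export
seed_fc_map <- function(data, seed, analysis_mask,
                        method = "mean", subject_id = NA_character_,
                        contrast_id = NA_character_) {
  d <- dim(data$data)
  stopifnot(d[4] >= 3)
  if (!same_geometry(data, analysis_mask)) .stop_geometry(data, analysis_mask)
  s <- seed_timeseries(data, seed, method)
  if (stats::sd(s) == 0) stop("zero-variance seed time series")
  idx <- which(analysis_mask$data == 1)
  Y <- t(matrix(data$data, prod(d[1:3]), d[4])[idx, , drop = FALSE])
  sds <- apply(Y, 2, stats::sd)
  r <- rep(0, length(idx))
  ok <- sds > 0
  if (any(ok)) r[ok] <- drop(stats::cor(s, Y[, ok, drop = FALSE]))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- fisher_z(r)
  z[!ok] <- 0
  zarr <- array(0, d[1:3])
  zarr[idx] <- z
  structure(list(z = vol3d(zarr, data$affine, data$space),
                 n_flagged_voxels = sum(!ok),
                 subject_id = subject_id, contrast_id = contrast_id),
            class = "fc_map")
}

#' Voxelwise one-sample t-test across subjects
#'
#' For each voxel: `t = mean(z) / (sd(z) / sqrt(n))` with `df = n - 1` and a
#' two-sided p-value. Voxels with zero across-subject variance get a signed
#' infinite t sentinel (p = 0) when the mean is nonzero, t = 0 (p = 1)
#' otherwise, and are counted in a QC flag.
#'
#' @param z_maps list of `fc_map` objects (or bare `vol3d`s) from >= 2
#'   subjects on identical grids.
#' @param analysis_mask optional `brain_mask`; statistics are computed only
#'   within it (out-of-mask voxels get t = 0, p = 1).
#' @param contrast_id optional label.
#' @return object of class `group_tmap`: `t_map` (`vol3d`), `p_map`
#'   (`vol3d`), `df`, `n_subjects`, `n_degenerate_voxels`, `contrast_id`.
#' @export
group_onesample_t <- function(z_maps, analysis_mask = NULL,
                              contrast_id = NA_character_) {
  vols <- lapply(z_maps, function(m) if (inherits(m, "fc_map")) m$z else m)
  n <- length(vols)
  stopifnot(n >= 2)
  ref <- vols[[1]]
  for (v in vols[-1]) if (!same_geometry(ref, v)) .stop_geometry(ref, v)
  d <- dim(ref$data)
  idx <- if (is.null(analysis_mask)) seq_len(prod(d)) else
    which(analysis_mask$data == 1)
  Z <- vapply(vols, function(v) v$data[idx], numeric(length(idx)))
  m <- rowMeans(Z)
  sdv <- sqrt(rowSums((Z - m)^2) / (n - 1))
  tval <- rep(0, length(idx))
  ok <- sdv > 0
  tval[ok] <- m[ok] / (sdv[ok] / sqrt(n))
  degen <- !ok & m != 0
  tval[degen] <- sign(m[degen]) * Inf
  df <- n - 1
  p <- 2 * stats::pt(-abs(tval), df)
  tarr <- array(0, d); parr <- array(1, d)
  tarr[idx] <- tval; parr[idx] <- p
  structure(list(t_map = vol3d(tarr, ref$affine, ref$space),
                 p_map = vol3d(parr, ref$affine, ref$space),
                 df = df, n_subjects = n,
                 n_degenerate_voxels = sum(degen),
                 contrast_id = contrast_id),
            class = "group_tmap")
}

#' @export
print.group_tmap <- function(x, ...) {
  cat(sprintf("<group_tmap> %s, n = %d (df = %d), max |t| = %.3g\n",
              ifelse(is.na(x$contrast_id), "unnamed contrast", x$contrast_id),
              x$n_subjects, x$df, max(abs(x$t_map$data))))
  invisible(x)
}

#' Threshold a group t-map by voxel-level FDR and binarize
#'
#' Benjamini–Hochberg correction over the two-sided p-values of all in-mask
#' voxels (the multiple-testing family is the analysis mask); surviving
#' voxels are kept only where t > 0 when `positive_only` (the FCNM
#' convention: negative connectivity is not interpreted). A one-sided mode
#' (`sided = "right"`) halves p-values for positive t before correction.
#'
#' @param tmap a [group_onesample_t()] result.
#' @param q FDR level (default 0.05).
#' @param positive_only retain only positively connected voxels.
#' @param analysis_mask `brain_mask` defining the voxel family.
#' @param sided `"two"` (default) or `"right"`.
#' @return `brain_mask` of significant voxels.
#' @export
fdr_binarize <- function(tmap, q = 0.05, positive_only = TRUE,
                         analysis_mask = NULL, sided = c("two", "right")) {
  sided <- match.arg(sided)
  d <- dim(tmap$p_map$data)
  idx <- if (is.null(analysis_mask)) seq_len(prod(d)) else
    which(analysis_mask$data == 1)
  if (!length(idx)) stop("empty analysis mask")
  p <- tmap$p_map$data[idx]
  tv <- tmap$t_map$data[idx]
  if (sided == "right") p <- ifelse(tv > 0, p / 2, 1 - p / 2)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj <= q
  if (positive_only) sig <- sig & tv > 0
  out <- array(0, d)
  out[idx[sig]] <- 1
  brain_mask(out, tmap$t_map$affine, tmap$t_map$space)
}

#' Overlap-probability map across contrasts
#'
#' Per voxel, the fraction of the K contrast-level binary maps that include
#' it; values lie on the grid \{0, 1/K, ..., 1\}.
#'
#' @param binary_maps list of K `brain_mask` objects on identical grids.
#' @return object of class `network_prob_map`: `prob` (`vol3d`) and
#'   `k_contrasts`.
#' @export
overlap_probability <- function(binary_maps) {
  k <- length(binary_maps)
  stopifnot(k >= 1)
  ref <- binary_maps[[1]]
  acc <- array(0, dim(ref$data))
  for (m in binary_maps) {
    if (!same_geometry(ref, m)) .stop_geometry(ref, m, "binary maps")
    acc <- acc + m$data
  }
  structure(list(prob = vol3d(acc / k, ref$affine, ref$space),
                 k_contrasts = k),
            class = "network_prob_map")
}

#' @export
print.network_prob_map <- function(x, ...) {
  cat(sprintf("<network_prob_map> K = %d contrasts, %d voxels with prob > 0\n",
              x$k_contrasts, sum(x$prob$data > 0)))
  invisible(x)
}

#' Threshold the overlap-probability map into the network mask
#'
#' Inclusive threshold: a voxel enters the network iff it is connected to at
#' least `tau` of the contrast seeds (the FCNM convention is tau = 0.5,
#' "at least 50% of the contrast seeds").
#'
#' @param prob_map a [overlap_probability()] result.
#' @param tau fraction in (0, 1].
#' @return `brain_mask` with attribute `threshold = tau` (class
#'   `network_mask`).
#' @export
threshold_network <- function(prob_map, tau = 0.5) {
  stopifnot(tau > 0, tau <= 1)
  m <- brain_mask(array(as.numeric(prob_map$prob$data >= tau - 1e-12),
                        dim(prob_map$prob$data)),
                  prob_map$prob$affine, prob_map$prob$space)
  if (sum(m$data) == 0)
    message("network mask is empty at threshold ", tau)
  attr(m, "threshold") <- tau
  class(m) <- c("network_mask", class(m))
  m
}
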