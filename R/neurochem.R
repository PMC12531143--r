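#' Parcellate a volume
#'
#' Mean of in-parcel voxel values for every nonzero atlas label. Parcels with
#' no voxels are dropped with a warning.
#'
#' @param volume `vol3d`.
#' @param parcel_atlas an [atlas_label_map()] (names optional for parcels:
#'   any nonzero label is a parcel) or a `vol3d` of integer labels.
#' @param mask optional `brain_mask`; only in-mask voxels contribute.
#' @return tibble with `parcel_id` (integer) and `value` (mean), one row per
#'   nonempty parcel.
#' @export
parcellate <- function(volume, parcel_atlas, mask = NULL) {
  labels <- if (inherits(parcel_atlas, "atlas_label_map"))
    parcel_atlas$labels else parcel_atlas
  if (!same_geometry(volume, labels))
    .stop_geometry(volume, labels, "volume and parcel atlas")
  lab <- as.vector(labels$data)
  val <- as.vector(volume$data)
  keep <- lab > 0
  if (!is.null(mask)) keep <- keep & as.vector(mask$data) == 1
  if (!any(keep)) stop("all parcels are empty")
  means <- tapply(val[keep], lab[keep], mean)
  all_ids <- sort(unique(lab[lab > 0]))
  got <- as.integer(names(means))
  if (length(setdiff(all_ids, got)))
    warning("dropped empty parcel(s): ",
            paste(setdiff(all_ids, got), collapse = ", "))
  tibble::tibble(parcel_id = got, value = as.numeric(means))
}

# align two parcel inputs (tibble with parcel_id/value, or bare numeric)
.align_parcels <- function(x, y) {
  if (is.numeric(x) && is.numeric(y)) {
    stopifnot(length(x) == length(y))
    return(list(x = as.numeric(x), y = as.numeric(y)))
  }
  as_tb <- function(v) {
    if (is.numeric(v)) tibble::tibble(parcel_id = seq_along(v),
                                      value = as.numeric(v))
    else v
  }
  j <- dplyr::inner_join(as_tb(x), as_tb(y), by = "parcel_id",
                         suffix = c("_x", "_y"))
  list(x = j$value_x, y = j$value_y)
}

#' Spatial correlation between parcel vectors
#'
#' Spearman (default, rank-based — the usual choice for receptor-map
#' comparisons) or Pearson correlation over the parcels shared by the two
#' inputs.
#'
#' @param x,y parcel tibbles (`parcel_id`, `value`) or plain numeric vectors
#'   of equal length; tibbles are aligned on `parcel_id`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return correlation coefficient (numeric scalar).
#' @export
spatial_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  al <- .align_parcels(x, y)
  if (length(al$x) < 3) stop("need at least 3 shared parcels")
  if (stats::sd(al$x) == 0 || stats::sd(al$y) == 0)
    stop("zero variance in a parcel vector")
  stats::cor(al$x, al$y, method = method)
}

#' Permutation test for a spatial correlation
#'
#' Null distribution from uniformly shuffling the parcel assignment of `y`;
#' two-sided p with the add-one correction
#' `p = (#\{|r*| >= |r_obs|\} + 1) / (n_perm + 1)`, so p is never exactly 0.
#' This null ignores spatial autocorrelation; `perm_fun` is a hook for
#' supplying a different permutation scheme (e.g. a spin-test-style null)
#' returning an index permutation per draw.
#'
#' @param x,y parcel tibbles or numeric vectors (see
#'   [spatial_correlation()]).
#' @param method correlation type.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed for reproducibility.
#' @param perm_fun optional `function(P)` returning an integer permutation of
#'   `1:P`.
#' @return list with `r` (observed), `p` (permutation p-value) and `n_perm`.
#' @export
permutation_test <- function(x, y, method = c("spearman", "pearson"),
                             n_perm = 5000, seed = NULL, perm_fun = NULL) {
  method <- match.arg(method)
  al <- .align_parcels(x, y)
  P <- length(al$x)
  if (P < 3) stop("need at least 3 shared parcels")
  xs <- if (method == "spearman") rank(al$x) else al$x
  ys <- if (method == "spearman") rank(al$y) else al$y
  xs <- (xs - mean(xs)) / stats::sd(xs)
  ys <- (ys - mean(ys)) / stats::sd(ys)
  r_obs <- sum(xs * ys) / (P - 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(perm_fun)) perm_fun <- function(P) sample.int(P)
  perm_idx <- vapply(seq_len(n_perm), function(i) perm_fun(P), integer(P))
  # ranks are permutation-invariant, so permuting standardized scores is
  # exactly permuting the parcel assignment
  YP <- matrix(ys[perm_idx], nrow = P, ncol = n_perm)
  r_null <- drop(crossprod(YP, xs)) / (P - 1)
  p <- (sum(abs(r_null) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n_perm = n_perm)
}

#' FDR correction across receptor maps
#'
#' Benjamini–Hochberg adjustment of the permutation p-values across the
#' whole tracer family tested (e.g. 30 maps), with significance flags at
#' level `q`.
#'
#' @param results tibble with at least a `p_perm` column (as returned by
#'   [neurochem_profile()]).
#' @param q FDR level (default 0.05).
#' @return the tibble with `p_fdr` and `significant` columns.
#' @export
fdr_across_maps <- function(results, q = 0.05) {
  stopifnot(nrow(results) >= 1, "p_perm" %in% names(results))
  dplyr::mutate(results,
                p_fdr = stats::p.adjust(.data$p_perm, method = "BH"),
                significant = .data$p_fdr <= q)
}

#' Neurochemical profile of a brain map
#'
#' Parcellates the network map and every receptor/transporter density map on
#' a common parcel atlas, computes the spatial correlation per tracer, tests
#' each with a permutation null, and applies FDR correction across the tracer
#' family. This is the JuSpace-style analysis relating a network map to
#' PET-derived neurotransmitter maps.
#'
#' @param network_input `vol3d` (e.g. the overlap-probability map restricted
#'   to gray matter) or a parcel tibble.
#' @param receptor_maps named list of `vol3d`s, a named list of parcel
#'   tibbles, or a wide tibble with `parcel_id` plus one column per tracer.
#' @param parcel_atlas parcel [atlas_label_map()] (required when any input is
#'   a volume).
#' @param method correlation type (`"spearman"` default).
#' @param n_perm permutations per tracer (default 5000).
#' @param q FDR level across the family.
#' @param seed RNG seed; per-tracer streams are derived from it.
#' @param mask optional `brain_mask` restricting parcellation.
#' @return tibble of class `neurochem_profile`: `tracer`, `r`, `p_perm`,
#'   `p_fdr`, `significant`, `n_parcels`, `method`.
#' @export
neurochem_profile <- function(network_input, receptor_maps,
                              parcel_atlas = NULL,
                              method = c("spearman", "pearson"),
                              n_perm = 5000, q = 0.05, seed = 1,
                              mask = NULL) {
  method <- match.arg(method)
  as_parcels <- function(obj) {
    if (inherits(obj, "vol3d")) {
      if (is.null(parcel_atlas)) stop("parcel_atlas required for volume input")
      parcellate(obj, parcel_atlas, mask)
    } else obj
  }
  net <- as_parcels(network_input)
  if (tibble::is_tibble(receptor_maps) && "parcel_id" %in% names(receptor_maps)) {
    tracers <- setdiff(names(receptor_maps), "parcel_id")
    receptor_maps <- stats::setNames(lapply(tracers, function(tr)
      tibble::tibble(parcel_id = receptor_maps$parcel_id,
                     value = receptor_maps[[tr]])), tracers)
  }
  stopifnot(length(receptor_maps) >= 1, !is.null(names(receptor_maps)))
  rows <- purrr::imap(receptor_maps, function(rmap, tracer) {
    pv <- as_parcels(rmap)
    al <- .align_parcels(net, pv)
    pt <- permutation_test(net, pv, method = method, n_perm = n_perm,
                           seed = seed + match(tracer, names(receptor_maps)))
    tibble::tibble(tracer = tracer, r = pt$r, p_perm = pt$p,
                   n_parcels = length(al$x), method = method)
  })
  out <- fdr_across_maps(dplyr::bind_rows(rows), q = q)
  out <- dplyr::relocate(out, "tracer", "r", "p_perm", "p_fdr",
                         "significant", "n_parcels", "method")
  class(out) <- c("neurochem_profile", class(out))
  attr(out, "q") <- q
  attr(out, "n_perm") <- n_perm
  out
}

#' Read receptor maps from a directory or parcel table
#'
#' A directory is scanned for `<tracer>.nii(.gz)` volumes; a CSV file is read
#' as a wide parcel table (`parcel_id` column plus one column per tracer).
#'
#' @param path directory of NIfTI files or a CSV path.
#' @return named list of `vol3d`s, or a wide parcel tibble.
#' @export
read_receptor_maps <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    if (!length(files)) stop("no NIfTI receptor maps in ", path)
    nm <- sub("\\.nii(\\.gz)?$", "", basename(files))
    stats::setNames(lapply(files, read_volume), nm)
  } else {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!"parcel_id" %in% names(tab))
      stop("receptor parcel table must have a parcel_id column")
    tab
  }
}
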