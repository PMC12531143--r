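#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an FCNM result
#'
#' Returns the canonical-network overlap table (when an atlas was supplied)
#' or, failing that, the per-contrast seed table.
#'
#' @param x an `fcnm_result`.
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.fcnm_result <- function(x, ...) {
  if (!is.null(x$overlap)) return(tibble::as_tibble(x$overlap))
  x$seeds
}

#' One-row summary of an FCNM run
#'
#' @param x an `fcnm_result`.
#' @param ... unused.
#' @return one-row tibble: contrasts, subjects, gray-matter and network voxel
#'   counts, thresholds, counts of involved networks / significant tracers.
#' @exportS3Method generics::glance
#' @export
glance.fcnm_result <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    k_contrasts = m$k_contrasts,
    n_subjects = m$n_subjects_used,
    gm_voxels = m$gm_voxels,
    network_voxels = m$voxel_counts$network,
    radius_mm = m$config$radius_mm,
    fdr_q = m$config$fdr_q,
    prob_threshold = m$config$prob_threshold,
    n_involved = if (is.null(x$overlap)) NA_integer_ else
      sum(x$overlap$involved),
    n_significant_tracers = if (is.null(x$neurochem)) NA_integer_ else
      sum(x$neurochem$significant))
}

#' Tidy a group t-map into a voxel table
#'
#' @param x a `group_tmap`.
#' @param mask optional `brain_mask` restricting rows.
#' @param ... unused.
#' @return tibble with voxel indices (0-based), mm coordinates, t and p.
#' @exportS3Method generics::tidy
#' @export
tidy.group_tmap <- function(x, mask = NULL, ...) {
  d <- dim(x$t_map$data)
  idx <- if (is.null(mask)) seq_len(prod(d)) else which(mask$data == 1)
  sub <- arrayInd(idx, d) - 1L
  mm <- voxel_to_mm(x$t_map$affine, sub)
  tibble::tibble(i = sub[, 1], j = sub[, 2], k = sub[, 3],
                 x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
                 t = x$t_map$data[idx], p = x$p_map$data[idx])
}

# ---- plots ------------------------------------------------------------------

#' Plot a canonical-network overlap report
#'
#' Bar chart of overlap proportions per canonical network with the
#' involvement threshold marked; `polar = TRUE` bends it into the polar
#' layout conventional for these reports.
#'
#' @param object an `overlap_report` tibble.
#' @param threshold_pct involvement threshold line (defaults to the one used
#'   in classification, else 20).
#' @param polar use polar coordinates.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.overlap_report <- function(object, threshold_pct = NULL,
                                    polar = FALSE, ...) {
  thr <- threshold_pct %||% attr(object, "threshold_pct") %||% 20
  has_involved <- "involved" %in% names(object)
  p <- ggplot2::ggplot(object,
         ggplot2::aes(x = .data$network, y = .data$proportion_pct,
                      fill = if (has_involved) .data$involved else NULL)) +
    ggplot2::geom_col(show.legend = has_involved) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "overlap with canonical network (%)",
                  fill = sprintf("involved (>= %g%%)", thr)) +
    ggplot2::theme_minimal()
  if (polar) p + ggplot2::coord_polar() else
    p + ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                           hjust = 1))
}

#' Plot a neurochemical profile
#'
#' Lollipop chart of the spatial correlation per tracer, FDR-significant
#' tracers highlighted.
#'
#' @param object a `neurochem_profile` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.neurochem_profile <- function(object, ...) {
  ord <- dplyr::arrange(object, .data$r)
  ord$tracer <- factor(ord$tracer, levels = ord$tracer)
  ggplot2::ggplot(ord, ggplot2::aes(x = .data$tracer, y = .data$r,
                                    color = .data$significant)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$tracer, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "spatial correlation (r)",
                  color = "FDR significant") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a volume
#'
#' Quick-look heat map of one axial (k) slice, with the network mask outline
#' optionally overlaid.
#'
#' @param vol a `vol3d` (e.g. an overlap-probability map).
#' @param k 0-based axial slice index (defaults to the middle slice).
#' @param mask optional `brain_mask` drawn as tile outlines.
#' @return a ggplot object.
#' @export
plot_slice <- function(vol, k = NULL, mask = NULL) {
  d <- dim(vol$data)
  if (is.null(k)) k <- floor(d[3] / 2)
  sl <- vol$data[, , k + 1]
  df <- tidyr::expand_grid(i = seq_len(d[1]) - 1L, j = seq_len(d[2]) - 1L)
  df$value <- sl[cbind(df$i + 1L, df$j + 1L)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("axial slice k = %d", k)) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    msl <- mask$data[, , k + 1]
    mdf <- df[msl[cbind(df$i + 1L, df$j + 1L)] == 1, , drop = FALSE]
    if (nrow(mdf))
      p <- p + ggplot2::geom_tile(data = mdf, fill = NA, color = "red",
                                  linewidth = 0.3)
  }
  p
}
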