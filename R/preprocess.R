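#' Motion trace container
#'
#' Six rigid-body realignment parameters per volume: translations in mm and
#' rotations in radians.
#'
#' @param translations T x 3 numeric matrix, mm.
#' @param rotations T x 3 numeric matrix, radians.
#' @return object of class `motion_trace`.
#' @export
motion_trace <- function(translations, rotations) {
  translations <- as.matrix(translations)
  rotations <- as.matrix(rotations)
  stopifnot(ncol(translations) == 3L, ncol(rotations) == 3L,
            nrow(translations) == nrow(rotations),
            all(is.finite(translations)), all(is.finite(rotations)))
  structure(list(translations = unname(translations),
                 rotations = unname(rotations)),
            class = "motion_trace")
}

#' Read/write a 6-column motion parameter file
#'
#' Whitespace-delimited text, one row per volume: three translations (mm)
#' followed by three rotations (radians).
#'
#' @param path text file path.
#' @return `read_motion()`: a [motion_trace()].
#' @export
read_motion <- function(path) {
  m <- as.matrix(utils::read.table(path))
  stopifnot(ncol(m) == 6L)
  motion_trace(m[, 1:3, drop = FALSE], m[, 4:6, drop = FALSE])
}

#' @rdname read_motion
#' @param motion a [motion_trace()].
#' @export
write_motion <- function(motion, path) {
  utils::write.table(cbind(motion$translations, motion$rotations), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` time points of a 4D scan (and, via
#' [discard_motion()], the matching motion rows) to allow for T1
#' equilibration; the conventional default is 10 volumes.
#'
#' @param data `vol4d`.
#' @param n_discard nonnegative integer, strictly less than the number of
#'   volumes.
#' @return `vol4d` with `T - n_discard` volumes; TR and affine unchanged.
#' @export
discard_initial_volumes <- function(data, n_discard = 10L) {
  stopifnot(inherits(data, "vol4d"), n_discard >= 0)
  tlen <- dim(data$data)[4]
  if (tlen <= n_discard)
    stop("cannot discard ", n_discard, " volumes from a scan of ", tlen)
  if (n_discard == 0) return(data)
  out <- data
  out$data <- data$data[, , , -seq_len(n_discard), drop = FALSE]
  out
}

#' @rdname discard_initial_volumes
#' @param motion a [motion_trace()].
#' @export
discard_motion <- function(motion, n_discard = 10L) {
  tlen <- nrow(motion$translations)
  if (tlen <= n_discard)
    stop("cannot discard ", n_discard, " rows from a trace of ", tlen)
  if (n_discard == 0) return(motion)
  keep <- -seq_len(n_discard)
  motion_trace(motion$translations[keep, , drop = FALSE],
               motion$rotations[keep, , drop = FALSE])
}

#' Gross head-motion quality control
#'
#' A scan fails iff any volume exceeds the translation limit on any axis or
#' the rotation limit on any axis — strictly "exceeding": values exactly at
#' the limit pass. Rotations are stored in radians and compared in degrees.
#'
#' @param motion a [motion_trace()].
#' @param max_trans_mm translation limit per axis, mm (default 2).
#' @param max_rot_deg rotation limit per axis, degrees (default 2).
#' @return list: `pass` (logical), `offending_frames` (integer vector),
#'   `max_translation_mm`, `max_rotation_deg`.
#' @export
motion_qc <- function(motion, max_trans_mm = 2, max_rot_deg = 2) {
  rot_deg <- motion$rotations * 180 / pi
  bad <- apply(abs(motion$translations) > max_trans_mm, 1, any) |
         apply(abs(rot_deg) > max_rot_deg, 1, any)
  list(pass = !any(bad),
       offending_frames = which(bad),
       max_translation_mm = max(abs(motion$translations)),
       max_rotation_deg = max(abs(rot_deg)))
}

#' Framewise displacement (Power convention)
#'
#' `FD_t = sum |Delta translations| + r * sum |Delta rotations|` with
#' rotations in radians converted to arc length on a sphere of radius
#' `head_radius_mm` (default 50 mm); `FD_1 = 0`. Depends on frame-to-frame
#' differences only, so it is invariant to constant offsets of the trace.
#'
#' @param motion a [motion_trace()].
#' @param head_radius_mm assumed head radius in mm.
#' @return numeric vector of length T.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  stopifnot(nrow(motion$translations) >= 2)
  dt <- abs(diff(motion$translations))
  dr <- abs(diff(motion$rotations))
  c(0, rowSums(dt) + head_radius_mm * rowSums(dr))
}

#' Friston 24-parameter motion expansion
#'
#' For each of the six realignment parameters p: the parameter itself, its
#' one-volume lag (row 1 of the lag set to 0), its square, and the squared
#' lag. Columns are grouped by block: the 6 parameters, their 6 lags, the 6
#' squares, the 6 squared lags.
#'
#' @param motion a [motion_trace()].
#' @return T x 24 numeric matrix with descriptive column names.
#' @export
friston24 <- function(motion) {
  p <- cbind(motion$translations, motion$rotations)
  stopifnot(nrow(p) >= 2)
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_lag"),
                     paste0("mp", 1:6, "_sq"), paste0("mp", 1:6, "_lagsq"))
  out
}

#' Spike regressors from framewise displacement
#'
#' One one-hot column per volume with FD strictly above the threshold
#' (default 0.5 mm); a volume at exactly the threshold is not flagged.
#'
#' @param fd numeric FD vector (see [framewise_displacement()]).
#' @param threshold_mm scalar threshold in mm.
#' @return T x s matrix (zero columns when no volume is flagged).
#' @export
spike_regressors <- function(fd, threshold_mm = 0.5) {
  flagged <- which(fd > threshold_mm)
  out <- matrix(0, length(fd), length(flagged))
  if (length(flagged)) {
    out[cbind(flagged, seq_along(flagged))] <- 1
    colnames(out) <- paste0("spike_", flagged)
  }
  out
}

#' Assemble the nuisance design matrix
#'
#' Columns, in order: constant, linear trend, the Friston-24 motion
#' expansion, per-spike one-hot regressors (FD above `spike_threshold_mm`),
#' then the global (if `include_gsr`), white-matter and cerebrospinal-fluid
#' mean signals. Regressing all nuisance terms simultaneously (trend
#' included) avoids reintroducing removed variance between steps.
#'
#' @param motion a [motion_trace()] (post-discard).
#' @param fd FD vector; computed from `motion` when `NULL`.
#' @param global_sig,wm_sig,csf_sig length-T nuisance series (any may be
#'   `NULL` to omit).
#' @param include_gsr include the global signal column (default `TRUE`).
#' @param spike_threshold_mm FD threshold for spike columns.
#' @return object of class `nuisance_design`: list with `matrix` (T x k) and
#'   `column_labels`.
#' @export
build_nuisance_design <- function(motion, fd = NULL, global_sig = NULL,
                                  wm_sig = NULL, csf_sig = NULL,
                                  include_gsr = TRUE,
                                  spike_threshold_mm = 0.5) {
  tlen <- nrow(motion$translations)
  if (is.null(fd)) fd <- framewise_displacement(motion)
  series <- list(global = global_sig, wm = wm_sig, csf = csf_sig)
  for (nm in names(series))
    if (!is.null(series[[nm]]) && length(series[[nm]]) != tlen)
      stop("length mismatch: ", nm, " signal has ", length(series[[nm]]),
           " rows, motion has ", tlen)
  if (length(fd) != tlen)
    stop("length mismatch: fd has ", length(fd), " rows, motion has ", tlen)
  f24 <- friston24(motion)
  spikes <- spike_regressors(fd, spike_threshold_mm)
  X <- cbind(constant = rep(1, tlen),
             trend = seq_len(tlen) - (tlen + 1) / 2,
             f24, spikes)
  if (include_gsr && !is.null(series$global)) X <- cbind(X, global = series$global)
  if (!is.null(series$wm)) X <- cbind(X, wm = series$wm)
  if (!is.null(series$csf)) X <- cbind(X, csf = series$csf)
  structure(list(matrix = X, column_labels = colnames(X)),
            class = "nuisance_design")
}

#' Voxelwise nuisance regression
#'
#' Ordinary least-squares residuals of every in-mask voxel time series
#' against the nuisance design; residuals are orthogonal to every retained
#' design column. A rank-deficient design has its dependent columns dropped
#' with a warning. Out-of-mask voxels are set to 0.
#'
#' @param data `vol4d`.
#' @param design a [build_nuisance_design()] result (rows must match T).
#' @param mask `brain_mask` on the same grid (defaults to all voxels).
#' @return `vol4d` of residuals.
#' @export
nuisance_regress <- function(data, design, mask = NULL) {
  stopifnot(inherits(data, "vol4d"))
  d <- dim(data$data)
  X <- design$matrix
  if (nrow(X) != d[4])
    stop("design has ", nrow(X), " rows but data has ", d[4], " volumes")
  if (is.null(mask)) {
    mask_arr <- array(1, d[1:3])
  } else {
    if (!same_geometry(data, mask)) .stop_geometry(data, mask)
    mask_arr <- mask$data
  }
  keep <- which(mask_arr == 1)
  Y <- matrix(data$data, prod(d[1:3]), d[4])[keep, , drop = FALSE]
  res <- t(.ols_residuals(X, t(Y)))
  out_mat <- matrix(0, prod(d[1:3]), d[4])
  out_mat[keep, ] <- res
  out <- data
  out$data <- array(out_mat, d)
  out
}

# least-squares residuals of each column of Y on X, dropping dependent columns
.ols_residuals <- function(X, Y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("rank-deficient nuisance design; dropping column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  qr.resid(qrX, Y)
}

#' Ideal frequency-domain bandpass filter
#'
#' Rectangular (brick-wall) filter applied per voxel in the frequency domain:
#' Fourier coefficients with frequency inside `[low_hz, high_hz]` (inclusive)
#' are kept, everything else — including the DC component — is zeroed, and
#' the series is inverse-transformed. Zero-phase by construction and
#' idempotent. The conventional resting-state band is 0.01–0.1 Hz.
#'
#' @param data `vol4d`, or a numeric vector/matrix of time series in columns
#'   (then `tr_seconds` must be given).
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1 / (2 TR)`.
#' @param tr_seconds sampling interval for vector/matrix input.
#' @return same shape as the input.
#' @export
bandpass <- function(data, low_hz = 0.01, high_hz = 0.1, tr_seconds = NULL) {
  if (inherits(data, "vol4d")) {
    d <- dim(data$data)
    Y <- t(matrix(data$data, prod(d[1:3]), d[4]))
    filtered <- .fft_bandpass(Y, data$tr_seconds, low_hz, high_hz)
    out <- data
    out$data <- array(t(filtered), d)
    return(out)
  }
  if (is.null(tr_seconds)) stop("tr_seconds required for non-volume input")
  if (is.null(dim(data)))
    drop(.fft_bandpass(matrix(data, ncol = 1), tr_seconds, low_hz, high_hz))
  else
    .fft_bandpass(data, tr_seconds, low_hz, high_hz)
}

.fft_bandpass <- function(Y, tr, low, high) {
  tlen <- nrow(Y)
  nyquist <- 1 / (2 * tr)
  if (!(low >= 0 && high > low)) stop("invalid band: low must be >= 0 and < high")
  if (high >= nyquist + 1e-12)
    stop(sprintf("band edge %.4g Hz not below Nyquist %.4g Hz for TR %.3g s",
                 high, nyquist, tr))
  freq <- (seq_len(tlen) - 1) / (tlen * tr)
  freq <- pmin(freq, 1 / tr - freq)   # two-sided spectrum
  keep <- freq >= low - 1e-12 & freq <= high + 1e-12
  Yf <- stats::mvfft(Y)
  Yf[!keep, ] <- 0
  Re(stats::mvfft(Yf, inverse = TRUE)) / tlen
}
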