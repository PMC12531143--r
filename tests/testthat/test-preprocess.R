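test_that("initial-volume discard shortens the time axis only", {
  v <- toy_vol4d(matrix(rnorm(120 * 8), 120, 8), c(2, 2, 2))
  out <- discard_initial_volumes(v, 10)
  expect_equal(dim(out$data)[4], 110)
  expect_equal(out$tr_seconds, v$tr_seconds)
  expect_equal(out$affine, v$affine)
  expect_equal(out$data[, , , 1], v$data[, , , 11])
  expect_identical(discard_initial_volumes(v, 0), v)
  v10 <- toy_vol4d(matrix(rnorm(10 * 8), 10, 8), c(2, 2, 2))
  expect_error(discard_initial_volumes(v10, 10), "cannot discard")
})

test_that("motion QC is strict about 'exceeding' the limits", {
  expect_true(motion_qc(zero_motion(20))$pass)

  m <- zero_motion(20)
  m$translations[7, 1] <- 2.5
  qc <- motion_qc(m)
  expect_false(qc$pass)
  expect_equal(qc$offending_frames, 7L)

  at_limit <- zero_motion(20)
  at_limit$rotations[5, 2] <- 2 * pi / 180  # exactly 2 degrees
  expect_true(motion_qc(at_limit)$pass)
  over <- zero_motion(20)
  over$rotations[5, 2] <- 2.01 * pi / 180
  expect_false(motion_qc(over)$pass)
})

test_that("framewise displacement follows the Power formula", {
  m <- zero_motion(10)
  expect_equal(framewise_displacement(m), rep(0, 10))

  step <- zero_motion(10)
  step$translations[5:10, 1] <- 1   # +1 mm sustained step at frame 5
  fd <- framewise_displacement(step)
  expect_equal(fd[5], 1.0)
  expect_equal(fd[-5], rep(0, 9))

  rot <- zero_motion(10)
  rot$rotations[4:10, 3] <- 0.02   # 0.02 rad step -> 50 mm * 0.02
  expect_equal(framewise_displacement(rot)[4], 1.0)

  # offset invariance: FD depends on frame differences only
  offset <- motion_trace(step$translations + 5, step$rotations + 0.1)
  expect_equal(framewise_displacement(offset), fd)
})

test_that("Friston-24 expansion matches hand computation", {
  expect_equal(friston24(zero_motion(5)), friston24(zero_motion(5)) * 0)
  expect_equal(dim(friston24(zero_motion(7))), c(7L, 24L))

  m <- zero_motion(3)
  m$translations[, 1] <- c(1, 2, 3)
  f <- friston24(m)
  expect_equal(unname(f[, 1]), c(1, 2, 3))          # parameter
  expect_equal(unname(f[, 7]), c(0, 1, 2))          # lag, first row 0
  expect_equal(unname(f[, 13]), c(1, 4, 9))         # square
  expect_equal(unname(f[, 19]), c(0, 1, 4))         # squared lag
  expect_true(all(f[, -c(1, 7, 13, 19)] == 0))
})

test_that("spike regressors use a strict threshold and one-hot columns", {
  expect_equal(ncol(spike_regressors(rep(0.3, 12))), 0)
  expect_equal(ncol(spike_regressors(c(0, 0.5, 0.2))), 0)  # exactly 0.5: no flag
  s <- spike_regressors(c(0, 0.6, 0.1, 0.9, 0.2))
  expect_equal(dim(s), c(5L, 2L))
  expect_equal(colSums(s), c(spike_2 = 1, spike_4 = 1))
})

test_that("nuisance design has the documented column arithmetic", {
  tlen <- 50
  m <- zero_motion(tlen)
  m$translations[] <- rnorm(tlen * 3, sd = 0.01)
  g <- rnorm(tlen); wm <- rnorm(tlen); csf <- rnorm(tlen)
  fd_quiet <- rep(0, tlen)
  d_on <- build_nuisance_design(m, fd_quiet, g, wm, csf, include_gsr = TRUE)
  expect_equal(ncol(d_on$matrix), 29)        # 2 + 24 + 0 spikes + 3
  d_off <- build_nuisance_design(m, fd_quiet, g, wm, csf, include_gsr = FALSE)
  expect_equal(ncol(d_off$matrix), 28)
  expect_error(build_nuisance_design(m, fd_quiet, g[-1], wm, csf),
               "length mismatch")
})

test_that("nuisance regression removes the design and is a projection", {
  set.seed(11)
  tlen <- 200
  m <- zero_motion(tlen)
  m$translations[] <- cumsum(rnorm(tlen * 3, sd = 0.005))
  m$rotations[] <- cumsum(rnorm(tlen * 3, sd = 5e-5))
  g <- rnorm(tlen); wm <- rnorm(tlen); csf <- rnorm(tlen)
  des <- build_nuisance_design(m, rep(0, tlen), g, wm, csf)

  # voxel 1: a design column; voxel 2: constant; rest noise
  Y <- cbind(g, rep(3, tlen), matrix(rnorm(tlen * 6), tlen, 6))
  v <- toy_vol4d(Y, c(2, 2, 2))
  res <- nuisance_regress(v, des)
  R <- t(matrix(res$data, 8, tlen))
  expect_lt(max(abs(R[, 1])), 1e-8)
  expect_lt(max(abs(R[, 2])), 1e-8)
  # residuals orthogonal to every design column
  expect_lt(max(abs(crossprod(des$matrix, R))), 1e-8)
  # projection: applying twice equals once
  res2 <- nuisance_regress(res, des)
  expect_equal(res2$data, res$data, tolerance = 1e-8)

  # known-noise recovery against a compact design: series = 2 * regressor +
  # noise, residual returns the noise (r > 0.99 at T = 200)
  small <- structure(list(matrix = cbind(constant = 1, trend = seq_len(tlen),
                                         wm = wm),
                          column_labels = c("constant", "trend", "wm")),
                     class = "nuisance_design")
  noise <- rnorm(tlen)
  vs <- toy_vol4d(cbind(2 * wm + noise, matrix(rnorm(tlen * 7), tlen, 7)),
                  c(2, 2, 2))
  Rs <- t(matrix(nuisance_regress(vs, small)$data, 8, tlen))
  # exact algebra: the regressor part lies in the design span, so the
  # residual equals the noise with its design projection removed
  expect_equal(Rs[, 1], drop(qr.resid(qr(small$matrix), noise)),
               tolerance = 1e-10)
  expect_gt(cor(Rs[, 1], noise), 0.97)
})

test_that("design = constant only demeans the series", {
  tlen <- 30
  des <- structure(list(matrix = cbind(constant = rep(1, tlen)),
                        column_labels = "constant"),
                   class = "nuisance_design")
  Y <- matrix(rnorm(tlen * 8, mean = 7), tlen, 8)
  v <- toy_vol4d(Y, c(2, 2, 2))
  R <- t(matrix(nuisance_regress(v, des)$data, 8, tlen))
  expect_equal(R, scale(Y, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("rank-deficient designs drop dependent columns with a warning", {
  tlen <- 40
  X <- cbind(constant = rep(1, tlen), trend = 1:40, dup = 2 * (1:40))
  des <- structure(list(matrix = X, column_labels = colnames(X)),
                   class = "nuisance_design")
  v <- toy_vol4d(matrix(rnorm(tlen * 8), tlen, 8), c(2, 2, 2))
  expect_warning(out <- nuisance_regress(v, des), "rank-deficient")
  R <- t(matrix(out$data, 8, tlen))
  expect_lt(max(abs(crossprod(X[, 1:2], R))), 1e-8)
})

test_that("ideal bandpass passes the band, rejects outside it, kills DC", {
  tlen <- 200; tr <- 2
  tt <- seq_len(tlen) * tr
  amp_ratio <- function(freq) {
    x <- sin(2 * pi * freq * tt)
    y <- bandpass(x, 0.01, 0.1, tr_seconds = tr)
    sqrt(sum(y^2) / sum(x^2))
  }
  expect_gte(amp_ratio(0.05), 0.95)
  expect_lte(amp_ratio(0.2), 0.05)
  expect_equal(bandpass(rep(4, tlen), 0.01, 0.1, tr_seconds = tr),
               rep(0, tlen), tolerance = 1e-10)
  # idempotence of the rectangular filter
  x <- rnorm(tlen)
  once <- bandpass(x, 0.01, 0.1, tr_seconds = tr)
  expect_equal(bandpass(once, 0.01, 0.1, tr_seconds = tr), once,
               tolerance = 1e-10)
  expect_error(bandpass(x, 0.01, 0.3, tr_seconds = tr), "Nyquist")
})
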