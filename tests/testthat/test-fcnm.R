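test_that("seed time series averages seed voxels", {
  a <- rnorm(50); b <- rnorm(50)
  Y <- cbind(a, b, matrix(rnorm(50 * 6), 50, 6))
  v <- toy_vol4d(Y, c(2, 2, 2))
  single <- brain_mask(array(c(1, rep(0, 7)), c(2, 2, 2)), v$affine)
  expect_equal(seed_timeseries(v, single), a)
  pair <- brain_mask(array(c(1, 1, rep(0, 6)), c(2, 2, 2)), v$affine)
  expect_equal(seed_timeseries(v, pair), (a + b) / 2)
  same <- toy_vol4d(cbind(a, a, Y[, 3:8]), c(2, 2, 2))
  expect_equal(seed_timeseries(same, pair), a)
  empty <- brain_mask(array(0, c(2, 2, 2)), v$affine)
  expect_error(seed_timeseries(v, empty), "empty seed")
})

test_that("Fisher z is atanh with guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "clip")
})

test_that("seed FC maps clip extreme correlations and flag flat voxels", {
  set.seed(3)
  tlen <- 200
  s <- rnorm(tlen)
  Y <- cbind(s, -s, rep(1, tlen), matrix(rnorm(tlen * 5), tlen, 5))
  v <- toy_vol4d(Y, c(2, 2, 2))
  seed <- brain_mask(array(c(1, rep(0, 7)), c(2, 2, 2)), v$affine)
  mask <- all_ones_mask(grid_template(c(2, 2, 2)))
  fc <- seed_fc_map(v, seed, mask, subject_id = "sub-01")
  z <- fc$z$data
  expect_equal(z[1], atanh(1 - 1e-7))          # self-correlation at clip
  expect_equal(z[2], -atanh(1 - 1e-7))         # anti-correlation at clip
  expect_equal(z[3], 0)                        # flat voxel flagged to 0
  expect_equal(fc$n_flagged_voxels, 1)
  # independent noise voxels stay small at T=200
  expect_lt(max(abs(tanh(z[4:8]))), 0.25)
})

test_that("group one-sample t matches hand computation and t.test", {
  tmpl <- grid_template(c(2, 2, 2))
  mk <- function(vals) vol3d(array(vals, c(2, 2, 2)), tmpl$affine)
  maps <- list(mk(rep(1, 8)), mk(rep(2, 8)), mk(rep(3, 8)))
  gt <- group_onesample_t(maps)
  expect_equal(gt$df, 2)
  expect_equal(gt$t_map$data[1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(gt$t_map$data[1], 3.4641, tolerance = 1e-4)

  sym <- group_onesample_t(list(mk(rep(-1, 8)), mk(rep(1, 8))))
  expect_equal(sym$t_map$data[3], 0)

  # degenerate: identical nonzero values across subjects
  degen <- group_onesample_t(list(mk(rep(5, 8)), mk(rep(5, 8))))
  expect_true(all(is.infinite(degen$t_map$data)))
  expect_equal(degen$p_map$data[1], 0)
  expect_equal(degen$n_degenerate_voxels, 8)

  # oracle: stats::t.test on random per-voxel samples
  set.seed(21)
  Z <- matrix(rnorm(10 * 8), 10, 8)
  maps <- lapply(seq_len(10), function(i) mk(Z[i, ]))
  gt <- group_onesample_t(maps)
  for (vx in 1:8) {
    ref <- t.test(Z[, vx])
    expect_equal(gt$t_map$data[vx], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(gt$p_map$data[vx], ref$p.value, tolerance = 1e-10)
  }
})

test_that("FDR binarization follows Benjamini-Hochberg and the positive-FC rule", {
  tmpl <- grid_template(c(3, 1, 1))
  gt <- list(t_map = vol3d(array(c(3, 3, -3), c(3, 1, 1)), tmpl$affine),
             p_map = vol3d(array(c(0.01, 0.02, 0.04), c(3, 1, 1)),
                           tmpl$affine),
             df = 9)
  class(gt) <- "group_tmap"
  m <- fdr_binarize(gt, q = 0.05, positive_only = FALSE)
  expect_equal(sum(m$data), 3)   # largest k with p_(k) <= k q / m is k = 3

  pos <- fdr_binarize(gt, q = 0.05, positive_only = TRUE)
  expect_equal(drop(pos$data), c(1, 1, 0))   # significant negative voxel excluded

  gt$p_map$data[] <- 1
  expect_equal(sum(fdr_binarize(gt, 0.05)$data), 0)
})

test_that("overlap probability counts maps and thresholding is inclusive", {
  tmpl <- grid_template(c(4, 4, 4))
  mk <- function(on) {
    a <- array(0, c(4, 4, 4)); a[on] <- 1
    brain_mask(a, tmpl$affine)
  }
  maps <- list(mk(1:10), mk(1:10), mk(5:20), mk(30:40))
  pm <- overlap_probability(maps)
  expect_equal(pm$k_contrasts, 4)
  expect_equal(pm$prob$data[1], 0.5)      # voxel in 2 of 4 maps
  expect_equal(pm$prob$data[5], 0.75)
  # prob * K is integral everywhere
  expect_true(all(abs(pm$prob$data * 4 - round(pm$prob$data * 4)) < 1e-9))

  net <- threshold_network(pm, 0.5)
  expect_equal(net$data[1], 1)            # exactly 50% is included
  net7 <- threshold_network(pm, 0.7)
  expect_true(all(net7$data <= net$data)) # antitone in tau
  expect_message(empty <- threshold_network(pm, 0.9), "empty")
  expect_equal(sum(empty$data), 0)

  single <- overlap_probability(maps[1])
  expect_equal(single$prob$data, maps[[1]]$data)
  zero <- overlap_probability(list(mk(integer(0)), mk(integer(0))))
  expect_true(all(zero$prob$data == 0))
})

test_that("removing a contrast changes K but never yields probability > 1", {
  tmpl <- grid_template(c(4, 4, 4))
  set.seed(5)
  maps <- lapply(1:5, function(i) {
    a <- array(rbinom(64, 1, 0.3), c(4, 4, 4))
    brain_mask(a, tmpl$affine)
  })
  for (k in 5:2) {
    pm <- overlap_probability(maps[seq_len(k)])
    expect_equal(pm$k_contrasts, k)
    expect_lte(max(pm$prob$data), 1)
  }
})
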