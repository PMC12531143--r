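test_that("cohorts are bit-reproducible functions of their seed", {
  spec <- tiny_cohort_spec(rng_seed = 17, n_subjects = 2, n_volumes = 40)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$subjects[[1]]$bold$data, b$subjects[[1]]$bold$data)
  expect_identical(a$subjects[[2]]$motion, b$subjects[[2]]$motion)
  expect_identical(a$gm_mask$data, b$gm_mask$data)
  c <- simulate_cohort(tiny_cohort_spec(rng_seed = 18, n_subjects = 2,
                                        n_volumes = 40))
  expect_false(identical(a$subjects[[1]]$bold$data,
                         c$subjects[[1]]$bold$data))
})

test_that("within-network correlation matches the w^2/(w^2+s^2) closed form", {
  spec <- cohort_spec(n_subjects = 4, n_volumes = 200,
                      grid_shape = c(14, 16, 14),
                      networks = list(planted_network(
                        component_centers = rbind(c(-9, -9, 0), c(9, 9, 0)),
                        component_radius_mm = 7,
                        loading_w = 1, noise_sd = 1)),
                      rng_seed = 33)
  co <- simulate_cohort(spec)
  net_idx <- which(co$truth_masks[[1]]$data == 1)
  gm_idx <- which(co$gm_mask$data == 1)
  bg_idx <- setdiff(gm_idx, net_idx)
  rs_net <- c(); rs_bg <- c()
  set.seed(1)
  for (subj in co$subjects) {
    flat <- matrix(subj$bold$data, prod(dim(co$gm_mask$data)), 200)
    pick <- sample(net_idx, 30)
    M <- t(flat[pick, ])
    cm <- cor(M)
    rs_net <- c(rs_net, cm[upper.tri(cm)])
    pickb <- sample(bg_idx, 30)
    cb <- cor(t(flat[pickb, ]))
    rs_bg <- c(rs_bg, cb[upper.tri(cb)])
  }
  expect_equal(mean(rs_net), 0.5, tolerance = 0.05)   # 1 / (1 + 1)
  # null |r| at T = 200 has E|r| = sqrt(2 / (pi T)) ~ 0.056
  expect_lt(mean(abs(rs_bg)), 0.07)
  expect_lt(abs(mean(rs_bg)), 0.02)
})

test_that("simulated motion exercises FD spikes exactly as injected", {
  m0 <- simulate_motion(50, base_sd = 0)
  expect_equal(framewise_displacement(m0), rep(0, 50))

  set.seed(8)
  m1 <- simulate_motion(60, spike_frames = 30, base_sd = 0)
  fd <- framewise_displacement(m1)
  expect_equal(which(fd > 0.5), 30L)

  m2 <- simulate_motion(60, spike_frames = c(20, 40), base_sd = 0.005)
  s <- spike_regressors(framewise_displacement(m2))
  expect_equal(ncol(s), 2)
})

test_that("synthetic foci respect counts, fractions and jitter", {
  spec <- tiny_cohort_spec()
  co <- simulate_cohort(spec)
  truth <- co$truth_masks[[1]]

  st <- study_spec(n_studies = 5, contrasts_per_study = 2,
                   foci_per_contrast = 3, in_network_fraction = 1,
                   jitter_sd_mm = 0, rng_seed = 2)
  foci <- simulate_study_foci(truth, st, co$gm_mask)
  expect_equal(nrow(foci), 5 * 2 * 3)
  expect_equal(dplyr::n_distinct(foci$study_id), 5)
  part <- filter_coords_in_mask(as.matrix(foci[, c("x", "y", "z")]), truth)
  expect_equal(nrow(part$dropped), 0)   # jitter 0, fraction 1: all in truth

  # heavy jitter pushes a positive fraction of foci outside gray matter
  stj <- study_spec(n_studies = 10, foci_per_contrast = 5,
                    jitter_sd_mm = 6, rng_seed = 3)
  focij <- simulate_study_foci(truth, stj, co$gm_mask)
  pj <- filter_coords_in_mask(as.matrix(focij[, c("x", "y", "z")]),
                              co$gm_mask)
  expect_gt(nrow(pj$dropped), 0)

  # schema is accepted downstream
  seeds <- suppressMessages(build_contrast_seeds(foci, co$gm_mask, 4))
  expect_equal(sum(vapply(seeds, function(s)
    s$n_foci_used + s$n_foci_dropped, numeric(1))), nrow(foci))
})

test_that("receptor maps hit their target Spearman correlations", {
  net <- tibble::tibble(parcel_id = 1:100, value = rnorm(100))
  rm1 <- simulate_receptor_maps(net, c(perfect = 1), rng_seed = 1)
  expect_equal(cor(net$value, rm1$perfect, method = "spearman"), 1)

  # null maps stay small
  set.seed(6)
  r0 <- replicate(30, {
    rm <- simulate_receptor_maps(net, c(x = 0),
                                 rng_seed = sample.int(1e6, 1))
    cor(net$value, rm$x, method = "spearman")
  })
  expect_lt(mean(abs(r0) < 0.2), 1.01)  # sanity bound
  expect_gt(mean(abs(r0) < 0.2), 0.85)

  # recovery curve is monotone in the planted rho
  rhos <- c(0, 0.2, 0.4, 0.8)
  rec <- vapply(rhos, function(rho) {
    mean(vapply(1:25, function(i) {
      rm <- simulate_receptor_maps(net, c(x = rho), rng_seed = 1000 + i)
      cor(net$value, rm$x, method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_equal(rec[3], 0.4, tolerance = 0.1)
  expect_equal(rec[1], 0, tolerance = 0.1)
  # negative targets recover with sign
  recn <- mean(vapply(1:25, function(i) {
    rm <- simulate_receptor_maps(net, c(x = -0.4), rng_seed = 2000 + i)
    cor(net$value, rm$x, method = "spearman")
  }, numeric(1)))
  expect_equal(recn, -0.4, tolerance = 0.1)
})

test_that("Voronoi atlases label every name and tile the mask", {
  spec <- tiny_cohort_spec()
  co <- simulate_cohort(spec)
  atlas <- simulate_label_atlas(co$gm_mask, n_labels = 8, rng_seed = 5)
  expect_length(atlas$names, 8)
  expect_setequal(unique(as.vector(atlas$labels$data[co$gm_mask$data == 1])),
                  1:8)
  expect_true(all(atlas$labels$data[co$gm_mask$data == 0] == 0))
  expect_true("frontoparietal" %in% atlas$names)
})

test_that("a planted network inside one label dominates that label's overlap", {
  spec <- tiny_cohort_spec()
  co <- simulate_cohort(spec)
  atlas <- simulate_label_atlas(co$gm_mask, n_labels = 4, rng_seed = 11)
  # plant the "network" entirely inside label 2
  inlab <- which(atlas$labels$data == 2)
  net <- array(0, dim(co$gm_mask$data))
  net[sample(inlab, min(50, length(inlab)))] <- 1
  rep <- overlap_proportions(brain_mask(net, co$gm_mask$affine), atlas)
  expect_equal(which.max(rep$proportion_pct), 2L)
})
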