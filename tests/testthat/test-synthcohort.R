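test_that("cohort generation respects sizes, duration and determinism", {
  coh <- generate_cohort(n_low = 3, n_high = 4, n_rois = 6, fs = 250,
                         duration_s = 2, order = 2, seed = 5)
  expect_length(coh$subjects, 7)
  expect_equal(sum(coh$groups == "low"), 3)
  expect_equal(sum(coh$groups == "high"), 4)
  expect_equal(ncol(coh$subjects[[1]]$data), 500)  # fs * duration
  coh2 <- generate_cohort(n_low = 3, n_high = 4, n_rois = 6, fs = 250,
                          duration_s = 2, order = 2, seed = 5)
  expect_identical(coh$subjects[[5]]$data, coh2$subjects[[5]]$data)
  # per-subject noise realisations differ
  expect_false(identical(coh$subjects[[1]]$data, coh$subjects[[2]]$data))
  expect_error(generate_cohort(n_low = 1, n_high = 3, n_rois = 4))
})

test_that("high-group model attenuates only the profiled couplings", {
  atlas <- synthetic_atlas(6)
  bt <- default_band_targets(which(atlas$cluster == "frontal"),
                             which(atlas$cluster == "posterior"),
                             slow_bands = "theta", fast_bands = "gamma")
  coh <- generate_cohort(n_low = 2, n_high = 2, n_rois = 6, fs = 250,
                         duration_s = 2, band_targets = bt, atlas = atlas,
                         effect_profile = default_effect_profile(0.7, "theta"),
                         order = 2, seed = 3)
  lo <- coh$models$low
  hi <- coh$models$high
  th <- bt[bt$band == "theta", ]
  gm <- bt[bt$band == "gamma", ]
  for (k in seq_len(nrow(th))) {
    expect_equal(hi$coeff[th$target[k], th$source[k], 1],
                 0.7 * lo$coeff[th$target[k], th$source[k], 1])
  }
  for (k in seq_len(nrow(gm))) {
    expect_equal(hi$coeff[gm$target[k], gm$source[k], 1],
                 lo$coeff[gm$target[k], gm$source[k], 1])
  }
  expect_identical(lo$noise_cov, hi$noise_cov)
})

test_that("analytic GC is exactly zero without direct or indirect paths", {
  m <- make_var_model(4, NULL, seed = 2, fs = 250)
  or <- analytic_spectral_gc(m, seq(0, 125, by = 1))
  expect_equal(max(abs(or$gc)), 0)
  # unidirectional coupling: no reverse causality at any frequency
  bt <- data.frame(source = 1, target = 2, f0 = 10, bw = 3,
                   gain = 0.02, band = "alpha")
  m2 <- make_var_model(2, bt, seed = 2, fs = 250)
  or2 <- analytic_spectral_gc(m2, seq(0, 125, by = 0.5))
  expect_equal(max(or2$gc[2, 1, ]), 0)
  expect_gt(max(or2$gc[1, 2, ]), 0.1)
})

test_that("oscillatory coupling peaks at the planted frequency", {
  freq <- seq(0, 125, by = 0.1)
  for (f0 in c(10, 22)) {
    bt <- data.frame(source = 1, target = 2, f0 = f0, bw = 3,
                     gain = 0.02, band = "x")
    m <- make_var_model(2, bt, seed = 1, fs = 250)
    or <- analytic_spectral_gc(m, freq)
    expect_lt(abs(freq[which.max(or$gc[1, 2, ])] - f0), 1)
  }
})

test_that("analytic spectral GC integrates to analytic time-domain GC", {
  bt <- data.frame(source = 1, target = 2, f0 = 10, bw = 4,
                   gain = 0.02, band = "alpha")
  m <- make_var_model(2, bt, seed = 6, fs = 250)
  lam <- seq(0, pi, by = 0.01)
  or <- analytic_spectral_gc(m, lam * m$fs / (2 * pi))
  g <- or$gc[1, 2, ]
  integ <- sum(diff(lam) * (g[-1] + g[-length(g)]) / 2) / pi
  td <- analytic_time_gc(m)
  expect_lt(abs(integ - td$gc_12) / td$gc_12, 0.01)
})

test_that("multi-region marginal oracle agrees with direct 2-region truth", {
  # embed an isolated coupled pair in a larger independent system: the
  # pairwise marginal equals the 2-region model, so the Yule-Walker
  # reduction must reproduce the exact bivariate answer
  bt <- data.frame(source = 1, target = 2, f0 = 10, bw = 3,
                   gain = 0.02, band = "alpha")
  m2 <- make_var_model(2, bt, seed = 4, fs = 250)
  m4 <- make_var_model(4, bt, seed = 4, fs = 250)
  freq <- seq(0, 125, by = 2.5)
  or2 <- analytic_spectral_gc(m2, freq)
  or4 <- analytic_spectral_gc(m4, freq, marginal_order = 150)
  expect_equal(or4$gc[1, 2, ], or2$gc[1, 2, ], tolerance = 1e-6)
})

test_that("cohort TSV round trip preserves data and metadata", {
  coh <- demo_cohort(seed = 2, n_low = 2, n_high = 2)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "model_spec.json")))
  back <- read_cohort(dir)
  expect_equal(back$fs, coh$fs)
  expect_identical(as.character(back$groups), as.character(coh$groups))
  expect_equal(back$subjects[[3]]$data, coh$subjects[[3]]$data,
               tolerance = 1e-12)
  expect_equal(back$roi_labels, coh$roi_labels)
})
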