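test_that("frequency grid matches the acquisition conventions", {
  g <- gc_freq_grid(500, 0.1)
  expect_equal(length(g), 2501)
  expect_equal(g[1], 0)
  expect_equal(g[length(g)], 250)
  expect_equal(length(gc_freq_grid(250, 0.5)), 251)
})

test_that("least-squares fit recovers a known stable VAR(2)", {
  set.seed(31)
  coeff <- random_stable_bivar(order = 2)
  m <- as_var_spec(coeff)
  ts <- simulate_var(m, 60000, seed = 13)
  fit <- fit_var(ts$data[1, ], ts$data[2, ], p = 2, fs = 250)
  expect_equal(fit$coeff, coeff, tolerance = 0.02)
  expect_equal(fit$noise_cov, diag(2), tolerance = 0.02)
  ev <- eigen(fit$noise_cov, only.values = TRUE)$values
  expect_true(all(ev >= -1e-10))
})

test_that("independent white-noise series fit to null coefficients", {
  set.seed(32)
  m <- as_var_spec(array(0, dim = c(2, 2, 1)))
  ts <- simulate_var(m, 60000, seed = 14)
  fit <- fit_var(ts$data[1, ], ts$data[2, ], p = 3, fs = 250)
  expect_lt(max(abs(fit$coeff)), 0.03)
  expect_lt(abs(fit$noise_cov[1, 2]), 0.03)
})

test_that("constant series raise a degenerate-input error", {
  expect_error(fit_var(rep(1, 500), rnorm(500), p = 2), "degenerate")
})

test_that("white-noise model has identity spectrum and transfer", {
  fit <- structure(list(order = 2, coeff = array(0, dim = c(2, 2, 2)),
                        noise_cov = diag(2), fs = 500, pair = c(1, 2),
                        reduced_var = c(i = 1, j = 1)),
                   class = "bivar_var")
  sf <- spectral_factors(fit, c(0, 10, 100, 250))
  for (k in 1:4) {
    expect_equal(sf$H[, , k], diag(2) + 0i)
    expect_equal(sf$S[, , k], diag(2) + 0i)
  }
})

test_that("AR(1) embedding reproduces the closed-form power spectrum", {
  coeff <- array(0, dim = c(2, 2, 1))
  coeff[1, 1, 1] <- 0.5
  fit <- structure(list(order = 1, coeff = coeff, noise_cov = diag(2),
                        fs = 500, pair = c(1, 2),
                        reduced_var = c(i = 1, j = 1)),
                   class = "bivar_var")
  freq <- c(0, 50, 125, 250)
  sf <- spectral_factors(fit, freq)
  s11 <- Re(sf$S[1, 1, ])
  expected <- 1 / Mod(1 - 0.5 * exp(-2i * pi * freq / 500))^2
  expect_equal(s11, expected, tolerance = 1e-12)
  expect_equal(s11[1], 4.0)
  # diagonal real and positive for a random stable fit
  set.seed(33)
  m <- as_var_spec(random_stable_bivar(2))
  ts <- simulate_var(m, 5000, seed = 5)
  f2 <- fit_var(ts$data[1, ], ts$data[2, ], p = 5, fs = 250)
  sf2 <- spectral_factors(f2, seq(0, 125, by = 5))
  expect_true(all(Re(sf2$S[1, 1, ]) > 0))
  expect_true(all(Re(sf2$S[2, 2, ]) > 0))
  expect_true(all(abs(Im(sf2$S[1, 1, ])) < 1e-12))
})

test_that("unidirectional coupling leaves the reverse direction near zero", {
  bt <- data.frame(source = 1, target = 2, f0 = 10, bw = 3,
                   gain = 0.02, band = "alpha")
  m <- make_var_model(2, bt, seed = 11, fs = 250)
  ts <- simulate_var(m, 60000, seed = 21)
  fit <- fit_var(ts$data[1, ], ts$data[2, ], p = 30, fs = 250)
  sp <- spectral_gc_pair(fit, gc_freq_grid(250, 0.1))
  expect_true(all(sp$gc_ij >= 0))
  expect_true(all(sp$gc_ji >= 0))
  expect_lt(max(sp$gc_ji), 0.01)
  expect_gt(max(sp$gc_ij), 0.5)
})

test_that("band-averaged GC is stable between order 30 and order 40", {
  bt <- data.frame(source = 1, target = 2, f0 = 10, bw = 3,
                   gain = 0.02, band = "alpha")
  m <- make_var_model(2, bt, seed = 12, fs = 250)
  ts <- simulate_var(m, 60000, seed = 22)
  grid <- gc_freq_grid(250, 0.1)
  bands <- default_bands()
  fit30 <- fit_var(ts$data[1, ], ts$data[2, ], p = 30, fs = 250)
  fit40 <- fit_var(ts$data[1, ], ts$data[2, ], p = 40, fs = 250)
  g30 <- spectral_gc_pair(fit30, grid)$gc_ij
  g40 <- spectral_gc_pair(fit40, grid)$gc_ij
  sel <- grid >= bands$alpha[1] & grid <= bands$alpha[2]
  expect_lt(abs(mean(g30[sel]) - mean(g40[sel])) / mean(g30[sel]), 0.15)
})

test_that("Geweke integral identity links spectral and time-domain GC", {
  set.seed(34)
  n_checked <- 0
  for (rep in 1:8) {
    m <- as_var_spec(random_stable_bivar(2))
    ts <- simulate_var(m, 30000, seed = rep)
    fit <- fit_var(ts$data[1, ], ts$data[2, ], p = 20, fs = 250)
    td <- time_domain_gc(fit)
    if (td$instantaneous >= 0.01) next
    lam <- seq(0, pi, by = 0.01)
    sp <- spectral_gc_pair(fit, lam * fit$fs / (2 * pi))
    integ <- sum(diff(lam) * (sp$gc_ij[-1] + sp$gc_ij[-length(lam)]) / 2) / pi
    if (td$gc_ij > 0.01) {
      expect_lt(abs(integ - td$gc_ij) / td$gc_ij, 0.02)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 2)
})

test_that("GC is invariant to positive rescaling of the data", {
  set.seed(35)
  m <- as_var_spec(random_stable_bivar(2))
  ts <- simulate_var(m, 20000, seed = 3)
  grid <- seq(0, 125, by = 1)
  f1 <- fit_var(ts$data[1, ], ts$data[2, ], p = 10, fs = 250)
  f2 <- fit_var(37.5 * ts$data[1, ], 37.5 * ts$data[2, ], p = 10, fs = 250)
  g1 <- spectral_gc_pair(f1, grid)
  g2 <- spectral_gc_pair(f2, grid)
  expect_equal(g1$gc_ij, g2$gc_ij, tolerance = 1e-8)
  expect_equal(g1$gc_ji, g2$gc_ji, tolerance = 1e-8)
})

test_that("all-pairs connectivity has zero diagonal and both directions", {
  atlas <- synthetic_atlas(3, n_frontal = 1, n_posterior = 1)
  bt <- data.frame(source = c(1, 2), target = c(2, 3), f0 = 10, bw = 3,
                   gain = c(0.02, 0.1), band = "alpha")
  m <- make_var_model(3, bt, seed = 2, fs = 250)
  ts <- simulate_var(m, 20000, seed = 6)
  conn <- connectivity_matrices(ts, p = 15, freq_resolution = 0.5)
  expect_equal(dim(conn$gc), c(3, 3, length(gc_freq_grid(250, 0.5))))
  expect_true(all(conn$gc[cbind(1:3, 1:3, 1)] == 0))
  expect_true(all(conn$gc >= 0, na.rm = TRUE))
  # chain topology: forward links dominate the absent reverse link
  tot <- apply(conn$gc, c(1, 2), sum)
  expect_gt(tot[1, 2], 5 * tot[3, 1])
  expect_gt(tot[2, 3], 5 * tot[3, 1])
})

test_that("whole-subject fits agree with standalone pair fits", {
  atlas <- synthetic_atlas(4, n_frontal = 1, n_posterior = 1)
  m <- make_var_model(4, NULL, seed = 8, fs = 250)
  ts <- simulate_var(m, 5000, seed = 4)
  conn <- connectivity_matrices(ts, p = 5, freq_resolution = 1)
  x <- t(scale(t(ts$data), center = TRUE, scale = FALSE))
  fit <- fit_var(ts$data[2, ], ts$data[4, ], p = 5, fs = 250)
  sp <- spectral_gc_pair(fit, conn$freq_grid)
  expect_equal(conn$gc[2, 4, ], sp$gc_ij, tolerance = 1e-10)
  expect_equal(conn$gc[4, 2, ], sp$gc_ji, tolerance = 1e-10)
})

test_that("band averaging respects inclusive edges and grid counts", {
  freq <- gc_freq_grid(500, 0.1)
  gc <- array(0, dim = c(2, 2, length(freq)))
  gc[1, 2, ] <- 1.5  # constant spectrum
  gc[2, 1, ] <- freq # identity in f
  conn <- structure(list(subject_id = "s", gc = gc, freq_grid = freq,
                         roi_labels = c("a", "b"), n_clamped = 0L,
                         failed_pairs = list()),
                    class = "spectral_connectivity")
  bc <- band_average(conn)
  expect_named(bc$bands, c("theta", "alpha", "beta", "gamma"))
  for (b in names(bc$bands)) expect_equal(bc$bands[[b]][1, 2], 1.5)
  # theta = mean of the 41 grid points 4.0, 4.1, ..., 8.0
  expect_equal(bc$bands$theta[2, 1], mean(seq(4, 8, by = 0.1)))
  expect_equal(bc$bands$gamma[2, 1], mean(seq(30, 40, by = 0.1)))
  expect_error(band_average(conn, list(empty = c(10.05, 10.06))),
               "no grid point")
})
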