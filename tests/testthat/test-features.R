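test_that("DCT matches closed forms and the brute-force oracle", {
  expect_equal(dct_ii(rep(0, 100)), rep(0, 100))

  # constant input: only the DC coefficient survives, v(0) = 10 for ones
  v <- dct_ii(rep(1, 100))
  expect_equal(v[1], 10)
  expect_equal(v[-1], rep(0, 99), tolerance = 1e-12)
  vl <- dct_ii(rep(1, 100), alpha = "literal")
  expect_equal(vl[1], 10)
  expect_equal(vl[-1], rep(0, 99), tolerance = 1e-12)

  set.seed(31)
  for (rep in 1:5) {
    u <- rnorm(100)
    expect_equal(dct_ii(u), dct_oracle(u), tolerance = 1e-9)
    expect_equal(dct_ii(u, "literal"), dct_oracle(u, "literal"),
                 tolerance = 1e-9)
  }
  u7 <- rnorm(7)
  expect_equal(dct_ii(u7), dct_oracle(u7), tolerance = 1e-9)
  expect_error(dct_ii(numeric(0)), "non-empty")
})

test_that("orthonormal DCT preserves energy; the literal variant does not", {
  set.seed(32)
  for (rep in 1:10) {
    u <- rnorm(100)
    expect_equal(sum(dct_ii(u)^2), sum(u^2), tolerance = 1e-9)
  }
  u <- rnorm(100)
  expect_gt(abs(sum(dct_ii(u, "literal")^2) - sum(u^2)), 1e-3)
})

test_that("dct_features zero-pads at the tail to 100 coefficients", {
  sp <- small_spikes()
  fm <- dct_features(sp)
  expect_identical(ncol(fm$values), 100L)
  expect_identical(nrow(fm$values), nrow(sp$waveforms))
  expect_identical(fm$kind, "dct")
  expect_identical(fm$labels, sp$labels)

  # any row equals the DCT of the explicitly padded vector
  padded <- c(sp$waveforms[3, ], rep(0, 40))
  expect_equal(fm$values[3, ], dct_ii(padded), tolerance = 1e-9,
               ignore_attr = TRUE)

  # a zero row maps to zero features
  z <- spike_set(matrix(0, 1, 60), fs = 20000, pre_ms = 1, post_ms = 2)
  expect_equal(dct_features(z)$values[1, ], rep(0, 100),
               ignore_attr = TRUE)

  long <- spike_set(matrix(0, 1, 120), fs = 40000, pre_ms = 1, post_ms = 2)
  expect_error(dct_features(long, n_coeff = 100), "longer than")
})

test_that("AP shape features recover the analytic triangle geometry", {
  f <- ap_shape_features(triangle_spike_set())$values[1, ]
  # 60 mV over 1 ms each side: slope 60 V/s, widths scale linearly
  expect_equal(f[["apt_mv"]], -60, tolerance = 0.05)
  expect_equal(f[["apd_ms"]], 1.0, tolerance = 0.01)
  expect_equal(f[["rt_ms"]], 0.8, tolerance = 0.01)
  expect_equal(f[["ft_ms"]], 0.8, tolerance = 0.01)
  expect_equal(f[["rr_v_per_s"]], 60, tolerance = 0.1)
  expect_equal(f[["fr_v_per_s"]], 60, tolerance = 0.1)
  expect_equal(f[["ahp_mv"]], 0)
})

test_that("AP duration matches the Gaussian full width at half maximum", {
  fs <- 20000
  sigma_ms <- 0.25
  idx <- seq_len(60) - 21
  v <- -70 + 60 * exp(-(idx * 1000 / fs)^2 / (2 * sigma_ms^2))
  sp <- spike_set(matrix(v, 1), fs = fs, pre_ms = 1, post_ms = 2)
  f <- ap_shape_features(sp)$values[1, ]
  fwhm <- 2 * sqrt(2 * log(2)) * sigma_ms
  expect_lt(abs(f[["apd_ms"]] - fwhm), 0.02 * fwhm)
})

test_that("an undershoot below threshold is read as the AHP depth", {
  sp <- triangle_spike_set()
  v <- sp$waveforms[1, ]
  v[45:60] <- -65                      # 5 mV below the -60 mV threshold
  sp$waveforms[1, ] <- v
  f <- ap_shape_features(sp)$values[1, ]
  expect_equal(f[["ahp_mv"]], 5, tolerance = 0.05)
})

test_that("shape features are offset-invariant except the threshold", {
  sp <- small_spikes()
  f0 <- ap_shape_features(sp)$values
  sp2 <- sp
  sp2$waveforms <- sp$waveforms + 12.5
  f1 <- ap_shape_features(sp2)$values
  diffcols <- c("apd_ms", "ahp_mv", "rt_ms", "ft_ms", "rr_v_per_s",
                "fr_v_per_s")
  expect_equal(f1[, diffcols], f0[, diffcols], tolerance = 1e-9)
  expect_equal(f1[, "apt_mv"], f0[, "apt_mv"] + 12.5, tolerance = 1e-9)
})

test_that("spikes without a dV/dt crossing are reported and dropped", {
  flat <- spike_set(matrix(rep(c(-60, -59.9), 30), 1, 60, byrow = TRUE),
                    fs = 20000, pre_ms = 1, post_ms = 2)
  expect_error(ap_shape_features(flat), "no spike yielded")
  both <- spike_set(rbind(triangle_spike_set()$waveforms,
                          rep(-60, 60) + rep(c(0, 0.01), 30)),
                    fs = 20000, pre_ms = 1, post_ms = 2)
  expect_warning(f <- ap_shape_features(both), "dropped")
  expect_identical(nrow(f$values), 1L)
})

test_that("correlation PCA retains by CPV with a deterministic sign", {
  # exact rank-1 correlation: one component explains everything
  set.seed(41)
  x1 <- rnorm(50)
  p1 <- suppressWarnings(fit_pca(cbind(x1, 2 * x1)))
  expect_identical(p1$q, 1L)
  expect_equal(p1$explained_ratio, 1.0, tolerance = 1e-12)

  x <- matrix(rnorm(2000), 200, 10)
  p <- fit_pca(x, cpv = 0.90)
  expect_equal(sum(p$eigenvalues), 10, tolerance = 1e-9)
  expect_true(all(diff(p$explained_ratio) <= 1e-12))
  expect_identical(p$q, which(cumsum(p$eigenvalues / 10) >= 0.9)[1])
  # orthonormal loadings with positive largest-magnitude entry
  expect_equal(crossprod(p$components), diag(p$q), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in seq_len(p$q))
    expect_gt(p$components[which.max(abs(p$components[, j])), j], 0)
  # override wins over the CPV rule
  expect_identical(fit_pca(x, n_components = 7)$q, 7L)
  expect_error(fit_pca(x[1, , drop = FALSE]), "at least 2 rows")
})

test_that("PCA agrees with prcomp as an independent eigendecomposition", {
  set.seed(42)
  x <- matrix(rnorm(2000), 200, 10) %*% diag(sqrt(1:10))
  p <- fit_pca(x, n_components = 10)
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  expect_equal(p$eigenvalues, pr$sdev^2, tolerance = 1e-8)
  for (j in 1:10) {
    v <- pr$rotation[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(p$components[, j], v, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("projection uses stored parameters and centers training data", {
  set.seed(43)
  x <- matrix(rnorm(600), 100, 6)
  p <- fit_pca(x, cpv = 0.90)
  s <- apply_pca(p, x)
  expect_identical(s$kind, "pc_scores")
  expect_equal(colMeans(s$values), rep(0, p$q), tolerance = 1e-9,
               ignore_attr = TRUE)
  # the training mean maps to the origin
  expect_equal(apply_pca(p, matrix(p$center, 1))$values[1, ],
               rep(0, p$q), tolerance = 1e-9, ignore_attr = TRUE)
  # new data: plain matrix product with the standardized input
  y <- matrix(rnorm(60), 10, 6)
  z <- sweep(sweep(y, 2, p$center), 2, p$scale, "/")
  expect_equal(apply_pca(p, y)$values, z %*% p$components,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(apply_pca(p, y[, 1:3]), "dimension")
})

test_that("rank-1 training scores carry the captured correlation variance", {
  set.seed(44)
  x1 <- rnorm(300)
  p <- suppressWarnings(fit_pca(cbind(x1, 2 * x1)))
  s <- apply_pca(p, cbind(x1, 2 * x1))
  expect_equal(stats::var(s$values[, 1]), 2, tolerance = 1e-9)
})
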