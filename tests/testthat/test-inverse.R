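test_that("noise covariance shrinks toward the scaled identity", {
  e <- noise_epochs(seed = 1, n_trials = 20, n_channels = 8, n_times = 300,
                    sd = 1)
  nc <- estimate_noise_cov(e, c(-299, 0))
  expect_true(all(abs(diag(nc$cov) - 1) < 0.1))
  expect_identical(nc$cov, t(nc$cov))
  expect_true(all(eigen(nc$cov, symmetric = TRUE)$values > 0))
  # two perfectly correlated channels: off/diag ratio strictly below 1
  e2 <- noise_epochs(seed = 2, n_trials = 10, n_channels = 8)
  e2$data[, 2, ] <- e2$data[, 1, ]
  nc2 <- estimate_noise_cov(e2, c(-299, 0))
  expect_lt(nc2$cov[1, 2] / nc2$cov[1, 1], 1)
  expect_gt(nc2$shrinkage, 0)
})

test_that("the inverse kernel matches the dense oracle to 1e-10", {
  for (s in 1:20) {
    set.seed(s)
    nch <- sample(6:16, 1)
    nsrc <- sample(4:24, 1)
    g <- matrix(rnorm(nch * nsrc), nch, nsrc)
    cv <- random_spd(nch)
    lambda2 <- runif(1, 0.05, 0.5)
    sm <- source_model(g, rep(1, nsrc), regions = "only", stim_region = 1)
    inv <- compute_inverse(sm, cv, lambda2)
    ora <- dense_inverse_oracle(g, cv, lambda2)
    expect_lt(max(abs(inv$kernel - ora$kernel)), 1e-10)
    expect_lt(max(abs(inv$norm - ora$norm)), 1e-10)
  }
})

test_that("a single-sensor single-source system returns the input", {
  sm <- source_model(matrix(1, 1, 1), 1L, regions = "r", stim_region = 1)
  # 2-channel minimal case (1 channel breaks the average reference idea but
  # the closed form still holds for the kernel): use the 1x1 algebra
  inv <- compute_inverse(sm, matrix(1, 1, 1), lambda2 = 0.3)
  x <- matrix(seq(-2, 2, by = 0.5), 1)
  z <- apply_dspm(inv, x)
  expect_equal(as.numeric(z), as.numeric(x))
})

test_that("rescaling C or G acts on dSPM only through the normalization", {
  set.seed(5)
  g <- matrix(rnorm(10 * 6), 10, 6)
  cv <- random_spd(10)
  sm <- source_model(g, rep(1:2, each = 3), regions = c("a", "b"),
                     stim_region = 1)
  x <- matrix(rnorm(10 * 7), 10, 7)
  inv1 <- compute_inverse(sm, cv, 1/9)
  inv2 <- compute_inverse(sm, 4 * cv, 1/9)
  # the kernel is invariant to a global rescaling of C ...
  expect_equal(inv1$kernel, inv2$kernel, tolerance = 1e-12)
  # ... so z changes only through the noise normalization: claiming 4x the
  # noise power halves the z-values
  expect_equal(apply_dspm(inv2, x), apply_dspm(inv1, x) / 2,
               tolerance = 1e-12)
  # and z is fully invariant to a global rescaling of the leadfield
  sm2 <- source_model(3 * g, rep(1:2, each = 3), regions = c("a", "b"),
                      stim_region = 1)
  z3 <- apply_dspm(compute_inverse(sm2, cv, 1/9), x)
  expect_equal(apply_dspm(inv1, x), z3, tolerance = 1e-12)
})

test_that("dSPM localizes a single active source", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    g <- icfmap:::make_leadfield(20, 10)
    cv <- icfmap:::make_sensor_correlation(20)
    sm <- source_model(g, 1:10, regions = sprintf("R%02d", 1:10),
                       stim_region = 1)
    src <- sample(10, 1)
    x <- g[, src] %o% rep(10, 5) +
      t(chol(cv)) %*% matrix(rnorm(20 * 5, sd = 0.2), 20)
    z <- apply_dspm(compute_inverse(sm, cv), x)
    which.max(rowMeans(abs(z))) == src
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("dSPM of pure baseline noise has near-unit variance per source", {
  cfg <- desk_config(seed = 21, planted_effect_d = 0, n_trd = 2, n_hc = 1)
  ds <- generate_tep_dataset(cfg)
  pair <- ds$epochs[[1]]
  ncov <- estimate_noise_cov(pair$single, c(-350, -20))
  inv <- compute_inverse(ds$source_model, ncov)
  # project single-trial baseline segments (noise only, t < -20 ms)
  bl_idx <- which(pair$single$times < -20)
  zvar <- numeric(0)
  for (tr in seq_len(4)) {
    z <- apply_dspm(inv, pair$single$data[tr, , bl_idx])
    zvar <- cbind(zvar, apply(z, 1, var))
  }
  expect_true(all(rowMeans(zvar) > 0.5 & rowMeans(zvar) < 2))
})

test_that("region extraction is a group-by mean", {
  set.seed(6)
  z <- matrix(rnorm(12 * 9), 12, 9)
  sm <- source_model(matrix(rnorm(5 * 12), 5, 12), rep(1:4, each = 3),
                     regions = c("w", "x", "y", "z"), stim_region = 1)
  rs <- extract_region_series(z, sm)
  for (r in 1:4) {
    expect_equal(unname(rs[r, ]),
                 colMeans(z[sm$source_region == r, , drop = FALSE]))
  }
  # permutation of the sources leaves the result unchanged
  perm <- sample(12)
  sm2 <- source_model(sm$leadfield[, perm], sm$source_region[perm],
                      regions = sm$regions, stim_region = 1)
  expect_equal(extract_region_series(z[perm, , drop = FALSE], sm2), rs,
               ignore_attr = TRUE)
  # constant region value passes through
  z2 <- matrix(2, 12, 9)
  expect_equal(unname(extract_region_series(z2, sm)[2, ]), rep(2, 9))
})

test_that("the windowed region contrast is consistent across modules", {
  tt <- seq(-100, 300, by = 4)
  set.seed(7)
  a <- matrix(rnorm(3 * length(tt)), 3); attr(a, "times") <- tt
  b <- matrix(rnorm(3 * length(tt)), 3); attr(b, "times") <- tt
  v <- icf_dspm(a, b)
  for (r in 1:3) {
    sa <- structure(a[r, ], times = tt); sb <- structure(b[r, ], times = tt)
    expect_equal(unname(v[r]), window_mean(icf_contrast(sa, sb)))
  }
  expect_equal(unname(icf_dspm(a, a)), rep(0, 3))
  expect_equal(unname(icf_dspm(a + 1, a)), rep(1, 3))
})
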