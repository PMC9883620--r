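test_that("copula transform matches closed-form normal quantiles", {
  z <- copula_gauss(c(5, 2, 9))
  expect_equal(z, qnorm(c(0.5, 1 / 6, 5 / 6)), tolerance = 1e-10)
  expect_equal(z[1], 0)
  expect_equal(z[2], -0.9674216, tolerance = 1e-6)

  x <- sort(rnorm(50))
  expect_false(is.unsorted(copula_gauss(x)))
  set.seed(1)
  x <- rnorm(200)
  expect_equal(copula_gauss(exp(x)), copula_gauss(x), tolerance = 1e-14)
  expect_error(copula_gauss(rep(1, 20)), "constant")
})

test_that("Gaussian MI matches an independent brute-force oracle", {
  set.seed(2)
  for (rep in 1:5) {
    n <- 400
    x <- rnorm(n)
    Y <- cbind(0.5 * x + rnorm(n), rnorm(n))
    got <- mi_gaussian_bits(x, Y, bias_correct = FALSE)
    want <- oracle_gauss_mi_bits(x, Y)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("bias-corrected MI hits the closed form across coupling levels", {
  set.seed(3)
  n <- 10000
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    est <- mean(replicate(5, {
      x <- rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
      mi_gaussian_bits(copula_gauss(x), copula_gauss(y))
    }))
    expect_lt(abs(est - (-0.5 * log2(1 - rho^2))), 0.02)
  }
  # corrected estimate fluctuates around zero under independence
  est0 <- mi_gaussian_bits(copula_gauss(rnorm(n)), copula_gauss(rnorm(n)))
  expect_lt(abs(est0), 0.01)
})

test_that("2-D Gaussian MI with one informative column matches theory", {
  set.seed(4)
  n <- 10000
  x <- rnorm(n)
  Y <- cbind(0.6 * x + 0.8 * rnorm(n), rnorm(n))
  est <- mi_gaussian_bits(copula_gauss(x), copula_gauss(Y))
  expect_lt(abs(est - (-0.5 * log2(1 - 0.36))), 0.02)
})

test_that("GCMI is invariant under strictly monotone marginal distortion", {
  set.seed(5)
  n <- 3000
  x <- rnorm(n)
  Y <- cbind(0.5 * x + rnorm(n), rnorm(n))
  base <- mi_gaussian_bits(copula_gauss(x), copula_gauss(Y))
  warp <- mi_gaussian_bits(copula_gauss(exp(2 * x)),
                           copula_gauss(cbind(atan(Y[, 1]), Y[, 2]^3)))
  expect_equal(base, warp, tolerance = 1e-12)
})

test_that("vectorized envelope-brain MI equals the generic estimator", {
  set.seed(6)
  n <- 1500; V <- 7
  e <- copula_gauss(rnorm(n))
  ZR <- copula_gauss(matrix(rnorm(n * V), n, V) + 0.3 * e)
  ZI <- copula_gauss(matrix(rnorm(n * V), n, V))
  fast <- sbswin:::mi_env_brain_vec(e, ZR, ZI)
  slow <- vapply(seq_len(V), function(v)
    mi_gaussian_bits(e, cbind(ZR[, v], ZI[, v])), 0)
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("uncoupled recordings give an SBS map at the bias floor", {
  st <- make_tiny_study(n_subjects = 2, rho_c = 0, seed = 31, duration = 20,
                        grid_dims = c(4, 4, 4), radii = c(1.8, 1.8, 1.8))
  m <- sbs_map(st$envelopes, st$recordings, st$cfg$band)
  # narrow-band autocorrelation shrinks the effective sample size, so single
  # voxels fluctuate beyond the iid-sample bound; the map as a whole sits at
  # the corrected bias floor around zero
  expect_lt(mean(abs(m$values)), 0.01)
  expect_lt(median(abs(m$values)), 0.005)
  expect_lt(abs(mean(m$values)), 0.005)
})

test_that("a planted coupled voxel clears the uncoupled distribution", {
  st <- make_tiny_study(n_subjects = 3, rho_c = 0.5, seed = 33)
  m <- sbs_map(st$envelopes, st$recordings, st$cfg$band)
  for (s in 1:3) {
    coupled <- mean(m$values[s, st$coupled, 1])
    expect_gt(coupled, quantile(m$values[s, -st$coupled, 1], 0.99))
  }
})

test_that("derangements never contain fixed points", {
  set.seed(7)
  for (k in 1:200) {
    n <- sample(2:6, 1)
    p <- rand_derangement(n)
    expect_true(all(p != seq_len(n)))
    expect_setequal(p, seq_len(n))
  }
  expect_error(rand_derangement(1), "derangement")
})

test_that("surrogate maps sit below real maps at coupled voxels", {
  st <- make_tiny_study(n_subjects = 4, rho_c = 0.6, seed = 35)
  sa <- sbs_analysis(st$envelopes, st$recordings, st$cfg$band, n_rand = 8,
                     seed = 36)
  cv <- st$coupled
  expect_gt(mean(sa$real$values[, cv, 1]), mean(sa$surrogate$values[, cv, 1]))
  # uncoupled voxels: real and surrogate agree on average
  d <- sa$real$values[, -cv, 1] - sa$surrogate$values[, -cv, 1]
  expect_lt(abs(mean(d)), 0.005)
})

test_that("mismatched story lengths are trimmed head-aligned", {
  cfg <- simulation_config(n_subjects = 1, n_stories = 2,
                           story_duration_s = 12, fs = 200,
                           grid_dims = c(3, 3, 3), mask_radii = c(1.6, 1.6, 1.6),
                           rho_c = 0, coupled_voxels = 1)
  grid <- voxel_grid(cfg$grid_dims, mask = ellipsoid_mask(cfg$grid_dims, cfg$mask_radii))
  e1 <- gen_envelope(4.5, 0.2, 12, 200, seed = 1)
  e2 <- gen_envelope(4.5, 0.2, 9, 200, seed = 2)   # shorter story
  r1 <- gen_subject_recording(list(e1), cfg, grid, 0.5, seed = 3)
  r2 <- gen_subject_recording(list(e2), cfg, grid, 0.5, seed = 4)
  rec <- r1
  rec$stories <- list(r1$stories[[1]], r2$stories[[1]])
  sa <- sbs_analysis(list(e1, e2), list(rec), cfg$band, n_rand = 2, seed = 5)
  expect_true(all(is.finite(sa$surrogate$values)))
  # surrogate pairing trims to the shorter member of each mismatched pair
  expect_lt(sa$surrogate$n_samples, sa$real$n_samples)
})
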