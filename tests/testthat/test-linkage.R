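test_that("rank-1 spectra compress into one dominant component", {
  set.seed(1)
  shape <- exp(-(1:100 - 30)^2 / 200)
  load <- runif(20, 0.5, 2)
  spectra <- array(outer(load, shape), c(20, 1, 100))
  red <- reduce_spectra(spectra, n_pc = 3)
  expect_gt(red$var_explained[1], 0.99)
  # reconstruction error complements variance explained
  M <- spectra[, 1, ]
  pc <- prcomp(M)
  rec <- pc$x[, 1:3] %*% t(pc$rotation[, 1:3])
  Mc <- sweep(M, 2, colMeans(M))
  expect_equal(1 - sum((Mc - rec)^2) / sum(Mc^2),
               red$var_explained[1], tolerance = 1e-9)
})

test_that("white-noise spectra trigger the variance-explained warning", {
  set.seed(2)
  spectra <- array(rnorm(30 * 1 * 100), c(30, 1, 100))
  expect_warning(reduce_spectra(spectra, n_pc = 3), "variance")
})

test_that("CCA finds exact and planted shared structure", {
  set.seed(3)
  Y <- matrix(rnorm(200 * 2), 200, 2)
  f <- cca_fit(cbind(Y, rnorm(200)), Y)
  expect_equal(f$cor[1], 1, tolerance = 1e-9)
  expect_equal(apply(f$scores_x, 2, sd), rep(1, 2), tolerance = 1e-9)

  # planted population canonical correlation 0.6: X = z + N(0, sqrt(2)),
  # Y = z + N(0, sqrt(4/3)) gives rho_x * rho_y = sqrt(.6)*sqrt(.6)
  n <- 500
  z <- rnorm(n)
  X <- matrix(z, n, 3) + matrix(rnorm(n * 3, 0, sqrt(2)), n, 3)
  Y2 <- matrix(z, n, 2) + matrix(rnorm(n * 2, 0, sqrt(4 / 3)), n, 2)
  expect_lt(abs(cca_fit(X, Y2)$cor[1] - 0.6), 0.08)

  # independent sets: first canonical correlation stays small
  expect_lt(cca_fit(matrix(rnorm(n * 3), n, 3),
                    matrix(rnorm(n * 2), n, 2))$cor[1], 0.25)
})

test_that("CCA is invariant to invertible linear mixing of either set", {
  set.seed(4)
  n <- 300
  z <- rnorm(n)
  X <- matrix(z, n, 3) + matrix(rnorm(n * 3), n, 3)
  Y <- matrix(z, n, 2) + matrix(rnorm(n * 2), n, 2)
  r0 <- cca_fit(X, Y)$cor[1]
  M3 <- matrix(c(2, 0.5, -1, 0, 1.5, 0.3, 1, 0, 1), 3, 3)
  M2 <- matrix(c(1, -0.7, 0.4, 2), 2, 2)
  expect_equal(cca_fit(X %*% M3, Y %*% M2)$cor[1], r0, tolerance = 1e-8)
})

test_that("Benjamini-Hochberg adjustment matches the closed form", {
  p <- c(0.01, 0.02, 0.5)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.5))
  res_like <- p.adjust(c(1, 0.2, 0.04), "BH")
  expect_true(all(res_like >= c(1, 0.2, 0.04)))
})

test_that("permutation p-values of the first canonical mode are honest", {
  set.seed(5)
  n <- 40
  X_list <- list(a = matrix(rnorm(n * 3), n, 3), b = matrix(rnorm(n * 3), n, 3))
  Y <- matrix(rnorm(n * 2), n, 2)
  res <- cca_perm_fdr(X_list, Y, n_perm = 150, seed = 6)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$p_fdr >= res$p - 1e-12))
  # planted structure is detected
  z <- rnorm(n)
  X_list2 <- list(sig = matrix(z, n, 3) + 0.5 * matrix(rnorm(n * 3), n, 3),
                  nul = matrix(rnorm(n * 3), n, 3))
  Y2 <- cbind(z + 0.5 * rnorm(n), z + 0.5 * rnorm(n))
  res2 <- cca_perm_fdr(X_list2, Y2, n_perm = 300, seed = 7)
  expect_lt(res2$p_fdr[1], 0.05)
  expect_gt(res2$p[2], 0.05)
})

test_that("post-hoc profiles recover the driving frequency band", {
  set.seed(8)
  n <- 60
  scores <- rnorm(n)
  spectra <- matrix(rnorm(n * 100), n, 100)
  drive <- 20:30
  spectra[, drive] <- spectra[, drive] + scores
  pp <- posthoc_profile(scores, sbs = scores + rnorm(n), win = rnorm(n),
                        spectra = spectra)
  expect_gte(which.max(pp$profile[, "r"]), 20)
  expect_lte(which.max(pp$profile[, "r"]), 30)
  expect_true(all(pp$profile[, "lo"] <= pp$profile[, "r"] + 1e-12))
  expect_true(all(pp$profile[, "hi"] >= pp$profile[, "r"] - 1e-12))
  # exact dependence gives r = 1 with a degenerate upper bound
  pexact <- posthoc_profile(scores, sbs = rnorm(n), win = scores)
  expect_equal(unname(pexact$win["r"]), 1, tolerance = 1e-12)
  expect_equal(unname(pexact$win["hi"]), 1, tolerance = 1e-9)
})

test_that("mediation decomposition is exact and its indirect measures agree", {
  set.seed(9)
  n <- 300
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- -0.4 * m - 0.3 * x + rnorm(n)
  md <- mediate(x, m, y, n_boot = 300, seed = 10)
  expect_equal(md$indirect_product, md$indirect_difference, tolerance = 1e-9)
  expect_equal(sign(md$sobel_z), sign(md$indirect_product))
  expect_true(md$boot_ci[1] < md$indirect_product &&
                md$indirect_product < md$boot_ci[2])
  # cross-check path coefficients against lm
  expect_equal(md$paths$coef[1], unname(coef(lm(m ~ x))[2]), tolerance = 1e-9)
  expect_equal(md$paths$coef[2], unname(coef(lm(y ~ x + m))[3]), tolerance = 1e-9)
  expect_equal(md$paths$coef[4], unname(coef(lm(y ~ x + m))[2]), tolerance = 1e-9)
})

test_that("a null mediator keeps the bootstrap interval around zero", {
  set.seed(11)
  n <- 150
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)     # a path present
  y <- -0.3 * x + rnorm(n)    # but b = 0
  hits <- 0
  for (k in 1:20) {
    xi <- rnorm(n); mi <- 0.5 * xi + rnorm(n); yi <- -0.3 * xi + rnorm(n)
    md <- mediate(xi, mi, yi, n_boot = 300, seed = 100 + k)
    hits <- hits + (md$boot_ci[1] <= 0 && 0 <= md$boot_ci[2])
  }
  expect_gte(hits, 18)  # CI contains 0 in at least 90% of null replicates
  expect_error(mediate(x, x * 1.0000001, y), "collinear")
})

test_that("the difference method reproduces the published-style arithmetic", {
  expect_equal(indirect_difference(-29.94, -17.59), -12.35, tolerance = 1e-9)
})
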