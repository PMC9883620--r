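test_that("word-in-noise threshold conversion matches the instrument rule", {
  expect_identical(win_threshold(0), 26)
  expect_equal(win_threshold(32.5), 0)
  expect_equal(win_threshold(26.75), 4.6, tolerance = 1e-12)
  expect_true(is.na(win_threshold(NA)))
  expect_error(win_threshold(-1), "nonnegative")
})

test_that("rank-based inverse normal transform is monotone, symmetric and standardized", {
  z <- rank_int(c(5, 2, 9, 7, 1))
  expect_equal(order(z), order(c(5, 2, 9, 7, 1)))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  # sign pattern: middle value maps to 0 under an odd count
  z3 <- rank_int(c(5, 2, 9, 3, 8))
  expect_equal(sum(sign(z3)), 0)

  set.seed(1)
  x <- rexp(53)  # heavily skewed input
  z53 <- rank_int(x)
  skew <- mean(z53^3) / sd(z53)^3
  expect_lt(abs(skew), 0.2)
})

test_that("missing scores are imputed by the observed median before the transform", {
  x <- c(10, 20, NA, 30, 40, 50)
  z <- rank_int(x)
  expect_equal(length(z), 6)
  expect_false(any(is.na(z)))
  # the imputed value ranks where the median (30) ranks
  expect_equal(z[3], z[4], tolerance = 1.1)  # adjacent ranks, both mid-scale
  expect_lt(abs(z[3]), max(abs(z)))
  expect_error(rank_int(c(NA, NA, 1, 2, 3)), "at least 5")
})

test_that("deconfounding produces residuals orthogonal to the covariate", {
  set.seed(2)
  age <- sample(22:35, 40, replace = TRUE)
  y <- rnorm(40)
  r <- deconfound(y, age)
  expect_lt(abs(cor(r, age)), 1e-10)
  expect_equal(deconfound(2 * age, age), rep(0, 40), tolerance = 1e-9)
  # uncorrelated covariate: residuals are approximately the centered input
  expect_gt(cor(r, y - mean(y)), 0.9)
  expect_error(deconfound(y, rep(30, 40)), "constant")
})

test_that("the correlation map flags an exact dependence and respects bounds", {
  set.seed(3)
  n <- 30
  X <- matrix(rnorm(n * 5), n, 5)
  win <- -X[, 2]
  cm <- sbs_win_corr_map(X, win, n_perm = 200, seed = 4)
  expect_equal(cm$rho[2], -1, tolerance = 1e-12)
  expect_true(all(abs(cm$rho) <= 1 + 1e-12))
  expect_true(cm$sig[2])
})

test_that("a planted behavioral association is recovered at cohort scale", {
  set.seed(5)
  reps <- 20
  got <- numeric(reps)
  for (k in seq_len(reps)) {
    n <- 53
    t <- rnorm(n)
    sbs <- matrix(0.5 * t + rnorm(n * 4, 0, 1), n, 4)
    win <- -0.4 * scale(t)[, 1] * sqrt(0.4^2 / (0.4^2)) # planted rho -0.4 vs t
    win <- -0.4 * scale(t)[, 1] + sqrt(1 - 0.16) * rnorm(n)
    cm <- sbs_win_corr_map(sbs, win, n_perm = 100, seed = 100 + k)
    got[k] <- mean(cm$rho)
  }
  # sbs columns correlate ~0.45 with t, so the planted -0.4 attenuates
  expect_gt(mean(got), -0.55)
  expect_lt(mean(got), -0.1)
})

test_that("null data flag about five percent of voxels", {
  set.seed(6)
  hits <- 0; tot <- 0
  for (k in 1:50) {
    X <- matrix(rnorm(30 * 20), 30, 20)
    cm <- sbs_win_corr_map(X, rnorm(30), n_perm = 100, seed = 200 + k)
    hits <- hits + sum(cm$sig); tot <- tot + length(cm$sig)
  }
  expect_gt(hits / tot, 0.02)
  expect_lt(hits / tot, 0.08)
})

test_that("an empty mask is a warning, not an error", {
  expect_warning(cm <- sbs_win_corr_map(matrix(numeric(0), 10, 0), rnorm(10)),
                 "empty")
  expect_equal(length(cm$rho), 0)
})

test_that("cluster pruning enforces the minimum component size exactly", {
  grid <- voxel_grid(c(10, 2, 1))
  # components of size 4 (voxels x=1..4) and 5 (x=6..10) in row y=1
  sel <- c(which(grid$coords[, 1] <= 4 & grid$coords[, 2] == 1),
           which(grid$coords[, 1] >= 6 & grid$coords[, 2] == 1))
  pruned <- prune_clusters(sel, grid, min_size = 5)
  expect_equal(sum(pruned), 5)
  expect_equal(attr(pruned, "n_removed_components"), 1L)
  expect_equal(attr(pruned, "n_removed_voxels"), 4L)

  empty <- prune_clusters(logical(nrow(grid$coords)), grid)
  expect_equal(sum(empty), 0)
})

test_that("pruning agrees with a brute-force component-size filter", {
  set.seed(7)
  grid <- voxel_grid(c(7, 7, 7))
  mask <- runif(343) < 0.2
  pruned <- prune_clusters(mask, grid, min_size = 3)
  sel <- which(mask)
  lab <- oracle_flood_components(sel, grid$coords, grid$dims)
  keep <- sel[lab %in% as.integer(names(which(table(lab) >= 3)))]
  expect_setequal(which(pruned), keep)
})

test_that("discard-rate arithmetic is a plain percentage", {
  expect_equal(discard_rate(33, 3724), 100 * 33 / 3724)
  expect_equal(round(discard_rate(33, 3724), 2), 0.89)
  expect_error(discard_rate(5, 0))
})
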