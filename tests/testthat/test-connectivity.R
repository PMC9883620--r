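test_that("first PC of identical voxels is the common series, sign-fixed", {
  set.seed(1)
  s <- rnorm(500)
  X <- cbind(s, s, s)
  pc <- first_pc_series(X)
  expect_gt(cor(pc, s), 0.999999)
  # sign convention is solver-independent and deterministic: repeated calls
  # agree exactly, and globally flipped data flips the score coherently
  expect_identical(first_pc_series(X), pc)
  expect_equal(first_pc_series(-X), -pc, tolerance = 1e-9)
  expect_equal(sd(pc), 1, tolerance = 1e-9)
  expect_error(first_pc_series(matrix(0, 10, 2)), "zero-variance")
})

test_that("first PC beats any single direction on explained variance", {
  set.seed(2)
  X <- matrix(rnorm(400 * 5), 400, 5) %*% matrix(rnorm(25), 5)
  pc <- first_pc_series(X)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  v_pc <- var(as.numeric(Xc %*% ev$vectors[, 1]))
  for (k in 2:5) expect_gte(v_pc, var(as.numeric(Xc %*% ev$vectors[, k])))
  expect_gt(abs(cor(pc, Xc %*% ev$vectors[, 1])), 0.999999)
})

test_that("k-means merging co-assigns duplicated parcels and restores rank", {
  set.seed(3)
  base <- matrix(rnorm(600 * 4), 600, 4)
  # 8 parcels of 3 voxels; parcels 1/2 and 3/4 are near-duplicates
  vox <- cbind(base[, 1] + matrix(rnorm(600 * 3, 0, 0.05), 600),
               base[, 1] + matrix(rnorm(600 * 3, 0, 0.05), 600),
               base[, 2] + matrix(rnorm(600 * 3, 0, 0.05), 600),
               base[, 2] + matrix(rnorm(600 * 3, 0, 0.05), 600),
               base[, 3] + matrix(rnorm(600 * 3, 0, 0.05), 600),
               base[, 4] + matrix(rnorm(600 * 3, 0, 0.05), 600),
               matrix(rnorm(600 * 6), 600))
  parcels <- split(1:24, rep(1:8, each = 3))
  names(parcels) <- paste0("P", 1:8)
  m <- merge_collinear(vox, parcels, k = 6, seed = 4)
  expect_equal(length(m$parcels), 6)
  expect_equal(m$assignment[["P1"]], m$assignment[["P2"]])
  expect_equal(m$assignment[["P3"]], m$assignment[["P4"]])
  R <- cor(m$series)
  expect_equal(qr(R)$rank, 6)
  expect_error(merge_collinear(vox, parcels, k = 8), "smaller")
})

test_that("symmetric orthogonalization removes all zero-lag correlations", {
  set.seed(5)
  L <- matrix(rnorm(1500 * 5), 1500, 5) %*% (diag(5) + 0.4)
  Lo <- symmetric_orthogonalize(L)
  C <- cor(Lo)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
  # idempotent
  Lo2 <- symmetric_orthogonalize(Lo)
  expect_lt(max(abs(Lo - Lo2)) / sd(Lo), 1e-9)
  # already-orthogonal input returns unchanged up to per-series scale
  Q <- qr.Q(qr(matrix(rnorm(400 * 3), 400, 3)))
  Qc <- sweep(Q, 2, colMeans(Q))
  Qo <- symmetric_orthogonalize(Qc)
  for (j in 1:3) expect_gt(abs(cor(Qo[, j], Qc[, j])), 0.9999)
})

test_that("orthogonalization is closest among random orthogonal alternatives", {
  set.seed(6)
  L <- matrix(rnorm(300 * 3), 300, 3) %*% (diag(3) + 0.5)
  Lc <- sweep(L, 2, colMeans(L))
  Lo <- symmetric_orthogonalize(L)
  d_opt <- sum((Lc - Lo)^2)
  for (k in 1:200) {
    O <- qr.Q(qr(matrix(rnorm(300 * 3), 300, 3)))
    d <- colSums(Lc * O)               # optimal scaling for this alternative
    expect_gte(sum((Lc - O %*% diag(d))^2), d_opt - 1e-8)
  }
})

test_that("rank-deficient parcel sets are refused", {
  set.seed(7)
  b <- rnorm(200)
  L <- cbind(b, b, rnorm(200))
  expect_error(symmetric_orthogonalize(L), "rank-deficient")
})

test_that("spectral GC matches the closed-form innovation ratio on a VAR(1) toy", {
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
  spec <- var_network_spec(A, diag(2), fs = 200)
  X <- gen_var_parcels(spec, 20000, seed = 8)
  gc <- spectral_gc(X[, 1], X[, 2], fs = 200, order_max = 10)
  expect_lt(abs(mean(gc$gc_xy) - log(1.25)) / log(1.25), 0.10)
  expect_lt(mean(gc$gc_yx), 0.02)
  expect_true(all(gc$gc_xy >= 0))
  expect_equal(gc$freq, 1:100)
})

test_that("spectral GC is invariant to rescaling and consistent with time GC", {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.4; A[2, 2, 1] <- 0.3; A[2, 1, 1] <- 0.4; A[2, 1, 2] <- -0.2
  spec <- var_network_spec(A, diag(2), fs = 200)
  X <- gen_var_parcels(spec, 15000, seed = 9)
  g1 <- spectral_gc(X[, 1], X[, 2], fs = 200, order = 2, freqs = seq(0.5, 99.5, by = 0.5))
  g2 <- spectral_gc(3 * X[, 1], X[, 2] / 2, fs = 200, order = 2,
                    freqs = seq(0.5, 99.5, by = 0.5))
  expect_equal(g1$gc_xy, g2$gc_xy, tolerance = 1e-9)
  # Geweke integral over (0, Nyquist) returns the time-domain measure
  expect_lt(abs(mean(g1$gc_xy) - g1$gc_time_xy) / g1$gc_time_xy, 0.05)
})

test_that("independent white noise shows no spectral GC anywhere", {
  set.seed(10)
  x <- rnorm(20000); y <- rnorm(20000)
  gc <- spectral_gc(x, y, fs = 200, order_max = 5)
  expect_lt(max(gc$gc_xy), 0.01)
  expect_lt(max(gc$gc_yx), 0.01)
})

test_that("the registered network has 24 edges with the expected family split", {
  e <- default_edge_set()
  expect_equal(nrow(e), 24)
  expect_equal(sum(e$family == "TD"), 12)
  expect_equal(sum(e$family == "BU"), 12)
  expect_equal(sum(grepl("^A1", e$source) | grepl("^A1", e$target)), 4)
  expect_equal(anyDuplicated(paste(e$source, e$target)), 0)
})

test_that("edge_gc returns both directions of each modeled pair", {
  A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
  spec <- var_network_spec(A, diag(2), fs = 200)
  sl <- lapply(1:2, function(i) {
    Z <- gen_var_parcels(spec, 6000, seed = 20 + i)
    colnames(Z) <- c("SRC", "TGT")
    Z
  })
  edges <- data.frame(source = c("SRC", "TGT"), target = c("TGT", "SRC"))
  G <- edge_gc(sl, edges, fs = 200, freqs = 1:100, order = 1)
  expect_equal(dim(G), c(2, 2, 100))
  expect_gt(mean(G[, 1, ]), 10 * mean(G[, 2, ]))
})
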