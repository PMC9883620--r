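# Parcel time series, source-leakage correction, and spectrally resolved
# directed (Granger) connectivity on registered network edges.

#' First-principal-component parcel series
#'
#' Score series of the first principal component of a parcel's voxel
#' signals, sign-fixed so the largest-magnitude loading is positive, and
#' scaled to unit variance.
#'
#' @param X time x voxels matrix of one parcel's signals.
#' @return Numeric series of length \code{nrow(X)}.
#' @export
first_pc_series <- function(X) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, all(is.finite(X)))
  Xc <- sweep(X, 2, colMeans(X))
  if (max(abs(Xc)) == 0) stop("zero-variance parcel")
  sv <- svd(Xc, nu = 1, nv = 1)
  load <- sv$v[, 1]
  s <- sign(load[which.max(abs(load))])
  pc <- sv$u[, 1] * sv$d[1] * s
  pc / sd(pc)
}

#' Merge collinear parcels by k-means on the correlation structure
#'
#' Clusters parcels via k-means on the rows of their correlation matrix and
#' merges the parcels of each cluster (voxel union, first PC re-extracted),
#' so that the resulting cross-parcel correlation matrix has full rank.
#'
#' @param voxel_data time x voxels matrix of all voxel signals.
#' @param parcels named list of integer voxel-index vectors (one per parcel).
#' @param k target number of merged parcels (< number of parcels).
#' @param seed integer seed for the k-means initialization.
#' @return List with \code{parcels} (merged voxel sets, named by their
#'   members), \code{series} (time x k matrix of re-extracted first PCs) and
#'   \code{assignment} (original parcel -> cluster).
#' @export
merge_collinear <- function(voxel_data, parcels, k = 30, seed = NULL) {
  P <- length(parcels)
  if (k >= P) stop("k must be smaller than the number of parcels")
  series <- sapply(parcels, function(vx) first_pc_series(voxel_data[, vx, drop = FALSE]))
  R <- cor(series)
  cl <- with_seed(seed, kmeans(R, centers = k, nstart = 10))
  merged <- lapply(seq_len(k), function(g) {
    sort(unique(unlist(parcels[cl$cluster == g])))
  })
  names(merged) <- vapply(seq_len(k), function(g) {
    paste(names(parcels)[cl$cluster == g], collapse = "+")
  }, "")
  ms <- sapply(merged, function(vx) first_pc_series(voxel_data[, vx, drop = FALSE]))
  list(parcels = merged, series = ms, assignment = cl$cluster)
}

#' Symmetric (multivariate) source-leakage correction
#'
#' Finds the set of mutually orthogonal series closest (in the Frobenius
#' sense) to the input parcel series — the closest matrix of the form
#' \code{O diag(d)} with orthonormal, zero-mean columns — removing all
#' zero-lag correlations at once. Iterates the closest-orthonormal-matrix
#' (Procrustes) step and the per-series scale step to convergence.
#'
#' @param L time x parcels matrix, full column rank, more rows than columns.
#' @param tol convergence tolerance on the relative Frobenius change.
#' @param max_iter iteration cap.
#' @return Corrected matrix of the same shape; pairwise zero-lag sample
#'   correlations of its columns are zero to numerical precision.
#' @export
symmetric_orthogonalize <- function(L, tol = 1e-12, max_iter = 200) {
  L <- as.matrix(L)
  n <- nrow(L); p <- ncol(L)
  if (p > n) stop("more series than samples")
  Lc <- sweep(L, 2, colMeans(L))
  sv0 <- svd(Lc)
  if (min(sv0$d) < max(sv0$d) * 1e-10)
    stop("rank-deficient input: source leakage correction fails; merge collinear parcels first")
  d <- sqrt(colSums(Lc^2))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    sv <- svd(Lc %*% diag(d, p))
    O <- sv$u %*% t(sv$v)
    d <- colSums(Lc * O)            # optimal per-series scale, O orthonormal
    err <- sum((Lc - O %*% diag(d, p))^2)
    if (abs(prev - err) <= tol * max(err, 1)) break
    prev <- err
  }
  out <- O %*% diag(d, p)
  dimnames(out) <- dimnames(L)
  out
}

# ---- VAR fitting and Geweke spectral Granger causality ----------------------

# OLS fit of a VAR(p) on the columns of Z (time x m), intercept-free on
# centered data; returns coefficient array, innovation covariance and the
# effective sample size.
fit_var <- function(Z, p) {
  Z <- as.matrix(Z)
  Z <- sweep(Z, 2, colMeans(Z))
  n <- nrow(Z); m <- ncol(Z)
  if (n - p <= m * p + 2) stop("series too short for VAR order ", p)
  Y <- Z[(p + 1):n, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(p), function(k) Z[(p + 1 - k):(n - k), , drop = FALSE]))
  B <- solve(crossprod(X), crossprod(X, Y))
  E <- Y - X %*% B
  N <- nrow(Y)
  Sigma <- crossprod(E) / N
  A <- array(0, c(m, m, p))
  for (k in seq_len(p)) A[, , k] <- t(B[((k - 1) * m + 1):(k * m), , drop = FALSE])
  list(A = A, Sigma = Sigma, n_eff = N, order = p)
}

select_var_order <- function(Z, order_max, ic = "bic") {
  m <- ncol(as.matrix(Z))
  best <- NULL
  best_ic <- Inf
  for (p in seq_len(order_max)) {
    f <- fit_var(Z, p)
    ld <- as.numeric(determinant(f$Sigma, TRUE)$modulus)
    pen <- if (ic == "bic") log(f$n_eff) else 2
    crit <- ld + pen * (m^2 * p) / f$n_eff
    if (crit < best_ic) {
      best_ic <- crit
      best <- f
    }
  }
  best
}

#' Spectrally resolved Granger causality between two series
#'
#' Fits a bivariate VAR (order selected by BIC up to \code{order_max}, or
#' fixed via \code{order}) and evaluates the Geweke spectral decomposition of
#' Granger causality in both directions on an integer frequency grid, along
#' with the time-domain (innovation-variance ratio) measures.
#'
#' @param x,y numeric series of equal length (source, target and vice versa).
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid in Hz (default 1..100).
#' @param order_max maximum VAR order scanned by BIC (default 20).
#' @param order optional fixed VAR order (skips selection).
#' @return Object of class \code{edge_spectrum}: \code{freq},
#'   \code{gc_xy}/\code{gc_yx} (spectral GC, nats, nonnegative),
#'   \code{gc_time_xy}/\code{gc_time_yx}, \code{order}.
#' @export
spectral_gc <- function(x, y, fs, freqs = 1:100, order_max = 20, order = NULL) {
  stopifnot(length(x) == length(y), max(freqs) <= fs / 2)
  Z <- cbind(x = as.numeric(x), y = as.numeric(y))
  fit <- if (is.null(order)) select_var_order(Z, order_max) else fit_var(Z, order)
  if (companion_radius(fit$A) >= 1) stop("fitted VAR is unstable")
  if (min(eigen(fit$Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("singular innovation covariance")
  gxy <- geweke_spectral(fit, source = 1, target = 2, freqs, fs)
  gyx <- geweke_spectral(fit, source = 2, target = 1, freqs, fs)
  td <- function(target) {
    zr <- Z[, target]
    fr <- fit_var(matrix(zr, ncol = 1), fit$order)
    log(fr$Sigma[1, 1] / fit$Sigma[target, target])
  }
  structure(list(freq = freqs, gc_xy = gxy, gc_yx = gyx,
                 gc_time_xy = max(td(2), 0), gc_time_yx = max(td(1), 0),
                 order = fit$order, fs = fs),
            class = "edge_spectrum")
}

geweke_spectral <- function(fit, source, target, freqs, fs) {
  A <- fit$A; S <- fit$Sigma
  p <- dim(A)[3]
  s2_cond <- S[source, source] - S[source, target]^2 / S[target, target]
  out <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (k in seq_len(p))
      Af <- Af - A[, , k] * exp(-2i * pi * freqs[i] * k / fs)
    H <- solve(Af)
    Sf <- Re((H %*% S %*% Conj(t(H)))[target, target])
    denom <- Sf - s2_cond * Mod(H[target, source])^2
    out[i] <- if (denom > 0 && Sf > 0) log(Sf / denom) else 0
  }
  pmax(out, 0)
}

#' @export
print.edge_spectrum <- function(x, ...) {
  cat(sprintf("<edge_spectrum> VAR order %d, grid %g-%g Hz\n",
              x$order, min(x$freq), max(x$freq)))
  cat(sprintf("  GC x->y: time %.4f, spectral mean %.4f | GC y->x: time %.4f, spectral mean %.4f (nats)\n",
              x$gc_time_xy, mean(x$gc_xy), x$gc_time_yx, mean(x$gc_yx)))
  invisible(x)
}

#' Registered edge set of the fronto-temporal and auditory networks
#'
#' The default network model: five frontal parcels per hemisphere (superior
#' frontal, inferior frontal and precentral/premotor subdivisions) each
#' connected top-down to the ipsilateral temporal SBS-ROI and bottom-up in
#' reverse (20 edges), plus primary auditory cortex to ipsilateral SBS-ROI
#' and reverse in each hemisphere (4 edges) — 24 modeled connections.
#'
#' @return A data frame with columns \code{source}, \code{target},
#'   \code{hemisphere}, \code{family} (\code{"TD"} top-down or \code{"BU"}
#'   bottom-up).
#' @export
default_edge_set <- function() {
  frontal <- c("SFG1", "SFG2", "IFG1", "IFG2", "PRG")
  rows <- list()
  for (h in c("L", "R")) {
    roi <- paste0("ROI_", h)
    for (f in frontal) {
      fp <- paste0(f, "_", h)
      rows[[length(rows) + 1]] <- data.frame(source = fp, target = roi,
                                             hemisphere = h, family = "TD")
      rows[[length(rows) + 1]] <- data.frame(source = roi, target = fp,
                                             hemisphere = h, family = "BU")
    }
    a1 <- paste0("A1_", h)
    rows[[length(rows) + 1]] <- data.frame(source = a1, target = roi,
                                           hemisphere = h, family = "BU")
    rows[[length(rows) + 1]] <- data.frame(source = roi, target = a1,
                                           hemisphere = h, family = "TD")
  }
  do.call(rbind, rows)
}

#' Spectral Granger causality for every registered edge and subject
#'
#' @param series_list list (one per subject) of time x nodes matrices with
#'   named columns.
#' @param edges data frame with \code{source} and \code{target} columns
#'   naming nodes.
#' @param fs sampling rate in Hz.
#' @param freqs frequency grid (default 1..100 Hz).
#' @param order_max,order VAR order control, see [spectral_gc()].
#' @return Numeric array subjects x edges x frequencies of spectral GC
#'   (nats), with edge names \code{"source->target"}.
#' @export
edge_gc <- function(series_list, edges, fs, freqs = 1:100, order_max = 20,
                    order = NULL) {
  nS <- length(series_list)
  nE <- nrow(edges)
  out <- array(NA_real_, c(nS, nE, length(freqs)),
               dimnames = list(NULL, paste0(edges$source, "->", edges$target),
                               freqs))
  pair_key <- apply(cbind(edges$source, edges$target), 1,
                    function(r) paste(sort(r), collapse = "|"))
  for (s in seq_len(nS)) {
    Z <- series_list[[s]]
    cache <- list()
    for (e in seq_len(nE)) {
      key <- pair_key[e]
      if (is.null(cache[[key]])) {
        a <- sort(c(edges$source[e], edges$target[e]))
        cache[[key]] <- spectral_gc(Z[, a[1]], Z[, a[2]], fs, freqs,
                                    order_max, order)
      }
      gc <- cache[[key]]
      fwd <- edges$source[e] == sort(c(edges$source[e], edges$target[e]))[1]
      out[s, e, ] <- if (fwd) gc$gc_xy else gc$gc_yx
    }
  }
  out
}
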