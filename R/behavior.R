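# Behavioral scoring and transformation, deconfounding, and the voxelwise
# SBS-behavior correlation map with permutation thresholds and cluster-size
# pruning.

#' Word-in-noise 50% SNR threshold
#'
#' Converts the raw score (number of correctly recognized words) of the
#' descending-SNR word-in-noise protocol to the 50%-correct threshold:
#' \code{26 dB - 0.8 * raw}. Lower thresholds mean better recognition.
#'
#' @param raw_correct nonnegative raw score(s); \code{NA} passes through.
#' @return Threshold(s) in dB SNR.
#' @examples
#' win_threshold(0)      # 26 dB
#' win_threshold(26.75)  # 4.6 dB
#' @export
win_threshold <- function(raw_correct) {
  if (any(raw_correct < 0, na.rm = TRUE)) stop("raw score must be nonnegative")
  26 - 0.8 * raw_correct
}

#' Rank-based inverse normal transformation
#'
#' Missing values are imputed with the median of the observed values, then
#' each value is mapped through its rank to \eqn{\Phi^{-1}((r - 0.5)/n)}, and
#' the result standardized to mean 0, SD 1. Ties are broken by
#' first-occurrence order.
#'
#' @param x numeric vector, possibly with \code{NA}s.
#' @return Transformed vector (no missing values).
#' @export
rank_int <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 5) stop("need at least 5 observed values")
  if (max(obs) == min(obs)) stop("constant input")
  x[is.na(x)] <- median(obs)
  n <- length(x)
  z <- qnorm((rank(x, ties.method = "first") - 0.5) / n)
  as.numeric((z - mean(z)) / sd(z))
}

#' Regress a covariate out of a variable
#'
#' Residualizes \code{y} on an intercept plus the covariate by least squares;
#' applied identically to the behavioral score and to each voxel's SBS value
#' before correlating them.
#'
#' @param y numeric vector or matrix (columns residualized independently).
#' @param covariate numeric vector (e.g. age in years), non-constant.
#' @return Residuals with the same shape as \code{y}.
#' @export
deconfound <- function(y, covariate) {
  n <- length(covariate)
  if (n < 3) stop("need at least 3 observations")
  if (max(covariate) == min(covariate)) stop("constant covariate")
  X <- cbind(1, covariate)
  Y <- as.matrix(y)
  stopifnot(nrow(Y) == n)
  beta <- solve(crossprod(X), crossprod(X, Y))
  R <- Y - X %*% beta
  if (is.null(dim(y))) as.numeric(R) else R
}

#' Voxelwise SBS-behavior correlation map with permutation threshold
#'
#' Pearson correlation between each voxel's (deconfounded) SBS value and the
#' (deconfounded, transformed) behavioral score, restricted to voxels with
#' significant SBS. The null is built by permuting subject labels of the
#' behavioral score; a voxel is significant when its |rho| exceeds the 95th
#' percentile of that voxel's null |rho| distribution (one-sided negative
#' available via \code{alternative}).
#'
#' @param sbs subjects x voxels matrix of SBS values (already restricted to
#'   the significant-SBS mask and deconfounded).
#' @param win numeric behavioral score per subject (deconfounded).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative \code{"two.sided"} (default) or \code{"less"}.
#' @param level quantile of the null (default 0.95).
#' @return Object of class \code{corr_map}: \code{rho}, \code{p}
#'   (permutation p per voxel), \code{sig} (logical), \code{threshold}
#'   (per-voxel null quantile).
#' @export
sbs_win_corr_map <- function(sbs, win, n_perm = 1000, seed = NULL,
                             alternative = c("two.sided", "less"),
                             level = 0.95) {
  alternative <- match.arg(alternative)
  X <- as.matrix(sbs)
  n <- nrow(X)
  if (ncol(X) == 0) {
    warning("empty voxel mask; nothing to correlate")
    return(structure(list(rho = numeric(0), p = numeric(0),
                          sig = logical(0), threshold = numeric(0),
                          n_perm = n_perm, alternative = alternative),
                     class = "corr_map"))
  }
  stopifnot(length(win) == n)
  Xs <- scale(X)
  ws <- as.numeric(scale(win))
  rho <- crossprod(Xs, ws)[, 1] / (n - 1)
  stat <- function(r) if (alternative == "two.sided") abs(r) else -r
  null <- with_seed(seed, {
    P <- matrix(0, n_perm, ncol(X))
    for (i in seq_len(n_perm))
      P[i, ] <- crossprod(Xs, ws[sample.int(n)])[, 1] / (n - 1)
    P
  })
  ns <- stat(null)
  os <- stat(rho)
  thr <- apply(ns, 2, quantile, probs = level, names = FALSE)
  p <- (1 + colSums(sweep(ns, 2, os, ">="))) / (n_perm + 1)
  structure(list(rho = rho, p = p, sig = os > thr, threshold = thr,
                 n_perm = n_perm, alternative = alternative),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("<corr_map> %d voxels, %d significant (%s, %d permutations)\n",
              length(x$rho), sum(x$sig), x$alternative, x$n_perm))
  if (sum(x$sig) > 0)
    cat(sprintf("  significant rho: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$rho[x$sig]), min(x$rho[x$sig]), max(x$rho[x$sig])))
  invisible(x)
}

#' Prune small clusters from a voxel mask
#'
#' Removes connected components with fewer than \code{min_size} voxels
#' (single voxels and small clutter), keeping components of \code{min_size}
#' or more.
#'
#' @param mask logical vector over the grid's voxel list, or integer voxel
#'   indices.
#' @param grid a \code{\link{voxel_grid}}.
#' @param min_size minimum surviving component size (default 5).
#' @return Logical mask of the same length, with attributes
#'   \code{n_removed_components} and \code{n_removed_voxels}.
#' @export
prune_clusters <- function(mask, grid, min_size = 5) {
  V <- nrow(grid$coords)
  sel <- if (is.logical(mask)) which(mask) else as.integer(mask)
  out <- logical(V)
  if (length(sel) == 0) {
    attr(out, "n_removed_components") <- 0L
    attr(out, "n_removed_voxels") <- 0L
    return(out)
  }
  labels <- label_components(sel, grid)
  sizes <- tapply(labels, labels, length)
  keep_labels <- as.integer(names(sizes))[sizes >= min_size]
  out[sel[labels %in% keep_labels]] <- TRUE
  attr(out, "n_removed_components") <- length(sizes) - length(keep_labels)
  attr(out, "n_removed_voxels") <- length(sel) - sum(out)
  out
}

#' Percentage of correlations discarded by pruning
#'
#' @param n_discarded number of discarded voxelwise correlations.
#' @param n_total total number of voxelwise correlations performed.
#' @return Percentage (0-100).
#' @examples
#' discard_rate(33, 3724)  # 0.886...
#' @export
discard_rate <- function(n_discarded, n_total) {
  stopifnot(n_total > 0, n_discarded >= 0, n_discarded <= n_total)
  100 * n_discarded / n_total
}
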