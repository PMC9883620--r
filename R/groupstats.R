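# Voxelwise real-vs-surrogate inference with cluster-based maximum
# permutation statistics honoring family (exchangeability) structure.

#' Construct a voxel grid
#'
#' @param dims integer length-3 grid dimensions.
#' @param spacing_mm voxel edge length in mm (default 8).
#' @param mask optional logical array of \code{dims} marking in-brain voxels
#'   (default: all).
#' @param connectivity neighborhood rule: 6 (faces), 18 (faces+edges) or 26.
#' @return Object of class \code{voxel_grid}: \code{coords} (in-mask voxel
#'   grid indices, one row per voxel), \code{mm} (coordinates in mm, centered),
#'   \code{dims}, \code{keymap} (linear-index lookup into the voxel list).
#' @export
voxel_grid <- function(dims, spacing_mm = 8, mask = NULL, connectivity = 6) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims > 0),
            connectivity %in% c(6, 18, 26))
  if (is.null(mask)) mask <- array(TRUE, dims)
  stopifnot(all(dim(mask) == dims))
  idx <- which(mask)
  co <- arrayInd(idx, dims)
  keymap <- rep(NA_integer_, prod(dims))
  keymap[idx] <- seq_along(idx)
  mm <- sweep(co, 2, (dims + 1) / 2) * spacing_mm
  structure(list(coords = co, mm = mm, dims = dims, keymap = keymap,
                 spacing_mm = spacing_mm, connectivity = connectivity),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %dx%dx%d, %d in-mask voxels, %d-connectivity\n",
              x$dims[1], x$dims[2], x$dims[3], nrow(x$coords), x$connectivity))
  invisible(x)
}

#' Ellipsoidal in-brain mask
#'
#' @param dims grid dimensions.
#' @param radii ellipsoid semi-axes in grid units.
#' @param center ellipsoid center (default: grid center).
#' @return Logical array of \code{dims}.
#' @export
ellipsoid_mask <- function(dims, radii, center = (dims + 1) / 2) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  d <- ((g$x - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
    ((g$z - center[3]) / radii[3])^2
  array(d <= 1, dims)
}

neighbor_offsets <- function(connectivity) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dist <- abs(off$dx) + abs(off$dy) + abs(off$dz)
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1,
                 "18" = dist >= 1 & pmax(abs(off$dx), abs(off$dy), abs(off$dz)) == 1 & dist <= 2,
                 "26" = dist >= 1)
  as.matrix(off[keep, ])
}

# label connected components among the voxel indices `sel` (into grid$coords)
label_components <- function(sel, grid) {
  if (length(sel) == 0) return(integer(0))
  dims <- grid$dims
  off <- neighbor_offsets(grid$connectivity)
  inset <- rep(NA_integer_, nrow(grid$coords))
  inset[sel] <- seq_along(sel)
  co <- grid$coords[sel, , drop = FALSE]
  labels <- integer(length(sel))
  comp <- 0L
  for (i in seq_along(sel)) {
    if (labels[i] > 0L) next
    comp <- comp + 1L
    stack <- i
    labels[i] <- comp
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      cc <- co[cur, ]
      for (k in seq_len(nrow(off))) {
        nb <- cc + off[k, ]
        if (any(nb < 1L) || any(nb > dims)) next
        lin <- nb[1] + dims[1] * (nb[2] - 1L + dims[2] * (nb[3] - 1L))
        vox <- grid$keymap[lin]
        if (is.na(vox)) next
        j <- inset[vox]
        if (!is.na(j) && labels[j] == 0L) {
          labels[j] <- comp
          stack <- c(stack, j)
        }
      }
    }
  }
  labels
}

# top-k cluster t-sums only (no bookkeeping): the permutation-loop hot path
top_cluster_sums <- function(t_map, grid, t_crit, top_k) {
  out <- numeric(top_k)
  sel <- which(!is.na(t_map) & t_map > t_crit)
  if (length(sel) == 0) return(out)
  labels <- label_components(sel, grid)
  sums <- sort(unname(tapply(t_map[sel], labels, sum)), decreasing = TRUE)
  k <- min(top_k, length(sums))
  out[seq_len(k)] <- sums[seq_len(k)]
  out
}

#' Paired t-statistics of real versus surrogate maps
#'
#' Classical paired t-test per voxel on the per-subject differences
#' (df = n_subjects - 1). Voxels with zero difference variance get \code{NA}.
#'
#' @param real,surrogate \code{sbs_map}s of identical shape, or numeric
#'   subjects x voxels matrices.
#' @param band band name or index when maps hold several bands.
#' @return List with \code{t} (per-voxel statistic), \code{df} and
#'   \code{diff} (the subjects x voxels difference matrix).
#' @export
paired_t_map <- function(real, surrogate, band = 1) {
  R <- if (inherits(real, "sbs_map")) real$values[, , band] else as.matrix(real)
  S <- if (inherits(surrogate, "sbs_map")) surrogate$values[, , band] else as.matrix(surrogate)
  stopifnot(all(dim(R) == dim(S)))
  n <- nrow(R)
  if (n < 3) stop("need at least 3 subjects")
  D <- R - S
  list(t = t_from_diff(D), df = n - 1, diff = D)
}

t_from_diff <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  # degenerate voxels: identically zero differences carry no effect (t = 0);
  # a nonzero mean with zero variance has no defined t and is flagged
  zero <- v <= 0
  t[zero] <- ifelse(abs(m[zero]) < 1e-12, 0, NA_real_)
  t
}

#' Find suprathreshold clusters in a t-map
#'
#' Thresholds the map at the one-tailed critical t for \code{alpha}, groups
#' surviving voxels by grid adjacency, and sums the member t-values.
#'
#' @param t_map numeric per-voxel t statistics.
#' @param grid a \code{\link{voxel_grid}}.
#' @param df degrees of freedom of the t statistics.
#' @param alpha cluster-forming threshold (default 0.001, one-tailed).
#' @return A data frame of class \code{cluster_set} sorted by descending
#'   \code{t_sum}, with a \code{members} attribute (list of voxel index
#'   vectors) and \code{t_crit}.
#' @export
find_clusters <- function(t_map, grid, df, alpha = 0.001) {
  t_crit <- qt(1 - alpha, df)
  sel <- which(!is.na(t_map) & t_map > t_crit)
  if (length(sel) == 0) {
    out <- data.frame(cluster = integer(0), n_voxels = integer(0),
                      t_sum = numeric(0))
    attr(out, "members") <- list()
    attr(out, "t_crit") <- t_crit
    class(out) <- c("cluster_set", "data.frame")
    return(out)
  }
  labels <- label_components(sel, grid)
  sums <- tapply(t_map[sel], labels, sum)
  sizes <- tapply(labels, labels, length)
  ord <- order(sums, decreasing = TRUE)
  members <- lapply(as.integer(names(sums))[ord],
                    function(l) sel[labels == l])
  out <- data.frame(cluster = seq_along(ord),
                    n_voxels = as.integer(sizes[ord]),
                    t_sum = as.numeric(sums[ord]))
  attr(out, "members") <- members
  attr(out, "t_crit") <- t_crit
  class(out) <- c("cluster_set", "data.frame")
  out
}

#' Cluster-based maximum permutation test with family blocks
#'
#' Builds the permutation null for the paired real-vs-surrogate contrast by
#' sign-flipping each subject's difference map, with flips held constant
#' within family blocks (the exchangeable null for paired designs with
#' related subjects). Each permutation is re-thresholded and the top
#' \code{top_k} cluster t-sums are recorded; the observed k-th largest
#' cluster is compared with the null distribution of k-th largest sums.
#'
#' @param real,surrogate \code{sbs_map}s or subjects x voxels matrices.
#' @param grid a \code{\link{voxel_grid}}.
#' @param band band name or index.
#' @param alpha cluster-forming threshold (one-tailed, default 0.001).
#' @param n_perm number of permutations (default 1000).
#' @param top_k number of cluster ranks followed (default 3).
#' @param blocks integer family block ids (default: all singletons).
#' @param seed integer seed.
#' @return Object of class \code{cluster_test}: the observed
#'   \code{cluster_set} with permutation p-values for the first \code{top_k}
#'   ranks, the null max-statistic matrix, and the test parameters.
#' @export
cluster_perm_test <- function(real, surrogate, grid, band = 1, alpha = 0.001,
                              n_perm = 1000, top_k = 3, blocks = NULL,
                              seed = NULL) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  tm <- paired_t_map(real, surrogate, band)
  D <- tm$diff
  n <- nrow(D)
  blocks <- blocks %||% seq_len(n)
  if (length(blocks) != n) stop("blocks must assign every subject")
  obs <- find_clusters(tm$t, grid, tm$df, alpha)
  ub <- unique(blocks)
  t_crit <- attr(obs, "t_crit")
  null_mat <- with_seed(seed, {
    flips_b <- matrix(sample(c(-1, 1), n_perm * length(ub), replace = TRUE),
                      n_perm, length(ub))
    Fm <- flips_b[, match(blocks, ub), drop = FALSE]
    M <- (Fm %*% D) / n
    SS <- matrix(colSums(D^2), n_perm, ncol(D), byrow = TRUE)
    Vv <- (SS - n * M^2) / (n - 1)
    Tm <- M / sqrt(Vv / n)
    nm <- matrix(0, n_perm, top_k)
    for (p in seq_len(n_perm)) {
      tp <- Tm[p, ]
      if (any(tp > t_crit, na.rm = TRUE))
        nm[p, ] <- top_cluster_sums(tp, grid, t_crit, top_k)
    }
    nm
  })
  p <- rep(NA_real_, nrow(obs))
  for (k in seq_len(min(top_k, nrow(obs))))
    p[k] <- (1 + sum(null_mat[, k] >= obs$t_sum[k])) / (n_perm + 1)
  obs$rank <- seq_len(nrow(obs))
  obs$p <- p
  structure(list(clusters = obs, null = null_mat, t = tm$t, df = tm$df,
                 alpha = alpha, n_perm = n_perm, top_k = top_k,
                 t_crit = t_crit),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> alpha = %g (t_crit = %.2f, df = %d), %d permutations\n",
              x$alpha, x$t_crit, x$df, x$n_perm))
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print.data.frame(head(as.data.frame(x$clusters), 10), row.names = FALSE)
  }
  invisible(x)
}

#' Voxels of the significant clusters
#'
#' @param x a \code{cluster_test}.
#' @param p_thresh significance level on the rank-wise permutation p
#'   (default 0.05).
#' @return Integer vector of voxel indices in significant clusters.
#' @export
significant_voxels <- function(x, p_thresh = 0.05) {
  stopifnot(inherits(x, "cluster_test"))
  members <- attr(x$clusters, "members")
  sig <- which(!is.na(x$clusters$p) & x$clusters$p < p_thresh)
  sort(unique(unlist(members[sig])))
}
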