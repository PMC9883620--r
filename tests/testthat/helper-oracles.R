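# Shared fixtures and independent brute-force oracles used across the suite.

# Brute-force Gaussian MI in bits from explicit covariance blocks; kept free
# of the package's determinant/bias code path on purpose.
oracle_gauss_mi_bits <- function(x, Y) {
  Y <- as.matrix(Y)
  Z <- cbind(x, Y)
  n <- nrow(Z)
  Zc <- sweep(Z, 2, colMeans(Z))
  C <- crossprod(Zc) / (n - 1)
  dx <- 1
  dy <- ncol(Y)
  det_of <- function(M) {
    # cofactor expansion, no determinant()/det() shortcut for small blocks
    d <- nrow(M)
    if (d == 1) return(M[1, 1])
    s <- 0
    for (j in seq_len(d))
      s <- s + (-1)^(1 + j) * M[1, j] * det_of(M[-1, -j, drop = FALSE])
    s
  }
  i_nats <- 0.5 * log(det_of(C[1, 1, drop = FALSE]) *
                        det_of(C[-1, -1, drop = FALSE]) / det_of(C))
  i_nats / log(2)
}

# Brute-force connected components by repeated flood fill over an explicit
# neighbor search (no shared code with label_components).
oracle_flood_components <- function(sel, coords, dims) {
  if (length(sel) == 0) return(integer(0))
  co <- coords[sel, , drop = FALSE]
  lab <- rep(0L, length(sel))
  comp <- 0L
  adjacent <- function(i, j) sum(abs(co[i, ] - co[j, ])) == 1
  for (i in seq_along(sel)) {
    if (lab[i] > 0) next
    comp <- comp + 1L
    frontier <- i
    lab[i] <- comp
    while (length(frontier)) {
      nxt <- integer(0)
      for (f in frontier) {
        for (j in seq_along(sel)) {
          if (lab[j] == 0 && adjacent(f, j)) {
            lab[j] <- comp
            nxt <- c(nxt, j)
          }
        }
      }
      frontier <- nxt
    }
  }
  lab
}

# Tiny synthetic study shared by several tests: 3 stories, small grid,
# subjects spanning the trait range.
make_tiny_study <- function(n_subjects = 6, rho_c = 0.6, seed = 42,
                            duration = 15, grid_dims = c(6, 6, 6),
                            radii = c(2.6, 2.6, 2.6)) {
  cfg <- simulation_config(n_subjects = n_subjects, n_stories = 3,
                           story_duration_s = duration, fs = 200,
                           grid_dims = grid_dims, mask_radii = radii,
                           rho_c = rho_c, seed = seed)
  grid <- voxel_grid(cfg$grid_dims, mask = ellipsoid_mask(cfg$grid_dims, cfg$mask_radii))
  envs <- lapply(seq_len(cfg$n_stories), function(s)
    gen_envelope(4.5, 0.25, duration, 200, seed = seed * 100 + s))
  traits <- seq(0.15, 0.95, length.out = n_subjects)
  recs <- lapply(seq_len(n_subjects), function(i)
    gen_subject_recording(envs, cfg, grid, traits[i], seed = seed * 1000 + i))
  list(cfg = cfg, grid = grid, envelopes = envs, traits = traits,
       recordings = recs, coupled = recs[[1]]$coupled_voxels)
}
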