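# Synthetic-data generators: every input the analysis pipeline consumes can
# be produced here with planted, recoverable ground truth (envelope coupling
# strength per voxel, behavioral effect sizes, directed network edges).

#' Simulation configuration
#'
#' Bundles the parameters of the synthetic study. Defaults are the package's
#' reference desk-scale conditions: 30 subjects, 6 stories of 40 s at 200 Hz,
#' a 10x10x10 source grid with an ellipsoidal in-brain mask of ~500 voxels,
#' an 18-voxel coupled patch at strength \code{rho_c = 0.5} in the syllable
#' band, a 120 ms brain response delay, and a behavioral effect calibrated to
#' a trait-threshold correlation of about -0.5.
#'
#' @param n_subjects,n_stories counts.
#' @param story_duration_s story length in seconds.
#' @param fs sampling rate in Hz.
#' @param grid_dims integer length-3 grid dimensions.
#' @param mask_radii ellipsoid semi-axes (grid units) of the in-brain mask.
#' @param coupled_voxels integer indices (into the masked voxel list) of the
#'   coupled patch; \code{NULL} selects a contiguous 3x3x2 patch automatically.
#' @param rho_c coupling strength in [0, 1) at full trait.
#' @param band coupling band, a \code{\link{rate_band}} or \code{c(f_lo,f_hi)}.
#' @param delay_ms brain response delay in ms.
#' @param syllable_rate_hz,jitter_cv envelope event rate and its regularity
#'   (coefficient of variation of inter-event intervals).
#' @param behavior_slope raw-score points gained per unit trait.
#' @param behavior_noise_sd raw-score noise standard deviation.
#' @param noise_exponent spectral exponent of the voxel background noise.
#' @param family_pair_frac fraction of subjects placed in 2-member family
#'   blocks (the rest are singletons).
#' @param seed master seed.
#' @return Object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_subjects = 30, n_stories = 6,
                              story_duration_s = 40, fs = 200,
                              grid_dims = c(10, 10, 10),
                              mask_radii = c(4.9, 4.9, 4.9),
                              coupled_voxels = NULL, rho_c = 0.5,
                              band = rate_band("syllable", 3.4, 6.5),
                              delay_ms = 120, syllable_rate_hz = 4.5,
                              jitter_cv = 0.2, behavior_slope = 12,
                              behavior_noise_sd = 6, noise_exponent = 1,
                              family_pair_frac = 0.2, seed = 1L) {
  stopifnot(rho_c >= 0, rho_c < 1, fs > 2 * band_edges(band)[2],
            n_subjects >= 1, n_stories >= 1, delay_ms >= 0,
            length(grid_dims) == 3)
  structure(list(n_subjects = n_subjects, n_stories = n_stories,
                 story_duration_s = story_duration_s, fs = fs,
                 grid_dims = as.integer(grid_dims), mask_radii = mask_radii,
                 coupled_voxels = coupled_voxels, rho_c = rho_c, band = band,
                 delay_ms = delay_ms, syllable_rate_hz = syllable_rate_hz,
                 jitter_cv = jitter_cv, behavior_slope = behavior_slope,
                 behavior_noise_sd = behavior_noise_sd,
                 noise_exponent = noise_exponent,
                 family_pair_frac = family_pair_frac, seed = seed),
            class = "simulation_config")
}

#' Generate a quasi-rhythmic envelope
#'
#' Event times follow a renewal process with gamma-distributed inter-event
#' intervals (mean \code{1/rate_hz}, coefficient of variation
#' \code{jitter_cv}); the impulse train is convolved with a smooth unit-area
#' Hann kernel. \code{jitter_cv = 0} gives a strictly periodic train.
#'
#' @param rate_hz mean event rate in Hz (< \code{fs/2}).
#' @param jitter_cv coefficient of variation of the intervals (>= 0).
#' @param duration_s envelope duration in seconds.
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed.
#' @param kernel_width_s width of the smoothing kernel in seconds.
#' @return Object of class \code{envelope}: \code{samples} (nonnegative),
#'   \code{fs}, \code{events} (event times in seconds).
#' @export
gen_envelope <- function(rate_hz, jitter_cv = 0.2, duration_s, fs = 200,
                         seed = NULL, kernel_width_s = 0.12) {
  stopifnot(rate_hz > 0, rate_hz < fs / 2, jitter_cv >= 0, duration_s > 0)
  with_seed(seed, {
    mean_isi <- 1 / rate_hz
    n_max <- ceiling(duration_s * rate_hz * 3) + 10
    isi <- if (jitter_cv == 0) rep(mean_isi, n_max) else {
      shape <- 1 / jitter_cv^2
      rgamma(n_max, shape = shape, scale = mean_isi / shape)
    }
    ev <- cumsum(c(mean_isi / 2, isi))
    ev <- ev[ev < duration_s]
    if (length(ev) < 2) stop("duration too short to hold at least 2 events")
    n <- round(duration_s * fs)
    train <- numeric(n)
    idx <- pmin(pmax(round(ev * fs) + 1, 1), n)
    for (i in idx) train[i] <- train[i] + 1
    kw <- max(3, round(kernel_width_s * fs))
    kern <- 0.5 * (1 - cos(2 * pi * seq_len(kw) / (kw + 1)))
    kern <- kern / sum(kern)
    samples <- as.numeric(stats::filter(c(train, numeric(kw)), kern,
                                        method = "convolution", sides = 2))
    samples <- samples[seq_len(n) + 0]
    samples[is.na(samples)] <- 0
    samples <- pmax(samples, 0)
    structure(list(samples = samples, fs = fs, events = ev,
                   rate_hz = rate_hz), class = "envelope")
  })
}

#' @export
print.envelope <- function(x, ...) {
  cat(sprintf("<envelope> %.1f s at %g Hz, %d events (realized rate %.2f Hz)\n",
              length(x$samples) / x$fs, x$fs, length(x$events),
              length(x$events) / (length(x$samples) / x$fs)))
  invisible(x)
}

env_samples <- function(e) if (inherits(e, "envelope")) e$samples else as.numeric(e)

#' Construct an annotation set
#'
#' @param tiers named list of data frames with columns \code{onset_s},
#'   \code{offset_s}, \code{label}.
#' @param story_id story identifier.
#' @return Object of class \code{annotation_set}.
#' @export
annotation_set <- function(tiers, story_id = "story") {
  for (nm in names(tiers)) {
    t <- tiers[[nm]]
    stopifnot(all(t$onset_s < t$offset_s))
    if (nrow(t) > 1 && any(t$onset_s[-1] < t$offset_s[-nrow(t)] - 1e-9))
      stop("overlapping intervals in tier ", nm)
  }
  structure(list(story_id = story_id, tiers = tiers), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> story %s\n", x$story_id))
  for (nm in names(x$tiers))
    cat(sprintf("  %-10s %4d intervals\n", nm, nrow(x$tiers[[nm]])))
  invisible(x)
}

#' Generate hierarchical linguistic annotations from an event train
#'
#' Builds four nested tiers (phoneme < syllable < word < phrase) from syllable
#' nucleus times: syllables span consecutive events, each split into equal
#' phoneme intervals, and consecutive syllables are grouped into words and
#' words into phrases. With integer group sizes the grouping is deterministic
#' (a trailing smaller group is kept); with \code{jitter = TRUE} group sizes
#' are drawn as \code{1 + Poisson(mean - 1)}.
#'
#' @param events ascending syllable event times in seconds.
#' @param hierarchy list with \code{phonemes_per_syllable},
#'   \code{syllables_per_word}, \code{words_per_phrase}.
#' @param seed optional integer seed (used when \code{jitter = TRUE}).
#' @param jitter randomize group sizes around the hierarchy means.
#' @param story_id story identifier.
#' @return An \code{annotation_set} with tiers phoneme, syllable, word, phrase.
#' @export
gen_annotations <- function(events,
                            hierarchy = list(phonemes_per_syllable = 3,
                                             syllables_per_word = 3,
                                             words_per_phrase = 2),
                            seed = NULL, jitter = FALSE, story_id = "story") {
  if (length(events) == 0) stop("empty event list")
  if (is.unsorted(events)) stop("events must be sorted ascending")
  with_seed(seed, {
    n_syl <- length(events)
    isi <- if (n_syl > 1) median(diff(events)) else 0.2
    on <- events
    off <- c(events[-1], events[n_syl] + isi)
    syl <- data.frame(onset_s = on, offset_s = off,
                      label = paste0("syl", seq_len(n_syl)),
                      stringsAsFactors = FALSE)
    # phonemes: equal subdivision of each syllable
    npp <- hierarchy$phonemes_per_syllable
    pho <- do.call(rbind, lapply(seq_len(n_syl), function(i) {
      k <- if (jitter) max(1, 1 + rpois(1, npp - 1)) else max(1, round(npp))
      edges <- seq(on[i], off[i], length.out = k + 1)
      data.frame(onset_s = edges[-(k + 1)], offset_s = edges[-1],
                 label = paste0("ph", i, "_", seq_len(k)),
                 stringsAsFactors = FALSE)
    }))
    group <- function(n, size) {
      if (jitter) {
        sizes <- integer(0)
        while (sum(sizes) < n) sizes <- c(sizes, max(1, 1 + rpois(1, size - 1)))
        sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
        sizes <- sizes[sizes > 0]
      } else {
        size <- max(1, round(size))
        sizes <- rep(size, n %/% size)
        if (n %% size) sizes <- c(sizes, n %% size)
      }
      rep(seq_along(sizes), sizes)
    }
    wid <- group(n_syl, hierarchy$syllables_per_word)
    word <- do.call(rbind, lapply(unique(wid), function(w) {
      i <- which(wid == w)
      data.frame(onset_s = on[min(i)], offset_s = off[max(i)],
                 label = paste0("w", w), stringsAsFactors = FALSE)
    }))
    pid <- group(nrow(word), hierarchy$words_per_phrase)
    phrase <- do.call(rbind, lapply(unique(pid), function(p) {
      i <- which(pid == p)
      data.frame(onset_s = word$onset_s[min(i)], offset_s = word$offset_s[max(i)],
                 label = paste0("p", p), stringsAsFactors = FALSE)
    }))
    annotation_set(list(phoneme = pho, syllable = syl, word = word,
                        phrase = phrase), story_id = story_id)
  })
}

#' Generate a subject's source-space recording
#'
#' Coupled voxels carry a band-limited, delayed copy of the speech envelope
#' at strength \code{trait * rho_c} (correlation scale) embedded in 1/f
#' background noise; uncoupled voxels are pure 1/f noise. The envelope
#' component is delayed by \code{delay_ms} via a circular shift.
#'
#' @param envelopes an \code{envelope} or list of envelopes (one per story).
#' @param config a \code{\link{simulation_config}}.
#' @param grid a \code{\link{voxel_grid}} (defaults to the grid implied by
#'   \code{config}).
#' @param subject_trait coupling trait in [0, 1].
#' @param seed optional integer seed.
#' @return Object of class \code{source_recording}: \code{stories} (list of
#'   time x voxel matrices), \code{fs}, \code{grid}, \code{coupled_voxels},
#'   \code{rho}.
#' @export
gen_subject_recording <- function(envelopes, config, grid = NULL,
                                  subject_trait, seed = NULL) {
  stopifnot(subject_trait >= 0, subject_trait <= 1)
  if (inherits(envelopes, "envelope")) envelopes <- list(envelopes)
  if (is.null(grid)) grid <- config_grid(config)
  V <- nrow(grid$coords)
  cv <- config$coupled_voxels %||% default_coupled_patch(grid)
  if (any(cv < 1 | cv > V)) stop("coupled voxels outside the grid mask")
  rho <- numeric(V)
  rho[cv] <- subject_trait * config$rho_c
  k <- round(config$delay_ms * config$fs / 1000)
  with_seed(seed, {
    stories <- lapply(envelopes, function(e) {
      x <- env_samples(e)
      n <- length(x)
      if (k >= n) stop("delay exceeds record length")
      s <- bandpass_zero_phase(x, config$band, config$fs)
      s <- s / sd(s)
      s_del <- c(s[(n - k + 1):n], s[seq_len(n - k)])  # circular delay
      noise <- pink_noise(n, V, exponent = config$noise_exponent)
      X <- noise * matrix(sqrt(1 - rho^2), n, V, byrow = TRUE) +
        outer(s_del, rho)
      X
    })
    structure(list(stories = stories, fs = config$fs, grid = grid,
                   coupled_voxels = cv, rho = rho),
              class = "source_recording")
  })
}

#' @export
print.source_recording <- function(x, ...) {
  cat(sprintf("<source_recording> %d stories, %d voxels at %g Hz, %d coupled\n",
              length(x$stories), ncol(x$stories[[1]]), x$fs,
              length(x$coupled_voxels)))
  invisible(x)
}

config_grid <- function(config) {
  voxel_grid(config$grid_dims,
             mask = ellipsoid_mask(config$grid_dims, config$mask_radii))
}

# contiguous 3x3x2 patch near the "temporal" face of the mask
default_coupled_patch <- function(grid) {
  co <- grid$coords
  cx <- round(quantile(co[, 1], 0.75))
  cy <- round(stats::median(co[, 2]))
  cz <- round(stats::median(co[, 3]))
  sel <- which(co[, 1] >= cx - 1 & co[, 1] <= cx + 1 &
                 co[, 2] >= cy - 1 & co[, 2] <= cy + 1 &
                 co[, 3] >= cz & co[, 3] <= cz + 1)
  if (length(sel) < 4) stop("mask too small to place a coupled patch")
  sel
}

#' Generate behavioral word-in-noise scores
#'
#' Raw scores (number of correctly recognized words) increase linearly with
#' the subject trait plus Gaussian noise, are rounded and clamped to the
#' instrument range 0-40, and converted to the 50% SNR threshold with
#' [win_threshold()]. Higher traits therefore yield lower (better)
#' thresholds.
#'
#' @param traits numeric vector of subject traits.
#' @param slope raw-score points per unit trait.
#' @param noise_sd raw-score noise standard deviation (>= 0).
#' @param missing_count number of subjects whose score is set missing.
#' @param seed optional integer seed.
#' @param baseline_raw raw score at trait 0 (default 20.75, which centers the
#'   cohort threshold near 4.6 dB for traits around 0.5).
#' @param ages optional ages in years (default: uniform 22-35).
#' @param family_blocks optional integer family block ids.
#' @return A \code{data.frame} of class \code{behavioral_table} with columns
#'   \code{subject}, \code{raw_correct}, \code{threshold_db}, \code{age},
#'   \code{family}.
#' @export
gen_behavior <- function(traits, slope = 12, noise_sd = 6, missing_count = 0,
                         seed = NULL, baseline_raw = 20.75, ages = NULL,
                         family_blocks = NULL) {
  n <- length(traits)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (missing_count < 0 || missing_count >= n)
    stop("missing_count must be in [0, n_subjects)")
  with_seed(seed, {
    raw <- baseline_raw + slope * traits + rnorm(n, 0, noise_sd)
    raw <- pmin(pmax(round(raw), 0), 40)
    if (is.null(ages)) ages <- round(runif(n, 22, 35))
    if (is.null(family_blocks)) family_blocks <- make_family_blocks(n)
    if (missing_count > 0) raw[sample.int(n, missing_count)] <- NA
    out <- data.frame(subject = seq_len(n), raw_correct = raw,
                      threshold_db = win_threshold(raw), age = ages,
                      family = family_blocks)
    class(out) <- c("behavioral_table", "data.frame")
    out
  })
}

#' Assign family (exchangeability) blocks
#'
#' Places \code{round(pair_frac * n / 2) * 2} subjects into 2-member blocks
#' (emulating twin pairs); the remainder are singletons.
#'
#' @param n number of subjects.
#' @param pair_frac fraction of subjects in 2-member blocks.
#' @param seed optional integer seed (pair membership is the leading
#'   subjects; the seed only matters if \code{shuffle}).
#' @param shuffle randomly permute block assignment over subjects.
#' @return Integer vector of block ids (a partition of \code{1:n}).
#' @export
make_family_blocks <- function(n, pair_frac = 0.2, seed = NULL, shuffle = FALSE) {
  n_pairs <- floor(pair_frac * n / 2)
  ids <- integer(n)
  b <- 0L
  i <- 1L
  while (b < n_pairs) {
    b <- b + 1L
    ids[i:(i + 1)] <- b
    i <- i + 2L
  }
  while (i <= n) {
    b <- b + 1L
    ids[i] <- b
    i <- i + 1L
  }
  if (shuffle) ids <- with_seed(seed, sample(ids))
  ids
}

# ---- VAR ground-truth networks ---------------------------------------------

#' Specify a stable VAR network
#'
#' @param A coefficient array \code{n_nodes x n_nodes x order}; entry
#'   \code{A[i, j, k]} is the influence of node \code{j} at lag \code{k} on
#'   node \code{i}.
#' @param Sigma innovation covariance (symmetric positive definite).
#' @param fs sampling rate in Hz.
#' @return Object of class \code{var_network_spec}.
#' @export
var_network_spec <- function(A, Sigma = diag(dim(A)[1]), fs = 200) {
  if (length(dim(A)) == 2) A <- array(A, c(dim(A), 1))
  m <- dim(A)[1]
  stopifnot(dim(A)[2] == m, nrow(Sigma) == m, ncol(Sigma) == m)
  if (max(abs(Sigma - t(Sigma))) > 1e-10) stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("Sigma must be positive definite")
  r <- companion_radius(A)
  if (r >= 1) stop(sprintf("unstable VAR: companion spectral radius %.3f >= 1", r))
  structure(list(A = A, Sigma = Sigma, fs = fs, n_nodes = m,
                 order = dim(A)[3], radius = r), class = "var_network_spec")
}

companion_radius <- function(A) {
  m <- dim(A)[1]; p <- dim(A)[3]
  C <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) C[1:m, ((k - 1) * m + 1):(k * m)] <- A[, , k]
  if (p > 1) C[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Simulate a stationary VAR realization
#'
#' @param spec a \code{\link{var_network_spec}}.
#' @param n_samples output length.
#' @param seed optional integer seed.
#' @param burn_in samples discarded at the start.
#' @return Numeric matrix \code{n_samples x n_nodes}.
#' @export
gen_var_parcels <- function(spec, n_samples, seed = NULL, burn_in = 500) {
  stopifnot(inherits(spec, "var_network_spec"))
  m <- spec$n_nodes; p <- spec$order
  L <- chol(spec$Sigma)
  with_seed(seed, {
    ntot <- n_samples + burn_in
    E <- matrix(rnorm(ntot * m), ntot, m) %*% L
    X <- matrix(0, ntot, m)
    A <- spec$A
    for (t in (p + 1):ntot) {
      acc <- E[t, ]
      for (k in seq_len(p)) acc <- acc + A[, , k] %*% X[t - k, ]
      X[t, ] <- acc
    }
    X[(burn_in + 1):ntot, , drop = FALSE]
  })
}

#' Analytic spectral density matrix of a VAR network
#'
#' Evaluates \eqn{S(f) = H(f) \Sigma H(f)^*} with
#' \eqn{H(f) = (I - \sum_k A_k e^{-2\pi i f k / fs})^{-1}} on a frequency
#' grid; used as the ground-truth spectrum for the simulated parcels.
#'
#' @param spec a \code{\link{var_network_spec}} (or list with \code{A},
#'   \code{Sigma}, \code{fs}).
#' @param freqs frequencies in Hz.
#' @return A complex array \code{n_nodes x n_nodes x length(freqs)}.
#' @export
var_spectrum <- function(spec, freqs) {
  m <- dim(spec$A)[1]; p <- dim(spec$A)[3]
  out <- array(NA_complex_, c(m, m, length(freqs)))
  for (i in seq_along(freqs)) {
    Af <- diag(m) + 0i
    for (k in seq_len(p))
      Af <- Af - spec$A[, , k] * exp(-2i * pi * freqs[i] * k / spec$fs)
    H <- solve(Af)
    out[, , i] <- H %*% spec$Sigma %*% Conj(t(H)) / spec$fs
  }
  out
}
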