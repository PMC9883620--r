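# Gaussian-copula mutual information between the speech envelope and brain
# signals, and its story-mismatch surrogate distribution.

#' Gaussian-copula transform
#'
#' Maps each value through its rank to a standard-normal quantile,
#' \eqn{\Phi^{-1}((r - 0.5)/n)}. Rank order is preserved exactly; ties are
#' broken by first-occurrence order (stable sort), so the transform is
#' deterministic.
#'
#' @param x numeric vector (or matrix; columns transformed independently).
#' @return Transformed object of the same shape.
#' @examples
#' copula_gauss(c(5, 2, 9))  # qnorm(c(0.5, 1/6, 5/6))
#' @export
copula_gauss <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) < 3) stop("need at least 3 samples")
    if (max(x) == min(x)) stop("constant input has no copula transform")
    return(qnorm((rank(x, ties.method = "first") - 0.5) / length(x)))
  }
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples")
  R <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (max(v) == min(v)) stop("constant input has no copula transform")
    R[, j] <- rank(v, ties.method = "first")
  }
  matrix(qnorm((R - 0.5) / n), n, ncol(x))
}

#' Gaussian mutual information in bits
#'
#' Closed-form mutual information of jointly Gaussian variables,
#' \eqn{I = \frac{1}{2}\log_2\left(\det R_{xx}\det R_{yy}/\det R\right)},
#' computed from the sample covariance of the inputs; with
#' \code{bias_correct} the analytic small-sample bias of the plug-in Gaussian
#' estimator (digamma expansion) is subtracted, so values under independence
#' fluctuate around zero instead of a positive bias floor.
#'
#' Inputs are expected on the copula or z scale (see [copula_gauss()]); the
#' estimator itself only uses their second moments.
#'
#' @param zx numeric vector (or single-column matrix).
#' @param zy numeric vector or matrix (variables in columns).
#' @param bias_correct subtract the analytic bias (default \code{TRUE}).
#' @return Mutual information in bits.
#' @export
mi_gaussian_bits <- function(zx, zy, bias_correct = TRUE) {
  zx <- as.matrix(zx)
  zy <- as.matrix(zy)
  n <- nrow(zx)
  stopifnot(nrow(zy) == n)
  dx <- ncol(zx); dy <- ncol(zy)
  if (n <= dx + dy + 2) stop("too few samples for the joint dimension")
  C <- cov(cbind(zx, zy))
  Cxx <- C[seq_len(dx), seq_len(dx), drop = FALSE]
  Cyy <- C[dx + seq_len(dy), dx + seq_len(dy), drop = FALSE]
  ld <- determinant(C, logarithm = TRUE)
  if (ld$sign <= 0) stop("singular joint covariance")
  i_nats <- 0.5 * (as.numeric(determinant(Cxx, TRUE)$modulus) +
                     as.numeric(determinant(Cyy, TRUE)$modulus) -
                     as.numeric(ld$modulus))
  if (bias_correct) i_nats <- i_nats - mi_bias_nats(n, dx, dy)
  i_nats / log(2)
}

# analytic bias (nats) of the plug-in Gaussian MI estimator
mi_bias_nats <- function(n, dx, dy) {
  psi_terms <- function(d) sum(digamma((n - seq_len(d)) / 2)) / 2
  psi_terms(dx) + psi_terms(dy) - psi_terms(dx + dy)
}

# Vectorized MI (bits) of a 1-D envelope against many 2-D (real, imag) brain
# signals: e is length-n, ZR/ZI are n x V matrices, all on the copula scale.
mi_env_brain_vec <- function(e, ZR, ZI, bias_correct = TRUE) {
  n <- length(e)
  V <- ncol(ZR)
  me <- mean(e)
  mr <- colMeans(ZR); mi_ <- colMeans(ZI)
  ve <- (sum(e * e) - n * me^2) / (n - 1)
  vrr <- (colSums(ZR * ZR) - n * mr^2) / (n - 1)
  vii <- (colSums(ZI * ZI) - n * mi_^2) / (n - 1)
  cri <- (colSums(ZR * ZI) - n * mr * mi_) / (n - 1)
  cer <- (crossprod(ZR, e)[, 1] - n * mr * me) / (n - 1)
  cei <- (crossprod(ZI, e)[, 1] - n * mi_ * me) / (n - 1)
  detyy <- vrr * vii - cri^2
  det3 <- ve * detyy - cer * (cer * vii - cri * cei) +
    cei * (cer * cri - vrr * cei)
  bad <- !(det3 > 0 & detyy > 0 & ve > 0)
  i_nats <- 0.5 * (log(ve) + log(detyy) - log(det3))
  if (bias_correct) i_nats <- i_nats - mi_bias_nats(n, 1, 2)
  i_nats[bad] <- NA_real_
  i_nats / log(2)
}

# ---- SBS maps ---------------------------------------------------------------

# Filter and align one subject's stories for one band: returns per-story
# aligned envelope (real) and analytic brain (complex matrix) blocks.
prepare_band <- function(envelopes, recording, band, delay_ms) {
  fs <- recording$fs
  S <- length(envelopes)
  stopifnot(S == length(recording$stories))
  env_b <- vector("list", S)
  brain_b <- vector("list", S)
  for (s in seq_len(S)) {
    e <- bandpass_zero_phase(env_samples(envelopes[[s]]), band, fs)
    br <- analytic_bandpass(recording$stories[[s]], band, fs)
    al <- analytic_delay(br, e, fs, delay_ms)
    env_b[[s]] <- al$speech
    brain_b[[s]] <- al$brain
  }
  list(env = env_b, brain = brain_b)
}

# MI per voxel for one story pairing: brain story s is paired with envelope
# story pairing[s]; lengths are trimmed head-aligned to the shorter member.
mi_of_pairing <- function(prep, pairing, bias_correct = TRUE) {
  S <- length(prep$env)
  es <- vector("list", S)
  bs <- vector("list", S)
  for (s in seq_len(S)) {
    e <- prep$env[[pairing[s]]]
    b <- prep$brain[[s]]
    L <- min(length(e), nrow(b))
    es[[s]] <- e[seq_len(L)]
    bs[[s]] <- b[seq_len(L), , drop = FALSE]
  }
  e_all <- copula_gauss(unlist(es))
  B <- do.call(rbind, bs)
  ZR <- copula_gauss(Re(B))
  ZI <- copula_gauss(Im(B))
  list(mi = mi_env_brain_vec(e_all, ZR, ZI, bias_correct),
       n = length(e_all))
}

# Fast path used when all aligned story lengths are equal: the copula
# transform of a concatenation does not depend on block order, so transforms
# are computed once and story blocks of the envelope are merely reordered
# per pairing.
precompute_copula <- function(prep) {
  lens <- vapply(prep$env, length, 1L)
  e_all <- copula_gauss(unlist(prep$env))
  B <- do.call(rbind, prep$brain)
  ZR <- copula_gauss(Re(B))
  ZI <- copula_gauss(Im(B))
  blocks <- split(seq_along(e_all), rep(seq_along(lens), lens))
  n <- length(e_all)
  # brain-side moments are invariant under story re-pairing (same samples in
  # the same order), so they are computed once per subject/band
  mr <- colMeans(ZR); mi_ <- colMeans(ZI)
  vrr <- (colSums(ZR * ZR) - n * mr^2) / (n - 1)
  vii <- (colSums(ZI * ZI) - n * mi_^2) / (n - 1)
  cri <- (colSums(ZR * ZI) - n * mr * mi_) / (n - 1)
  me <- mean(e_all)
  ve <- (sum(e_all * e_all) - n * me^2) / (n - 1)
  list(e = e_all, Z = cbind(ZR, ZI), blocks = blocks, n = n, V = ncol(ZR),
       mr = mr, mi_ = mi_, vrr = vrr, vii = vii, cri = cri,
       me = me, ve = ve, detyy = vrr * vii - cri^2)
}

mi_of_pairing_fast <- function(pc, pairing, bias_correct = TRUE) {
  idx <- unlist(pc$blocks[pairing], use.names = FALSE)
  e <- pc$e[idx]
  n <- pc$n; V <- pc$V
  cross <- crossprod(pc$Z, e)[, 1]
  cer <- (cross[seq_len(V)] - n * pc$mr * pc$me) / (n - 1)
  cei <- (cross[V + seq_len(V)] - n * pc$mi_ * pc$me) / (n - 1)
  det3 <- pc$ve * pc$detyy - cer * (cer * pc$vii - pc$cri * cei) +
    cei * (cer * pc$cri - pc$vrr * cei)
  bad <- !(det3 > 0 & pc$detyy > 0 & pc$ve > 0)
  i_nats <- 0.5 * (log(pc$ve) + log(pc$detyy) - log(det3))
  if (bias_correct) i_nats <- i_nats - mi_bias_nats(n, 1, 2)
  i_nats[bad] <- NA_real_
  list(mi = i_nats / log(2), n = n)
}

new_sbs_map <- function(values, n_samples, bands, n_rand = NULL) {
  structure(list(values = values, n_samples = n_samples,
                 bands = bands, n_rand = n_rand),
            class = "sbs_map")
}

#' @export
print.sbs_map <- function(x, ...) {
  d <- dim(x$values)
  what <- if (is.null(x$n_rand)) "sbs_map" else
    sprintf("sbs_map (surrogate, %d randomizations)", x$n_rand)
  cat(sprintf("<%s> %d subjects x %d voxels x %d band(s), %d samples\n",
              what, d[1], d[2], d[3], x$n_samples))
  for (b in seq_len(d[3]))
    cat(sprintf("  %-10s mean %.4f bits, max %.4f bits\n",
                dimnames(x$values)[[3]][b], mean(x$values[, , b]),
                max(x$values[, , b])))
  invisible(x)
}

#' Speech-brain synchrony map
#'
#' For every subject, voxel and band: band-pass both signals, take the
#' analytic brain representation, apply the fixed response delay, concatenate
#' stories, Gaussian-copula transform, and estimate the bias-corrected
#' Gaussian MI between the 1-D envelope and the 2-D (real, imaginary) brain
#' signal.
#'
#' @param envelopes list of story envelopes ([gen_envelope()] objects or
#'   numeric vectors at the recording rate).
#' @param recordings list of \code{source_recording}s, one per subject.
#' @param bands list of \code{\link{rate_band}}s.
#' @param delay_ms brain response delay in ms (default 120).
#' @param bias_correct subtract the analytic MI bias (default \code{TRUE}).
#' @return An \code{sbs_map}: \code{values} is a subjects x voxels x bands
#'   array in bits.
#' @export
sbs_map <- function(envelopes, recordings, bands, delay_ms = 120,
                    bias_correct = TRUE) {
  if (length(envelopes) < 2) stop("need at least 2 stories")
  if (inherits(bands, "rate_band")) bands <- list(bands)
  res <- sbs_analysis(envelopes, recordings, bands, delay_ms,
                      n_rand = 0, bias_correct = bias_correct)
  res$real
}

#' Surrogate (story-mismatched) speech-brain synchrony map
#'
#' Re-estimates GCMI after pairing every recording with a different story
#' (each randomization is a derangement of the story labels, so no pairing is
#' partially matched), trimming the longer member of each mismatched pair,
#' and averages the resulting maps over randomizations.
#'
#' @inheritParams sbs_map
#' @param n_rand number of randomizations (default 50).
#' @param seed integer seed for the derangements.
#' @return An \code{sbs_map} whose values are the surrogate mean.
#' @export
surrogate_sbs <- function(envelopes, recordings, bands, delay_ms = 120,
                          n_rand = 50, seed = NULL, bias_correct = TRUE) {
  if (length(envelopes) < 2) stop("no derangement exists for fewer than 2 stories")
  if (inherits(bands, "rate_band")) bands <- list(bands)
  res <- sbs_analysis(envelopes, recordings, bands, delay_ms,
                      n_rand = n_rand, seed = seed, bias_correct = bias_correct)
  res$surrogate
}

#' Real and surrogate SBS maps in one pass
#'
#' Computes [sbs_map()] and [surrogate_sbs()] while sharing the expensive
#' filtering step; used by [run_pipeline()]. Recordings may be supplied as a
#' list or as a generator \code{function(i)} returning subject \code{i}'s
#' \code{source_recording}, which keeps only one subject in memory at a time.
#'
#' @inheritParams surrogate_sbs
#' @param n_subjects required when \code{recordings} is a generator function.
#' @return List with \code{real} and (if \code{n_rand > 0}) \code{surrogate}
#'   \code{sbs_map}s.
#' @export
sbs_analysis <- function(envelopes, recordings, bands, delay_ms = 120,
                         n_rand = 50, seed = NULL, bias_correct = TRUE,
                         n_subjects = NULL) {
  if (inherits(bands, "rate_band")) bands <- list(bands)
  get_rec <- if (is.function(recordings)) recordings else function(i) recordings[[i]]
  nS <- if (is.function(recordings)) {
    if (is.null(n_subjects)) stop("n_subjects required with a recording generator")
    n_subjects
  } else length(recordings)
  S <- length(envelopes)
  first <- get_rec(1)
  V <- ncol(first$stories[[1]])
  B <- length(bands)
  bnames <- vapply(seq_len(B), function(i) bands[[i]]$name %||% paste0("band", i), "")
  real <- array(NA_real_, c(nS, V, B), dimnames = list(NULL, NULL, bnames))
  surr <- array(NA_real_, c(nS, V, B), dimnames = list(NULL, NULL, bnames))
  pairings <- if (n_rand > 0) {
    with_seed(seed, lapply(seq_len(n_rand), function(i) rand_derangement(S)))
  } else list()
  n_used <- NA_integer_
  for (subj in seq_len(nS)) {
    rec <- if (subj == 1) first else get_rec(subj)
    if (subj == 1) first <- NULL      # allow the generator case to free memory
    for (b in seq_len(B)) {
      prep <- prepare_band(envelopes, rec, bands[[b]], delay_ms)
      lens <- vapply(prep$env, length, 1L)
      if (length(unique(lens)) == 1L) {
        pc <- precompute_copula(prep)
        r <- mi_of_pairing_fast(pc, seq_len(S), bias_correct)
        real[subj, , b] <- r$mi
        if (n_rand > 0) {
          acc <- 0
          for (pg in pairings)
            acc <- acc + mi_of_pairing_fast(pc, pg, bias_correct)$mi
          surr[subj, , b] <- acc / n_rand
        }
      } else {
        r <- mi_of_pairing(prep, seq_len(S), bias_correct)
        real[subj, , b] <- r$mi
        if (n_rand > 0) {
          acc <- 0
          for (pg in pairings) {
            rs <- mi_of_pairing(prep, pg, bias_correct)
            acc <- acc + rs$mi
            n_surr <- rs$n
          }
          surr[subj, , b] <- acc / n_rand
        }
      }
      n_used <- r$n
    }
  }
  if (n_rand > 0 && !exists("n_surr", inherits = FALSE)) n_surr <- n_used
  out <- list(real = new_sbs_map(real, n_used, bands))
  if (n_rand > 0)
    out$surrogate <- new_sbs_map(surr, n_surr, bands, n_rand = n_rand)
  out
}

#' Random derangement of 1..n
#'
#' A uniformly random permutation with no fixed points, drawn by rejection
#' sampling; used to pair recordings with mismatched stories.
#'
#' @param n number of elements (>= 2).
#' @return Integer permutation vector with \code{all(p != 1:n)}.
#' @export
rand_derangement <- function(n) {
  if (n < 2) stop("no derangement exists for n < 2")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}
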