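test_that("zero-jitter envelope is strictly periodic and nonnegative", {
  e <- gen_envelope(4, jitter_cv = 0, duration_s = 5, fs = 200, seed = 1)
  expect_equal(diff(e$events), rep(0.25, length(e$events) - 1), tolerance = 1e-12)
  expect_gte(min(e$samples), 0)
  e2 <- gen_envelope(7, jitter_cv = 0.5, duration_s = 10, fs = 200, seed = 2)
  expect_gte(min(e2$samples), 0)
})

test_that("realized event rate and spectral peak track the target rate", {
  e <- gen_envelope(5, jitter_cv = 0.25, duration_s = 60, fs = 200, seed = 3)
  rate <- length(e$events) / 60
  expect_lt(abs(rate - 5) / 5, 0.05)
  ms <- modulation_spectrum(e)
  peak <- ms$freq[which.max(ms$average)]
  expect_gte(peak, 4.5)
  expect_lte(peak, 5.5)
})

test_that("envelope generation refuses degenerate durations", {
  expect_error(gen_envelope(0.5, 0, duration_s = 1.5, fs = 200),
               "2 events")
})

test_that("annotation hierarchy counts follow integer grouping", {
  ev <- seq(0.2, by = 0.25, length.out = 12)
  ann <- gen_annotations(ev, list(phonemes_per_syllable = 3,
                                  syllables_per_word = 3,
                                  words_per_phrase = 2))
  expect_equal(nrow(ann$tiers$syllable), 12)
  expect_equal(nrow(ann$tiers$word), 4)
  expect_equal(nrow(ann$tiers$phrase), 2)
  expect_equal(nrow(ann$tiers$phoneme), 36)
})

test_that("annotation tiers are disjoint, sorted and nested in the story span", {
  e <- gen_envelope(4.5, 0.3, 20, 200, seed = 11)
  ann <- gen_annotations(e$events, seed = 5, jitter = TRUE)
  for (t in ann$tiers) {
    expect_true(all(t$onset_s < t$offset_s))
    expect_true(!is.unsorted(t$onset_s))
    expect_true(all(t$onset_s[-1] >= t$offset_s[-nrow(t)] - 1e-9))
    expect_gte(min(t$onset_s), min(ann$tiers$syllable$onset_s) - 1e-9)
    expect_lte(max(t$offset_s), max(ann$tiers$syllable$offset_s) + 1e-9)
  }
  ann2 <- gen_annotations(e$events, seed = 5, jitter = TRUE)
  expect_identical(vapply(ann$tiers, nrow, 1L), vapply(ann2$tiers, nrow, 1L))
  expect_error(gen_annotations(numeric(0)), "empty")
})

test_that("coupled voxels carry the envelope at the configured delay", {
  st <- make_tiny_study(n_subjects = 2, seed = 7)
  s <- bandpass_zero_phase(env_samples <- st$envelopes[[1]]$samples,
                           st$cfg$band, 200)
  v <- st$recordings[[2]]$stories[[1]][, st$coupled[1]]
  cc <- stats::ccf(v, s, lag.max = 60, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], round(0.120 * 200))
})

test_that("GCMI grows with the planted subject trait", {
  st <- make_tiny_study(n_subjects = 2, seed = 13)
  # same noise seed structure, traits 0.2 vs 0.9
  rec_lo <- gen_subject_recording(st$envelopes, st$cfg, st$grid, 0.2, seed = 99)
  rec_hi <- gen_subject_recording(st$envelopes, st$cfg, st$grid, 0.9, seed = 99)
  m <- sbs_map(st$envelopes, list(rec_lo, rec_hi), st$cfg$band)
  cv <- st$coupled
  expect_gt(mean(m$values[2, cv, 1]), mean(m$values[1, cv, 1]))
})

test_that("behavioral scores recover the planted association", {
  set.seed(21)
  traits <- runif(500)
  # slope/noise chosen for a planted trait-threshold correlation of -0.4:
  # |r| = s*sd(t)/sqrt(s^2 var(t) + sd_n^2) with sd(t) = sqrt(1/12)
  s <- 12; sd_n <- s * sqrt(1 / 12) * sqrt(1 / 0.4^2 - 1)
  b <- gen_behavior(traits, slope = s, noise_sd = sd_n, seed = 22)
  r <- cor(traits, b$threshold_db)
  expect_lt(abs(r - (-0.4)), 0.1)
  # null effect at the cohort size of the reference study
  b0 <- gen_behavior(runif(53), slope = 0, noise_sd = 4, seed = 23)
  expect_lt(abs(cor(b0$raw_correct, seq_len(53))), 0.3)
})

test_that("exactly the requested number of scores is missing", {
  b <- gen_behavior(runif(20, 0, 1), missing_count = 1, seed = 3)
  expect_equal(sum(is.na(b$threshold_db)), 1)
  expect_equal(sum(is.na(b$raw_correct)), 1)
  expect_error(gen_behavior(runif(5), noise_sd = -1), "nonnegative")
})

test_that("family blocks partition subjects with paired leading blocks", {
  bl <- make_family_blocks(20, pair_frac = 0.2)
  expect_equal(length(bl), 20)
  expect_equal(sum(table(bl) == 2), 2)
  expect_equal(sort(unique(bl)), seq_len(max(bl)))
})

test_that("VAR simulation is deterministic, stable and spectrally faithful", {
  A <- array(0, c(2, 2, 2))
  A[1, 1, 1] <- 0.5; A[1, 1, 2] <- -0.3
  A[2, 2, 1] <- 0.4; A[2, 1, 1] <- 0.4
  spec <- var_network_spec(A, matrix(c(1, 0.2, 0.2, 1), 2), fs = 200)
  X1 <- gen_var_parcels(spec, 3000, seed = 8)
  X2 <- gen_var_parcels(spec, 3000, seed = 8)
  expect_identical(X1, X2)

  # unstable spec refused
  Abad <- array(0, c(2, 2, 1)); Abad[1, 1, 1] <- 1.01
  expect_error(var_network_spec(Abad), "unstable")

  # realized Welch spectrum close to the analytic one at n = 20000
  X <- gen_var_parcels(spec, 20000, seed = 9)
  nseg <- 37; L <- 1024
  acc <- 0
  for (k in seq_len(nseg)) {
    seg <- X[((k - 1) * 512 + 1):((k - 1) * 512 + L), 1]
    seg <- (seg - mean(seg)) * (0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)))
    acc <- acc + Mod(fft(seg))^2
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  emp <- acc / nseg / (sum(w^2) * 200)
  # average adjacent (near-independent) frequency bins to suppress
  # periodogram variance before comparing with the analytic spectrum
  emp <- as.numeric(stats::filter(emp, rep(1 / 5, 5), sides = 2))
  f <- (0:(L - 1)) * 200 / L
  keep <- which(f >= 2 & f <= 90)
  thry <- Re(var_spectrum(spec, f[keep])[1, 1, ])
  mad_rel <- mean(abs(emp[keep] - thry)) / mean(thry)
  expect_lt(mad_rel, 0.10)
})

test_that("uncoupled VAR nodes show no Granger causality", {
  A <- array(0, c(2, 2, 1)); A[1, 1, 1] <- 0.5; A[2, 2, 1] <- 0.5
  spec <- var_network_spec(A, diag(2), fs = 200)
  X <- gen_var_parcels(spec, 20000, seed = 10)
  gc <- spectral_gc(X[, 1], X[, 2], fs = 200, order_max = 5)
  expect_lt(gc$gc_time_xy, 0.01)
  expect_lt(gc$gc_time_yx, 0.01)
})
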