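# Linguistic-rate frequency bands, speech envelope extraction and the
# modulation spectrum of the stimulus material.

#' Construct a linguistic rate band
#'
#' @param name one of \code{"phrase"}, \code{"word"}, \code{"syllable"},
#'   \code{"phoneme"} (other labels are allowed for custom bands).
#' @param f_lo,f_hi band edges in Hz, \code{0 < f_lo < f_hi}.
#' @return An object of class \code{rate_band}.
#' @export
rate_band <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(f_lo), is.finite(f_hi), f_lo > 0, f_hi > f_lo)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "rate_band")
}

#' @export
print.rate_band <- function(x, ...) {
  cat(sprintf("<rate_band> %s: %.2f-%.2f Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

band_edges <- function(band) {
  if (inherits(band, "rate_band")) c(band$f_lo, band$f_hi) else as.numeric(band)
}

#' Corpus-derived default rate bands
#'
#' Pass-band edges for the four linguistic timescales as established on the
#' 14-story corpus the method was developed with: phrase 0.2-2 Hz, word
#' 2.4-4.9 Hz, syllable 3.4-6.5 Hz (word and syllable overlap) and phoneme
#' 8.4-14.1 Hz.
#'
#' @return Named list of \code{\link{rate_band}} objects.
#' @export
default_rate_bands <- function() {
  list(phrase   = rate_band("phrase",   0.2, 2.0),
       word     = rate_band("word",     2.4, 4.9),
       syllable = rate_band("syllable", 3.4, 6.5),
       phoneme  = rate_band("phoneme",  8.4, 14.1))
}

#' Per-story unit rate of a linguistic tier
#'
#' Rate of occurrence of a tier's units within one story: unit count divided
#' by the tier span (last offset minus first onset).
#'
#' @param annotations an \code{annotation_set} (see [gen_annotations()] or
#'   [read_annotations_tsv()]).
#' @param tier tier name, e.g. \code{"syllable"}.
#' @return Rate in Hz.
#' @export
unit_rates <- function(annotations, tier) {
  tr <- annotations$tiers[[tier]]
  if (is.null(tr) || nrow(tr) == 0L) stop("tier absent or empty: ", tier)
  span <- max(tr$offset_s) - min(tr$onset_s)
  if (span <= 0) stop("zero tier span")
  nrow(tr) / span
}

#' Derive a pass band from per-story unit rates
#'
#' The band edges are the minimum and maximum of the per-story rates, so the
#' result is invariant to story order.
#'
#' @param rates numeric vector of per-story rates (Hz), length >= 2.
#' @param name band name.
#' @return A \code{\link{rate_band}}.
#' @export
derive_bands <- function(rates, name = "band") {
  stopifnot(length(rates) >= 2, all(is.finite(rates)), all(rates > 0))
  lo <- min(rates); hi <- max(rates)
  if (lo == hi) stop("degenerate band: all stories have identical rate")
  rate_band(name, lo, hi)
}

#' Extract the amplitude envelope of a waveform
#'
#' Magnitude of the analytic signal of the broadband waveform, low-passed
#' with a zero-phase 4th-order Butterworth at \code{lp_hz}, optionally
#' decimated to a target rate. Negative values arising from filter overshoot
#' are clipped at zero.
#'
#' @param waveform numeric vector.
#' @param fs sampling rate of \code{waveform} in Hz (> 60).
#' @param lp_hz low-pass edge in Hz (default 30).
#' @param fs_out optional output rate; must divide \code{fs}.
#' @return Numeric nonnegative envelope (at \code{fs_out} if given).
#' @export
extract_envelope <- function(waveform, fs, lp_hz = 30, fs_out = NULL) {
  stopifnot(is.numeric(waveform), all(is.finite(waveform)), fs > 60)
  if (all(waveform == 0)) {
    warning("all-zero waveform; returning zero envelope")
    env <- waveform
  } else {
    n <- length(waveform)
    m <- nextn(n, c(2, 3, 5))
    xp <- c(waveform, numeric(m - n))
    h <- numeric(m); h[1] <- 1
    if (m %% 2 == 0) { h[m / 2 + 1] <- 1; h[2:(m / 2)] <- 2 } else h[2:((m + 1) / 2)] <- 2
    analytic <- fft(fft(xp) * h, inverse = TRUE) / m
    env <- Mod(analytic[seq_len(n)])
    env <- zero_phase_apply(env, function(m) lowpass_response(m, lp_hz, fs),
                            pad = round(3 * fs / lp_hz))
    env <- pmax(env, 0)
  }
  if (!is.null(fs_out)) {
    dec <- fs / fs_out
    if (abs(dec - round(dec)) > 1e-9) stop("fs_out must divide fs")
    env <- env[seq(1, length(env), by = round(dec))]
  }
  env
}

#' Normalized modulation spectrum of the stimulus material
#'
#' Computes the spectrum of each story's (demeaned) envelope, normalizes each
#' to unit maximum, interpolates onto a common frequency grid and averages
#' across stories.
#'
#' @param envelopes a numeric envelope, an \code{envelope} object, or a list
#'   of either (one per story).
#' @param fs sampling rate in Hz (taken from \code{envelope} objects when
#'   available).
#' @param bands optional list of \code{\link{rate_band}}s attached for
#'   plotting of the band ranges.
#' @param f_min,f_max frequency grid limits (defaults 0.5 and 30 Hz); every
#'   story must span at least two cycles of \code{f_min}.
#' @param df grid step (default 0.05 Hz).
#' @return Object of class \code{modulation_spectrum} with fields \code{freq},
#'   \code{per_story} (stories in columns, each with maximum 1) and
#'   \code{average}.
#' @export
modulation_spectrum <- function(envelopes, fs = NULL, bands = NULL,
                                f_min = 0.5, f_max = 30, df = 0.05) {
  if (inherits(envelopes, "envelope") || is.numeric(envelopes))
    envelopes <- list(envelopes)
  stopifnot(length(envelopes) >= 1, f_min > 0, f_max > f_min)
  grid <- seq(f_min, f_max, by = df)
  spec <- sapply(envelopes, function(e) {
    if (inherits(e, "envelope")) { x <- e$samples; fse <- e$fs } else { x <- e; fse <- fs }
    if (is.null(fse)) stop("fs must be supplied for plain numeric envelopes")
    if (length(x) < 2 * fse / f_min) stop("story too short for the lowest frequency")
    x <- x - mean(x)
    m <- nextn(length(x), c(2, 3, 5))
    P <- Mod(fft(c(x, numeric(m - length(x)))))^2
    f <- (0:(m - 1)) * fse / m
    keep <- f > 0 & f <= f_max + 1
    # smooth over a fixed ~0.5 Hz window: stabilizes the peak location of
    # quasi-rhythmic envelopes without shifting symmetric peaks
    binw <- fse / m
    half <- max(1, floor(0.25 / binw))
    kern <- (half + 1) - abs(-half:half)   # triangular: unique max at center
    kern <- kern / sum(kern)
    ps <- stats::filter(P[keep], kern, sides = 2)
    ps[is.na(ps)] <- P[keep][is.na(ps)]
    s <- stats::approx(f[keep], as.numeric(ps), xout = grid, rule = 2)$y
    s / max(s)
  })
  spec <- as.matrix(spec)
  structure(list(freq = grid, per_story = spec, average = rowMeans(spec),
                 bands = bands),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  pk <- x$freq[which.max(x$average)]
  cat(sprintf("<modulation_spectrum> %d stories, grid %.2f-%.1f Hz, average peak at %.2f Hz\n",
              ncol(x$per_story), min(x$freq), max(x$freq), pk))
  invisible(x)
}

#' @export
plot.modulation_spectrum <- function(x, ...) {
  graphics::plot(x$freq, x$average, type = "n", log = "x",
                 xlab = "Modulation frequency (Hz)",
                 ylab = "Normalized power", ...)
  if (!is.null(x$bands)) {
    cols <- grDevices::adjustcolor(seq_along(x$bands) + 1, alpha.f = 0.2)
    for (i in seq_along(x$bands)) {
      b <- x$bands[[i]]
      graphics::rect(b$f_lo, 0, b$f_hi, 1.02, col = cols[i], border = NA)
    }
  }
  graphics::matlines(x$freq, x$per_story, col = "grey70", lty = 1)
  graphics::lines(x$freq, x$average, lwd = 2)
  invisible(x)
}

# ---- annotation I/O ---------------------------------------------------------

#' Read tiered annotations from TSV
#'
#' Expected columns: \code{tier}, \code{onset_s}, \code{offset_s},
#' \code{label} (UTF-8, seconds).
#'
#' @param path file path.
#' @param story_id optional story identifier stored on the result.
#' @return An \code{annotation_set}.
#' @export
read_annotations_tsv <- function(path, story_id = basename(path)) {
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("tier", "onset_s", "offset_s", "label")
  if (!all(need %in% names(d))) stop("TSV must have columns: ", paste(need, collapse = ", "))
  tiers <- split(d[c("onset_s", "offset_s", "label")], d$tier)
  tiers <- lapply(tiers, function(t) t[order(t$onset_s), , drop = FALSE])
  annotation_set(tiers, story_id = story_id)
}

#' Write tiered annotations to TSV
#'
#' @param annotations an \code{annotation_set}.
#' @param path file path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  rows <- do.call(rbind, lapply(names(annotations$tiers), function(nm) {
    t <- annotations$tiers[[nm]]
    data.frame(tier = nm, onset_s = sprintf("%.4f", t$onset_s),
               offset_s = sprintf("%.4f", t$offset_s), label = t$label,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a Praat TextGrid (long format, interval tiers)
#'
#' A minimal parser for the long TextGrid dialect produced by forced
#' aligners: interval tiers only, one interval per \code{intervals [k]} block.
#' Intervals with empty labels are dropped.
#'
#' @param path file path.
#' @param story_id optional story identifier.
#' @return An \code{annotation_set}.
#' @export
read_textgrid <- function(path, story_id = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  num <- function(s) as.numeric(sub(".*=\\s*", "", s))
  str <- function(s) gsub("^\\s*|\"|\\s*$", "", sub(".*=", "", s))
  tiers <- list()
  cur <- NULL
  xmin <- xmax <- NA_real_
  for (ln in lines) {
    if (grepl("name\\s*=", ln)) {
      cur <- str(ln)
      tiers[[cur]] <- data.frame(onset_s = numeric(), offset_s = numeric(),
                                 label = character(), stringsAsFactors = FALSE)
    } else if (grepl("^\\s*xmin\\s*=", ln)) {
      xmin <- num(ln)
    } else if (grepl("^\\s*xmax\\s*=", ln)) {
      xmax <- num(ln)
    } else if (grepl("^\\s*text\\s*=", ln) && !is.null(cur)) {
      lab <- str(ln)
      if (nzchar(lab)) {
        tiers[[cur]] <- rbind(tiers[[cur]],
                              data.frame(onset_s = xmin, offset_s = xmax,
                                         label = lab, stringsAsFactors = FALSE))
      }
    }
  }
  tiers <- Filter(function(t) nrow(t) > 0, tiers)
  annotation_set(tiers, story_id = story_id)
}

#' Write an annotation set as a long-format Praat TextGrid
#'
#' @param annotations an \code{annotation_set}.
#' @param path file path.
#' @export
write_textgrid <- function(annotations, path) {
  span <- range(unlist(lapply(annotations$tiers, function(t) c(t$onset_s, t$offset_s))))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"'); w('Object class = "TextGrid"'); w("")
  w("xmin = %.6f", span[1]); w("xmax = %.6f", span[2])
  w("tiers? <exists>"); w("size = %d", length(annotations$tiers))
  w("item []:")
  for (i in seq_along(annotations$tiers)) {
    t <- annotations$tiers[[i]]
    w("    item [%d]:", i)
    w('        class = "IntervalTier"')
    w('        name = "%s"', names(annotations$tiers)[i])
    w("        xmin = %.6f", span[1]); w("        xmax = %.6f", span[2])
    w("        intervals: size = %d", nrow(t))
    for (k in seq_len(nrow(t))) {
      w("        intervals [%d]:", k)
      w("            xmin = %.6f", t$onset_s[k])
      w("            xmax = %.6f", t$offset_s[k])
      w('            text = "%s"', t$label[k])
    }
  }
  invisible(path)
}
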