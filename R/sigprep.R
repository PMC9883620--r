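# Band-limiting, analytic representation and temporal alignment of speech
# and brain signals.
#
# All frequency-band filtering in the package goes through a 4th-order
# Butterworth band-pass applied with zero net phase: the squared magnitude
# response of the digital Butterworth design (signal::butter) is applied in
# the frequency domain after odd reflective padding, which realizes exactly
# the transfer function of forward-backward time-domain filtering while
# operating on whole voxel matrices at once.

butter_response <- function(m, band, fs, order = 4) {
  ba <- signal::butter(order, c(band[1], band[2]) / (fs / 2), type = "pass")
  w <- 2 * pi * (0:(m - 1)) / m
  z <- exp(-1i * w)
  num <- outer(z, seq_along(ba$b) - 1, "^") %*% ba$b
  den <- outer(z, seq_along(ba$a) - 1, "^") %*% ba$a
  as.vector(Mod(num / den)^2)
}

lowpass_response <- function(m, f_hi, fs, order = 4) {
  ba <- signal::butter(order, f_hi / (fs / 2), type = "low")
  w <- 2 * pi * (0:(m - 1)) / m
  z <- exp(-1i * w)
  num <- outer(z, seq_along(ba$b) - 1, "^") %*% ba$b
  den <- outer(z, seq_along(ba$a) - 1, "^") %*% ba$a
  as.vector(Mod(num / den)^2)
}

pad_reflect <- function(X, ip) {
  n <- nrow(X)
  top <- 2 * matrix(X[1, ], ip, ncol(X), byrow = TRUE) - X[(ip + 1):2, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], ip, ncol(X), byrow = TRUE) - X[(n - 1):(n - ip), , drop = FALSE]
  rbind(top, X, bot)
}

zero_phase_apply <- function(x, gain_fun, pad, analytic = FALSE) {
  xvec <- is.null(dim(x))
  X <- as.matrix(x)
  n <- nrow(X)
  ip <- min(pad, n - 1)
  Xp <- pad_reflect(X, ip)
  m0 <- nrow(Xp)
  m <- nextn(m0, c(2, 3, 5))
  if (m > m0) Xp <- rbind(Xp, matrix(0, m - m0, ncol(Xp)))
  G <- gain_fun(m)
  if (analytic) {
    h <- numeric(m)
    h[1] <- 1
    if (m %% 2 == 0) {
      h[m / 2 + 1] <- 1
      h[2:(m / 2)] <- 2
    } else h[2:((m + 1) / 2)] <- 2
    G <- G * h
  }
  Y <- mvfft(mvfft(Xp) * G, inverse = TRUE) / m
  if (!analytic) Y <- Re(Y)
  Y <- Y[(ip + 1):(ip + n), , drop = FALSE]
  if (xvec) Y <- drop(Y)
  Y
}

#' Zero-phase Butterworth band-pass filter
#'
#' Filters a series (or each column of a matrix) with a 4th-order Butterworth
#' band-pass applied with zero net phase, after odd reflective edge padding.
#'
#' @param x numeric vector or matrix (series in columns).
#' @param band numeric length-2 \code{c(f_lo, f_hi)} in Hz, or a
#'   \code{\link{rate_band}}.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return Filtered object of the same shape as \code{x}.
#' @examples
#' fs <- 200
#' x <- sin(2 * pi * 5 * seq(0, 10, by = 1 / fs))
#' y <- bandpass_zero_phase(x, c(3.4, 6.5), fs)
#' @export
bandpass_zero_phase <- function(x, band, fs, order = 4) {
  band <- band_edges(band)
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fs / 2))
    stop("band edges must satisfy 0 < f_lo < f_hi < fs/2")
  if (n < 4 * order) stop("series too short to filter")
  pad <- round(3 * fs / band[1])
  zero_phase_apply(x, function(m) butter_response(m, band, fs, order), pad)
}

#' Band-limited analytic signal
#'
#' Zero-phase band-pass as in [bandpass_zero_phase()] combined with the
#' Hilbert transform: the real part is the band-passed series and the
#' imaginary part its quadrature (90 degree shifted) counterpart.
#'
#' @inheritParams bandpass_zero_phase
#' @return Complex vector or matrix of the same shape as \code{x}.
#' @export
analytic_bandpass <- function(x, band, fs, order = 4) {
  band <- band_edges(band)
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (!(band[1] > 0 && band[2] > band[1] && band[2] < fs / 2))
    stop("band edges must satisfy 0 < f_lo < f_hi < fs/2")
  if (n < 4 * order) stop("series too short to filter")
  pad <- round(3 * fs / band[1])
  zero_phase_apply(x, function(m) butter_response(m, band, fs, order), pad,
                   analytic = TRUE)
}

#' Align a brain signal to the speech envelope at a fixed response delay
#'
#' Cortical responses trail the speech input by roughly 120 ms; this advances
#' the brain series by the corresponding integer number of samples so that
#' concurrent samples of the two outputs are matched at that delay, and trims
#' both to the common support.
#'
#' @param brain complex (analytic) vector or matrix, time in rows.
#' @param speech numeric band-limited speech envelope at the same sampling
#'   rate.
#' @param fs sampling rate in Hz.
#' @param delay_ms assumed brain response delay in milliseconds (default 120).
#' @return A list with elements \code{speech}, \code{brain} (trimmed to equal
#'   length) and \code{shift}, the integer sample shift applied.
#' @export
analytic_delay <- function(brain, speech, fs, delay_ms = 120) {
  stopifnot(delay_ms >= 0)
  k <- round(delay_ms * fs / 1000)
  bmat <- !is.null(dim(brain))
  nb <- if (bmat) nrow(brain) else length(brain)
  ns <- length(speech)
  n <- min(nb, ns)
  if (k >= n) stop("delay exceeds record length")
  sp <- speech[seq_len(n - k)]
  br <- if (bmat) brain[(k + 1):n, , drop = FALSE] else brain[(k + 1):n]
  list(speech = sp, brain = br, shift = k)
}
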