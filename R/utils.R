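#' @keywords internal
"_PACKAGE"

#' @importFrom stats qnorm qt pnorm pt rnorm runif rgamma cor sd quantile fft
#'   mvfft nextn cov kmeans prcomp cancor p.adjust rpois median approx
#'   complete.cases
#' @importFrom utils write.table read.table head tail
#' @importFrom graphics plot lines rect
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master integer seed and a stage label to a new
#' seed below 2^31, so that every stochastic stage of a pipeline draws from
#' an independent, reproducible stream.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  p <- 2147483647
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% p
  s <- ((abs(master) %% p) * 48271 + h + 1) %% p
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Generate 1/f ("pink") noise
#'
#' Spectrally shaped Gaussian noise with power spectral density proportional
#' to \code{1/f^exponent}, used as the neural background in the synthetic
#' source recordings. Shaping is done in the frequency domain; the output is
#' scaled to unit standard deviation.
#'
#' @param n number of samples (one column per series if \code{n_series > 1}).
#' @param n_series number of independent series.
#' @param exponent spectral exponent (1 gives classic pink noise).
#' @param seed optional integer seed.
#' @return Numeric matrix \code{n x n_series} (a vector if \code{n_series = 1}).
#' @export
pink_noise <- function(n, n_series = 1, exponent = 1, seed = NULL) {
  stopifnot(n > 3, n_series >= 1, exponent >= 0)
  with_seed(seed, {
    m <- nextn(n, c(2, 3, 5))
    W <- matrix(rnorm(m * n_series), m, n_series)
    k <- 0:(m - 1)
    f_phys <- pmin(k, m - k)              # symmetric physical frequency index
    amp <- ifelse(f_phys == 0, 0, f_phys^(-exponent / 2))
    X <- mvfft(W) * amp
    Y <- Re(mvfft(X, inverse = TRUE)) / m
    Y <- Y[seq_len(n), , drop = FALSE]
    Y <- scale(Y)
    attr(Y, "scaled:center") <- NULL
    attr(Y, "scaled:scale") <- NULL
    if (n_series == 1) as.numeric(Y) else Y
  })
}

# closed-form 3x3 / 2x2 determinant helpers used by the vectorized MI path
det2 <- function(a, b, c) a * c - b * b
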