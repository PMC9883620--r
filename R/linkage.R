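# Linking edge connectivity spectra to speech tracking and behavior:
# spectral PCA reduction, canonical correlation with permutation/FDR,
# post-hoc mode characterization, and mediation analysis.

#' Reduce edge spectra to principal-component features
#'
#' Per edge, a PCA across subjects over the frequency dimension retains
#' \code{n_pc} component scores per subject. A warning (not an error) is
#' emitted when the retained variance falls below \code{min_var}.
#'
#' @param spectra subjects x edges x frequencies array (see [edge_gc()]), or
#'   a subjects x frequencies matrix for a single edge.
#' @param n_pc components retained per edge (default 3).
#' @param min_var variance-explained warning threshold (default 0.98).
#' @return List with \code{features} (list per edge of subjects x n_pc score
#'   matrices), \code{var_explained} (per edge), \code{rotation} (per-edge
#'   loadings), \code{center}.
#' @export
reduce_spectra <- function(spectra, n_pc = 3, min_var = 0.98) {
  if (length(dim(spectra)) == 2) {
    spectra <- array(spectra, c(nrow(spectra), 1, ncol(spectra)))
  }
  stopifnot(length(dim(spectra)) == 3)
  nS <- dim(spectra)[1]; nE <- dim(spectra)[2]
  if (nS < n_pc + 2) stop("need at least n_pc + 2 subjects")
  feats <- vector("list", nE)
  ve <- numeric(nE)
  rot <- vector("list", nE)
  ctr <- vector("list", nE)
  for (e in seq_len(nE)) {
    M <- spectra[, e, ]
    if (max(M) == min(M)) stop("constant spectra for edge ", e)
    pc <- prcomp(M, center = TRUE, scale. = FALSE)
    k <- min(n_pc, ncol(pc$x))
    feats[[e]] <- pc$x[, seq_len(k), drop = FALSE]
    ve[e] <- sum(pc$sdev[seq_len(k)]^2) / sum(pc$sdev^2)
    rot[[e]] <- pc$rotation[, seq_len(k), drop = FALSE]
    ctr[[e]] <- pc$center
  }
  names(feats) <- names(ve) <- dimnames(spectra)[[2]]
  if (any(ve < min_var))
    warning(sprintf("%d edge(s) below %.0f%% variance explained by %d PCs",
                    sum(ve < min_var), 100 * min_var, n_pc))
  list(features = feats, var_explained = ve, rotation = rot, center = ctr)
}

#' Canonical correlation analysis of two variable sets
#'
#' Standardizes the columns of both sets and finds the paired linear
#' combinations with maximal correlation. Canonical scores are scaled to
#' unit variance.
#'
#' @param X,Y numeric matrices with subjects in rows.
#' @return Object of class \code{cca_fit}: \code{cor} (canonical
#'   correlations), \code{xweights}, \code{yweights} (for the standardized
#'   columns), \code{scores_x}, \code{scores_y}.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(nrow(Y) == n, n > ncol(X) + ncol(Y))
  if (any(apply(X, 2, sd) == 0) || any(apply(Y, 2, sd) == 0))
    stop("constant columns are not allowed")
  Xs <- scale(X); Ys <- scale(Y)
  cc <- cancor(Xs, Ys, xcenter = FALSE, ycenter = FALSE)
  k <- length(cc$cor)
  xw <- cc$xcoef[, seq_len(k), drop = FALSE]
  yw <- cc$ycoef[, seq_len(k), drop = FALSE]
  sx <- Xs %*% xw
  sy <- Ys %*% yw
  fx <- apply(sx, 2, sd); fy <- apply(sy, 2, sd)
  sx <- sweep(sx, 2, fx, "/"); xw <- sweep(xw, 2, fx, "/")
  sy <- sweep(sy, 2, fy, "/"); yw <- sweep(yw, 2, fy, "/")
  structure(list(cor = cc$cor, xweights = xw, yweights = yw,
                 scores_x = sx, scores_y = sy, n = n),
            class = "cca_fit")
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("<cca_fit> n = %d; canonical correlations: %s\n", x$n,
              paste(sprintf("%.3f", x$cor), collapse = ", ")))
  invisible(x)
}

#' Permutation significance of CCA modes with FDR correction
#'
#' For each registered test (one CCA per edge/direction), the first
#' canonical correlation is compared with its null distribution obtained by
#' permuting the subject labels of the outcome set; raw p-values are then
#' Benjamini-Hochberg adjusted across all \code{m_tests} tests.
#'
#' @param X_list list of connectivity feature matrices (one per test).
#' @param Y outcome matrix shared by all tests (e.g. standardized SBS and
#'   behavioral score).
#' @param n_perm permutations per test (default 1000).
#' @param seed integer seed.
#' @param m_tests number of tests in the correction family (default
#'   \code{length(X_list)}).
#' @return Data frame with \code{test}, \code{rho} (first canonical
#'   correlation), \code{p}, \code{p_fdr}, plus attribute \code{fits} (the
#'   \code{cca_fit} per test).
#' @export
cca_perm_fdr <- function(X_list, Y, n_perm = 1000, seed = NULL,
                         m_tests = length(X_list)) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values are coarse")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  fits <- lapply(X_list, cca_fit, Y = Y)
  rho <- vapply(fits, function(f) f$cor[1], 0)
  p <- with_seed(seed, {
    vapply(seq_along(X_list), function(i) {
      X <- as.matrix(X_list[[i]])
      null <- vapply(seq_len(n_perm), function(b) {
        cca_fit(X, Y[sample.int(n), , drop = FALSE])$cor[1]
      }, 0)
      (1 + sum(null >= rho[i])) / (n_perm + 1)
    }, 0)
  })
  p_fdr <- p.adjust(p, method = "BH", n = max(m_tests, length(p)))
  out <- data.frame(test = names(X_list) %||% seq_along(X_list),
                    rho = rho, p = p, p_fdr = p_fdr,
                    stringsAsFactors = FALSE)
  attr(out, "fits") <- fits
  out
}

#' Post-hoc characterization of a canonical mode
#'
#' Pearson correlations of the canonical scores with the speech-tracking and
#' behavioral variables and (optionally) with the fully resolved
#' connectivity spectrum at each frequency, with Fisher-z 95% confidence
#' intervals.
#'
#' @param scores canonical score vector (one value per subject).
#' @param sbs,win numeric vectors per subject.
#' @param spectra optional subjects x frequencies matrix of the edge's
#'   spectrally resolved connectivity.
#' @param conf confidence level (default 0.95).
#' @return List with \code{sbs}, \code{win} (each \code{c(r, lo, hi, p)})
#'   and, when spectra are given, \code{profile} (per-frequency r with CI).
#' @export
posthoc_profile <- function(scores, sbs, win, spectra = NULL, conf = 0.95) {
  if (sd(scores) == 0) stop("degenerate canonical scores")
  n <- length(scores)
  ci <- function(r) {
    r <- max(min(r, 1), -1)
    if (abs(r) >= 1 || n <= 3) return(c(r = r, lo = r, hi = r, p = 0))
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    q <- qnorm(1 - (1 - conf) / 2)
    pv <- 2 * pnorm(-abs(z) / se)
    c(r = r, lo = tanh(z - q * se), hi = tanh(z + q * se), p = pv)
  }
  out <- list(sbs = ci(cor(scores, sbs)), win = ci(cor(scores, win)))
  if (!is.null(spectra)) {
    spectra <- as.matrix(spectra)
    rr <- as.numeric(cor(scores, spectra))
    out$profile <- t(vapply(rr, ci, c(r = 0, lo = 0, hi = 0, p = 0)))
  }
  out
}

#' Indirect effect by the difference method
#'
#' The portion of a total effect carried by a mediator, computed as the
#' total effect minus the direct effect, \code{c - c'}.
#'
#' @param c_total total-effect path coefficient.
#' @param c_direct direct-effect path coefficient (mediator included).
#' @return The indirect effect.
#' @export
indirect_difference <- function(c_total, c_direct) c_total - c_direct

# closed-form OLS with intercept: returns coefficients, SEs, residuals
ols_fit <- function(X, y) {
  X1 <- cbind(1, X)
  XtX <- crossprod(X1)
  b <- solve(XtX, crossprod(X1, y))
  r <- y - X1 %*% b
  n <- length(y); k <- ncol(X1)
  s2 <- sum(r^2) / (n - k)
  se <- sqrt(diag(solve(XtX)) * s2)
  pt2 <- 2 * stats::pt(-abs(b / se), df = n - k)
  list(coef = as.numeric(b), se = as.numeric(se), p = as.numeric(pt2))
}

#' Mediation analysis with Sobel test and bootstrap confidence interval
#'
#' Ordinary-least-squares decomposition of the predictor-outcome effect into
#' a direct path and a mediator-carried (indirect) path: fits
#' \code{m ~ x} (path a), \code{y ~ x + m} (paths c' and b) and
#' \code{y ~ x} (path c). The indirect effect is reported both as the
#' product \code{a*b} and the difference \code{c - c'} (identical for a
#' single mediator with complete data). Significance of the indirect path is
#' assessed by Sobel's z and by a percentile bootstrap of \code{a*b} over
#' subject resamples.
#'
#' @param x predictor (e.g. speech-brain synchrony score).
#' @param m mediator (e.g. CCA-weighted top-down connectivity).
#' @param y outcome (e.g. transformed word-in-noise score).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return Object of class \code{mediation} with the path table, Sobel z and
#'   p, the bootstrap CI of \code{a*b}, and both indirect-effect estimates.
#' @export
mediate <- function(x, m, y, n_boot = 1000, seed = NULL, conf = 0.95) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete cases")
  if (abs(cor(x, m)) > 0.999) stop("predictor and mediator are collinear")
  fa <- ols_fit(cbind(x), m)
  fb <- ols_fit(cbind(x, m), y)
  fc <- ols_fit(cbind(x), y)
  a <- fa$coef[2]; se_a <- fa$se[2]
  cprime <- fb$coef[2]; se_cp <- fb$se[2]
  b <- fb$coef[3]; se_b <- fb$se[3]
  cpath <- fc$coef[2]; se_c <- fc$se[2]
  sobel_z <- (a * b) / sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  sobel_p <- 2 * pnorm(-abs(sobel_z))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      id <- sample.int(n, replace = TRUE)
      xb <- x[id]; mb <- m[id]; yb <- y[id]
      ab <- tryCatch({
        aa <- ols_fit(cbind(xb), mb)$coef[2]
        bb <- ols_fit(cbind(xb, mb), yb)$coef[3]
        aa * bb
      }, error = function(e) NA_real_)
      ab
    }, 0)
  })
  qs <- quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE,
                 names = FALSE)
  paths <- data.frame(
    path = c("a (x -> m)", "b (m -> y | x)", "c (total)", "c' (direct)"),
    coef = c(a, b, cpath, cprime),
    se = c(se_a, se_b, se_c, se_cp),
    p = c(fa$p[2], fb$p[3], fc$p[2], fb$p[2]))
  structure(list(paths = paths, indirect_product = a * b,
                 indirect_difference = indirect_difference(cpath, cprime),
                 sobel_z = sobel_z, sobel_p = sobel_p,
                 boot_ci = qs, conf = conf, n = n, n_boot = n_boot,
                 partial_mediation = (qs[1] > 0 || qs[2] < 0) && fb$p[2] > 0.05),
            class = "mediation")
}

#' @export
print.mediation <- function(x, digits = 3, ...) {
  cat(sprintf("<mediation> n = %d complete cases\n", x$n))
  print.data.frame(format(x$paths, digits = digits), row.names = FALSE)
  cat(sprintf("  indirect effect: product a*b = %.*f, difference c - c' = %.*f\n",
              digits, x$indirect_product, digits, x$indirect_difference))
  cat(sprintf("  Sobel z = %.*f (p = %.*f)\n", digits, x$sobel_z, digits, x$sobel_p))
  cat(sprintf("  %d-rep bootstrap %.0f%% CI of a*b: [%.*f, %.*f]%s\n",
              x$n_boot, 100 * x$conf, digits, x$boot_ci[1], digits, x$boot_ci[2],
              if (x$boot_ci[1] > 0 || x$boot_ci[2] < 0) " (excludes 0)" else ""))
  invisible(x)
}
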