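# Detrended fluctuation analysis ----

#' Integrated (profile) series for DFA
#'
#' Cumulative sum of the mean-subtracted signal.
#'
#' @param x numeric series.
#' @param min_window smallest window the profile must support (default 4).
#' @return Numeric profile of the same length.
#' @export
dfa_profile <- function(x, min_window = 4L) {
  if (length(x) < 4L * min_window) stop("series too short for DFA")
  cumsum(x - mean(x))
}

#' Root-mean-square fluctuation at one window size
#'
#' Partitions the profile into non-overlapping windows of size `n` from the
#' start (trailing partial window discarded), fits an ordinary least-squares
#' line per window, and pools the residuals into a single RMS value.
#'
#' @param profile integrated series from [dfa_profile()].
#' @param n window size; must satisfy `4 <= n <= length(profile) / 4`.
#' @param naive if `TRUE`, use an explicit per-window `lm` loop (test oracle)
#'   instead of the vectorized computation.
#' @return `F(n)`, a non-negative scalar.
#' @export
dfa_fluctuation <- function(profile, n, naive = FALSE) {
  L <- length(profile)
  if (n < 4 || n > L / 4) stop("window size out of range")
  m <- L %/% n
  y <- profile[seq_len(m * n)]
  if (naive) {
    ss <- 0
    for (win in seq_len(m)) {
      seg <- y[((win - 1) * n + 1):(win * n)]
      fit <- stats::lm(seg ~ seq_len(n))
      ss <- ss + sum(stats::residuals(fit)^2)
    }
    return(sqrt(ss / (m * n)))
  }
  Y <- matrix(y, nrow = n)
  qrx <- qr(cbind(1, seq_len(n)))
  res <- qr.resid(qrx, Y)
  sqrt(mean(res^2))
}

#' DFA scaling exponent
#'
#' Computes `F(n)` over logarithmically spaced window sizes and fits the
#' scaling exponent `alpha` as the least-squares slope of `log F` versus
#' `log n`. `alpha = 0.5` indicates white (uncorrelated) noise, `alpha = 1`
#' long-range correlated 1/f noise, and `alpha = 1.5` Brownian noise; the
#' power-spectral slope follows as `beta = 2 alpha - 1`.
#'
#' @param x numeric series (e.g. the global state `S(t)`).
#' @param n_min,n_max fit range of window sizes (defaults 10 and 1000).
#' @param n_points number of log-spaced window sizes (default 20).
#' @return A `dfa` object: `n`, `F`, `alpha`, `fit_range`, `fit_residual`
#'   (mean squared residual of the log-log fit).
#' @export
dfa <- function(x, n_min = 10L, n_max = 1000L, n_points = 20L) {
  stopifnot(n_min >= 4, n_max > n_min)
  n_max <- min(n_max, length(x) %/% 4L)
  prof <- dfa_profile(x)
  ns <- unique(round(exp(seq(log(n_min), log(n_max), length.out = n_points))))
  Fv <- vapply(ns, function(n) dfa_fluctuation(prof, n), numeric(1))
  keep <- Fv > 0
  if (!all(keep)) {
    warning("windows with zero fluctuation excluded from the fit")
    ns <- ns[keep]
    Fv <- Fv[keep]
  }
  fit <- stats::lm(log10(Fv) ~ log10(ns))
  structure(list(
    n = ns, F = Fv,
    alpha = unname(stats::coef(fit)[2]),
    fit_range = c(n_min, n_max),
    fit_residual = mean(stats::residuals(fit)^2)
  ), class = "dfa")
}

#' @export
print.dfa <- function(x, ...) {
  cat(sprintf("DFA: alpha = %.3f over n in [%d, %d] (%d window sizes)\n",
              x$alpha, x$fit_range[1], x$fit_range[2], length(x$n)))
  invisible(x)
}
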