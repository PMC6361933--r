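# Synthetic surrogate signals ----
#
# Stand-ins with known statistical structure, so every analysis stage can be
# validated without running the spiking simulator: colored noise with a
# prescribed spectral slope (DFA anchors alpha = (beta + 1) / 2), sinusoid
# ensembles with controlled phase offsets (synchrony fixtures), and bounded
# power-law samples (oracle for the exponent fit).

#' Colored noise with prescribed spectral slope
#'
#' Spectral synthesis: Gaussian Fourier coefficients shaped by `f^(-beta/2)`,
#' inverse-transformed and standardized to zero mean and unit variance.
#' `beta = 0` gives white noise (DFA alpha ~ 0.5), `beta = 1` gives 1/f noise
#' (alpha ~ 1), `beta = 2` Brownian noise (alpha ~ 1.5), via
#' `beta = 2 alpha - 1`.
#'
#' @param n series length (>= 256).
#' @param beta spectral slope in `[0, 2]`.
#' @return Numeric series of length `n`; uses the R RNG.
#' @export
colored_noise <- function(n, beta) {
  stopifnot(n >= 256, beta >= 0, beta <= 2)
  n_half <- n %/% 2
  freq <- seq_len(n_half) / n
  amp <- freq^(-beta / 2)
  coef <- amp * complex(real = stats::rnorm(n_half),
                        imaginary = stats::rnorm(n_half))
  spec <- complex(real = numeric(n))
  spec[2:(n_half + 1)] <- coef
  if (n %% 2 == 0) {
    spec[n_half + 1] <- complex(real = amp[n_half] * stats::rnorm(1))
    spec[seq(n, n_half + 2)] <- Conj(spec[2:n_half])
  } else {
    spec[seq(n, n_half + 2)] <- Conj(spec[2:(n_half + 1)])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  as.vector(scale(x))
}

#' Ensemble of noisy sinusoids
#'
#' Common-frequency sinusoids with per-signal phase offsets and optional
#' additive Gaussian noise; fixtures for the pairwise synchrony pipeline.
#'
#' @param n_signals number of signals.
#' @param n series length.
#' @param freq frequency in cycles per sample.
#' @param phase_offsets scalar or length-`n_signals` phase offsets (radians).
#' @param noise_sd additive noise standard deviation (default 0).
#' @return `n x n_signals` matrix; uses the R RNG when `noise_sd > 0`.
#' @export
sinusoid_ensemble <- function(n_signals, n, freq, phase_offsets = 0,
                              noise_sd = 0) {
  phase_offsets <- rep_len(phase_offsets, n_signals)
  tt <- seq_len(n)
  base <- sapply(phase_offsets, function(ph) sin(2 * pi * freq * tt + ph))
  if (noise_sd > 0) base <- base + matrix(stats::rnorm(n * n_signals, sd = noise_sd),
                                          n, n_signals)
  base
}

#' Bounded power-law samples
#'
#' Inverse-CDF sampling from the density proportional to `x^-delta` on
#' `[xmin, xmax]`, `0 < delta <= 1`.
#'
#' @param n sample size.
#' @param delta exponent in `(0, 1]`.
#' @param xmin,xmax support bounds, `0 < xmin < xmax`.
#' @return Numeric samples; uses the R RNG.
#' @export
powerlaw_samples <- function(n, delta, xmin = 1, xmax = 1e6) {
  stopifnot(delta > 0, delta <= 1, xmin > 0, xmax > xmin)
  u <- stats::runif(n)
  if (abs(delta - 1) < 1e-12) {
    xmin * (xmax / xmin)^u
  } else {
    e <- 1 - delta
    (xmin^e + u * (xmax^e - xmin^e))^(1 / e)
  }
}
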