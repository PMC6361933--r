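# Global lability of synchronization ----
#
# Pipeline: cluster-averaged membrane signals -> Hilbert analytic phases ->
# pairwise wrapped phase differences -> windowed synchronization index ->
# synchronized-pair count M(t) -> lability l(t) = |M(t+1) - M(t)|^2 ->
# log-binned density and bounded-exponent power-law fit.

#' Cluster-averaged signals
#'
#' Averages membrane-potential traces within groups of nodes (by default the
#' contiguous 5-node clusters), producing one signal per cluster.
#'
#' @param traces `T x N` matrix of per-neuron traces.
#' @param cluster_id integer cluster label per neuron.
#' @return `T x n_clusters` matrix, columns ordered by cluster label.
#' @export
cluster_signals <- function(traces, cluster_id) {
  stopifnot(ncol(traces) == length(cluster_id))
  t(rowsum(t(traces), cluster_id) / as.vector(table(cluster_id)))
}

#' Analytic signal via the FFT Hilbert transform
#'
#' Returns `s + i * H(s)` where `H` is the discrete Hilbert transform of the
#' mean-removed signal, computed by zeroing negative frequencies in the FFT.
#'
#' @param x real series; must not be constant.
#' @return Complex series of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant signal: analytic phase undefined")
  X <- stats::fft(x - mean(x))
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[c(1, n / 2 + 1)] <- 1
    hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1
    hmul[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * hmul, inverse = TRUE) / n
}

#' Instantaneous phase of a signal
#'
#' @param x real series.
#' @return Phase of the analytic signal, in `(-pi, pi]`.
#' @export
analytic_phase <- function(x) Arg(analytic_signal(x))

#' Wrapped pairwise phase difference
#'
#' Instantaneous phase difference `theta_i - theta_j`, computed as the
#' argument of the product of the first analytic signal with the conjugate of
#' the second, wrapped to `(-pi, pi]`.
#'
#' @param s_i,s_j equal-length real series.
#' @return Phase-difference series.
#' @export
phase_difference <- function(s_i, s_j) {
  stopifnot(length(s_i) == length(s_j))
  Arg(analytic_signal(s_i) * Conj(analytic_signal(s_j)))
}

#' Windowed phase synchronization index
#'
#' Mean resultant length of the phase difference over the forward window
#' `[t, t + nu)`:
#' `gamma(t) = |mean(exp(i * dtheta))|`, between 0 (drifting frequencies) and
#' 1 (constant phase lag, full synchronization). The final `nu - 1` samples
#' have no complete window and are dropped.
#'
#' @param delta_theta phase-difference series.
#' @param nu window length in steps (default 50).
#' @return Series of length `length(delta_theta) - nu + 1`.
#' @export
sync_index <- function(delta_theta, nu = 50L) {
  L <- length(delta_theta)
  if (nu > L) stop("window exceeds series length")
  cs <- c(0, cumsum(exp(1i * delta_theta)))
  idx <- seq_len(L - nu + 1L)
  Mod(cs[idx + nu] - cs[idx]) / nu
}

#' Count synchronized signal pairs over time
#'
#' A pair `(i, j)` is synchronized at step `t` when `|dtheta_ij(t)| < pi/4`
#' and the windowed synchronization index over `[t, t + nu)` exceeds
#' `sqrt(1/2)`. Counts all unordered pairs per step. The first and last `nu`
#' samples of each phase series are excluded (FFT edge distortion), and the
#' forward window must fit, so the valid steps are
#' `t = nu + 1, ..., T - 2 nu + 1`.
#'
#' @param signals `T x K` matrix of real signals (one column per cluster).
#' @param nu synchronization-index window (default 50).
#' @param naive if `TRUE`, use the per-pair [phase_difference()] /
#'   [sync_index()] primitives directly (test oracle) instead of the shared
#'   cumulative-sum path.
#' @return List with `M` (counts) and `t` (the recorded step each entry
#'   refers to).
#' @export
count_synchronized_pairs <- function(signals, nu = 50L, naive = FALSE) {
  K <- ncol(signals)
  T_len <- nrow(signals)
  stopifnot(K >= 2, T_len > 3L * nu)
  t_idx <- seq.int(nu + 1L, T_len - 2L * nu + 1L)
  cos_thr <- cos(pi / 4)
  gam_thr <- sqrt(1 / 2)
  M <- integer(length(t_idx))
  if (naive) {
    for (i in seq_len(K - 1)) {
      for (j in (i + 1):K) {
        dth <- phase_difference(signals[, i], signals[, j])
        gam <- sync_index(dth, nu)
        ok <- abs(dth[t_idx]) < pi / 4 & gam[t_idx] > gam_thr
        M <- M + as.integer(ok)
      }
    }
    return(list(M = M, t = t_idx))
  }
  phasor <- matrix(0i, T_len, K)
  for (k in seq_len(K)) {
    z <- analytic_signal(signals[, k])
    phasor[, k] <- z / Mod(z)
  }
  for (i in seq_len(K - 1)) {
    pi_conj <- Conj(phasor[, i])
    for (j in (i + 1):K) {
      q <- phasor[, j] * pi_conj        # unit phasor of theta_j - theta_i
      cs <- c(0, cumsum(q))
      win <- Mod(cs[t_idx + nu] - cs[t_idx]) / nu
      ok <- Re(q[t_idx]) > cos_thr & win > gam_thr
      M <- M + as.integer(ok)
    }
  }
  list(M = M, t = t_idx)
}

#' Global lability of synchronization
#'
#' Squared change in the number of synchronized pairs between successive
#' steps: `l(t) = |M(t+1) - M(t)|^2`. Large values indicate global
#' synchronization/desynchronization events, small values local changes.
#'
#' @param M synchronized-pair count series (or the list from
#'   [count_synchronized_pairs()]).
#' @return Non-negative integer-valued series of length `length(M) - 1`.
#' @export
lability <- function(M) {
  if (is.list(M)) M <- M$M
  stopifnot(length(M) >= 2)
  diff(M)^2
}

#' Log-binned probability density of lability values
#'
#' Bins the positive lability values into logarithmically spaced bins and
#' normalizes counts by bin width and the total positive count, so the
#' density integrates to 1 over the binned support.
#'
#' @param ell lability values.
#' @param n_bins number of log-spaced bins (default 40).
#' @return Data frame with `center` (geometric bin center), `density`,
#'   `count`, `lo`, `hi`; zero-count bins are dropped.
#' @export
lability_density <- function(ell, n_bins = 40L) {
  pos <- ell[ell > 0]
  if (length(pos) == 0) {
    warning("no positive lability values")
    return(data.frame(center = numeric(0), density = numeric(0),
                      count = integer(0), lo = numeric(0), hi = numeric(0)))
  }
  lo <- min(pos)
  hi <- max(pos) * (1 + 1e-9)
  breaks <- exp(seq(log(lo), log(hi), length.out = n_bins + 1L))
  cnt <- tabulate(findInterval(pos, breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  width <- diff(breaks)
  out <- data.frame(center = sqrt(breaks[-length(breaks)] * breaks[-1]),
                    density = cnt / (width * length(pos)),
                    count = cnt,
                    lo = breaks[-length(breaks)], hi = breaks[-1])
  out[out$count > 0, , drop = FALSE]
}

#' Bounded-support maximum-likelihood power-law exponent
#'
#' Fits `G(l) ~ l^-delta` on the bounded support `[ell_min, ell_max]` by
#' maximizing the truncated-Pareto likelihood, suitable for exponents in
#' `(0, 1]` where unbounded-support estimators fail. The quoted `mse` is the
#' mean squared error between the log-binned empirical density and the
#' fitted density in log10 space.
#'
#' @param ell positive values (zeros are dropped).
#' @param ell_min lower support bound (default 1).
#' @param ell_max upper support bound; defaults to the 99th percentile of the
#'   positive values (guards against single extreme global events).
#' @param n_bins bins used for the mse diagnostic.
#' @return List with `delta`, `mse`, `n`, `support`, `loglik`.
#' @export
fit_powerlaw_delta <- function(ell, ell_min = 1, ell_max = NULL,
                               n_bins = 25L) {
  pos <- ell[ell > 0]
  if (is.null(ell_max)) ell_max <- stats::quantile(pos, 0.99, names = FALSE)
  x <- pos[pos >= ell_min & pos <= ell_max]
  if (length(x) < 100) stop("need at least 100 positive samples in range")
  if (length(unique(x)) < 2) stop("degenerate sample: all values equal")
  slog <- sum(log(x))
  n <- length(x)
  norm_const <- function(delta) {
    if (abs(delta - 1) < 1e-9) return(log(ell_max / ell_min))
    (ell_max^(1 - delta) - ell_min^(1 - delta)) / (1 - delta)
  }
  nll <- function(delta) n * log(norm_const(delta)) + delta * slog
  opt <- stats::optimize(nll, c(1e-6, 1))
  delta <- opt$minimum
  # log-log diagnostic against the fitted density
  dens <- lability_density(x, n_bins = n_bins)
  dens <- dens[dens$center >= ell_min & dens$center <= ell_max, ]
  model <- dens$center^(-delta) / norm_const(delta)
  mse <- mean((log10(dens$density) - log10(model))^2)
  list(delta = delta, mse = mse, n = n,
       support = c(ell_min, ell_max), loglik = -opt$objective)
}
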