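# Izhikevich dynamics on rcnet networks ----

#' Per-neuron Izhikevich parameters
#'
#' Draws the heterogeneity variable `r` (uniform on \[0, 1\]) once per neuron and maps it
#' to the standard excitatory/inhibitory parameter repertoire: excitatory
#' neurons have `a = 0.02`, `b = 0.2`, `c = -65 + 15 r`, `d = 8 - 6 r` and
#' thalamic noise scale 5 (regular spiking at `r` = 0, chattering at `r` = 1);
#' inhibitory neurons have `a = 0.02 + 0.08 r`, `b = 0.25 - 0.05 r`,
#' `c = -65`, `d = 2` and noise scale 2 (low-threshold to fast spiking).
#'
#' @param is_excitatory logical vector, one entry per neuron.
#' @param r optional heterogeneity draws; defaults to fresh `runif` draws.
#' @return Data frame with columns `a`, `b`, `c`, `d`, `I_scale`, `r`,
#'   `is_excitatory`.
#' @export
neuron_params <- function(is_excitatory, r = stats::runif(length(is_excitatory))) {
  stopifnot(length(r) == length(is_excitatory))
  data.frame(
    a = ifelse(is_excitatory, 0.02, 0.02 + 0.08 * r),
    b = ifelse(is_excitatory, 0.2, 0.25 - 0.05 * r),
    c = ifelse(is_excitatory, -65 + 15 * r, -65),
    d = ifelse(is_excitatory, 8 - 6 * r, 2),
    I_scale = ifelse(is_excitatory, 5, 2),
    r = r,
    is_excitatory = is_excitatory
  )
}

#' Izhikevich derivatives
#'
#' Right-hand side of the two-variable model: `dv/dt = 0.04 v^2 + 5 v + 140 -
#' u + I + s`, `du/dt = a (b v - u)`. The integration step size is applied by
#' the integrator, not here.
#'
#' @param v,u membrane potential (mV) and recovery variable.
#' @param a,b recovery time scale and sensitivity.
#' @param I thalamic input; `s` summed synaptic input.
#' @param s synaptic input.
#' @return List with `dv` and `du`.
#' @export
izh_derivatives <- function(v, u, a, b, I = 0, s = 0) {
  list(dv = 0.04 * v^2 + 5 * v + 140 - u + I + s,
       du = a * (b * v - u))
}

#' After-spike reset rule
#'
#' If `v >= 30` mV the neuron spikes: `v` resets to `c` and `u` increments by
#' `d`; otherwise the state is unchanged.
#'
#' @param v,u state; `c,d` reset parameters.
#' @param c,d after-spike reset of `v` and increment of `u`.
#' @return List with `v`, `u`, `spiked`.
#' @export
izh_reset <- function(v, u, c, d) {
  spiked <- v >= 30
  list(v = ifelse(spiked, c, v),
       u = ifelse(spiked, u + d, u),
       spiked = spiked)
}

#' One midpoint Runge-Kutta step (reference implementation)
#'
#' Advances `(v, u)` by one RK-2 (midpoint) step of size `h` with the inputs
#' `I` and `s` held constant across the step, then applies the reset rule.
#' This plain-R stepper mirrors the compiled integrator and is used as its
#' oracle in tests; vectorized over neurons.
#'
#' @param v,u state vectors.
#' @param params data frame from [neuron_params()].
#' @param I,s inputs held constant within the step.
#' @param h step size (ms).
#' @return List with `v`, `u`, `spiked` (post-reset state).
#' @export
izh_rk2_step <- function(v, u, params, I = 0, s = 0, h = 0.1) {
  stopifnot(h > 0)
  k1 <- izh_derivatives(v, u, params$a, params$b, I, s)
  vm <- v + 0.5 * h * k1$dv
  um <- u + 0.5 * h * k1$du
  k2 <- izh_derivatives(vm, um, params$a, params$b, I, s)
  v1 <- v + h * k2$dv
  u1 <- u + h * k2$du
  if (any(!is.finite(v1)) || any(!is.finite(u1))) {
    stop("non-finite state after RK-2 step")
  }
  izh_reset(v1, u1, params$c, params$d)
}

rcnet_csr <- function(net) {
  ord <- order(net$edges[, 1])
  from <- net$edges[ord, 1]
  to <- net$edges[ord, 2]
  counts <- tabulate(from, nbins = net$n)
  list(ptr = c(0L, cumsum(counts)), idx = to - 1L)
}

#' Simulate Izhikevich dynamics on a network
#'
#' Integrates the full network with RK-2 at step `h` (ms). Each neuron
#' receives an independent Gaussian thalamic input (sd 5 for excitatory, 2
#' for inhibitory neurons), redrawn once per millisecond and held constant
#' across the sub-steps within it, so the per-millisecond drive is identical
#' to the original 1-ms-step formulation of the model at every resolution
#' `h`; a spike at step `t` delivers `+w` (excitatory
#' source) or `-w` (inhibitory source) to each outgoing neighbour's synaptic
#' input at step `t + 1` only. The first `transient_steps` steps are
#' discarded; the following `record_steps` steps are recorded.
#'
#' Recorded traces are group means of the membrane potentials (with `v`
#' capped at 30 mV at spike steps); by default each neuron is its own group.
#' Passing `groups = net$cluster5` records the 125 cluster signals used by
#' the synchrony analysis directly. The global state `S(t)` is the mean over
#' all neurons. Uses the R RNG: call `set.seed()` for reproducibility.
#'
#' @param net an `rcnet` with neuron types assigned.
#' @param weight synaptic magnitude `w` (mV); sign set by the presynaptic type.
#' @param h integration step (ms), default 0.1.
#' @param transient_steps,record_steps discarded and recorded step counts
#'   (defaults 8000 and 10^4).
#' @param groups optional integer grouping (1..G) for recorded traces.
#' @param noise_hold_ms thalamic-noise refresh interval in ms (default 1).
#' @param noise_mode `"held"` (default) delivers each thalamic draw as a
#'   current held constant over the sub-steps of its millisecond, the direct
#'   refinement of the original 1-ms update; `"impulse"` delivers it as an
#'   instantaneous jump in `v` at the millisecond boundary. Both reduce to
#'   the same update at `h = 1` ms.
#' @param I_const optional constant bias current per neuron (default 0).
#' @param params optional data frame from [neuron_params()]; freshly drawn
#'   when `NULL`.
#' @param v_init initial membrane potential(s), recycled over neurons
#'   (default -65 mV; `u` starts at `b * v`).
#' @return An `izhsim` object: `raster` (data frame `neuron`, `step`),
#'   `traces` (`record_steps` x G matrix), `S`, `rate_exc` (spks/s),
#'   `groups`, `params`, `config`.
#' @export
simulate_network <- function(net, weight, h = 0.1,
                             transient_steps = 8000L, record_steps = 10000L,
                             groups = NULL, noise_hold_ms = 1,
                             noise_mode = c("held", "impulse"), I_const = 0,
                             params = NULL, v_init = -65) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(net, "rcnet"), h > 0, weight >= 0)
  if (anyNA(net$neuron_type)) stop("assign neuron types before simulating")
  is_exc <- net$neuron_type == "excitatory"
  if (is.null(params)) params <- neuron_params(is_exc)
  if (is.null(groups)) groups <- seq_len(net$n)
  stopifnot(length(groups) == net$n, min(groups) >= 1)
  csr <- rcnet_csr(net)
  I_const <- rep_len(I_const, net$n)
  out <- simulate_izh_cpp(
    net$n, csr$ptr, csr$idx,
    params$a, params$b, params$c, params$d,
    params$I_scale, I_const, is_exc,
    weight, h, as.integer(transient_steps), as.integer(record_steps),
    as.integer(groups), max(groups),
    max(1L, as.integer(round(noise_hold_ms / h))),
    noise_mode == "impulse",
    rep_len(v_init, net$n)
  )
  raster <- data.frame(neuron = out$spike_neuron, step = out$spike_step)
  duration_s <- record_steps * h / 1000
  res <- structure(list(
    raster = raster,
    traces = out$traces,
    S = out$S,
    groups = as.integer(groups),
    is_excitatory = is_exc,
    params = params,
    config = list(weight = weight, h = h, transient_steps = transient_steps,
                  record_steps = record_steps, duration_s = duration_s,
                  link_mode = net$link_mode)
  ), class = "izhsim")
  res$rate_exc <- firing_rate(res)
  res
}

#' Mean excitatory firing rate
#'
#' Total excitatory spikes divided by the number of excitatory neurons and
#' the recorded duration in seconds.
#'
#' @param sim an `izhsim` result.
#' @param duration_s recorded duration; defaults to
#'   `record_steps * h / 1000`.
#' @return Rate in spikes per second per neuron (spks/s).
#' @export
firing_rate <- function(sim, duration_s = sim$config$duration_s) {
  stopifnot(duration_s > 0)
  n_exc <- sum(sim$is_excitatory)
  if (n_exc == 0) return(0)
  sum(sim$is_excitatory[sim$raster$neuron]) / (n_exc * duration_s)
}

#' Calibrate the synaptic weight to a target firing rate
#'
#' Runs the simulation over a grid of synaptic weights (several independent
#' repetitions per weight) and returns the smallest grid weight whose mean
#' excitatory rate reaches the target, together with the full rate-vs-weight
#' curve. Smaller integration steps require larger weights: because a spike
#' is delivered for a single step, its effect scales as `h * w`, so the
#' calibration curves at different `h` are scaled versions of each other.
#'
#' @param net an `rcnet` with neuron types assigned.
#' @param w_grid increasing vector of candidate weights.
#' @param target_rate target mean excitatory rate (spks/s), default 5.
#' @param runs repetitions per weight (default 1).
#' @param h,transient_steps,record_steps passed to [simulate_network()].
#' @return List with `w_star` (`NA` if the target is unreachable on the grid)
#'   and `curve` (data frame `w`, `rate`).
#' @export
calibrate_weight <- function(net, w_grid, target_rate = 5, runs = 1,
                             h = 0.1, transient_steps = 8000L,
                             record_steps = 10000L) {
  stopifnot(runs >= 1, length(w_grid) >= 1)
  rates <- vapply(w_grid, function(w) {
    mean(vapply(seq_len(runs), function(i) {
      simulate_network(net, w, h = h, transient_steps = transient_steps,
                       record_steps = record_steps,
                       groups = rep(1L, net$n))$rate_exc
    }, numeric(1)))
  }, numeric(1))
  hit <- which(rates >= target_rate)
  list(w_star = if (length(hit)) w_grid[min(hit)] else NA_real_,
       curve = data.frame(w = w_grid, rate = rates))
}

#' @export
print.izhsim <- function(x, ...) {
  cat(sprintf(
    "izhsim: %d neurons, %d recorded steps (h = %g ms), %d spikes, %.2f spks/s (excitatory)\n",
    length(x$is_excitatory), x$config$record_steps, x$config$h,
    nrow(x$raster), x$rate_exc))
  invisible(x)
}
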