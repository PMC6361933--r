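# Experiment orchestration ----

#' Build a fully configured network
#'
#' Convenience constructor for the standard study systems: the 625-node
#' assembly (5 replicas of the step-2 unit) or the bare step-1/step-2 units,
#' with rich-club wiring at `kappa` and neuron types assigned.
#'
#' @param case 1 (inhibitory global hubs) or 2 (excitatory global hubs).
#' @param kappa rich-club wiring probability.
#' @param eta probability that a local hub is inhibitory.
#' @param n_nodes 25, 125 or 625 (default 625).
#' @param local_hub_inhibitory optional explicit local-hub types, passed to
#'   [assign_neuron_types()].
#' @return A typed `rcnet`; uses the R RNG.
#' @export
build_study_network <- function(case = 1, kappa = 0.5, eta = 0,
                                n_nodes = 625L,
                                local_hub_inhibitory = NULL) {
  net <- switch(as.character(n_nodes),
    "25" = build_base_network(1L),
    "125" = build_base_network(2L),
    "625" = assemble_replicas(build_base_network(2L), 5L),
    stop("n_nodes must be 25, 125 or 625"))
  net <- connect_rich_club(net, kappa)
  assign_neuron_types(net, case = case, eta = eta,
                      local_hub_inhibitory = local_hub_inhibitory)
}

#' Run one cell of the kappa-eta design
#'
#' One full pipeline pass: build the network, assign types, simulate, run DFA
#' on the global state, and (optionally) the synchrony-lability analysis on
#' the 5-node cluster signals.
#'
#' @param case,kappa,eta network configuration (see
#'   [build_study_network()]).
#' @param weight synaptic weight (mV); default 40, the value calibrated to 5
#'   spks/s at `h = 0.1` ms.
#' @param seed integer seed for the whole cell (network wiring, types,
#'   heterogeneity and noise).
#' @param n_nodes system size (default 625).
#' @param h,transient_steps,record_steps integration settings.
#' @param compute_lability also run the pairwise synchrony pipeline (default
#'   `FALSE`; it dominates the run time).
#' @param nu synchronization-index window (default 50).
#' @return List with `alpha`, `dfa`, `rate_exc`, `S`, and (when requested)
#'   `M` and `ell`.
#' @export
run_cell <- function(case, kappa, eta, weight = 40, seed = 1L,
                     n_nodes = 625L, h = 0.1,
                     transient_steps = 8000L, record_steps = 10000L,
                     compute_lability = FALSE, nu = 50L) {
  set.seed(seed)
  net <- build_study_network(case, kappa, eta, n_nodes)
  sim <- simulate_network(net, weight, h = h,
                          transient_steps = transient_steps,
                          record_steps = record_steps,
                          groups = net$cluster5)
  d <- dfa(sim$S)
  out <- list(alpha = d$alpha, dfa = d, rate_exc = sim$rate_exc, S = sim$S,
              seed = seed,
              config = list(case = case, kappa = kappa, eta = eta,
                            weight = weight, n_nodes = n_nodes, h = h))
  if (compute_lability) {
    sync <- count_synchronized_pairs(sim$traces, nu = nu)
    out$M <- sync$M
    out$ell <- lability(sync$M)
  }
  out
}

#' Phase diagram of the DFA exponent over the kappa-eta grid
#'
#' Per-cell mean of the DFA scaling exponent `alpha` over `n_runs`
#' independently seeded pipeline runs. Per-run seeds are drawn
#' deterministically from `base_seed`, so any pixel can be regenerated.
#'
#' @param case 1 or 2.
#' @param kappa_grid,eta_grid probability grids.
#' @param n_runs independent runs per cell.
#' @param base_seed master seed.
#' @param ... further arguments to [run_cell()].
#' @return List with `alpha_mean` (matrix, rows = kappa, cols = eta),
#'   `kappa_grid`, `eta_grid`, `n_runs`, `case`, `seeds`.
#' @export
sweep_phase_diagram <- function(case, kappa_grid, eta_grid, n_runs = 50L,
                                base_seed = 1L, ...) {
  stopifnot(all(kappa_grid >= 0 & kappa_grid <= 1),
            all(eta_grid >= 0 & eta_grid <= 1))
  n_cells <- length(kappa_grid) * length(eta_grid)
  set.seed(base_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, n_cells * n_runs),
                  nrow = n_cells)
  alpha_mean <- matrix(NA_real_, length(kappa_grid), length(eta_grid),
                       dimnames = list(kappa_grid, eta_grid))
  cell <- 0L
  for (ik in seq_along(kappa_grid)) {
    for (ie in seq_along(eta_grid)) {
      cell <- cell + 1L
      alphas <- vapply(seq_len(n_runs), function(run) {
        run_cell(case, kappa_grid[ik], eta_grid[ie],
                 seed = seeds[cell, run], ...)$alpha
      }, numeric(1))
      alpha_mean[ik, ie] <- mean(alphas)
    }
  }
  list(alpha_mean = alpha_mean, kappa_grid = kappa_grid,
       eta_grid = eta_grid, n_runs = n_runs, case = case, seeds = seeds)
}

#' Pooled lability distribution and exponent per configuration
#'
#' Runs `n_runs` independent pipeline passes for each `(kappa, eta)` cell,
#' pools the positive lability values across runs, and fits the
#' bounded-exponent power law.
#'
#' @param case 1 or 2.
#' @param kappa_values,eta_values paired configuration coordinates (recycled
#'   to a common length).
#' @param n_runs independent runs pooled per configuration.
#' @param base_seed master seed.
#' @param ... further arguments to [run_cell()].
#' @return List of per-configuration results: `kappa`, `eta`, `delta`,
#'   `mse`, `density`, `n_ell`.
#' @export
lability_grid <- function(case, kappa_values, eta_values, n_runs = 10L,
                          base_seed = 1L, ...) {
  len <- max(length(kappa_values), length(eta_values))
  kappa_values <- rep_len(kappa_values, len)
  eta_values <- rep_len(eta_values, len)
  set.seed(base_seed)
  seeds <- matrix(sample.int(.Machine$integer.max, len * n_runs), nrow = len)
  lapply(seq_len(len), function(icell) {
    ell <- unlist(lapply(seq_len(n_runs), function(run) {
      run_cell(case, kappa_values[icell], eta_values[icell],
               seed = seeds[icell, run], compute_lability = TRUE, ...)$ell
    }))
    fit <- fit_powerlaw_delta(ell)
    list(kappa = kappa_values[icell], eta = eta_values[icell],
         delta = fit$delta, mse = fit$mse,
         density = lability_density(ell), n_ell = length(ell))
  })
}
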