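# Shared fixtures, built in code.

# fully typed 625-node system, cached per session
study_net_625 <- local({
  cache <- NULL
  function(case = 1, kappa = 0.5, eta = 0, seed = 42) {
    key <- paste(case, kappa, eta, seed)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    set.seed(seed)
    net <- build_study_network(case, kappa, eta, 625L)
    attr(net, "key") <- key
    cache <<- net
    net
  }
})

# short simulation for tests that only need plausible dynamics
quick_sim <- function(net, weight = 40, record_steps = 2000L,
                      transient_steps = 1000L, seed = 1, ...) {
  set.seed(seed)
  simulate_network(net, weight, transient_steps = transient_steps,
                   record_steps = record_steps, ...)
}
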