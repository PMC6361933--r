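#' @useDynLib critsync, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif lm coef optimize quantile rnorm
#' @importFrom utils read.delim write.table
NULL

new_rcnet <- function(n, pairs, hub_class, link_mode = "bidirectional",
                      neuron_type = rep(NA_character_, n)) {
  # pairs: 2-column integer matrix of undirected links (canonical i < j),
  # expanded into two directed links per pair in bidirectional mode.
  pairs <- canonical_pairs(pairs)
  edges <- if (link_mode == "bidirectional") {
    rbind(pairs, pairs[, 2:1, drop = FALSE])
  } else {
    pairs
  }
  net <- structure(list(
    n = as.integer(n),
    edges = edges,               # directed links, from = col 1, to = col 2
    pairs = pairs,               # underlying undirected adjacency
    hub_class = hub_class,
    neuron_type = neuron_type,
    cluster5 = ((seq_len(n) - 1L) %/% 5L) + 1L,
    cluster25 = ((seq_len(n) - 1L) %/% 25L) + 1L,
    cluster125 = ((seq_len(n) - 1L) %/% 125L) + 1L,
    link_mode = link_mode
  ), class = "rcnet")
  validate_rcnet(net)
  net
}

canonical_pairs <- function(pairs) {
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  storage.mode(pairs) <- "integer"
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

validate_rcnet <- function(net) {
  stopifnot(
    is.matrix(net$edges), ncol(net$edges) == 2,
    all(net$edges >= 1L), all(net$edges <= net$n),
    all(net$edges[, 1] != net$edges[, 2]),
    length(net$hub_class) == net$n,
    all(net$hub_class %in% c("none", "local", "global"))
  )
  if (anyDuplicated(net$pairs)) stop("duplicate undirected links")
  invisible(net)
}

#' Undirected degree of every node
#'
#' @param net an `rcnet` network.
#' @return Integer vector of undirected degrees (each linked pair counts once
#'   per endpoint, regardless of link mode).
#' @export
node_degree <- function(net) {
  tabulate(c(net$pairs[, 1], net$pairs[, 2]), nbins = net$n)
}

#' Build the deterministic hierarchical scale-free base network
#'
#' Constructs the clique-hierarchy network: step 1 wires five complete
#' 5-cliques, attaching the four peripheral nodes of each of the four replica
#' cliques to the hub of the primary clique (25 nodes, one hub of degree 20).
#' Step 2 replicates the step-1 unit four more times and attaches each
#' replica's 16 peripheral nodes to the step-1 hub (125 nodes, 5 hubs).
#'
#' Node layout is deterministic: 5-clusters are contiguous index blocks, the
#' hub of every 25-node unit is its highest index (25, 50, ...), and the
#' top-level hub of a 125-node unit is node 125. Hub classification is
#' structural: the top-level hub of a step-2 unit is `"global"`, the four
#' intermediate hubs are `"local"`; the single hub of a step-1 network is
#' `"local"` (it touches only one 25-node group).
#'
#' @param steps hierarchy depth, 1 or 2.
#' @return An `rcnet` with 25 (`steps = 1`) or 125 (`steps = 2`) nodes.
#' @export
build_base_network <- function(steps) {
  if (!steps %in% c(1L, 2L)) stop("steps must be 1 or 2")
  unit <- build_step1_pairs()        # 25 nodes, hub = 25
  if (steps == 1) {
    hub_class <- rep("none", 25L)
    hub_class[25L] <- "local"
    return(new_rcnet(25L, unit$pairs, hub_class))
  }
  pairs <- NULL
  for (copy in 0:4) pairs <- rbind(pairs, unit$pairs + 25L * copy)
  # peripheral nodes of each replica copy (the 16 attached to its own hub)
  # wire to the top-level hub, node 125
  for (copy in 0:3) {
    periph <- unit$periph + 25L * copy
    pairs <- rbind(pairs, cbind(periph, 125L))
  }
  hub_class <- rep("none", 125L)
  hub_class[c(25L, 50L, 75L, 100L)] <- "local"
  hub_class[125L] <- "global"
  new_rcnet(125L, pairs, hub_class)
}

build_step1_pairs <- function() {
  pairs <- NULL
  for (block in 0:4) {
    ids <- block * 5L + 1:5
    pairs <- rbind(pairs, t(utils::combn(ids, 2L)))
  }
  # four peripheral nodes of each replica clique (blocks 0-3) attach to hub 25
  periph <- as.integer(outer(1:4, (0:3) * 5L, `+`))
  pairs <- rbind(pairs, cbind(periph, 25L))
  list(pairs = pairs, periph = sort(periph))
}

#' Assemble disjoint replicas of a step-2 unit
#'
#' Forms the full system as a disjoint union of `n_replicas` copies of a
#' 125-node unit; connectivity across replicas arises only from subsequent
#' rich-club wiring. Hub classes carry over (one global, four local hubs per
#' replica), cluster labels are recomputed at all three scales.
#'
#' @param unit a 125-node step-2 `rcnet`.
#' @param n_replicas number of copies (default 5, giving 625 nodes).
#' @return An `rcnet` with `125 * n_replicas` nodes.
#' @export
assemble_replicas <- function(unit, n_replicas = 5L) {
  stopifnot(inherits(unit, "rcnet"), unit$n == 125L)
  pairs <- NULL
  for (copy in seq_len(n_replicas) - 1L) {
    pairs <- rbind(pairs, unit$pairs + 125L * copy)
  }
  new_rcnet(125L * n_replicas, pairs,
            hub_class = rep(unit$hub_class, n_replicas))
}

#' Wire the rich club
#'
#' Every unordered pair of hubs (global or local, within and across replicas)
#' that is not already adjacent gains a bidirectional edge independently with
#' probability `kappa`. Existing links are untouched; uses the R RNG.
#'
#' @param net an `rcnet` with hubs classified.
#' @param kappa wiring probability in \[0, 1\].
#' @return The network with rich-club links added.
#' @export
connect_rich_club <- function(net, kappa) {
  stopifnot(inherits(net, "rcnet"))
  if (!is.numeric(kappa) || kappa < 0 || kappa > 1) {
    stop("kappa must be a probability in [0, 1]")
  }
  hubs <- which(net$hub_class != "none")
  if (length(hubs) < 2) return(net)
  cand <- canonical_pairs(t(utils::combn(hubs, 2L)))
  key <- function(p) p[, 1] * (net$n + 1L) + p[, 2]
  cand <- cand[!(key(cand) %in% key(net$pairs)), , drop = FALSE]
  keep <- stats::runif(nrow(cand)) < kappa
  add <- cand[keep, , drop = FALSE]
  if (nrow(add) == 0) return(net)
  out <- new_rcnet(net$n, rbind(net$pairs, add), net$hub_class,
                   link_mode = net$link_mode,
                   neuron_type = net$neuron_type)
  out
}

#' Assign excitatory/inhibitory neuron types
#'
#' Global hubs are all inhibitory (case 1) or all excitatory (case 2). Each
#' local hub becomes inhibitory independently with probability `eta` (or per
#' an explicit logical vector). Among non-hubs an exact 80/20
#' excitatory/inhibitory split is drawn uniformly at random.
#'
#' @param net an `rcnet` with hubs classified.
#' @param case 1 (inhibitory global hubs) or 2 (excitatory global hubs).
#' @param eta probability that a local hub is inhibitory.
#' @param local_hub_inhibitory optional logical vector (one entry per local
#'   hub, in node-index order) overriding the Bernoulli(`eta`) draws; used to
#'   pin down explicit configurations.
#' @return The network with `neuron_type` set ("excitatory"/"inhibitory").
#' @export
assign_neuron_types <- function(net, case = 1, eta = 0,
                                local_hub_inhibitory = NULL) {
  stopifnot(inherits(net, "rcnet"), case %in% c(1, 2))
  if (!is.numeric(eta) || eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  type <- rep("excitatory", net$n)
  glob <- which(net$hub_class == "global")
  loc <- which(net$hub_class == "local")
  if (case == 1) type[glob] <- "inhibitory"
  if (is.null(local_hub_inhibitory)) {
    local_hub_inhibitory <- stats::runif(length(loc)) < eta
  }
  stopifnot(length(local_hub_inhibitory) == length(loc))
  type[loc[local_hub_inhibitory]] <- "inhibitory"
  nonhub <- which(net$hub_class == "none")
  n_inh <- round(0.2 * length(nonhub))
  type[sample(nonhub, n_inh)] <- "inhibitory"
  net$neuron_type <- type
  net
}

#' Normalized rich-club coefficient
#'
#' For each degree threshold `k`, counts undirected edges among nodes with
#' degree greater than `k` and normalizes by the mean of the same count over
#' degree-preserving randomized rewirings (double-edge swaps) of the network.
#' Values above 1 indicate rich-club organization.
#'
#' @param net an `rcnet`.
#' @param k_values degree thresholds.
#' @param n_null number of null-model rewirings (default 100).
#' @param swap_factor double-edge swaps per null as a multiple of the edge
#'   count (default 10).
#' @return Data frame with columns `k`, `phi_norm`, `edges_obs`,
#'   `edges_null_mean`; `phi_norm` is `NA` where no node exceeds `k`.
#' @export
normalized_rich_club <- function(net, k_values, n_null = 100, swap_factor = 10) {
  stopifnot(n_null >= 1)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  m <- igraph::ecount(g)
  rich_edges <- function(graph, nodes) {
    if (length(nodes) < 2) return(NA_real_)
    igraph::ecount(igraph::induced_subgraph(graph, nodes))
  }
  nulls <- lapply(seq_len(n_null), function(i) {
    igraph::rewire(g, igraph::keeping_degseq(niter = swap_factor * m))
  })
  res <- lapply(k_values, function(k) {
    nodes <- which(deg > k)
    obs <- rich_edges(g, nodes)
    nl <- mean(vapply(nulls, rich_edges, numeric(1), nodes = nodes))
    data.frame(k = k, phi_norm = if (is.na(obs) || is.na(nl) || nl == 0)
      NA_real_ else obs / nl,
      edges_obs = obs, edges_null_mean = nl)
  })
  do.call(rbind, res)
}

#' Convert to an igraph graph
#'
#' @param net an `rcnet`.
#' @param directed if `TRUE`, one igraph edge per directed link; otherwise one
#'   per undirected pair.
#' @return An igraph object with `hub_class` and `neuron_type` vertex
#'   attributes.
#' @export
as_igraph <- function(net, directed = FALSE) {
  el <- if (directed) net$edges else net$pairs
  g <- igraph::graph_from_edgelist(el, directed = directed)
  g <- igraph::add_vertices(g, max(0L, net$n - igraph::vcount(g)))
  igraph::V(g)$hub_class <- net$hub_class
  igraph::V(g)$neuron_type <- net$neuron_type
  g
}

#' Degree-distribution power-law exponent
#'
#' Discrete maximum-likelihood fit of `P(k) ~ k^-gamma` with the lower cutoff
#' selected by Kolmogorov-Smirnov minimization over the observed degree
#' values (Clauset-style). The likelihood uses the Hurwitz zeta normalization.
#'
#' @param x an `rcnet` network or an integer vector of degrees.
#' @param xmin optional fixed lower cutoff; when `NULL` it is chosen by KS
#'   minimization.
#' @return List with `gamma`, `xmin`, `ks` and the log-likelihood.
#' @export
degree_exponent <- function(x, xmin = NULL) {
  deg <- if (inherits(x, "rcnet")) node_degree(x) else as.integer(x)
  deg <- deg[deg > 0]
  cands <- if (is.null(xmin)) sort(unique(deg)) else xmin
  cands <- cands[vapply(cands, function(xm) sum(deg >= xm) >= 2 &&
                          length(unique(deg[deg >= xm])) >= 2, logical(1))]
  if (length(cands) == 0) stop("not enough tail data for a power-law fit")
  fits <- lapply(cands, function(xm) {
    tail_k <- deg[deg >= xm]
    nll <- function(alpha) {
      length(tail_k) * log(hurwitz_zeta(alpha, xm)) + alpha * sum(log(tail_k))
    }
    opt <- stats::optimize(nll, c(1.01, 20))
    alpha <- opt$minimum
    # KS distance between empirical and model CDF on the tail
    ks_grid <- sort(unique(tail_k))
    zf <- hurwitz_zeta(alpha, xm)
    # model CDF up to each observed value (sum over all integers in between)
    full <- seq.int(xm, max(tail_k))
    model_cdf_full <- cumsum(full^(-alpha)) / zf
    model_cdf <- model_cdf_full[match(ks_grid, full)]
    emp_cdf <- cumsum(tabulate(tail_k - xm + 1L)[ks_grid - xm + 1L]) /
      length(tail_k)
    list(alpha = alpha, xmin = xm, ks = max(abs(emp_cdf - model_cdf)),
         loglik = -opt$objective)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks"))]]
  list(gamma = best$alpha, xmin = best$xmin, ks = best$ks,
       loglik = best$loglik)
}

hurwitz_zeta <- function(alpha, xmin, n_terms = 10000L) {
  k <- seq.int(xmin, xmin + n_terms - 1L)
  # Euler-Maclaurin tail beyond the summed terms
  tail_from <- xmin + n_terms
  sum(k^(-alpha)) + tail_from^(1 - alpha) / (alpha - 1) +
    0.5 * tail_from^(-alpha)
}

#' Keep a single random direction per link
#'
#' Supplementary variant: every undirected link keeps exactly one randomly
#' chosen direction, halving the directed link count.
#'
#' @param net a bidirectional `rcnet`.
#' @return The network in unidirectional mode.
#' @export
variant_unidirectional <- function(net) {
  stopifnot(net$link_mode == "bidirectional")
  flip <- stats::runif(nrow(net$pairs)) < 0.5
  edges <- net$pairs
  edges[flip, ] <- edges[flip, 2:1]
  net$edges <- edges
  net$link_mode <- "unidirectional"
  net
}

#' Destroy hierarchy while preserving the indegree distribution
#'
#' Supplementary variant: every directed link keeps its target but redraws its
#' source uniformly at random among the other nodes (no self-loops), so each
#' node's indegree is unchanged while clustering and hierarchy are destroyed.
#'
#' @param net an `rcnet`.
#' @return The rewired network (marked `link_mode = "randomized"`).
#' @export
variant_randomize_keep_indegree <- function(net) {
  edges <- net$edges
  new_from <- vapply(edges[, 2], function(to) {
    s <- sample.int(net$n - 1L, 1L)
    if (s >= to) s + 1L else s
  }, integer(1))
  net$edges <- cbind(new_from, edges[, 2])
  colnames(net$edges) <- NULL
  net$pairs <- unique(canonical_pairs(net$edges))
  net$link_mode <- "randomized"
  net
}

#' @export
print.rcnet <- function(x, ...) {
  cat(sprintf(
    "rcnet: %d nodes, %d directed links (%s)\n", x$n, nrow(x$edges),
    x$link_mode))
  cat(sprintf("hubs: %d global, %d local\n",
              sum(x$hub_class == "global"), sum(x$hub_class == "local")))
  if (!all(is.na(x$neuron_type))) {
    cat(sprintf("types: %d excitatory, %d inhibitory\n",
                sum(x$neuron_type == "excitatory"),
                sum(x$neuron_type == "inhibitory")))
  }
  invisible(x)
}
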