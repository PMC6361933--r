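test_that("step-1 construction has 25 nodes, one hub of degree 20", {
  net <- build_base_network(1)
  expect_equal(net$n, 25L)
  expect_equal(sum(net$hub_class != "none"), 1L)
  deg <- node_degree(net)
  expect_equal(deg[25], 20L)           # 4 clique neighbours + 16 peripherals
  # every undirected pair appears as exactly two directed links
  expect_equal(nrow(net$edges), 2L * nrow(net$pairs))
  expect_error(build_base_network(3), "steps")
})

test_that("step-2 construction has 125 nodes, 5 hubs, global hub degree >= 80", {
  net <- build_base_network(2)
  expect_equal(net$n, 125L)
  expect_equal(sum(net$hub_class == "global"), 1L)
  expect_equal(sum(net$hub_class == "local"), 4L)
  deg <- node_degree(net)
  expect_gte(deg[125], 80L)
  expect_equal(deg[c(25, 50, 75, 100)], rep(20L, 4))
})

test_that("5-replica assembly: 625 nodes, 25 hubs (4%), 5x unit edges, no inter-replica links", {
  unit <- build_base_network(2)
  net <- assemble_replicas(unit, 5)
  expect_equal(net$n, 625L)
  expect_equal(sum(net$hub_class == "global"), 5L)
  expect_equal(sum(net$hub_class == "local"), 20L)
  expect_equal(sum(net$hub_class != "none") / net$n, 0.04)
  expect_equal(nrow(net$pairs), 5L * nrow(unit$pairs))
  replica <- (net$pairs - 1L) %/% 125L
  expect_true(all(replica[, 1] == replica[, 2]))
})

test_that("degree sequence of the base assembly is deterministic", {
  d1 <- node_degree(assemble_replicas(build_base_network(2), 5))
  d2 <- node_degree(assemble_replicas(build_base_network(2), 5))
  expect_identical(d1, d2)
  expect_identical(as.vector(table(d1)), c(200L, 80L, 320L, 20L, 5L))
})

test_that("local-hub neighbourhoods stay within one 25-node cluster before rich-club wiring", {
  net <- assemble_replicas(build_base_network(2), 5)
  for (hub in which(net$hub_class == "local")) {
    nb <- c(net$pairs[net$pairs[, 1] == hub, 2], net$pairs[net$pairs[, 2] == hub, 1])
    expect_equal(length(unique(net$cluster25[nb])), 1L)
  }
})

test_that("rich-club wiring: kappa = 0 adds nothing, kappa = 1 adds all 300 pairs", {
  net <- assemble_replicas(build_base_network(2), 5)
  set.seed(1)
  expect_equal(nrow(connect_rich_club(net, 0)$pairs), nrow(net$pairs))
  full <- connect_rich_club(net, 1)
  expect_equal(nrow(full$pairs) - nrow(net$pairs), choose(25, 2))
  deg <- node_degree(full)
  expect_true(all(deg[full$hub_class == "global"] >= 100))
  expect_true(all(deg[full$hub_class == "local"] >= 20 &
                  deg[full$hub_class == "local"] <= 44))
  # non-hub degrees untouched
  expect_identical(deg[full$hub_class == "none"],
                   node_degree(net)[net$hub_class == "none"])
  expect_error(connect_rich_club(net, 1.5), "kappa")
})

test_that("rich-club added-pair count is Binomial(300, kappa) on average", {
  net <- assemble_replicas(build_base_network(2), 5)
  set.seed(99)
  added <- replicate(40, nrow(connect_rich_club(net, 0.5)$pairs) - nrow(net$pairs))
  expect_gt(mean(added), 150 - 3 * sqrt(300 * 0.25 / 40))
  expect_lt(mean(added), 150 + 3 * sqrt(300 * 0.25 / 40))
})

test_that("neuron-type assignment follows case, eta and the exact 80/20 split", {
  net <- assemble_replicas(build_base_network(2), 5)
  set.seed(7)
  t1 <- assign_neuron_types(net, case = 1, eta = 0)
  expect_true(all(t1$neuron_type[t1$hub_class == "global"] == "inhibitory"))
  expect_true(all(t1$neuron_type[t1$hub_class == "local"] == "excitatory"))
  expect_equal(sum(t1$neuron_type[t1$hub_class == "none"] == "excitatory"), 480L)
  expect_equal(sum(t1$neuron_type[t1$hub_class == "none"] == "inhibitory"), 120L)
  t2 <- assign_neuron_types(net, case = 2, eta = 1)
  expect_true(all(t2$neuron_type[t2$hub_class == "global"] == "excitatory"))
  expect_true(all(t2$neuron_type[t2$hub_class == "local"] == "inhibitory"))
  # law of large numbers in eta
  set.seed(11)
  frac <- mean(replicate(60, {
    ty <- assign_neuron_types(net, case = 1, eta = 0.3)
    mean(ty$neuron_type[ty$hub_class == "local"] == "inhibitory")
  }))
  expect_lt(abs(frac - 0.3), 0.06)
  expect_error(assign_neuron_types(net, case = 1, eta = -0.1), "eta")
})

test_that("normalized rich-club coefficient matches brute force on a toy graph and exceeds 1 at kappa = 1", {
  # toy graph: two high-degree nodes wired to everything and to each other
  pairs <- rbind(t(utils::combn(1:2, 2)),
                 cbind(1L, 3:10), cbind(2L, 3:10), cbind(3L, 4L))
  toy <- structure(list(
    n = 10L, pairs = pairs, edges = rbind(pairs, pairs[, 2:1]),
    hub_class = rep("none", 10), neuron_type = rep(NA_character_, 10),
    cluster5 = rep(1L, 10), cluster25 = rep(1L, 10), cluster125 = rep(1L, 10),
    link_mode = "bidirectional"), class = "rcnet")
  deg <- node_degree(toy)
  k <- 5
  brute <- sum(apply(pairs, 1, function(p) all(deg[p] > k)))
  set.seed(3)
  rc <- normalized_rich_club(toy, k, n_null = 20)
  expect_equal(rc$edges_obs, brute)
  # degree-preserving null cannot create more than one edge between the two hubs
  expect_gte(rc$phi_norm, 1)

  set.seed(5)
  net <- connect_rich_club(assemble_replicas(build_base_network(2), 5), 1)
  rc2 <- normalized_rich_club(net, k_values = 19, n_null = 5)
  expect_gt(rc2$phi_norm, 1)
  # no nodes above threshold -> missing value
  expect_true(is.na(normalized_rich_club(toy, 50, n_null = 2)$phi_norm))
})

test_that("degree-exponent ML fit recovers a known exponent on synthetic discrete power-law data", {
  set.seed(8)
  # approximate discrete power-law sampler (continuous Pareto + half-shift floor)
  rzeta <- function(n, alpha, xmin = 1) {
    floor((xmin - 0.5) * (1 - runif(n))^(-1 / (alpha - 1)) + 0.5)
  }
  # sample from xmin = 5, where the half-shift approximation is accurate
  x <- rzeta(5000, 2.5, xmin = 5)
  fit <- degree_exponent(x, xmin = 5)
  expect_lt(abs(fit$gamma - 2.5), 0.15)
  # independent cross-check against igraph's plfit at the same fixed cutoff
  ig <- igraph::fit_power_law(x, xmin = 5, implementation = "plfit")
  expect_lt(abs(fit$gamma - ig$alpha), 0.1)
  # KS cutoff selection lands at (or below) the true xmin on clean tails
  fit_ks <- degree_exponent(x)
  expect_lt(abs(fit_ks$gamma - 2.5), 0.25)
})

test_that("unidirectional variant halves directed links; indegree-preserving randomization keeps indegree and lowers clustering", {
  set.seed(21)
  net <- connect_rich_club(assemble_replicas(build_base_network(2), 5), 0.5)
  uni <- variant_unidirectional(net)
  expect_equal(nrow(uni$edges), nrow(net$edges) / 2)
  rnd <- variant_randomize_keep_indegree(net)
  indeg <- function(x) tabulate(x$edges[, 2], nbins = x$n)
  expect_identical(indeg(rnd), indeg(net))
  expect_true(all(rnd$edges[, 1] != rnd$edges[, 2]))
  cc <- function(x) igraph::transitivity(igraph::simplify(as_igraph(x)))
  expect_lt(cc(rnd), cc(net))
})

test_that("network round-trips through the TSV serialization", {
  set.seed(12)
  net <- build_study_network(1, 0.5, 0.5, 125)
  dir <- tempfile("netdir")
  write_network(net, dir)
  back <- read_network(dir)
  expect_identical(sort(paste(back$pairs[, 1], back$pairs[, 2])),
                   sort(paste(net$pairs[, 1], net$pairs[, 2])))
  expect_identical(back$neuron_type, net$neuron_type)
  expect_identical(back$hub_class, net$hub_class)
  expect_identical(node_degree(back), node_degree(net))
  unlink(dir, recursive = TRUE)
})
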