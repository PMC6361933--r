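# Plain-text network serialization ----

#' Write a network to a directory of TSV files
#'
#' Writes `edges.tsv` (`src`, `dst`, `sign`; 0-based node ids, one row per
#' directed link, sign +1/-1 by the source neuron's type or `NA` when types
#' are unassigned) and `nodes.tsv` (`node`, `degree`, `hub_class`,
#' `neuron_type`, `cluster5`, `cluster25`, `cluster125`).
#'
#' @param net an `rcnet`.
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sign <- if (anyNA(net$neuron_type)) rep(NA_integer_, nrow(net$edges)) else
    ifelse(net$neuron_type[net$edges[, 1]] == "excitatory", 1L, -1L)
  utils::write.table(
    data.frame(src = net$edges[, 1] - 1L, dst = net$edges[, 2] - 1L,
               sign = sign),
    file.path(dir, "edges.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node = seq_len(net$n) - 1L, degree = node_degree(net),
               hub_class = net$hub_class, neuron_type = net$neuron_type,
               cluster5 = net$cluster5, cluster25 = net$cluster25,
               cluster125 = net$cluster125),
    file.path(dir, "nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a network written by [write_network()]
#'
#' @param dir directory containing `edges.tsv` and `nodes.tsv`.
#' @param link_mode link mode to record on the object (default
#'   `"bidirectional"`).
#' @return An `rcnet`.
#' @export
read_network <- function(dir, link_mode = "bidirectional") {
  edges <- utils::read.delim(file.path(dir, "edges.tsv"))
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"))
  net <- structure(list(
    n = nrow(nodes),
    edges = cbind(edges$src + 1L, edges$dst + 1L),
    pairs = unique(canonical_pairs(cbind(edges$src + 1L, edges$dst + 1L))),
    hub_class = nodes$hub_class,
    neuron_type = as.character(nodes$neuron_type),
    cluster5 = nodes$cluster5,
    cluster25 = nodes$cluster25,
    cluster125 = nodes$cluster125,
    link_mode = link_mode
  ), class = "rcnet")
  validate_rcnet(net)
  net
}
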