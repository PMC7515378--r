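# Network permutation entropy: embedded vectors become network nodes; a
# later vector connects to the FIRST earlier vector that shares its ordinal
# pattern and whose signed variance weight lies within a tolerance. Node
# scores (connection counts over a tiny floor) are normalized into a
# probability distribution whose normalized Shannon entropy is the NPE.

#' Build the pattern-and-weight connection network of a signal
#'
#' For each vector i = 2..N-d+1, earlier vectors j = 1..i-1 are scanned in
#' ascending order; the first j with an identical ordinal pattern AND
#' `|w_i - w_j| <= error` (signed weights) receives one edge `(i, j)` and
#' one increment of its score, after which the scan for i stops. Vectors
#' never matched keep the initial score floor.
#'
#' The scan is indexed by pattern code so each i only touches same-pattern
#' predecessors; the result is identical to the naive all-pairs scan.
#'
#' @param x numeric signal of length `N >= d+1`.
#' @param d embedding dimension (3..9).
#' @param error weight tolerance, `>= 0`. Connections require the absolute
#'   signed-weight difference to be at most `error`.
#' @param score_floor initial per-node score (default `1e-5`).
#' @return an object of class `complexity_network`: a list with `n_nodes`,
#'   `raw_scores`, `edges` (two-column matrix, later node first), `d`,
#'   `error`, and `score_floor`.
#' @examples
#' net <- build_network(c(1, 3, 4, 5, 4, 5, 3, 1, 2, 4, 5, 3), 3, 0.5)
#' net$edges # (9,1) and (10,5)
#' @export
build_network <- function(x, d, error, score_floor = 1e-5) {
  d <- check_dim(d)
  check_signal(x, n_min = d + 1L) # need >= 2 vectors
  if (!is.numeric(error) || length(error) != 1L || !is.finite(error) || error < 0)
    stop("error must be a single non-negative number", call. = FALSE)
  X <- embed_series(x, d)
  codes <- pattern_codes(X)
  w <- signed_weights(X)
  n <- length(w)
  raw <- rep(score_floor, n)
  ei <- integer(0); ej <- integer(0)
  for (g in split(seq_len(n), codes)) {
    m <- length(g)
    if (m < 2L) next
    wg <- w[g]
    for (k in 2:m) {
      hit <- which(abs(wg[seq_len(k - 1L)] - wg[k]) <= error)
      if (length(hit)) {
        j <- g[hit[1L]]
        raw[j] <- raw[j] + 1
        ei <- c(ei, g[k]); ej <- c(ej, j)
      }
    }
  }
  edges <- cbind(node_i = ei, node_j = ej)
  edges <- edges[order(ei), , drop = FALSE]
  structure(
    list(n_nodes = n, raw_scores = raw, edges = edges,
         d = d, error = error, score_floor = score_floor),
    class = "complexity_network"
  )
}

#' Network permutation entropy of a signal
#'
#' Builds the connection network (see [build_network()]), normalizes the
#' node scores into a probability distribution over all N-d+1 nodes, and
#' returns `NPE = -sum(p * ln p) / ln(N-d+1)`.
#'
#' @inheritParams build_network
#' @return an object of class `npe_result`: list with `value` (the NPE, in
#'   `[0, 1]`), `probabilities` (length N-d+1), and `network`.
#' @examples
#' npe(rep(1:5, length.out = 2000), d = 3, error = 0.0005)$value
#' @export
npe <- function(x, d, error = 0.005, score_floor = 1e-5) {
  net <- build_network(x, d, error, score_floor)
  p <- net$raw_scores / sum(net$raw_scores)
  structure(
    list(value = shannon(p) / log(net$n_nodes), probabilities = p, network = net),
    class = "npe_result"
  )
}

#' Summarize a connection network
#'
#' @param network a `complexity_network` from [build_network()].
#' @return list with `n_nodes`, `n_edges`, `n_isolated` (degree-0 nodes),
#'   `degree` (per-node degree sequence), and `probabilities` (normalized
#'   node scores).
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "complexity_network"))
  deg <- tabulate(c(network$edges[, 1L], network$edges[, 2L]), nbins = network$n_nodes)
  list(
    n_nodes = network$n_nodes,
    n_edges = nrow(network$edges),
    n_isolated = sum(deg == 0L),
    degree = deg,
    probabilities = network$raw_scores / sum(network$raw_scores)
  )
}

#' Dense adjacency matrix of a connection network
#'
#' Materializes the symmetric, hollow 0/1 adjacency matrix `M` from the
#' canonical edge list.
#'
#' @inheritParams network_summary
#' @return an `n_nodes x n_nodes` integer matrix.
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "complexity_network"))
  M <- matrix(0L, network$n_nodes, network$n_nodes)
  if (nrow(network$edges)) {
    M[network$edges] <- 1L
    M[network$edges[, 2:1, drop = FALSE]] <- 1L
  }
  M
}

#' @export
print.complexity_network <- function(x, ...) {
  s <- network_summary(x)
  cat("Pattern-weight connection network\n")
  cat(sprintf("  nodes: %d  edges: %d  isolated: %d\n",
              s$n_nodes, s$n_edges, s$n_isolated))
  cat(sprintf("  d = %d, error = %g, score floor = %g\n",
              x$d, x$error, x$score_floor))
  invisible(x)
}

#' @export
print.npe_result <- function(x, ...) {
  cat(sprintf("NPE = %.4f  (d = %d, error = %g, nodes = %d, edges = %d)\n",
              x$value, x$network$d, x$network$error,
              x$network$n_nodes, nrow(x$network$edges)))
  invisible(x)
}

#' Write a network as a tab-separated edge list
#'
#' Columns `node_i`, `node_j` (1-based, later node first), preceded by
#' '#'-comment lines echoing d, error, and node count.
#'
#' @inheritParams network_summary
#' @param path output file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "complexity_network"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# complexity network edge list: nodes=%d d=%d error=%g",
                     network$n_nodes, network$d, network$error), con)
  writeLines("node_i\tnode_j", con)
  if (nrow(network$edges))
    writeLines(sprintf("%d\t%d", network$edges[, 1L], network$edges[, 2L]), con)
  invisible(path)
}

#' Write node scores as TSV
#'
#' Columns `node`, `raw_score`, `probability`.
#'
#' @inheritParams write_edge_list
#' @export
write_node_scores <- function(network, path) {
  stopifnot(inherits(network, "complexity_network"))
  p <- network$raw_scores / sum(network$raw_scores)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# node scores: nodes=%d d=%d error=%g",
                     network$n_nodes, network$d, network$error), con)
  writeLines("node\traw_score\tprobability", con)
  writeLines(sprintf("%d\t%.10g\t%.10g",
                     seq_len(network$n_nodes), network$raw_scores, p), con)
  invisible(path)
}

#' Write a network in GraphML format
#'
#' Minimal undirected GraphML with the raw node score as a node attribute.
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "complexity_network"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="score" for="node" attr.name="raw_score" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="n%d"><data key="score">%.10g</data></node>',
                     seq_len(network$n_nodes), network$raw_scores), con)
  if (nrow(network$edges))
    writeLines(sprintf('    <edge source="n%d" target="n%d"/>',
                       network$edges[, 1L], network$edges[, 2L]), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
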