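#' Shortest-path visiting time (SVT) profile
#'
#' Deterministic baseline for the random-walk EVT: for every absorbing node k
#' other than the initiation site, all unweighted shortest paths from the
#' initiation site to k are enumerated, and each node on a path (endpoint
#' included, start excluded) receives credit 1 per path. Credits are averaged
#' over the n possible absorbing choices, mirroring the EVT averaging so the
#' two profiles are directly comparable.
#'
#' @param net an \code{affinity_network} over a connected graph.
#' @param initiation initiation node (index, id, or spec).
#' @return an \code{svt_profile}: list with \code{initiation}, \code{counts}
#'   (per-node average shortest-path visit counts, named by node id) and
#'   \code{nodes}.
#' @export
svt_profile <- function(net, initiation) {
  stopifnot(inherits(net, "affinity_network"))
  g <- contact_graph(net)
  if (igraph::components(g)$no > 1L)
    stop("SVT requires a connected network")
  n <- length(net$nodes)
  i <- match_node(net$nodes, initiation)
  counts <- numeric(n)
  paths <- igraph::all_shortest_paths(g, from = i, to = igraph::V(g),
                                      weights = NA)$vpaths
  for (p in paths) {
    v <- as.integer(p)
    if (v[length(v)] == i) next      # the trivial path to the start itself
    inc <- v[-1L]                    # start node receives no credit
    counts[inc] <- counts[inc] + 1
  }
  structure(list(initiation = net$nodes[i],
                 counts = stats::setNames(counts / n, net$nodes),
                 nodes = net$nodes),
            class = "svt_profile")
}

#' @export
print.svt_profile <- function(x, ...) {
  cat("svt_profile from", x$initiation, "over", length(x$counts), "nodes\n")
  invisible(x)
}
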