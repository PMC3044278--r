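#' Count inter-residue heavy-atom contacts
#'
#' \code{N[i, j]} is the number of heavy-atom pairs (one atom from node i, one
#' from node j) whose Euclidean distance is at most \code{cutoff}; the
#' diagonal is zero. The boundary is closed (distance equal to the cutoff
#' counts as a contact) and sequence-adjacent residues are counted like any
#' other pair.
#'
#' @param model a \code{structure_model}.
#' @param cutoff contact distance cutoff in Angstrom; the useful range for
#'   residue networks is about 3-12, default 8.
#' @return symmetric integer matrix with node ids as dimnames.
#' @export
count_contacts <- function(model, cutoff = 8) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a single positive number (Angstrom)")
  n <- nrow(model$nodes)
  if (n < 2L) stop("need at least 2 nodes")
  xyz <- do.call(rbind, model$coords)
  node_of <- rep.int(seq_len(n), vapply(model$coords, nrow, integer(1)))

  inco <- as.matrix(stats::dist(xyz)) <= cutoff
  # aggregate the atom-atom incidence to node pairs
  N <- rowsum(t(rowsum(inco + 0L, node_of)), node_of)
  N <- t(N)
  diag(N) <- 0L
  storage.mode(N) <- "integer"
  dimnames(N) <- list(model$nodes$node_id, model$nodes$node_id)
  N
}

#' Build the affinity-weighted network from contact counts
#'
#' The affinity between residues i and j is the size-normalised contact count
#' \deqn{a_{ij} = N_{ij} / \sqrt{N_i N_j},}
#' where \eqn{N_i}, \eqn{N_j} are the numbers of heavy atoms in the two
#' residues. Pairs with no contact within the cutoff get affinity zero; the
#' normalisation removes the bias large residues would otherwise have.
#'
#' @param N symmetric integer matrix of contact counts (zero diagonal).
#' @param heavy_counts integer vector of heavy-atom counts per node, all >= 1.
#' @param nodes optional character vector of node ids (defaults to the
#'   dimnames of \code{N}).
#' @param cutoff the cutoff (Angstrom) used to build \code{N}, kept for
#'   provenance.
#' @return an \code{affinity_network}: list with \code{nodes}, \code{A}
#'   (symmetric affinity matrix, zero diagonal), \code{contact_counts} and
#'   \code{cutoff}.
#' @export
affinity_matrix <- function(N, heavy_counts, nodes = NULL, cutoff = NA_real_) {
  N <- as.matrix(N)
  if (nrow(N) != ncol(N) || !isTRUE(all.equal(N, t(N), tolerance = 0)))
    stop("contact matrix must be square and symmetric")
  if (any(diag(N) != 0)) stop("contact matrix must have a zero diagonal")
  if (any(N < 0)) stop("contact counts must be non-negative")
  if (length(heavy_counts) != nrow(N))
    stop("need one heavy-atom count per node")
  if (any(!is.finite(heavy_counts)) || any(heavy_counts < 1))
    stop("heavy-atom counts must all be >= 1 (zero would make the affinity undefined)")
  nodes <- nodes %||% rownames(N) %||% as.character(seq_len(nrow(N)))

  A <- N / sqrt(outer(as.numeric(heavy_counts), as.numeric(heavy_counts)))
  diag(A) <- 0
  dimnames(A) <- list(nodes, nodes)
  dimnames(N) <- list(nodes, nodes)
  structure(list(nodes = nodes, A = A, contact_counts = N,
                 cutoff = cutoff, heavy_counts = as.integer(heavy_counts)),
            class = "affinity_network")
}

#' One-step network construction from a structure model
#'
#' Convenience wrapper: [count_contacts()] then [affinity_matrix()].
#'
#' @inheritParams count_contacts
#' @return an \code{affinity_network}.
#' @export
build_network <- function(model, cutoff = 8) {
  N <- count_contacts(model, cutoff)
  affinity_matrix(N, model$nodes$heavy_count,
                  nodes = model$nodes$node_id, cutoff = cutoff)
}

#' @export
print.affinity_network <- function(x, ...) {
  ne <- sum(x$A[upper.tri(x$A)] > 0)
  cat("affinity_network: ", length(x$nodes), " nodes, ", ne, " edges",
      if (!is.na(x$cutoff)) paste0(", cutoff ", x$cutoff, " A"), "\n",
      sep = "")
  invisible(x)
}

#' Markov transition matrix of the weighted residue network
#'
#' Normalises each node's affinities by its degree \eqn{d_i = \sum_j a_{ij}}:
#' \deqn{T_{ij} = a_{ij} / d_i,} giving the row-stochastic one-step transition
#' matrix of the random walk. Self-edges are not considered (the diagonal is
#' zero). The walk is reversible with stationary distribution proportional to
#' the degrees.
#'
#' The absorbing-chain machinery requires a single connected component with no
#' isolated node; by default a violation is an error naming the offending
#' nodes, so a truncated profile can never go unnoticed. With
#' \code{component_policy = "largest"} the network is reduced to its largest
#' connected component instead.
#'
#' @param net an \code{affinity_network}.
#' @param component_policy \code{"error"} (default) or \code{"largest"}.
#' @return a \code{transition_matrix}: list with row-stochastic \code{T},
#'   \code{degrees} and \code{nodes}.
#' @export
transition_matrix <- function(net, component_policy = c("error", "largest")) {
  stopifnot(inherits(net, "affinity_network"))
  component_policy <- match.arg(component_policy)
  A <- net$A
  d <- rowSums(A)
  comp <- igraph::components(contact_graph(net))
  bad <- d <= 0 | comp$membership != which.max(comp$csize)
  if (any(bad)) {
    if (component_policy == "error")
      stop("network is not a single connected component; offending node(s): ",
           paste(net$nodes[bad], collapse = ", "))
    A <- A[!bad, !bad, drop = FALSE]
    d <- rowSums(A)
    net$nodes <- net$nodes[!bad]
  }
  if (length(net$nodes) < 2L)
    stop("connected network must retain at least 2 nodes")
  Tm <- A / d
  dimnames(Tm) <- list(net$nodes, net$nodes)
  structure(list(T = Tm, degrees = stats::setNames(d, net$nodes),
                 nodes = net$nodes),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", length(x$nodes), "nodes, row-stochastic\n")
  invisible(x)
}

#' Edge list of an affinity network
#'
#' @param net an \code{affinity_network}.
#' @param file optional path to write the edge list as TSV.
#' @return data frame with node_i, node_j, n_contacts, affinity (one row per
#'   undirected edge).
#' @export
network_edges <- function(net, file = NULL) {
  stopifnot(inherits(net, "affinity_network"))
  ut <- which(upper.tri(net$A) & net$A > 0, arr.ind = TRUE)
  edges <- data.frame(
    node_i = net$nodes[ut[, 1L]],
    node_j = net$nodes[ut[, 2L]],
    n_contacts = net$contact_counts[ut],
    affinity = net$A[ut],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(file))
    utils::write.table(edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  edges
}

# unweighted igraph view of the contact topology
contact_graph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$A > 0, mode = "undirected")
}
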