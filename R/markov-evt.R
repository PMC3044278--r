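#' Fundamental matrix of the absorbing chain with absorbing node k
#'
#' Removing row and column k from the transition matrix T gives the reduced
#' matrix \eqn{T^{(k)}}; the fundamental matrix of the absorbing chain is
#' \deqn{F = (I - T^{(k)})^{-1}.}
#' Entry (i, j) is the expected number of times node j is visited by a walk
#' started at i before absorption at k (the start's own initial occupancy
#' counts, so \eqn{F_{ii} \ge 1}). The system is solved by LU factorisation
#' against the identity rather than explicit inversion.
#'
#' @param tm a \code{transition_matrix} over a connected network.
#' @param k absorbing node (index, id, or \code{"CHAIN:RESNUM"} spec).
#' @return a \code{fundamental_matrix}: list with \code{k} (node id),
#'   \code{F} ((n-1) x (n-1) matrix over the non-absorbing nodes) and
#'   \code{nodes} (their ids).
#' @export
fundamental_matrix <- function(tm, k) {
  stopifnot(inherits(tm, "transition_matrix"))
  ki <- match_node(tm$nodes, k)
  Tk <- tm$T[-ki, -ki, drop = FALSE]
  m <- nrow(Tk)
  S <- diag(m) - Tk
  rc <- rcond(S)
  if (!is.finite(rc) || rc < .Machine$double.eps)
    stop("I - T^k is numerically singular; is the remaining network connected?")
  if (rc < 1e-12)
    warning("I - T^k is ill-conditioned (rcond ", format(rc), ")")
  Fm <- solve(S)
  dimnames(Fm) <- list(tm$nodes[-ki], tm$nodes[-ki])
  structure(list(k = tm$nodes[ki], F = Fm, nodes = tm$nodes[-ki]),
            class = "fundamental_matrix")
}

#' Expected visiting time (EVT) matrix
#'
#' For every choice of absorbing node k the fundamental matrix \eqn{F^{(k)}}
#' is extended back to n x n by filling its k-th row with 0 (an absorbing
#' start emits nothing) and its k-th column with 1 (the absorbing node is
#' entered exactly once); the EVT matrix is the average over all n absorbing
#' choices,
#' \deqn{M = \frac{1}{n} \sum_k \mathrm{ext}(F^{(k)}).}
#' Row i of M is the EVT profile for signal initiation at node i: the mean
#' number of visits each node receives from a random walk out of i, averaged
#' over all possible absorbing sites. Every entry is at least 1/n (each node
#' is the absorbing site of exactly one of the n averaged chains).
#'
#' @param tm a \code{transition_matrix} over a connected network.
#' @return an \code{evt_matrix}: list with \code{M}, \code{nodes},
#'   \code{cutoff}.
#' @export
evt_matrix <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- length(tm$nodes)
  if (n < 2L) stop("EVT needs at least 2 nodes")
  Tm <- unname(tm$T)
  M <- matrix(0, n, n)
  I <- diag(n - 1L)
  for (k in seq_len(n)) {
    Fk <- tryCatch(solve(I - Tm[-k, -k, drop = FALSE]),
                   error = function(e)
                     stop("singular system at absorbing node ", tm$nodes[k],
                          ": ", conditionMessage(e), call. = FALSE))
    M[-k, -k] <- M[-k, -k] + Fk
    M[, k] <- M[, k] + 1     # column of ones; covers the (k, k) diagonal too
  }
  M <- M / n
  dimnames(M) <- list(tm$nodes, tm$nodes)
  structure(list(M = M, nodes = tm$nodes, cutoff = attr(tm, "cutoff")),
            class = "evt_matrix")
}

#' @export
print.evt_matrix <- function(x, ...) {
  cat("evt_matrix:", length(x$nodes), "nodes; rows are EVT profiles\n")
  invisible(x)
}

#' EVT profile for one signal initiation site
#'
#' Extracts row i of the EVT matrix and attaches its z-score normalisation.
#'
#' @param em an \code{evt_matrix}.
#' @param initiation initiation node (index, id, or spec).
#' @param sd_type passed to [zscore_profile()].
#' @return an \code{evt_profile}: list with \code{initiation}, \code{raw},
#'   \code{z} (both named by node id) and \code{nodes}.
#' @export
evt_profile <- function(em, initiation, sd_type = "population") {
  stopifnot(inherits(em, "evt_matrix"))
  i <- match_node(em$nodes, initiation)
  raw <- em$M[i, ]
  structure(list(initiation = em$nodes[i], raw = raw,
                 z = zscore_profile(raw, sd_type), nodes = em$nodes),
            class = "evt_profile")
}

#' @export
print.evt_profile <- function(x, ...) {
  cat("evt_profile from", x$initiation, "over", length(x$raw), "nodes\n")
  top <- utils::head(sort(x$z, decreasing = TRUE), 5L)
  cat("  top z:", paste(names(top), sprintf("%.2f", top), collapse = ", "),
      "\n")
  invisible(x)
}

#' Z-score normalisation of an EVT profile
#'
#' Centres and scales a profile so its mean is 0 and its standard deviation 1,
#' making values comparable across structures of different size. The default
#' scale is the population standard deviation (divisor n); set
#' \code{sd_type = "sample"} for the n-1 divisor.
#'
#' @param raw numeric vector (length >= 2, non-constant).
#' @param sd_type \code{"population"} (default) or \code{"sample"}.
#' @return numeric vector of z-scores, names preserved.
#' @export
zscore_profile <- function(raw, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (length(raw) < 2L) stop("z-scores need at least 2 values")
  if (any(!is.finite(raw))) stop("profile contains non-finite values")
  mu <- mean(raw)
  sigma <- if (sd_type == "population")
    sqrt(mean((raw - mu)^2)) else stats::sd(raw)
  if (sigma == 0) stop("constant profile: standard deviation is zero")
  (raw - mu) / sigma
}

#' Distance-scaled EVT profile
#'
#' Multiplies each node's EVT by its hop distance (unweighted shortest-path
#' length on the contact graph) from the initiation site, highlighting nodes
#' that are both strongly visited and far from the perturbation - candidate
#' allosteric sites. The initiation node itself scales to 0.
#'
#' @param raw numeric EVT profile (model/network node order).
#' @param initiation initiation node (index, id, or spec).
#' @param net the \code{affinity_network} the profile was computed on.
#' @return numeric vector of scaled values, named by node id.
#' @export
scaled_profile <- function(raw, initiation, net) {
  stopifnot(inherits(net, "affinity_network"))
  if (length(raw) != length(net$nodes))
    stop("profile length does not match the network")
  i <- match_node(net$nodes, initiation)
  d <- igraph::distances(contact_graph(net), v = i, weights = NA)[1L, ]
  if (any(!is.finite(d)))
    stop("node(s) unreachable from the initiation site: ",
         paste(net$nodes[!is.finite(d)], collapse = ", "))
  stats::setNames(as.numeric(raw) * d, net$nodes)
}

#' Ratio comparison of two EVT profiles
#'
#' For two structures of the same protein (e.g. a light and a dark state)
#' profiled from the same initiation site, \code{raw_a / raw_b - 1} per node
#' highlights residues whose signalling role differs between the states.
#' Profiles are matched by node id; EVT entries are strictly positive
#' (>= 1/n), so the ratio is always defined.
#'
#' @param p_a,p_b \code{evt_profile} objects (or named numeric vectors) over
#'   the same node set and initiation site.
#' @return numeric vector of ratio-minus-one values in \code{p_a}'s node
#'   order.
#' @export
profile_ratio <- function(p_a, p_b) {
  ra <- profile_raw(p_a)
  rb <- profile_raw(p_b)
  if (inherits(p_a, "evt_profile") && inherits(p_b, "evt_profile") &&
      !identical(p_a$initiation, p_b$initiation))
    stop("profiles have different initiation sites: ",
         p_a$initiation, " vs ", p_b$initiation)
  miss_a <- setdiff(names(ra), names(rb))
  miss_b <- setdiff(names(rb), names(ra))
  if (length(miss_a) > 0L || length(miss_b) > 0L)
    stop("node sets differ; unmatched node(s): ",
         paste(c(miss_a, miss_b), collapse = ", "))
  ra / rb[names(ra)] - 1
}

profile_raw <- function(p) {
  r <- if (inherits(p, "evt_profile")) p$raw else p
  if (is.null(names(r))) stop("profiles must carry node ids as names")
  r
}

#' Average signal traffic over all initiation sites
#'
#' Sums the EVT profiles of all initiation nodes (the column sums of M),
#' giving a betweenness-like centrality: a node with high average traffic is
#' heavily visited during site-to-site communication and acts as a signalling
#' bridge.
#'
#' @param em an \code{evt_matrix}.
#' @return numeric vector of traffic values, named by node id.
#' @export
average_evt <- function(em) {
  stopifnot(inherits(em, "evt_matrix"))
  colSums(em$M)
}

#' EVT profile robustness across contact cutoffs
#'
#' Rebuilds the network at each cutoff, recomputes the EVT profile from the
#' same initiation site, and returns the matrix of pairwise Pearson
#' correlations between the profiles. Cutoffs whose network is disconnected
#' are excluded and reported. High off-diagonal correlations mean the choice
#' of cutoff hardly matters in that range.
#'
#' @param model a \code{structure_model}.
#' @param initiation initiation node (index, id, or spec).
#' @param cutoffs numeric vector of cutoffs in Angstrom.
#' @return a \code{cutoff_scan}: list with \code{correlations} (symmetric,
#'   unit diagonal, labelled by cutoff), \code{profiles} (one column per
#'   usable cutoff) and \code{failed} (named character vector of error
#'   messages for excluded cutoffs).
#' @export
profile_correlation_scan <- function(model, initiation, cutoffs) {
  stopifnot(inherits(model, "structure_model"))
  profiles <- list()
  failed <- character()
  for (co in cutoffs) {
    key <- format(co)
    res <- tryCatch({
      tm <- transition_matrix(build_network(model, co))
      em <- evt_matrix(tm)
      em$M[match_node(em$nodes, initiation), ]
    }, error = function(e) e)
    if (inherits(res, "error"))
      failed[key] <- conditionMessage(res)
    else profiles[[key]] <- res
  }
  if (length(profiles) < 1L)
    stop("no cutoff produced a connected network")
  P <- do.call(cbind, profiles)
  structure(list(correlations = stats::cor(P), profiles = P,
                 failed = failed),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("cutoff_scan over", ncol(x$profiles), "cutoffs\n")
  print(round(x$correlations, 3))
  if (length(x$failed) > 0L)
    cat("excluded (disconnected):", paste(names(x$failed), collapse = ", "),
        "\n")
  invisible(x)
}

#' Full per-residue EVT analysis of one structure
#'
#' End-to-end convenience: builds the network at the given cutoff, computes
#' the EVT matrix, and tabulates the profile from the initiation site with
#' its z-scores, hop distances and distance-scaled values.
#'
#' @param model a \code{structure_model}.
#' @param initiation initiation node (index, id, or spec).
#' @param cutoff contact cutoff in Angstrom, default 8.
#' @param component_policy passed to [transition_matrix()].
#' @return data frame with chain, resnum, icode, resname, evt_raw, evt_z,
#'   hop_distance, evt_scaled.
#' @export
evt_analysis <- function(model, initiation, cutoff = 8,
                         component_policy = "error") {
  net <- build_network(model, cutoff)
  tm <- transition_matrix(net, component_policy)
  em <- evt_matrix(tm)
  prof <- evt_profile(em, initiation)
  keep <- match(em$nodes, model$nodes$node_id)
  i <- match_node(em$nodes, initiation)
  g <- contact_graph(net)
  if (length(em$nodes) != length(net$nodes))
    g <- igraph::induced_subgraph(g, match(em$nodes, net$nodes))
  d <- igraph::distances(g, v = i, weights = NA)[1L, ]
  out <- model$nodes[keep, c("chain", "resnum", "icode", "resname")]
  out$evt_raw <- as.numeric(prof$raw)
  out$evt_z <- as.numeric(prof$z)
  out$hop_distance <- as.numeric(d)
  out$evt_scaled <- out$evt_raw * out$hop_distance
  rownames(out) <- NULL
  out
}
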