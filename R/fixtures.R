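#' Generate a synthetic toy structure with known contact topology
#'
#' Emits PDB-format text for a toy "protein" whose residue contact graph at
#' the stated cutoff is exactly the requested topology: each node is a
#' cluster of carbon atoms within 1 Angstrom of its centre, centres of
#' bonded nodes are \code{spacing} apart, and non-bonded centres are placed
#' far enough apart that no stray contact arises. Atom offsets use a
#' deterministic golden-angle arrangement (no RNG), so the same spec and
#' seed always give byte-identical text. The realised contact graph is
#' verified by brute force before returning; an unrealisable geometry is an
#' error.
#'
#' @param topology one of \code{"path"}, \code{"ring"}, \code{"star"},
#'   \code{"grid"}, \code{"custom"}.
#' @param n_nodes number of nodes (>= 2; a star supports at most 7 with the
#'   default spacing).
#' @param atoms_per_node heavy atoms per node, scalar or length-n vector.
#' @param spacing centre-to-centre distance of bonded nodes in Angstrom,
#'   default 7.
#' @param jitter_seed integer folded into the atom-offset angles.
#' @param edges for \code{"custom"}: two-column integer matrix of undirected
#'   edges.
#' @param centers for \code{"custom"}: n x 3 matrix of node centres.
#' @param cutoff contact cutoff the topology must hold at, default 8.
#' @return character vector of PDB lines.
#' @export
make_toy_structure <- function(topology = c("path", "ring", "star", "grid",
                                            "custom"),
                               n_nodes, atoms_per_node = 3, spacing = 7,
                               jitter_seed = 1, edges = NULL, centers = NULL,
                               cutoff = 8) {
  topology <- match.arg(topology)
  n <- as.integer(n_nodes)
  if (n < 2L) stop("a toy structure needs at least 2 nodes")
  m <- rep_len(as.integer(atoms_per_node), n)
  if (any(m < 1L)) stop("atoms_per_node must be >= 1")

  want <- switch(topology,
    path = cbind(1:(n - 1L), 2:n),
    ring = if (n == 2L) cbind(1L, 2L) else cbind(1:n, c(2:n, 1L)),
    star = cbind(1L, 2:n),
    grid = grid_edges(n),
    custom = {
      if (is.null(edges) || is.null(centers))
        stop("custom topology needs both 'edges' and 'centers'")
      as.matrix(edges)
    })
  want <- t(apply(want, 1L, sort))
  want <- unique(want[want[, 1L] != want[, 2L], , drop = FALSE])

  ctr <- switch(topology,
    path = cbind((seq_len(n) - 1) * spacing, 0, 0),
    ring = {
      if (n == 2L) cbind(c(0, spacing), 0, 0)
      else {
        R <- spacing / (2 * sin(pi / n))
        th <- 2 * pi * (seq_len(n) - 1) / n
        cbind(R * cos(th), R * sin(th), 0)
      }
    },
    star = {
      dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
      if (n - 1L > nrow(dirs))
        stop("geometrically unrealizable spec: a star supports at most ",
             nrow(dirs) + 1L, " nodes at this spacing")
      rbind(c(0, 0, 0), dirs[seq_len(n - 1L), , drop = FALSE] * spacing)
    },
    grid = {
      k <- ceiling(sqrt(n))
      idx <- seq_len(n) - 1L
      cbind((idx %% k) * spacing, (idx %/% k) * spacing, 0)
    },
    custom = as.matrix(centers))
  if (nrow(ctr) != n || ncol(ctr) != 3L)
    stop("centers must be an n x 3 matrix")

  # deterministic golden-angle offsets, all within 0.35 A of the centre
  golden <- pi * (3 - sqrt(5))
  coords <- lapply(seq_len(n), function(i) {
    t <- seq_len(m[i])
    if (m[i] == 1L) return(matrix(ctr[i, ], 1L, 3L))
    z <- (2 * t - 1) / m[i] - 1
    rxy <- sqrt(pmax(0, 1 - z^2))
    phi <- t * golden + i * 1.2345 + jitter_seed * 0.61803
    off <- 0.35 * cbind(rxy * cos(phi), rxy * sin(phi), z)
    sweep(off, 2L, ctr[i, ], "+")
  })

  # brute-force verification that the realised contact graph is the request
  has_edge <- matrix(FALSE, n, n)
  has_edge[want] <- TRUE
  has_edge <- has_edge | t(has_edge)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d2 <- outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), "+") -
      2 * tcrossprod(coords[[i]], coords[[j]])
    dmin <- sqrt(max(0, min(d2)))
    if (has_edge[i, j] && dmin > cutoff)
      stop("geometrically unrealizable spec: intended edge ", i, "-", j,
           " has no atom pair within ", cutoff, " A")
    if (!has_edge[i, j] && dmin <= cutoff)
      stop("geometrically unrealizable spec: unintended contact ", i, "-", j,
           " at ", format(dmin, digits = 4), " A")
  }

  lines <- character(sum(m) + 1L)
  serial <- 0L
  for (i in seq_len(n)) for (t in seq_len(m[i])) {
    serial <- serial + 1L
    lines[serial] <- sprintf(
      "ATOM  %5d  C%-2d%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, t, "", "ALA", "A", i, "",
      coords[[i]][t, 1L], coords[[i]][t, 2L], coords[[i]][t, 3L],
      1, 0, "C")
  }
  lines[serial + 1L] <- "END"
  lines
}

grid_edges <- function(n) {
  k <- ceiling(sqrt(n))
  e <- NULL
  for (i in seq_len(n)) {
    col <- (i - 1L) %% k
    if (col < k - 1L && i + 1L <= n) e <- rbind(e, c(i, i + 1L))
    if (i + k <= n) e <- rbind(e, c(i, i + k))
  }
  e
}

#' Monte-Carlo random-walk oracle for absorbing-chain visit counts
#'
#' Simulates independent random walks that start at \code{start}, step
#' according to the transition matrix, and stop on first arrival at
#' \code{absorbing}. A visit is counted on every arrival at a node (the
#' start's initial occupancy counts once; the absorbing node counts once on
#' entry), matching the visiting-frequency semantics of the fundamental
#' matrix, whose row \code{start} the mean visit counts estimate. If
#' \code{start == absorbing}, the walk is absorbed immediately and the
#' estimate is exact.
#'
#' @param tm a \code{transition_matrix}.
#' @param start,absorbing node (index, id, or spec).
#' @param n_walks number of independent walks.
#' @param seed RNG seed; the caller's RNG state is not disturbed.
#' @param max_total_steps abort threshold over all walks (default 1e7),
#'   guarding against non-absorbing systems.
#' @return a \code{walk_estimate}: list with \code{visits} (per-node mean
#'   visit count), \code{se} (its standard error), \code{n_walks},
#'   \code{seed}, \code{start}, \code{absorbing}.
#' @export
random_walk_oracle <- function(tm, start, absorbing, n_walks = 10000,
                               seed = 1, max_total_steps = 1e7) {
  stopifnot(inherits(tm, "transition_matrix"))
  n <- length(tm$nodes)
  i <- match_node(tm$nodes, start)
  k <- match_node(tm$nodes, absorbing)
  V <- matrix(0, n_walks, n)
  V[, i] <- 1
  if (i != k) {
    cum <- t(apply(unname(tm$T), 1L, cumsum))
    cum[, n] <- 1
    with_local_seed(seed, {
      state <- rep.int(i, n_walks)
      alive <- rep.int(TRUE, n_walks)
      total <- 0
      while (any(alive)) {
        idx <- which(alive)
        u <- stats::runif(length(idx))
        nxt <- rowSums(cum[state[idx], , drop = FALSE] < u) + 1L
        V[cbind(idx, nxt)] <- V[cbind(idx, nxt)] + 1
        state[idx] <- nxt
        alive[idx[nxt == k]] <- FALSE
        total <- total + length(idx)
        if (total > max_total_steps)
          stop("random walk exceeded the step cap (", max_total_steps,
               "); the chain is probably not absorbing")
      }
    })
  }
  visits <- colMeans(V)
  se <- sqrt(apply(V, 2L, stats::var) / n_walks)
  structure(list(visits = stats::setNames(visits, tm$nodes),
                 se = stats::setNames(se, tm$nodes),
                 n_walks = n_walks, seed = seed,
                 start = tm$nodes[i], absorbing = tm$nodes[k]),
            class = "walk_estimate")
}

#' @export
print.walk_estimate <- function(x, ...) {
  cat("walk_estimate:", x$n_walks, "walks", x$start, "->", x$absorbing,
      "(seed", paste0(x$seed, ")"), "\n")
  print(round(rbind(visits = x$visits, se = x$se), 4))
  invisible(x)
}
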