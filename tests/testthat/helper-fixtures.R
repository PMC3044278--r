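# Shared fixtures and independent oracles for the test suite.

# One fixed-column PDB record (ATOM/HETATM).
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element, altloc = "", occ = 1, b = 0,
                     record = "ATOM", icode = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resno, icode,
          x, y, z, occ, b, element)
}

# Two-residue fixture: GLY with 4 heavy atoms + 2 hydrogens, ALA with
# 5 heavy atoms, plus a water. Residues ~4 A apart.
gly_ala_pdb <- function(with_water = TRUE) {
  lines <- c(
    pdb_line(1, " N",  "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_line(2, " CA", "GLY", "A", 1, 1.5, 0.0, 0.0, "C"),
    pdb_line(3, " C",  "GLY", "A", 1, 2.0, 1.4, 0.0, "C"),
    pdb_line(4, " O",  "GLY", "A", 1, 1.3, 2.4, 0.0, "O"),
    pdb_line(5, " H",  "GLY", "A", 1, -0.5, 0.8, 0.0, "H"),
    pdb_line(6, " HA", "GLY", "A", 1, 1.9, -0.9, 0.5, "H"),
    pdb_line(7, " N",  "ALA", "A", 2, 3.3, 1.5, 0.0, "N"),
    pdb_line(8, " CA", "ALA", "A", 2, 4.0, 2.8, 0.0, "C"),
    pdb_line(9, " C",  "ALA", "A", 2, 5.5, 2.6, 0.0, "C"),
    pdb_line(10, " O", "ALA", "A", 2, 6.1, 1.5, 0.0, "O"),
    pdb_line(11, " CB","ALA", "A", 2, 3.6, 3.7, 1.2, "C")
  )
  if (with_water)
    lines <- c(lines,
               pdb_line(12, " O", "HOH", "A", 101, 9.0, 9.0, 9.0, "O",
                        record = "HETATM"))
  c(lines, "END")
}

# Abstract affinity network from an edge list with unit contact counts and
# unit heavy-atom counts, so every edge has affinity exactly 1.
edge_network <- function(edges, n, nodes = LETTERS[seq_len(n)]) {
  N <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    N[i, j] <- N[j, i] <- 1L
  }
  affinity_matrix(N, rep(1L, n), nodes = nodes)
}

path_network <- function(n = 3) edge_network(cbind(1:(n - 1L), 2:n), n)

# Independent brute-force contact counter: O(n^2 * atoms^2) double loop.
brute_contacts <- function(model, cutoff) {
  n <- nrow(model$nodes)
  N <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- model$coords[[i]]; cj <- model$coords[[j]]
    cnt <- 0L
    for (p in seq_len(nrow(ci))) for (q in seq_len(nrow(cj)))
      if (sqrt(sum((ci[p, ] - cj[q, ])^2)) <= cutoff) cnt <- cnt + 1L
    N[i, j] <- N[j, i] <- cnt
  }
  N
}

# Independent SVT oracle: BFS distances + recursive enumeration of all
# shortest paths (no graph library involved).
svt_oracle <- function(adj, start) {
  n <- nrow(adj)
  dist <- rep(Inf, n); dist[start] <- 0
  queue <- start
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in which(adj[v, ] > 0))
      if (!is.finite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
  }
  paths_to <- function(k) {
    if (k == start) return(list(start))
    preds <- which(adj[k, ] > 0 & dist == dist[k] - 1)
    out <- list()
    for (p in preds)
      for (pp in paths_to(p)) out <- c(out, list(c(pp, k)))
    out
  }
  counts <- numeric(n)
  for (k in seq_len(n)) {
    if (k == start) next
    for (p in paths_to(k)) {
      v <- p[-1L]
      counts[v] <- counts[v] + 1
    }
  }
  counts / n
}

# Monte-Carlo estimate of the full EVT matrix: splits a total walk budget
# evenly over the n(n-1) non-trivial (start, absorbing) chains and applies
# the same row-0 / column-1 fill conventions as evt_matrix().
oracle_evt_matrix <- function(tm, total_walks, seed) {
  n <- length(tm$nodes)
  per <- max(50L, floor(total_walks / (n * (n - 1L))))
  M <- matrix(0, n, n)
  Vr <- matrix(0, n, n)  # accumulated variances of each M entry
  chain <- 0L
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) {
      contrib <- numeric(n); contrib[k] <- 1   # immediate absorption
      M[i, ] <- M[i, ] + contrib
      next
    }
    chain <- chain + 1L
    est <- random_walk_oracle(tm, i, k, n_walks = per, seed = seed + chain)
    M[i, ] <- M[i, ] + est$visits
    Vr[i, ] <- Vr[i, ] + est$se^2
  }
  list(M = M / n, se = sqrt(Vr) / n, walks_per_chain = per)
}

# Random realizable toy-structure spec (used for property-style loops).
random_toy_model <- function(seed) {
  set.seed(seed)
  topo <- sample(c("path", "ring", "star", "grid"), 1L)
  n <- sample(3:6, 1L)
  atoms <- sample(1:4, n, replace = TRUE)
  pdb <- make_toy_structure(topo, n, atoms_per_node = atoms,
                            jitter_seed = seed)
  parse_structure(pdb, source_id = paste0(topo, n, "-", seed))
}
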