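---
title: "Modelling allosteric signal propagation with expected visiting times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling allosteric signal propagation with expected visiting times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evtnet)
```

## The problem

When an effector binds a protein, or light isomerises a chromophore, the
perturbation is often felt at sites far from where it happened. Single-path
descriptions of this communication are too narrow: experimental work points
to cooperative transmission through many parallel routes. `evtnet` therefore
treats the protein as a weighted residue network and the signal as a random
walker on it, scoring each residue by how often the walker visits it when
*all* routes and *all* possible terminations are integrated.

## From structure to network

Each amino acid is a node; a bound ligand (a chromophore, a cofactor) is a
node too, because it can initiate or relay signals. Two nodes are linked
when any pair of their heavy atoms lies within the distance cutoff, and the
edge weight is the size-normalised contact count

$$a_{ij} = \frac{N_{ij}}{\sqrt{N_i\,N_j}},$$

with $N_{ij}$ the number of heavy-atom pairs within the cutoff and $N_i$ the
residue's heavy-atom count; pairs without contact get $a_{ij}=0$. The square
root denominators stop large residues from dominating merely by size. The
cutoff defaults to 8 Å — long enough that the weighted network changes little
under rewiring (see the robustness scan below) while staying within the
physically meaningful 3–12 Å range. The contact test uses a closed boundary
(distance $\le$ cutoff), sequence-adjacent residues are counted like any
other pair, and both $N_{ij}$ and the edge criterion use the same cutoff.

Parsing rules that matter for reproducibility, since coordinate files are
messier than formulas:

* hydrogens (elements H and D, with an atom-name fallback when the element
  column is blank) and waters (HOH/WAT/DOD) are removed before anything is
  counted;
* alternate locations are reduced to the highest-occupancy copy, ties broken
  by altloc code order — a deterministic convention, not a physical claim;
* only the first MODEL of a multi-model file is used: the method is defined
  on a single static structure;
* a covalently attached group can be merged into its host residue with a
  `merge_map` (e.g. a retinal into its Schiff-base lysine), producing one
  node with the union of heavy atoms; unmerged hetero-groups are separate
  nodes by default so a cofactor can serve as the initiation site.

## The random walk and its expected visiting times

Normalising affinities by the node degree $d_i=\sum_j a_{ij}$ gives the
transition matrix $T_{ij} = a_{ij}/d_i$ (no self-edges). Because $a$ is
symmetric the walk is reversible, with stationary distribution proportional
to the degrees — one of the conservation laws the test suite checks.

Fixing an absorbing node $k$ and deleting its row and column yields $T^k$;
the fundamental matrix of the absorbing chain,

$$F^k = (I - T^k)^{-1},$$

holds in entry $(i,j)$ the expected number of visits to $j$ on the way from
$i$ to absorption at $k$. $F^k$ is computed by LU solves against the
identity rather than explicit inversion; the user-facing single-$k$ routine
warns when the system's reciprocal condition number falls below $10^{-12}$.
Invertibility is guaranteed on a connected network, which is why a
disconnected network is a hard error by default (reduction to the largest
component is available but must be requested — silent truncation of a
profile is worse than a stop).

The EVT matrix averages over every absorbing choice:

$$M = \frac1n \sum_k \mathrm{ext}(F^k),$$

where $\mathrm{ext}$ pads $F^k$ back to $n \times n$ with the $k$-th row
filled with 0 (an absorbed start emits nothing) and the $k$-th column filled
with 1 (the absorbing node is entered exactly once). When initiation and
absorption coincide the two conventions meet on the diagonal and the chain
contributes a lone 1 there — the immediate-absorption case. A direct
consequence is that every entry of $M$ is at least $1/n$, so ratios of EVT
profiles are always well defined. On the 3-node path A–B–C with unit
affinities all of this is solvable by hand ($F^C = [[2,2],[1,2]]$, row A of
$M = (4/3, 1, 1/3)$), and those values anchor the test suite to $10^{-10}$.

### Profile transforms

* **z-scores.** Profiles are normalised per structure to mean 0, sd 1. The
  scale is the population standard deviation (divisor $n$); the sample
  variant is available via `sd_type = "sample"`. Normalisation is per
  profile (per initiation site), and the initiation node's own EVT enters
  the mean and sd; both choices are conventions of this package where the
  underlying method statement is silent.
* **Distance scaling.** Multiplying each EVT by the hop distance from the
  initiation site (unweighted shortest-path length on the contact graph)
  suppresses the trivially high values next to the perturbation and
  highlights distant, strongly visited residues — candidate allosteric
  sites. The initiation node scales to zero.
* **Ratios.** For two structures of the same protein (for instance dark and
  light states of a photoreceptor domain) profiled from the same initiation
  site, $\mathrm{raw}_a/\mathrm{raw}_b - 1$ per matched node highlights
  state-dependent signalling changes.
* **Average traffic.** Column sums of $M$ aggregate the EVT profiles of all
  initiation sites into a betweenness-like centrality; a high value marks a
  node that bridges site-to-site communication.

## The shortest-path baseline (SVT)

To show that integrating over all routes matters, the package includes the
analogous count restricted to shortest paths: for every absorbing node $k$
all tied unweighted shortest paths from the initiation site are enumerated,
each node on a path receives credit 1 per path (endpoint included, start
excluded, mirroring the EVT fill conventions), and credits are averaged over
the $n$ absorbing choices. Hop count is used as the path length because no
edge length is defined for this baseline, and counting *all* tied paths
avoids an arbitrary tie-break. On a tree each node's raw credit equals the
number of nodes in the subtree behind it, which the tests exploit as a
closed form; general cases are cross-checked against an independent
enumeration oracle.

## Binding hot spots and the ΔΔG regression

If binding hot spots act as signal transmitters between interacting domains,
interface residues with high average traffic should show large binding
free-energy changes when mutated to alanine. The package fits, per complex,
an ordinary least-squares regression of ΔΔG (kcal/mol) on the traffic of
the mutated wild-type residues. Conventions:

* complexes with fewer than three mutations are removed first — two points
  always correlate perfectly, so such fits are meaningless;
* one model per complex, never pooled: pooling would answer a different
  question and let large complexes dominate;
* the predictor is the z-scored traffic (z-scored over all nodes of the
  structure), so slopes are in kcal/mol per traffic-SD and comparable
  across complexes;
* residues are mapped to nodes by exact chain + residue number (+ insertion
  code) match; an unmapped mutation is an error, not a silent drop;
* quality is reported as residual standard error, the overall F-test
  p-value, and the Pearson correlation between fitted and observed ΔΔG
  (for a single predictor this equals the absolute predictor–response
  correlation, which the tests verify).

## Synthetic structures and the Monte-Carlo oracle

All tests run on generated fixtures. `make_toy_structure()` renders a node
as a cluster of carbon atoms within 1 Å of its centre and places centres so
the contact graph at the default cutoff is *exactly* a requested topology
(path, ring, star, grid, or custom centres), verified by brute force before
the text is returned. Atom offsets use a deterministic golden-angle
arrangement rather than random jitter so the same spec always yields
byte-identical coordinates on every platform. For regression-recovery
studies the generator uses heterogeneous residue sizes (atoms per node
cycling 2, 3, 4, 1 on a lattice): a uniform lattice has symmetry classes
with exactly equal traffic, which can hand a synthetic complex a
zero-variance predictor — a degeneracy real proteins do not have.

What the toys emulate is contact topology and size-normalised weighting;
what they do not emulate is real protein geometry — secondary structure,
packing densities, ligand chemistry, crystallographic noise. Green tests
therefore certify the mathematics and the conventions, not agreement with
any particular crystal structure.

`random_walk_oracle()` simulates the absorbing walk directly: a visit is
counted on every arrival (the start's initial occupancy once, the absorbing
node once on entry), matching the visiting-frequency semantics of $F$. The
acceptance suite re-estimates entire EVT matrices by splitting a 200,000-walk
budget over all (initiation, absorbing) chains of random toy networks and
requires every entry of $M$ to agree within three standard errors; a
separate check confirms the estimator's error shrinks like
$1/\sqrt{n_\text{walks}}$.

## Problem sizes and numerical choices

The test suite works at $n \le 16$ nodes where everything has a closed form
or an affordable simulation; the full pipeline is dense linear algebra with
$n$ solves of an $(n-1)$-dimensional system, comfortably handling the
$n \approx 350$ nodes of a receptor chain in minutes on one core. Other
numerical decisions: contact counting aggregates a vectorised atom distance
matrix (the brute-force double loop remains in the tests as the oracle);
z-scoring refuses constant profiles rather than returning NaN; B-factor
annotation clips values to the fixed-width column range [−99.99, 999.99].

## Limitations

* The method scores the *importance* of sites for transmitting a
  perturbation; it does not predict the direction or magnitude of any
  conformational change.
* A single static structure is analysed; ensemble averaging and dynamics
  are out of scope (the long 8 Å default cutoff partially compensates by
  admitting long-range interactions).
* The affinity form $N_{ij}/\sqrt{N_iN_j}$ is adopted from the established
  size-normalised contact formulation; together with the deterministic
  altloc and hydrogen rules, small differences against other
  implementations' per-residue values are expected even at identical
  cutoffs.
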