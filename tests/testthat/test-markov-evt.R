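test_that("fundamental matrix matches hand-solved small systems", {
  tm <- transition_matrix(path_network(3))
  fm <- fundamental_matrix(tm, "C")
  expect_equal(unname(fm$F), matrix(c(2, 1, 2, 2), 2, 2), tolerance = 1e-12)
  expect_equal(fm$nodes, c("A", "B"))

  tm2 <- transition_matrix(edge_network(cbind(1, 2), 2))
  expect_equal(unname(fundamental_matrix(tm2, "B")$F),
               matrix(1, 1, 1), tolerance = 1e-12)
})

test_that("fundamental matrix equals its Neumann series and has sane visit counts", {
  for (seed in c(61, 62, 63)) {
    tm <- transition_matrix(build_network(random_toy_model(seed), 8))
    n <- length(tm$nodes)
    k <- ((seed * 7) %% n) + 1L
    fm <- fundamental_matrix(tm, k)
    Tk <- unname(tm$T[-k, -k, drop = FALSE])
    S <- diag(n - 1L)
    P <- diag(n - 1L)
    for (m in 1:200) { P <- P %*% Tk; S <- S + P }
    expect_equal(unname(fm$F), S, tolerance = 1e-6)
    expect_true(all(fm$F >= 0))
    expect_true(all(diag(fm$F) >= 1))      # a start node visits itself
    expect_true(all(rowSums(fm$F) >= 1))   # expected absorption times
  }
})

test_that("EVT matrix reproduces the hand-averaged extended fundamental matrices", {
  em <- evt_matrix(transition_matrix(path_network(3)))
  expect_equal(unname(em$M[1, ]), c(4, 3, 1) / 3, tolerance = 1e-12)
  expect_equal(unname(em$M[2, ]), c(2, 5, 2) / 3, tolerance = 1e-12)
})

test_that("every EVT entry is at least 1/n", {
  for (seed in c(71, 72, 73)) {
    em <- evt_matrix(transition_matrix(build_network(random_toy_model(seed))))
    n <- length(em$nodes)
    expect_true(all(em$M >= 1 / n - 1e-12))
    expect_true(all(is.finite(em$M)))
  }
})

test_that("z-scored profiles have mean 0, sd 1 under the population convention", {
  z <- zscore_profile(c(4, 3, 1) / 3)
  expect_equal(unname(z), c(1.0690450, 0.2672612, -1.3363062),
               tolerance = 1e-6)
  for (seed in 81:83) {
    set.seed(seed)
    x <- rnorm(sample(5:30, 1))
    z <- zscore_profile(x)
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  }
  # sample-sd variant and degenerate input
  expect_equal(sd(zscore_profile(rnorm(10), sd_type = "sample")), 1,
               tolerance = 1e-10)
  expect_error(zscore_profile(rep(2, 5)), "constant")
})

test_that("distance scaling multiplies by hop count and zeroes the initiation site", {
  net <- path_network(3)
  raw <- c(4, 3, 1) / 3
  sc <- scaled_profile(raw, "A", net)
  expect_equal(unname(sc), c(0, 1, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(scaled_profile(2 * raw, "A", net)), 2 * unname(sc))

  disc <- edge_network(rbind(c(1, 2), c(3, 4)), 4)
  expect_error(scaled_profile(rep(1, 4), "A", disc), "unreachable")
})

test_that("profile ratios compare matched node sets and flag mismatches", {
  em <- evt_matrix(transition_matrix(path_network(3)))
  pa <- evt_profile(em, "A")
  expect_equal(unname(profile_ratio(pa, pa)), rep(0, 3))
  doubled <- pa; doubled$raw <- 2 * pa$raw
  expect_equal(unname(profile_ratio(doubled, pa)), rep(1, 3))

  other <- setNames(c(1, 1, 1), c("A", "B", "X"))
  expect_error(profile_ratio(pa$raw, other), "unmatched node")
  pb <- pa; pb$initiation <- "B"
  expect_error(profile_ratio(pa, pb), "initiation")
})

test_that("average traffic peaks on bridges and is permutation-equivariant", {
  em <- evt_matrix(transition_matrix(path_network(3)))
  tr <- average_evt(em)
  expect_equal(unname(tr), c(7, 11, 7) / 3, tolerance = 1e-12)
  expect_equal(names(which.max(tr)), "B")

  # vertex-transitive ring: all traffic values equal
  ring <- edge_network(cbind(1:6, c(2:6, 1)), 6)
  trr <- average_evt(evt_matrix(transition_matrix(ring)))
  expect_equal(max(trr) - min(trr), 0, tolerance = 1e-12)

  # relabeling equivariance
  star <- edge_network(cbind(1L, 2:5), 5)
  M1 <- evt_matrix(transition_matrix(star))$M
  p <- c(3L, 5L, 1L, 2L, 4L)
  starp <- edge_network(
    cbind(match(1L, p), match(2:5, p)), 5,
    nodes = LETTERS[1:5])
  M2 <- evt_matrix(transition_matrix(starp))$M
  expect_equal(unname(M2[match(1:5, p), match(1:5, p)]), unname(M1),
               tolerance = 1e-12)
  expect_equal(unname(average_evt(evt_matrix(transition_matrix(starp)))[match(1:5, p)]),
               unname(average_evt(evt_matrix(transition_matrix(star)))),
               tolerance = 1e-12)
})

test_that("EVT matrix is invariant under ring automorphisms", {
  ring <- edge_network(cbind(1:6, c(2:6, 1)), 6)
  M <- unname(evt_matrix(transition_matrix(ring))$M)
  rot <- c(2:6, 1)  # rotation by one position
  expect_equal(M[rot, rot], M, tolerance = 1e-12)
  refl <- c(1, 6:2)  # reflection fixing node 1
  expect_equal(M[refl, refl], M, tolerance = 1e-12)
})

test_that("cutoff scan reports disconnected cutoffs and correlates connected ones", {
  m <- parse_structure(make_toy_structure("path", 3, atoms_per_node = 3))
  scan <- profile_correlation_scan(m, "A:1", c(6, 8, 10))
  expect_named(scan$failed, "6")
  expect_equal(dim(scan$correlations), c(2L, 2L))
  expect_equal(unname(diag(scan$correlations)), c(1, 1))
  expect_equal(scan$correlations, t(scan$correlations))
  # 8 and 10 A give the identical topology here, so identical profiles
  expect_equal(unname(scan$correlations["8", "10"]), 1, tolerance = 1e-12)
})

test_that("evt_analysis tabulates profile, z-scores, hops and scaled values", {
  m <- parse_structure(make_toy_structure("path", 4, atoms_per_node = 2))
  tab <- evt_analysis(m, "A:1", cutoff = 8)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$hop_distance, 0:3)
  expect_equal(tab$evt_scaled, tab$evt_raw * tab$hop_distance)
  expect_equal(mean(tab$evt_z), 0, tolerance = 1e-10)
  em <- evt_matrix(transition_matrix(build_network(m, 8)))
  expect_equal(tab$evt_raw, unname(em$M[1, ]))
})
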