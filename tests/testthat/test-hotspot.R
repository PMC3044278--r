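simple_nodes <- function(n) {
  data.frame(chain = "A", resnum = seq_len(n), icode = "",
             resname = "ALA",
             node_id = paste0("A:", seq_len(n), "::ALA"),
             stringsAsFactors = FALSE)
}

mut <- function(resnum, ddg, complex_id = "c1") {
  data.frame(complex_id = complex_id, chain = "A", resnum = resnum,
             icode = "", ddg_kcal_mol = ddg, stringsAsFactors = FALSE)
}

test_that("complexes with fewer than three mutations are filtered out", {
  recs <- rbind(mut(1:2, c(1, 2), "small"),
                mut(1:3, c(1, 2, 3), "exact3"),
                mut(1:5, 1:5, "big"))
  kept <- suppressMessages(filter_complexes(recs))
  expect_setequal(unique(kept$complex_id), c("exact3", "big"))
  expect_equal(attr(kept, "removed")$complex_id, "small")
  expect_equal(attr(kept, "removed")$n_mutations, 2L)

  empty <- filter_complexes(recs[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("a perfect linear relation is fit exactly", {
  res <- suppressWarnings(  # summary.lm flags the zero-residual fit
    fit_hotspot_model(traffic = c(1, 2, 3, 4, 5),
                      records = mut(1:3, c(2, 4, 6)),
                      nodes = simple_nodes(5), zscore = FALSE))
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$pearson_r, 1, tolerance = 1e-10)
  expect_equal(res$residual_se, 0, tolerance = 1e-10)
  expect_equal(res$n_mutations, 3L)
})

test_that("OLS on three hand-checked points gives slope 0.5, intercept 1, r 0.5", {
  res <- fit_hotspot_model(traffic = c(1, 2, 3),
                           records = mut(1:3, c(1, 3, 2)),
                           nodes = simple_nodes(3), zscore = FALSE)
  expect_equal(res$slope, 0.5, tolerance = 1e-12)
  expect_equal(res$intercept, 1.0, tolerance = 1e-12)
  expect_equal(res$pearson_r, 0.5, tolerance = 1e-12)
})

test_that("reported r equals |cor(predictor, response)| for simple regression", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    tr <- runif(30)
    rec <- mut(sample(30, n), rnorm(n))
    res <- fit_hotspot_model(tr, rec, simple_nodes(30), zscore = FALSE)
    expect_equal(res$pearson_r,
                 abs(cor(tr[rec$resnum], rec$ddg_kcal_mol)),
                 tolerance = 1e-10)
    expect_true(res$f_pvalue > 0 && res$f_pvalue <= 1)
  }
})

test_that("an orthogonal response gives slope 0 and F p-value 1", {
  res <- fit_hotspot_model(traffic = c(-1, 0, 1, 5),
                           records = mut(1:3, c(1, 2, 1)),
                           nodes = simple_nodes(4), zscore = FALSE)
  expect_equal(res$slope, 0, tolerance = 1e-12)
  expect_equal(res$f_pvalue, 1, tolerance = 1e-10)
})

test_that("degenerate designs and unmapped residues are explicit errors", {
  expect_error(fit_hotspot_model(rep(2, 5), mut(1:3, 1:3), simple_nodes(5),
                                 zscore = FALSE),
               "zero-variance")
  expect_error(fit_hotspot_model(1:5, mut(c(1, 2, 99), 1:3), simple_nodes(5),
                                 zscore = FALSE),
               "A:99")
  expect_error(fit_hotspot_model(1:5, mut(1:2, 1:2), simple_nodes(5)),
               "at least 3")
})

test_that("the regression recovers a planted slope on synthetic complexes", {
  m <- parse_structure(
    make_toy_structure("grid", 12, atoms_per_node = 1 + (seq_len(12) %% 4)))
  em <- evt_matrix(transition_matrix(build_network(m, 8)))
  traffic <- average_evt(em)
  recs <- simulate_hotspot_data(traffic, n_complexes = 60, beta = 1.5,
                                noise_sd = 0.3, mutations_range = c(5, 10),
                                n_undersized = 4, seed = 7)
  kept <- suppressMessages(filter_complexes(recs))
  expect_setequal(attr(kept, "removed")$complex_id, attr(recs, "undersized"))

  fits <- lapply(split(kept, kept$complex_id), function(r)
    fit_hotspot_model(traffic, r, m$nodes))
  slopes <- vapply(fits, `[[`, 0, "slope")
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 1.5), 2 * se)
})

test_that("hotspot_regressions runs the per-complex pipeline end to end", {
  m <- parse_structure(make_toy_structure("grid", 9, atoms_per_node = 3))
  traffic <- average_evt(evt_matrix(transition_matrix(build_network(m, 8))))
  recs <- simulate_hotspot_data(traffic, n_complexes = 3, beta = 2,
                                noise_sd = 0.1, mutations_range = c(5, 8),
                                seed = 11)
  res <- suppressMessages(
    hotspot_regressions(setNames(list(m, m, m), unique(recs$complex_id)),
                        recs))
  expect_equal(nrow(res), 3L)
  expect_true(all(res$slope > 0))
  expect_true(all(abs(res$pearson_r) <= 1))
  expect_true(all(res$f_pvalue > 0 & res$f_pvalue <= 1))
  muts <- attr(fit_hotspot_model(
    traffic, recs[recs$complex_id == recs$complex_id[1], ], m$nodes), "mutations")
  expect_true(all(c("evt", "fitted", "residual") %in% names(muts)))
})

test_that("read_ddg validates the table shape", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id\tpdb_id\tchain\tresnum\tddg_kcal_mol",
               "c1\t1ABC\tA\t10\t1.5",
               "c1\t1ABC\tA\t11\t0.2"), tf)
  rec <- read_ddg(tf)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$ddg_kcal_mol, c(1.5, 0.2))

  writeLines(c("complex_id\tchain\tresnum", "c1\tA\t10"), tf)
  expect_error(read_ddg(tf), "missing column")

  writeLines(c("complex_id\tpdb_id\tchain\tresnum\tddg_kcal_mol",
               "c1\t1ABC\tA\t10\t1.5",
               "c1\t1ABC\tA\t10\t0.2"), tf)
  expect_error(read_ddg(tf), "duplicate")
})
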