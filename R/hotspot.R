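#' Read an alanine-scanning ddG table
#'
#' Expects a TSV with header columns \code{complex_id}, \code{pdb_id},
#' \code{chain}, \code{resnum}, \code{ddg_kcal_mol} (an optional \code{icode}
#' column is honoured; it defaults to ""). One row per alanine mutation:
#' the change in binding free energy (kcal/mol) measured for that interface
#' residue.
#'
#' @param path TSV file path.
#' @return data frame of mutation records.
#' @export
read_ddg <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("complex_id", "chain", "resnum", "ddg_kcal_mol")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L)
    stop("ddG table is missing column(s): ", paste(miss, collapse = ", "))
  if (!("icode" %in% names(rec))) rec$icode <- ""
  rec$icode[is.na(rec$icode)] <- ""
  if (any(!is.finite(rec$ddg_kcal_mol)))
    stop("ddG values must be finite")
  key <- with(rec, paste(complex_id, chain, resnum, icode))
  if (anyDuplicated(key))
    stop("duplicate mutation record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rec
}

#' Drop complexes with too few mutations
#'
#' A linear fit on fewer than three points is meaningless (two points always
#' correlate perfectly), so complexes below the threshold are removed.
#'
#' @param records mutation-record data frame (see [read_ddg()]).
#' @param min_mutations minimum records per complex to retain, default 3.
#' @return the retained records; the removed complexes and their sizes are
#'   attached as attribute \code{"removed"}.
#' @export
filter_complexes <- function(records, min_mutations = 3) {
  if (nrow(records) == 0L) {
    attr(records, "removed") <- data.frame(complex_id = character(),
                                           n_mutations = integer())
    return(records)
  }
  sizes <- table(records$complex_id)
  drop <- names(sizes)[sizes < min_mutations]
  out <- records[!(records$complex_id %in% drop), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    complex_id = drop,
    n_mutations = as.integer(sizes[drop]),
    stringsAsFactors = FALSE)
  if (length(drop) > 0L)
    message("removed ", length(drop),
            " complex(es) with < ", min_mutations, " mutations: ",
            paste(drop, collapse = ", "))
  out
}

#' Regress ddG on average EVT traffic for one complex
#'
#' Ordinary least squares of the mutations' binding free-energy changes on
#' the average-EVT traffic of the mutated wild-type residues in the complex
#' structure. The predictor is z-scored over the whole structure by default
#' so slopes are comparable across complexes. Fit quality is reported as the
#' residual standard error, the overall F-test p-value, and the Pearson
#' correlation between fitted and observed ddG.
#'
#' @param traffic per-node average EVT (from [average_evt()]), in the order
#'   of \code{nodes}.
#' @param records this complex's mutation records (chain, resnum, optional
#'   icode, ddg_kcal_mol), at least 3 rows.
#' @param nodes node data frame of the complex's \code{structure_model}
#'   (needs chain, resnum, icode columns), aligned with \code{traffic}.
#' @param complex_id label for the result row; defaults to the records'
#'   common complex_id if present.
#' @param zscore z-score the traffic over all nodes before fitting (default
#'   TRUE).
#' @return a \code{regression_result}: one-row data frame with complex_id,
#'   n_mutations, slope, intercept, pearson_r, residual_se, f_pvalue; the
#'   per-mutation table (with fitted values) is attached as attribute
#'   \code{"mutations"}.
#' @export
fit_hotspot_model <- function(traffic, records, nodes, complex_id = NULL,
                              zscore = TRUE) {
  if (length(traffic) != nrow(nodes))
    stop("traffic must have one value per node")
  if (nrow(records) < 3L)
    stop("need at least 3 mutations to fit a regression; got ", nrow(records))
  if (is.null(complex_id))
    complex_id <- if ("complex_id" %in% names(records))
      as.character(records$complex_id[1L]) else "complex"
  if (!("icode" %in% names(records))) records$icode <- ""
  records$icode[is.na(records$icode)] <- ""

  node_key <- paste(nodes$chain, nodes$resnum, nodes$icode, sep = ":")
  rec_key <- paste(records$chain, records$resnum, records$icode, sep = ":")
  idx <- match(rec_key, node_key)
  if (any(is.na(idx)))
    stop("mutated residue(s) not found in the structure: ",
         paste(rec_key[is.na(idx)], collapse = ", "))

  x_all <- if (zscore) zscore_profile(traffic) else as.numeric(traffic)
  df <- data.frame(evt = x_all[idx], ddg = records$ddg_kcal_mol)
  if (stats::sd(df$evt) == 0)
    stop("zero-variance predictor: all mutated residues have the same traffic")

  fit <- stats::lm(ddg ~ evt, data = df)
  s <- summary(fit)
  fs <- s$fstatistic
  out <- data.frame(
    complex_id = complex_id,
    n_mutations = nrow(df),
    slope = unname(stats::coef(fit)["evt"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    pearson_r = if (stats::sd(stats::fitted(fit)) == 0) 0
      else stats::cor(stats::fitted(fit), df$ddg),
    residual_se = s$sigma,
    f_pvalue = unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("regression_result", class(out))
  mut <- cbind(records, evt = df$evt, fitted = stats::fitted(fit),
               residual = stats::resid(fit))
  rownames(mut) <- NULL
  attr(out, "mutations") <- mut
  out
}

#' Hot-spot regressions for a set of complexes
#'
#' Runs the full pipeline per complex: build the network of its structure at
#' the given cutoff, compute average EVT traffic, and regress the complex's
#' ddG values on it. Complexes with fewer than \code{min_mutations} records
#' are filtered out first.
#'
#' @param structures named list of \code{structure_model} objects keyed by
#'   complex_id.
#' @param records mutation-record data frame covering the complexes.
#' @param cutoff contact cutoff in Angstrom, default 8.
#' @param min_mutations passed to [filter_complexes()].
#' @return data frame with one \code{regression_result} row per fitted
#'   complex.
#' @export
hotspot_regressions <- function(structures, records, cutoff = 8,
                                min_mutations = 3) {
  records <- filter_complexes(records, min_mutations)
  ids <- unique(records$complex_id)
  miss <- setdiff(ids, names(structures))
  if (length(miss) > 0L)
    stop("no structure supplied for complex(es): ",
         paste(miss, collapse = ", "))
  rows <- lapply(ids, function(id) {
    model <- structures[[id]]
    em <- evt_matrix(transition_matrix(build_network(model, cutoff)))
    keep <- match(em$nodes, model$nodes$node_id)
    fit_hotspot_model(average_evt(em),
                      records[records$complex_id == id, , drop = FALSE],
                      model$nodes[keep, , drop = FALSE], complex_id = id)
  })
  do.call(rbind, rows)
}

#' Simulate alanine-scanning data with a known traffic effect
#'
#' Draws synthetic complexes whose ddG values follow the generating model
#' \code{ddg = beta * z(traffic) + Gaussian noise}, for parameter-recovery
#' checks of the hot-spot regression. A fraction of planted complexes get
#' fewer than 3 mutations so the size filter can be exercised.
#'
#' @param traffic named per-node traffic vector (names are node ids of the
#'   form chain:resnum:icode:resname) to sample mutated residues from.
#' @param n_complexes number of adequately sized complexes, default 500.
#' @param beta true slope on the z-scored traffic, default 1.
#' @param noise_sd Gaussian noise standard deviation in kcal/mol, default 0.5.
#' @param mutations_range inclusive range of mutations per complex, default
#'   c(5, 15).
#' @param n_undersized number of planted complexes with 1-2 mutations,
#'   default 0.
#' @param seed RNG seed (the caller's RNG state is not disturbed).
#' @return mutation-record data frame; the planted undersized complex ids are
#'   attached as attribute \code{"undersized"} and the true slope as
#'   \code{"beta"}.
#' @export
simulate_hotspot_data <- function(traffic, n_complexes = 500, beta = 1,
                                  noise_sd = 0.5, mutations_range = c(5, 15),
                                  n_undersized = 0, seed = 1) {
  stopifnot(!is.null(names(traffic)), length(traffic) >= max(mutations_range))
  z <- zscore_profile(traffic)
  parse_id <- function(ids) {
    p <- strsplit(ids, ":", fixed = TRUE)
    data.frame(chain = vapply(p, `[`, "", 1L),
               resnum = as.integer(vapply(p, `[`, "", 2L)),
               icode = vapply(p, `[`, "", 3L),
               stringsAsFactors = FALSE)
  }
  with_local_seed(seed, {
    sizes <- c(sample(mutations_range[1L]:mutations_range[2L],
                      n_complexes, replace = TRUE),
               sample(1:2, n_undersized, replace = TRUE))
    ids <- sprintf("cpx%04d", seq_along(sizes))
    recs <- lapply(seq_along(sizes), function(i) {
      pick <- sample(length(z), sizes[i])
      cbind(data.frame(complex_id = ids[i], pdb_id = "SYNTH",
                       stringsAsFactors = FALSE),
            parse_id(names(z)[pick]),
            data.frame(ddg_kcal_mol = beta * as.numeric(z[pick]) +
                         stats::rnorm(sizes[i], 0, noise_sd)))
    })
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "undersized") <-
      if (n_undersized > 0L) ids[n_complexes + seq_len(n_undersized)]
      else character()
    attr(out, "beta") <- beta
    out
  })
}
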