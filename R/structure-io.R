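#' Parse a PDB structure into residue/ligand nodes
#'
#' Reads PDB-format coordinates and reduces them to the node set of a protein
#' structure network: one node per residue, plus (optionally) one node per
#' bound hetero-group. Hydrogens (and deuteriums) and water molecules are
#' removed, alternate locations are resolved to a single copy, and only the
#' first MODEL of multi-model files is used. Heavy-atom counts per node are
#' retained because the affinity weighting normalises contact counts by them.
#'
#' A \code{merge_map} collapses a covalently attached hetero-group into its
#' host residue (for example a retinal conjugated to a lysine, or a flavin
#' bonded to a cysteine), producing a single node whose heavy atoms are the
#' union of both groups.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param chains character vector of chain ids to keep; \code{NULL} keeps all.
#' @param ligand_policy \code{"include"} keeps each non-water hetero-group as
#'   its own node (the default; a ligand can then serve as a signal initiation
#'   site), \code{"exclude"} drops them.
#' @param merge_map named character vector applied before the ligand policy:
#'   each name selects hetero-group(s) by residue name (e.g. \code{"RET"}) or
#'   by \code{"CHAIN:RESNUM"}, and its value names the target residue as
#'   \code{"CHAIN:RESNUM"}. Selected groups are merged into the target node.
#' @param source_id label stored on the returned model.
#' @return A \code{structure_model}: list with \code{nodes} (data frame with
#'   columns chain, resnum, icode, resname, heavy_count, is_ligand, node_id),
#'   \code{atoms} (per-atom table with a \code{node} index), \code{coords}
#'   (list of per-node heavy-atom coordinate matrices), \code{source_id} and
#'   \code{merges}.
#' @export
parse_structure <- function(pdb, chains = NULL,
                            ligand_policy = c("include", "exclude"),
                            merge_map = NULL, source_id = NULL) {
  ligand_policy <- match.arg(ligand_policy)
  lines <- pdb_lines(pdb)
  if (is.null(source_id)) source_id <- attr(lines, "source_id") %||% "structure"

  # static single-structure method: first MODEL only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L] - 1L)]

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  a <- bio3d::read.pdb(tf, rm.alt = FALSE, verbose = FALSE)$atom

  for (col in c("chain", "insert", "alt", "elesy", "elety", "resid"))
    a[[col]][is.na(a[[col]])] <- ""
  if (!is.null(chains)) a <- a[a$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no nodes: no ATOM/HETATM records in the selected chains")

  a <- a[!(toupper(a$resid) %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (nrow(a) == 0L) stop("no nodes: only water records present")

  res_key_all <- with(a, paste(chain, resno, insert, resid, sep = "\r"))
  heavy <- !is_hydrogen(a$elety, a$elesy)
  dropped <- setdiff(res_key_all, res_key_all[heavy])
  if (length(dropped) > 0L)
    warning("dropped node(s) with zero heavy atoms: ",
            paste(gsub("\r", " ", dropped), collapse = ", "))
  a <- a[heavy, , drop = FALSE]
  if (nrow(a) == 0L) stop("no nodes: no heavy atoms left after filtering")

  # altloc resolution: one copy per atom name, highest occupancy wins,
  # ties broken by altloc code order
  occ <- a$o
  occ[is.na(occ)] <- 1
  akey <- with(a, paste(chain, resno, insert, resid, elety, sep = "\r"))
  ord <- order(akey, -occ, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(akey[ord]), , drop = FALSE]
  a <- a[order(a$eleno), , drop = FALSE]

  a$is_het <- a$type == "HETATM"
  a$res_key <- with(a, paste(chain, resno, insert, resid, sep = "\r"))

  # residue-level table
  first <- !duplicated(a$res_key)
  res <- data.frame(
    key     = a$res_key[first],
    chain   = a$chain[first],
    resnum  = a$resno[first],
    icode   = a$insert[first],
    resname = a$resid[first],
    stringsAsFactors = FALSE
  )
  res$is_ligand <- vapply(split(a$is_het, a$res_key), all,
                          logical(1))[res$key]

  merges <- data.frame(merged = character(), into = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(merge_map) && length(merge_map) > 0L) {
    if (is.null(names(merge_map)) || any(names(merge_map) == ""))
      stop("merge_map must be a named character vector")
    for (sel in names(merge_map)) {
      tgt <- merge_map[[sel]]
      src <- select_het_group(res, sel)
      if (length(src) == 0L)
        stop("merge_map: no hetero-group matches '", sel, "'")
      tgt_parts <- strsplit(tgt, ":", fixed = TRUE)[[1L]]
      if (length(tgt_parts) < 2L)
        stop("merge_map target must be 'CHAIN:RESNUM': ", tgt)
      ti <- which(res$chain == tgt_parts[1L] &
                    res$resnum == as.integer(tgt_parts[2L]) &
                    res$icode == (if (length(tgt_parts) >= 3L) tgt_parts[3L] else "") &
                    !res$is_ligand)
      if (length(ti) != 1L)
        stop("merge_map: target residue ", tgt, " not found in structure")
      for (si in src) {
        a$res_key[a$res_key == res$key[si]] <- res$key[ti]
        merges <- rbind(merges, data.frame(
          merged = gsub("\r", ":", res$key[si]),
          into   = gsub("\r", ":", res$key[ti]),
          stringsAsFactors = FALSE))
      }
      res <- res[-src, , drop = FALSE]
    }
  }

  if (ligand_policy == "exclude") {
    keep <- !res$is_ligand
    a <- a[a$res_key %in% res$key[keep], , drop = FALSE]
    res <- res[keep, , drop = FALSE]
    if (nrow(res) == 0L) stop("no nodes: all nodes were hetero-groups")
  }

  # deterministic ordering: polymer residues by (chain, resnum, icode),
  # unmerged ligands last
  o <- order(res$is_ligand, res$chain, res$resnum, res$icode)
  res <- res[o, , drop = FALSE]
  res$node_id <- node_id_string(res$chain, res$resnum, res$icode, res$resname)
  if (anyDuplicated(res$node_id))
    stop("duplicate node ids in structure: ",
         paste(res$node_id[duplicated(res$node_id)], collapse = ", "))
  a$node <- match(a$res_key, res$key)
  res$heavy_count <- as.integer(tabulate(a$node, nbins = nrow(res)))
  stopifnot(all(res$heavy_count >= 1L))
  if (nrow(res) < 2L)
    stop("a structure network needs at least 2 nodes; found ", nrow(res))

  coords <- lapply(seq_len(nrow(res)), function(i) {
    m <- as.matrix(a[a$node == i, c("x", "y", "z"), drop = FALSE])
    dimnames(m) <- NULL
    m
  })

  rownames(res) <- NULL
  structure(list(
    nodes = res[, c("chain", "resnum", "icode", "resname",
                    "heavy_count", "is_ligand", "node_id")],
    atoms = a[, c("type", "eleno", "elety", "resid", "chain", "resno",
                  "insert", "x", "y", "z", "node")],
    coords = coords,
    source_id = source_id,
    merges = merges
  ), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", x$source_id, "': ", nrow(x$nodes), " nodes (",
      sum(x$nodes$is_ligand), " ligand), ",
      sum(x$nodes$heavy_count), " heavy atoms\n", sep = "")
  if (nrow(x$merges) > 0L)
    cat("  merged:", paste(x$merges$merged, "->", x$merges$into,
                           collapse = "; "), "\n")
  invisible(x)
}

#' Write per-node values into the B-factor column of a PDB file
#'
#' Produces a copy of the input PDB text in which every atom of every node
#' carries its node's value in the B-factor column (fixed columns 61-66),
#' the standard trick for colouring structures by a per-residue score in a
#' molecular viewer. Atoms that belong to no node (waters, unselected chains)
#' are left untouched; atom order is preserved.
#'
#' @param model a \code{structure_model} from [parse_structure()].
#' @param values numeric vector, one finite value per node (model order).
#' @param pdb the original PDB file or text the model was parsed from.
#' @param file optional path; when given the text is also written there.
#' @return character vector of PDB lines, invisibly when \code{file} is set.
#' @export
write_annotated_pdb <- function(model, values, pdb, file = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (length(values) != nrow(model$nodes))
    stop("need one value per node: got ", length(values),
         " values for ", nrow(model$nodes), " nodes")
  if (any(!is.finite(values)))
    stop("values must be finite (no NA/NaN/Inf)")
  lines <- pdb_lines(pdb)

  # residue-key -> node lookup (covers merged hetero-groups and hydrogens)
  lut <- unique(model$atoms[, c("chain", "resno", "insert", "node")])
  lut_key <- with(lut, paste(chain, resno, insert, sep = "\r"))

  rec <- grepl("^(ATOM  |HETATM)", lines)
  out <- lines
  v <- pmin(pmax(values, -99.99), 999.99)  # column is %6.2f
  for (i in which(rec)) {
    ln <- out[i]
    if (nchar(ln) < 66L)
      ln <- formatC(ln, width = -66L)  # pad right to B-factor column
    ch <- trimws(substr(ln, 22L, 22L))
    rn <- suppressWarnings(as.integer(trimws(substr(ln, 23L, 26L))))
    ic <- trimws(substr(ln, 27L, 27L))
    j <- match(paste(ch, rn, ic, sep = "\r"), lut_key)
    if (!is.na(j)) {
      substr(ln, 61L, 66L) <- sprintf("%6.2f", v[lut$node[j]])
      out[i] <- ln
    }
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Per-node summary table of a structure model
#'
#' @param model a \code{structure_model}.
#' @param file optional path to write the table as TSV.
#' @return data frame with chain, resnum, icode, resname, heavy_count,
#'   is_ligand.
#' @export
node_table <- function(model, file = NULL) {
  stopifnot(inherits(model, "structure_model"))
  tab <- model$nodes[, c("chain", "resnum", "icode", "resname",
                         "heavy_count", "is_ligand")]
  if (!is.null(file))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}

# -- internal helpers ---------------------------------------------------------

pdb_lines <- function(pdb) {
  if (is.character(pdb) && length(pdb) == 1L && !grepl("\n", pdb) &&
      file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    attr(lines, "source_id") <- sub("\\.(pdb|ent)$", "", basename(pdb))
    return(lines)
  }
  if (!is.character(pdb)) stop("pdb must be a file path or PDB-format text")
  if (length(pdb) == 1L) pdb <- strsplit(pdb, "\n", fixed = TRUE)[[1L]]
  pdb
}

# element in {H, D}, inferred from the element column with an atom-name
# fallback (leading digits stripped, first letter H or D)
is_hydrogen <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  name_h <- grepl("^[HD]", sub("^[0-9]+", "", toupper(trimws(elety))))
  ifelse(el != "", el %in% c("H", "D"), name_h)
}

select_het_group <- function(res, sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) {
    which(res$is_ligand & res$resname == parts[1L])
  } else {
    which(res$is_ligand & res$chain == parts[1L] &
            res$resnum == as.integer(parts[2L]))
  }
}
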