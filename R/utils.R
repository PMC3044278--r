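`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a node specification to a node index
#'
#' Node ids in this package are strings of the form
#' \code{"chain:resnum:icode:resname"} (toy graphs may use bare labels such as
#' \code{"A"}). A node can be selected by integer index, by exact id, or by a
#' prefix of colon-separated fields, e.g. \code{"A:296"} or \code{"A:296::LYS"}.
#'
#' @param nodes character vector of node ids.
#' @param spec integer index, exact node id, or colon-separated prefix.
#' @return integer index into \code{nodes}.
#' @export
match_node <- function(nodes, spec) {
  if (is.numeric(spec)) {
    i <- as.integer(spec)
    if (length(i) != 1L || is.na(i) || i < 1L || i > length(nodes))
      stop("node index out of range: ", spec)
    return(i)
  }
  spec <- as.character(spec)
  hit <- which(nodes == spec)
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L) stop("ambiguous node id: ", spec)
  want <- strsplit(spec, ":", fixed = TRUE)[[1L]]
  parts <- strsplit(nodes, ":", fixed = TRUE)
  hit <- which(vapply(parts, function(p) {
    length(p) >= length(want) && all(p[seq_along(want)] == want)
  }, logical(1)))
  if (length(hit) == 0L)
    stop("node not found: '", spec, "'")
  if (length(hit) > 1L)
    stop("node spec '", spec, "' matches several nodes: ",
         paste(nodes[hit], collapse = ", "))
  hit
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

node_id_string <- function(chain, resnum, icode, resname) {
  paste(chain, resnum, icode, resname, sep = ":")
}
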