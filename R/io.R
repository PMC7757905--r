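#' Read a hypergraph from a text file
#'
#' One hyperedge per line, whitespace-separated node tokens (hMETIS-like
#' dialect). Lines starting with `#` or `%` are comments (covers SNAP and
#' Matrix-Market style headers). An optional leading header line with exactly
#' two integer tokens equal to the node and hyperedge counts of the remaining
#' lines is tolerated and ignored.
#'
#' @param path path to the file
#' @return a [hypergraph()] with edges in file order
#' @export
read_hypergraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*([#%]|$)", lines)
  lineno <- which(keep)
  toks <- lapply(lines[keep], function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (length(toks) == 0L) return(hypergraph(list()))
  # header detection: "n m" matching the counts implied by the body
  if (length(toks[[1]]) == 2L &&
      !anyNA(suppressWarnings(as.integer(toks[[1]])))) {
    body <- toks[-1]
    hdr <- as.integer(toks[[1]])
    n_body <- length(unique(unlist(body, use.names = FALSE)))
    if (hdr[1] == n_body && hdr[2] == length(body)) {
      toks <- body
      lineno <- lineno[-1]
    }
  }
  for (i in seq_along(toks)) {
    if (length(unique(toks[[i]])) < 2L) {
      stop("line ", lineno[i], ": hyperedge needs >= 2 distinct nodes, got '",
           paste(toks[[i]], collapse = " "), "'")
    }
    if (anyDuplicated(toks[[i]])) {
      stop("line ", lineno[i], ": repeated node in hyperedge '",
           paste(toks[[i]], collapse = " "), "'")
    }
  }
  hypergraph(toks)
}

#' Write a hypergraph to a text file
#'
#' One hyperedge per line using the external node labels; reading the file
#' back yields the same hypergraph up to node relabeling.
#'
#' @param H a [hypergraph()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_hypergraph <- function(H, path) {
  stopifnot(inherits(H, "hypergraph"))
  writeLines(vapply(hg_edges(H), paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Read a graph from a whitespace-separated edge list
#'
#' Each non-comment line is `u v` or `u v w` (w a non-negative edge weight).
#' Directedness is supplied by the caller, not the file. Comment prefixes
#' `#` and `%` are accepted.
#'
#' @param path path to the file
#' @param directed logical; interpret the pairs as directed arcs
#' @return an [igraph::igraph] graph with vertex names; weighted when any
#'   line carries a third token
#' @export
read_edgelist <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*([#%]|$)", lines)]
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  if (length(toks) == 0L) {
    return(igraph::make_empty_graph(0, directed = directed))
  }
  nt <- lengths(toks)
  if (any(nt < 2L | nt > 3L)) {
    stop("edge list lines must have 2 or 3 tokens")
  }
  el <- t(vapply(toks, function(x) x[1:2], character(2)))
  G <- igraph::graph_from_edgelist(el, directed = directed)
  if (any(nt == 3L)) {
    w <- vapply(toks, function(x) if (length(x) == 3L) as.numeric(x[3]) else 1, numeric(1))
    if (any(w < 0)) stop("edge weights must be non-negative")
    igraph::E(G)$weight <- w
  }
  G
}

#' Read / write ground-truth communities
#'
#' One community per line, whitespace-separated node labels (the SNAP
#' `com-*` dialect). Comment prefixes `#` and `%` are accepted.
#'
#' @param path path to the file
#' @return for `read_communities`, a list of character vectors
#' @export
read_communities <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*([#%]|$)", lines)]
  lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
}

#' @rdname read_communities
#' @param communities list of node-label vectors
#' @export
write_communities <- function(communities, path) {
  writeLines(vapply(communities, paste, character(1), collapse = " "), path)
  invisible(path)
}
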