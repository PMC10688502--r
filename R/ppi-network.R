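#' Construct a PPI network from an edge table
#'
#' Builds the undirected protein-protein interaction graph that all other
#' components operate on. Self-loops and duplicate interactions (in either
#' orientation) are dropped, with the number of dropped records reported as
#' a message. Nodes are the endpoints of the surviving edges.
#'
#' @param edges two-column character data frame or matrix of interacting
#'   protein IDs; extra columns are ignored.
#' @return An object of class `ppi_network`: a list with `nodes` (sorted
#'   character vector), `edges` (two-column character matrix, one row per
#'   undirected edge with the lexicographically smaller ID first) and
#'   `adjacency` (named list mapping each node to its sorted neighbor set).
#' @examples
#' net <- ppi_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3")))
#' net$adjacency[["p2"]]
#' @export
ppi_network <- function(edges) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    stop("`edges` must have at least two columns of protein IDs")
  u <- as.character(edges[[1L]])
  v <- as.character(edges[[2L]])
  n_in <- length(u)
  if (n_in == 0L) stop("empty input: no interactions supplied")
  g <- igraph::graph_from_data_frame(data.frame(u = u, v = v), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0L)
    stop("empty input: no interactions left after dropping self-loops and duplicates")
  a <- pmin(el[, 1L], el[, 2L])
  b <- pmax(el[, 1L], el[, 2L])
  ord <- order_ids(a, b)
  a <- a[ord]
  b <- b[ord]
  dropped <- n_in - length(a)
  if (dropped > 0L)
    message(sprintf("ppi_network: dropped %d self-loop/duplicate record(s)", dropped))
  nodes <- sort_ids(unique(c(a, b)))
  adj <- split(c(b, a), factor(c(a, b), levels = nodes))
  adj <- lapply(adj, sort_ids)
  structure(
    list(nodes = nodes,
         edges = cbind(protein1 = a, protein2 = b),
         adjacency = adj),
    class = "ppi_network"
  )
}

#' Read a PPI network from an edge-list file
#'
#' The file is whitespace- or tab-delimited with at least two columns per
#' line; lines starting with `#` and blank lines are ignored. Cleaning
#' (self-loop and duplicate removal) follows [ppi_network()].
#'
#' @param path path to the edge-list file.
#' @return A [ppi_network()] object.
#' @export
read_ppi <- function(path) {
  if (!file.exists(path)) stop("cannot read PPI file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty input: no interaction records in ", path)
  fields <- strsplit(lines, "[ \t]+")
  short <- vapply(fields, length, integer(1L)) < 2L
  if (any(short))
    stop(sprintf("malformed PPI file %s: %d line(s) with fewer than 2 columns",
                 path, sum(short)))
  ppi_network(data.frame(
    u = vapply(fields, `[[`, character(1L), 1L),
    v = vapply(fields, `[[`, character(1L), 2L),
    stringsAsFactors = FALSE
  ))
}

#' Write a PPI network as a two-column edge list
#'
#' @param net a [ppi_network()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppi <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Convert a PPI network to an igraph object
#'
#' @param net a [ppi_network()] object.
#' @return An undirected [igraph::igraph] graph with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(as.data.frame(net$edges), directed = FALSE,
                                vertices = net$nodes)
}

#' Read an ID mapping table
#'
#' Two-column TSV mapping source IDs to target IDs (many-to-one allowed).
#' Duplicate source IDs keep their first mapping, with a warning.
#'
#' @param path path to the mapping file.
#' @return Named character vector: `names()` are source IDs, values targets.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("cannot read mapping file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("mapping file must have two columns")
  src <- tab[[1L]]
  dup <- duplicated(src)
  if (any(dup)) {
    warning(sprintf("mapping: %d duplicate source ID(s); first mapping kept",
                    sum(dup)))
    tab <- tab[!dup, , drop = FALSE]
    src <- src[!dup]
  }
  stats::setNames(tab[[2L]], src)
}

# Translate an ID vector through a mapping, keeping unmapped IDs verbatim.
map_ids <- function(ids, mapping) {
  out <- unname(mapping[ids])
  miss <- is.na(out)
  out[miss] <- ids[miss]
  attr(out, "n_unmapped") <- sum(miss)
  out
}

#' Apply an ID mapping to a data object
#'
#' Translates protein/gene IDs through a source-to-target mapping table.
#' IDs absent from the table are kept unchanged (the count is reported via
#' a message). Objects are re-validated after translation, so e.g. an edge
#' collapsed onto a single protein becomes a self-loop and is dropped.
#'
#' @param x a [ppi_network()], [annotation_bundle()], [raw_expression()]
#'   object or a character vector of IDs.
#' @param mapping named character vector as returned by [read_mapping()].
#' @return An object of the same type as `x` with translated IDs.
#' @export
apply_mapping <- function(x, mapping) UseMethod("apply_mapping")

#' @export
apply_mapping.character <- function(x, mapping) {
  out <- map_ids(x, mapping)
  n <- attr(out, "n_unmapped")
  if (n > 0L) message(sprintf("apply_mapping: %d ID(s) not in mapping, kept verbatim", n))
  attr(out, "n_unmapped") <- NULL
  out
}

#' @export
apply_mapping.ppi_network <- function(x, mapping) {
  u <- map_ids(x$edges[, 1L], mapping)
  v <- map_ids(x$edges[, 2L], mapping)
  n <- attr(u, "n_unmapped") + attr(v, "n_unmapped")
  if (n > 0L) message(sprintf("apply_mapping: %d endpoint(s) not in mapping, kept verbatim", n))
  ppi_network(data.frame(u = as.character(u), v = as.character(v)))
}

#' @export
apply_mapping.annotation_bundle <- function(x, mapping) {
  remap_setlist <- function(sl) {
    if (!length(sl)) return(sl)
    new_names <- map_ids(names(sl), mapping)
    out <- tapply(sl, factor(new_names, levels = sort_ids(unique(new_names))),
                  function(parts) sort_ids(unique(unlist(parts))),
                  simplify = FALSE)
    lapply(out, identity)
  }
  annotation_bundle(
    go_terms = remap_setlist(x$go_terms),
    complexes = lapply(x$complexes, function(m) unique(as.character(map_ids(m, mapping)))),
    subcellular = remap_setlist(x$subcellular),
    essentials = sort_ids(unique(as.character(map_ids(x$essentials, mapping))))
  )
}

#' @export
apply_mapping.raw_expression <- function(x, mapping) {
  new_ids <- as.character(map_ids(rownames(x$values), mapping))
  raw_expression(collapse_duplicate_rows(x$values, new_ids), x$plan)
}
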