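#' Protein-protein interaction network objects
#'
#' A `ppi_network` is a simple undirected graph over protein identifiers:
#' no self-loops, no duplicate edges, every edge endpoint present in the
#' node set. Identifiers are opaque case-sensitive strings; symbol mapping
#' is upstream curation and deliberately out of scope.
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the identifiers appearing in `edges`. Extra entries become isolated
#'   nodes.
#' @return An object of class `ppi_network` with components `nodes` (sorted
#'   character vector) and `edges` (two-column character matrix, each row
#'   sorted within and rows sorted lexicographically). Attributes
#'   `n_loops_dropped` and `n_duplicates_dropped` record cleaning actions.
#' @examples
#' net <- ppi_network(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
#' net$edges      # one edge: A-B
#' @export
ppi_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (!is.matrix(edges) || ncol(edges) < 2L)
    stop("`edges` must have two columns")
  edges <- matrix(as.character(edges[, 1:2, drop = FALSE]), ncol = 2L)
  if (anyNA(edges) || any(!nzchar(edges)))
    stop("edge endpoints must be non-missing, non-empty identifiers")

  loops <- edges[, 1L] == edges[, 2L]
  n_loops <- sum(loops)
  edges <- edges[!loops, , drop = FALSE]
  # canonical within-row order so {A,B} == {B,A}
  swap <- edges[, 1L] > edges[, 2L]
  if (any(swap)) edges[swap, ] <- edges[swap, 2:1]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  all_nodes <- sort(unique(c(as.character(nodes), as.vector(edges))))
  if (!is.null(nodes) && !all(as.vector(edges) %in% nodes))
    stop("edges reference identifiers missing from `nodes`")
  structure(
    list(nodes = all_nodes, edges = edges),
    n_loops_dropped = n_loops,
    n_duplicates_dropped = n_dup,
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

# integer edge endpoints (1-based indices into net$nodes)
edge_index <- function(net) {
  cbind(match(net$edges[, 1L], net$nodes),
        match(net$edges[, 2L], net$nodes))
}

# adjacency list of integer neighbour indices
adjacency_list <- function(net) {
  n <- n_nodes(net)
  ei <- edge_index(net)
  adj <- vector("list", n)
  if (nrow(ei)) {
    spl1 <- split(ei[, 2L], factor(ei[, 1L], levels = seq_len(n)))
    spl2 <- split(ei[, 1L], factor(ei[, 2L], levels = seq_len(n)))
    adj <- Map(c, spl1, spl2)
  } else {
    adj <- rep(list(integer(0)), n)
  }
  adj
}

#' Read a protein interaction network from a file
#'
#' Supports whitespace/tab-delimited edge lists (first two columns are the
#' endpoints, extra columns ignored) and Cytoscape SIF
#' (`A relation B [C ...]`, expanding to pairwise edges from `A`). Lines
#' starting with `#` are ignored; a single-token line declares an isolated
#' node in either dialect, so round-trips through [write_network()]
#' preserve the node set. Duplicate edges are collapsed and self-loops
#' dropped; both are counted on the returned object.
#'
#' @param path file path.
#' @param format `"auto"` (by file extension: `.sif` means SIF, anything
#'   else edge list), `"edgelist"` or `"sif"`.
#' @param header logical; skip the first non-comment line.
#' @return A [ppi_network].
#' @export
read_network <- function(path, format = c("auto", "edgelist", "sif"),
                         header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edgelist"
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines)) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  if (!length(lines)) stop("empty network file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  pairs <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) == 1L) {
      # single-token line: an isolated node (how write_network round-trips
      # nodes without interactions)
      pairs[[i]] <- matrix(character(0), ncol = 2L)
      attr(pairs[[i]], "node") <- tk[1L]
    } else if (format == "edgelist") {
      pairs[[i]] <- cbind(tk[1L], tk[2L])
    } else {
      if (length(tk) < 3L) {
        stop("malformed SIF line ", line_no[i], ": expected >= 3 fields")
      } else {
        pairs[[i]] <- cbind(tk[1L], tk[-(1:2)])
      }
    }
  }
  iso <- unlist(lapply(pairs, attr, "node"))
  edges <- do.call(rbind, pairs)
  if ((is.null(edges) || nrow(edges) == 0L) && is.null(iso))
    stop("empty network file: ", path)
  ppi_network(edges, nodes = unique(c(iso, as.vector(edges))))
}

#' Write a network as a canonical edge list
#'
#' Two-column tab-delimited file, each pair sorted within and rows sorted
#' lexicographically, so write-read round-trips are identity on node and
#' edge sets (isolated nodes are emitted as single-token lines).
#'
#' @param net a [ppi_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  lines <- paste(net$edges[, 1L], net$edges[, 2L], sep = "\t")
  iso <- setdiff(net$nodes, as.vector(net$edges))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Connected components of a network
#'
#' @param net a [ppi_network].
#' @param method `"bfs"` (breadth-first labelling) or `"unionfind"`
#'   (disjoint-set forest); both produce the same partition and exist as
#'   mutual cross-checks.
#' @return Integer vector of component labels named by node, labels
#'   renumbered so that component 1 is the largest (ties by
#'   lexicographically smallest member node).
#' @export
network_components <- function(net, method = c("bfs", "unionfind")) {
  method <- match.arg(method)
  n <- n_nodes(net)
  if (n == 0L) return(setNames(integer(0), character(0)))
  comp <- integer(n)
  if (method == "bfs") {
    adj <- adjacency_list(net)
    cur <- 0L
    for (s in seq_len(n)) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        nb <- adj[[v]]
        new <- nb[comp[nb] == 0L]
        comp[new] <- cur
        queue <- c(queue, new)
      }
    }
  } else {
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    ei <- edge_index(net)
    for (e in seq_len(nrow(ei))) {
      ra <- find(ei[e, 1L]); rb <- find(ei[e, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(n), find, integer(1))
    comp <- match(roots, unique(roots))
  }
  # deterministic renumbering: size desc, then smallest member node
  sizes <- tabulate(comp)
  first_member <- net$nodes[match(seq_along(sizes), comp)]
  ord <- order(-sizes, first_member)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  setNames(relabel[comp], net$nodes)
}

#' Extract the giant (largest connected) component
#'
#' Ties on component size are broken toward the component containing the
#' lexicographically smallest node, so pipelines are reproducible.
#'
#' @param net a non-empty [ppi_network].
#' @return The induced [ppi_network] on the largest component.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (n_nodes(net) == 0L) stop("empty network")
  comp <- network_components(net)
  keep <- names(comp)[comp == 1L]
  induced_subnetwork(net, keep)
}

#' Induced subnetwork on a node subset
#'
#' @param net a [ppi_network].
#' @param nodes character vector of node identifiers to keep.
#' @return The induced [ppi_network].
#' @export
induced_subnetwork <- function(net, nodes) {
  stopifnot(inherits(net, "ppi_network"))
  nodes <- unique(as.character(nodes))
  missing <- setdiff(nodes, net$nodes)
  if (length(missing))
    stop("nodes not in network: ", paste(head(missing, 5L), collapse = ", "))
  keep <- net$edges[, 1L] %in% nodes & net$edges[, 2L] %in% nodes
  ppi_network(net$edges[keep, , drop = FALSE], nodes = nodes)
}

#' Summary counts for a network
#'
#' Mean degree is `2 * n_edges / n_nodes` (reported as 0 for an empty
#' graph).
#'
#' @param net a [ppi_network].
#' @return A one-row data frame: `n_nodes`, `n_edges`, `mean_degree`,
#'   `n_components`, `giant_size`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_nodes(net); m <- n_edges(net)
  comp <- network_components(net)
  data.frame(
    n_nodes = n,
    n_edges = m,
    mean_degree = if (n > 0L) 2 * m / n else 0,
    n_components = if (n > 0L) max(comp) else 0L,
    giant_size = if (n > 0L) sum(comp == 1L) else 0L
  )
}
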