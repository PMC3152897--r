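#' Node degrees
#'
#' @param net a [ppi_network].
#' @return Named integer vector, one entry per node; degrees sum to twice
#'   the edge count.
#' @export
degree_all <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_nodes(net)
  ei <- edge_index(net)
  setNames(tabulate(c(ei[, 1L], ei[, 2L]), nbins = n), net$nodes)
}

#' Node traffic (betweenness centrality)
#'
#' Traffic of a node v is the sum over unordered node pairs (s, t), s and t
#' both distinct from v, of the fraction of shortest s-t paths passing
#' through v (Brandes accumulation). Unweighted, undirected, endpoints
#' excluded, unnormalized; pairs in different components contribute
#' nothing. High-traffic nodes are the network's "bottlenecks".
#'
#' @param net a [ppi_network].
#' @return Named numeric vector of traffic values; isolated and degree-1
#'   nodes have traffic 0.
#' @export
traffic_all <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_nodes(net)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  ei <- edge_index(net)
  bc <- .brandes_betweenness(n, as.integer(ei[, 1L]) - 1L,
                             as.integer(ei[, 2L]) - 1L)
  setNames(bc, net$nodes)
}

#' Per-node topology table
#'
#' Combines degree and traffic and assigns a deterministic 1-based traffic
#' rank: traffic descending, ties broken by degree descending, then by
#' identifier ascending.
#'
#' @param net a [ppi_network].
#' @return Data frame with columns `protein`, `degree`, `traffic`,
#'   `traffic_rank`, sorted by rank.
#' @export
node_topology <- function(net) {
  deg <- degree_all(net)
  tr <- traffic_all(net)
  ord <- order(-tr, -deg, names(tr))
  out <- data.frame(
    protein = names(tr)[ord],
    degree = unname(deg[ord]),
    traffic = unname(tr[ord]),
    traffic_rank = seq_along(tr),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out
}

#' Top-k high-traffic bottlenecks
#'
#' @param table a topology table from [node_topology()].
#' @param k number of nodes to return (`k > n` returns all with a warning).
#' @return The first `k` rows of the ranked table.
#' @export
rank_bottlenecks <- function(table, k = 10L) {
  stopifnot(is.data.frame(table),
            all(c("protein", "degree", "traffic") %in% names(table)))
  if (k < 1L) stop("`k` must be >= 1")
  tb <- table[order(-table$traffic, -table$degree, table$protein), , drop = FALSE]
  tb$traffic_rank <- seq_len(nrow(tb))
  if (k > nrow(tb)) {
    warning("k = ", k, " exceeds the ", nrow(tb), " available nodes; returning all")
    k <- nrow(tb)
  }
  out <- tb[seq_len(k), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Degree-traffic Spearman correlation
#'
#' Spearman rank correlation between node degree and traffic, with average
#' ranks for ties. The p-value comes from a label-permutation null by
#' default, using the add-one estimator
#' `p = (1 + #\{|rho_perm| >= |rho_obs|\}) / (1 + n_perm)` so p is never 0;
#' an asymptotic t-approximation is also available.
#'
#' @param table topology table from [node_topology()] (or any data frame
#'   with `degree` and `traffic` columns; >= 3 rows).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation null.
#' @param method `"permutation"` or `"asymptotic"`.
#' @return List with elements `rho` and `p`.
#' @export
degree_traffic_spearman <- function(table, n_perm = 10000L, seed = 1L,
                                    method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(table), nrow(table) >= 3L)
  x <- table$degree
  y <- table$traffic
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("Spearman correlation undefined for a constant vector")
  rho <- cor(rank(x), rank(y), method = "pearson")
  if (method == "asymptotic") {
    n <- length(x)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    if (n_perm < 1L) stop("`n_perm` must be >= 1")
    rx <- rank(x); ry <- rank(y)
    p <- with_local_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        r <- cor(rx, sample(ry), method = "pearson")
        if (abs(r) >= abs(rho) - 1e-12) hits <- hits + 1L
      }
      (1 + hits) / (1 + n_perm)
    })
  }
  list(rho = rho, p = p)
}
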