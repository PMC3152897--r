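#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_c [ e_c/m - (d_c/(2m))^2 ]`, where `e_c` is the number of edges
#' with both endpoints in module c, `d_c` the degree sum of module c and
#' `m` the total edge count. The subtracted term is the expected in-module
#' edge fraction under the degree-preserving (configuration-model) null,
#' i.e. the fraction of in-module edges minus what random pairing of the
#' module's proteins would give.
#'
#' @param net a [ppi_network] with at least one edge.
#' @param assignment module labels, a vector named by node (or in
#'   `net$nodes` order) covering every node.
#' @return The modularity score Q (a real number, at most 1; 0 for the
#'   single-module partition).
#' @export
modularity_q <- function(net, assignment) {
  stopifnot(inherits(net, "ppi_network"))
  m <- n_edges(net)
  if (m == 0L) stop("modularity is undefined for an edgeless network")
  assignment <- resolve_assignment(net, assignment)
  ei <- edge_index(net)
  lab <- match(assignment, unique(assignment))
  deg <- degree_all(net)
  d_c <- tapply(as.numeric(deg), lab, sum)
  same <- lab[ei[, 1L]] == lab[ei[, 2L]]
  e_c <- tabulate(lab[ei[same, 1L]], nbins = max(lab))
  sum(e_c / m) - sum((d_c / (2 * m))^2)
}

# normalize an assignment to an integer-ish vector in net$nodes order
resolve_assignment <- function(net, assignment) {
  nodes <- net$nodes
  if (!is.null(names(assignment))) {
    miss <- setdiff(nodes, names(assignment))
    if (length(miss))
      stop("assignment missing nodes: ", paste(head(miss, 5L), collapse = ", "))
    assignment <- assignment[nodes]
  } else if (length(assignment) != length(nodes)) {
    stop("assignment must cover every node")
  }
  if (anyNA(assignment)) stop("assignment contains NA")
  unname(assignment)
}

#' Greedy modularity maximization (agglomerative CNM-style)
#'
#' Starts from singleton modules and repeatedly merges the connected module
#' pair with the largest modularity gain, stopping when no merge has
#' `deltaQ > 0`; the returned partition is the one of maximal encountered
#' Q. Only connected pairs are considered (merging disconnected modules
#' never increases Q). Ties on deltaQ are broken toward the
#' lexicographically smallest module-id pair, so the merge history is
#' reproducible without a seed.
#'
#' @param net a [ppi_network] with at least one edge (may be disconnected).
#' @param min_size modules smaller than this are kept but flagged
#'   (default 3).
#' @return An object of class `module_partition`: list with `assignment`
#'   (integer module ids named by node; modules numbered by decreasing
#'   size, ties by smallest member identifier), `Q`, `merge_log` (data
#'   frame of merged community pairs with their `delta_q` and running `Q`),
#'   `flagged` (ids of modules smaller than `min_size`), and `n_modules`.
#' @export
greedy_modules <- function(net, min_size = 3L) {
  stopifnot(inherits(net, "ppi_network"))
  n <- n_nodes(net)
  m <- n_edges(net)
  if (m == 0L) stop("greedy clustering is undefined for an edgeless network")
  ei <- edge_index(net)
  deg <- unname(degree_all(net))
  a <- deg / (2 * m)              # configuration-model weights per community

  # per-community neighbour lists and deltaQ values (parallel vectors)
  nb <- lapply(adjacency_list(net), function(x) as.integer(unname(x)))
  dq <- vector("list", n)
  for (v in seq_len(n)) {
    nbv <- nb[[v]]
    dq[[v]] <- 1 / m - 2 * a[v] * a[nbv]
  }
  maxv <- vapply(seq_len(n), function(v)
    if (length(dq[[v]])) max(dq[[v]]) else -Inf, numeric(1))
  alive <- rep(TRUE, n)
  comm <- seq_len(n)              # node -> community label
  Q <- -sum(a^2)                  # modularity of the all-singletons start
  log_i <- integer(0); log_j <- integer(0)
  log_dq <- numeric(0); log_q <- numeric(0)

  repeat {
    best <- max(maxv[alive])
    if (!is.finite(best) || best <= 0) break
    # candidate pairs attaining the maximum, tie-broken lexicographically
    cand <- which(alive & maxv >= best)
    pick_i <- NA_integer_; pick_j <- NA_integer_
    for (ci in cand) {
      js <- nb[[ci]][dq[[ci]] >= best]
      for (cj in js) {
        pi <- min(ci, cj); pj <- max(ci, cj)
        if (is.na(pick_i) || pi < pick_i || (pi == pick_i && pj < pick_j)) {
          pick_i <- pi; pick_j <- pj
        }
      }
    }
    i <- pick_i; j <- pick_j
    # merge j into i
    nbi <- nb[[i]]; nbj <- nb[[j]]
    dqi <- dq[[i]]; dqj <- dq[[j]]
    ks <- setdiff(unique(c(nbi, nbj)), c(i, j))
    pos_i <- match(ks, nbi); pos_j <- match(ks, nbj)
    newdq <- numeric(length(ks))
    for (t in seq_along(ks)) {
      k <- ks[t]
      if (!is.na(pos_i[t]) && !is.na(pos_j[t])) {
        newdq[t] <- dqi[pos_i[t]] + dqj[pos_j[t]]
      } else if (!is.na(pos_i[t])) {
        newdq[t] <- dqi[pos_i[t]] - 2 * a[j] * a[k]
      } else {
        newdq[t] <- dqj[pos_j[t]] - 2 * a[i] * a[k]
      }
    }
    nb[[i]] <- ks; dq[[i]] <- newdq
    nb[[j]] <- integer(0); dq[[j]] <- numeric(0)
    a[i] <- a[i] + a[j]
    alive[j] <- FALSE
    maxv[j] <- -Inf
    maxv[i] <- if (length(newdq)) max(newdq) else -Inf
    # mirror the update into each neighbour's lists
    for (t in seq_along(ks)) {
      k <- ks[t]
      nbk <- nb[[k]]; dqk <- dq[[k]]
      has_i <- match(i, nbk)
      if (!is.na(has_i)) {
        dqk[has_i] <- newdq[t]
      } else {
        nbk <- c(nbk, i); dqk <- c(dqk, newdq[t])
      }
      keep <- nbk != j
      nb[[k]] <- nbk[keep]; dq[[k]] <- dqk[keep]
      maxv[k] <- if (length(dq[[k]])) max(dq[[k]]) else -Inf
    }
    comm[comm == j] <- i
    Q <- Q + best
    log_i <- c(log_i, i); log_j <- c(log_j, j)
    log_dq <- c(log_dq, best); log_q <- c(log_q, Q)
  }

  # deterministic module numbering: size desc, then smallest member node
  labs <- match(comm, unique(comm))
  sizes <- tabulate(labs)
  first_member <- net$nodes[match(seq_along(sizes), labs)]
  ord <- order(-sizes, first_member)
  relabel <- integer(length(sizes))
  relabel[ord] <- seq_along(ord)
  assignment <- setNames(relabel[labs], net$nodes)
  mod_sizes <- tabulate(assignment)

  structure(
    list(
      assignment = assignment,
      Q = Q,
      merge_log = data.frame(comm_i = log_i, comm_j = log_j,
                             delta_q = log_dq, q_after = log_q),
      flagged = which(mod_sizes < min_size),
      n_modules = length(mod_sizes),
      min_size = as.integer(min_size)
    ),
    class = "module_partition"
  )
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition:", x$n_modules, "modules, Q =",
      format(x$Q, digits = 4), "\n")
  if (length(x$flagged))
    cat("  flagged (<", x$min_size, "nodes):", length(x$flagged), "modules\n")
  invisible(x)
}

#' Per-module topology statistics
#'
#' For each module: `NP` (number of proteins), `IntraMI` (edges with both
#' endpoints inside), `InterMI` (edges with exactly one endpoint inside),
#' `TotInt = IntraMI + InterMI`, and `MTraffic`, defined here as the sum
#' of betweenness traffic of the module's nodes computed on the module's
#' induced subgraph.
#'
#' @param net the clustered [ppi_network].
#' @param partition a `module_partition` (or assignment vector named by
#'   node).
#' @return Data frame with columns `module_id`, `NP`, `IntraMI`, `InterMI`,
#'   `TotInt`, `MTraffic`, one row per module, sorted by id. Satisfies
#'   `sum(IntraMI) + sum(InterMI)/2 == n_edges(net)`.
#' @export
module_stats <- function(net, partition) {
  stopifnot(inherits(net, "ppi_network"))
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  assignment <- setNames(resolve_assignment(net, assignment), net$nodes)
  ei <- edge_index(net)
  lab <- match(assignment, sort(unique(assignment)))
  ids <- sort(unique(assignment))
  k <- length(ids)
  l1 <- lab[ei[, 1L]]; l2 <- lab[ei[, 2L]]
  intra <- tabulate(l1[l1 == l2], nbins = k)
  inter <- tabulate(c(l1[l1 != l2], l2[l1 != l2]), nbins = k)
  mtraffic <- vapply(seq_len(k), function(c) {
    sub <- induced_subnetwork(net, names(assignment)[lab == c])
    sum(traffic_all(sub))
  }, numeric(1))
  data.frame(
    module_id = ids,
    NP = tabulate(lab, nbins = k),
    IntraMI = intra,
    InterMI = inter,
    TotInt = intra + inter,
    MTraffic = mtraffic,
    row.names = NULL
  )
}

#' Brute-force maximum-modularity partition (small graphs)
#'
#' Enumerates every set partition of the node set (restricted growth
#' strings) and returns the global modularity maximum. Exponential; limited
#' to 12 nodes. Serves as an independent reference for validating greedy
#' clustering.
#'
#' @param net a [ppi_network] with 1-12 nodes and at least one edge.
#' @return List with `Q` (the maximum) and `assignment` (named integer
#'   labels attaining it).
#' @export
exhaustive_modularity <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  ei <- edge_index(net)
  res <- .exhaustive_modularity_max(n_nodes(net),
                                    as.integer(ei[, 1L]) - 1L,
                                    as.integer(ei[, 2L]) - 1L)
  res$assignment <- setNames(res$assignment, net$nodes)
  res
}
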