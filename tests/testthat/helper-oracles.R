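# Shared fixtures and brute-force oracles, all built in code.

net_from <- function(...) ppi_network(do.call(rbind, list(...)))

triangle_net <- function() net_from(c("A", "B"), c("B", "C"), c("A", "C"))

star_net <- function(leaves = 4L) {
  ppi_network(cbind("C0", sprintf("L%d", seq_len(leaves))))
}

# two triangles joined by one bridge edge C-D
bridge_net <- function() {
  net_from(c("A", "B"), c("B", "C"), c("A", "C"),
           c("D", "E"), c("E", "F"), c("D", "F"),
           c("C", "D"))
}

complete_net <- function(n) {
  ppi_network(t(combn(sprintf("K%02d", seq_len(n)), 2L)))
}

# Erdos-Renyi G(n, p) with optional restriction to the giant component
rand_net <- function(n, p, seed, connected = FALSE) {
  nodes <- sprintf("N%03d", seq_len(n))
  pairs <- t(combn(seq_len(n), 2L))
  set.seed(seed)
  keep <- runif(nrow(pairs)) < p
  net <- ppi_network(cbind(nodes[pairs[keep, 1L]], nodes[pairs[keep, 2L]]),
                     nodes = nodes)
  if (connected) net <- largest_component(net)
  net
}

# Betweenness by explicit shortest-path counting: BFS from every source
# gives distances and path counts; each ordered triple (s, v, t) with
# d(s,v) + d(v,t) = d(s,t) contributes sigma_sv * sigma_vt / sigma_st.
# Independent of the Brandes dependency accumulation it validates.
betweenness_oracle <- function(net) {
  n <- length(net$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(net$edges)) {
    e1 <- match(net$edges[, 1L], net$nodes)
    e2 <- match(net$edges[, 2L], net$nodes)
    for (k in seq_along(e1)) {
      adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
      adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
    }
  }
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]]) {
        if (!is.finite(dist[s, w])) {
          dist[s, w] <- d
          nxt <- c(nxt, w)
        }
        if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (!is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  stats::setNames(bc, net$nodes)
}

# BFS distance matrix (for the sum-of-(d-1) identity)
distance_matrix <- function(net) {
  n <- length(net$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(net$edges)) {
    e1 <- match(net$edges[, 1L], net$nodes)
    e2 <- match(net$edges[, 2L], net$nodes)
    for (k in seq_along(e1)) {
      adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
      adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
    }
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]])
        if (!is.finite(D[s, w])) { D[s, w] <- d; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
  }
  D
}

# Exact two-sided Fisher p by direct hypergeometric enumeration using
# log-binomial arithmetic (no dhyper), the independent oracle.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  p_obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U_obs <- u_of(seq_len(n1))
  combos <- combn(n1 + n2, n1)
  us <- apply(combos, 2L, u_of)
  mu <- n1 * n2 / 2
  mean(abs(us - mu) >= abs(U_obs - mu) - 1e-9)
}

# direct BH step-up formula, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

small_expression <- function(n_genes = 20L, seed = 1L, ...) {
  synth_expression(n_genes, n_good = 16L, n_poor = 16L, seed = seed, ...)
}
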