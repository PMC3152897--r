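test_that("modularity Q reproduces hand-computed values", {
  tri2 <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                            c("D", "E"), c("E", "F"), c("D", "F")))
  one <- setNames(rep(1, 6), tri2$nodes)
  expect_equal(modularity_q(tri2, one), 0)
  split2 <- setNames(c(1, 1, 1, 2, 2, 2), tri2$nodes)
  expect_equal(modularity_q(tri2, split2), 0.5)   # 2*(3/6 - (6/12)^2)
  br <- bridge_net()
  expect_equal(modularity_q(br, setNames(c(1, 1, 1, 2, 2, 2), br$nodes)),
               5 / 14)
  expect_error(modularity_q(ppi_network(NULL, nodes = "A"), c(A = 1)),
               "edgeless")
})

test_that("modularity Q agrees with igraph on random partitions", {
  skip_if_not_installed("igraph")
  for (seed in 1:6) {
    net <- rand_net(25, 0.15, seed = seed)
    set.seed(seed + 100)
    memb <- sample(1:4, 25, replace = TRUE)
    ig <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, length(setdiff(net$nodes, igraph::V(ig)$name)),
                               name = setdiff(net$nodes, igraph::V(ig)$name))
    m2 <- memb[match(igraph::V(ig)$name, net$nodes)]
    expect_equal(modularity_q(net, memb), igraph::modularity(ig, m2),
                 tolerance = 1e-12)
  }
})

test_that("greedy clustering recovers known optima on canonical graphs", {
  br <- bridge_net()
  p <- greedy_modules(br)
  expect_equal(p$Q, 5 / 14)
  expect_equal(unname(tapply(names(p$assignment), p$assignment, paste,
                             collapse = "")[1]), "ABC")
  ex <- exhaustive_modularity(br)
  expect_equal(p$Q, ex$Q)           # greedy attains the global maximum here

  k5 <- complete_net(5)
  pk <- greedy_modules(k5)
  expect_equal(pk$n_modules, 1L)
  expect_equal(pk$Q, 0)
  expect_equal(exhaustive_modularity(k5)$Q, 0)
})

test_that("greedy Q is bracketed by singletons and the exhaustive maximum", {
  for (seed in 1:25) {
    n <- 5 + seed %% 6
    net <- rand_net(n, 0.4, seed = seed)
    if (nrow(net$edges) == 0) next
    singletonQ <- modularity_q(net, seq_along(net$nodes))
    p <- greedy_modules(net)
    exQ <- exhaustive_modularity(net)$Q
    expect_gte(p$Q, singletonQ)
    expect_lte(p$Q, exQ + 1e-12)
    expect_lte(p$Q, 1)
    # self-consistency: reported Q is the recomputed Q of the assignment
    expect_equal(p$Q, modularity_q(net, p$assignment), tolerance = 1e-12)
  }
})

test_that("planted partitions are recovered (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  sn <- synth_network(rep(15L, 4L), p_in = 0.4, p_out = 0.01, seed = 1)
  p <- greedy_modules(largest_component(sn$network))
  truth <- sn$membership[names(p$assignment)]
  expect_gte(mclust::adjustedRandIndex(p$assignment, truth), 0.9)
})

test_that("merge history is deterministic and internally consistent", {
  net <- rand_net(30, 0.12, seed = 7)
  p1 <- greedy_modules(net)
  p2 <- greedy_modules(net)
  expect_identical(p1$merge_log, p2$merge_log)
  expect_identical(p1$assignment, p2$assignment)
  # each logged deltaQ equals the realized Q increment
  expect_equal(diff(c(p1$merge_log$q_after[1] - p1$merge_log$delta_q[1],
                      p1$merge_log$q_after)),
               p1$merge_log$delta_q, tolerance = 1e-12)
  expect_true(all(p1$merge_log$delta_q > 0))
  expect_equal(p1$Q, utils::tail(p1$merge_log$q_after, 1))
})

test_that("module statistics satisfy their counting identities", {
  tri2 <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("A", "C"),
                            c("D", "E"), c("E", "F"), c("D", "F")))
  st <- module_stats(tri2, setNames(c(1, 1, 1, 2, 2, 2), tri2$nodes))
  expect_equal(st$NP, c(3L, 3L))
  expect_equal(st$IntraMI, c(3L, 3L))
  expect_equal(st$InterMI, c(0L, 0L))
  expect_equal(st$TotInt, c(3L, 3L))

  br <- bridge_net()
  stb <- module_stats(br, setNames(c(1, 1, 1, 2, 2, 2), br$nodes))
  expect_equal(stb$InterMI, c(1L, 1L))
  expect_equal(stb$TotInt, c(4L, 4L))

  for (seed in 1:6) {
    net <- rand_net(30, 0.1, seed = seed)
    set.seed(seed)
    memb <- setNames(sample(1:5, 30, replace = TRUE), net$nodes)
    st <- module_stats(net, memb)
    expect_equal(st$TotInt, st$IntraMI + st$InterMI)
    expect_equal(sum(st$IntraMI) + sum(st$InterMI) / 2, nrow(net$edges))
    expect_true(all(st$NP >= 1))
    expect_true(all(st$MTraffic >= 0))
  }
})

test_that("small modules are flagged against the min_size threshold", {
  br <- bridge_net()
  p <- greedy_modules(br, min_size = 4L)
  expect_equal(sort(p$flagged), 1:2)     # both triangles are below 4
  expect_equal(length(greedy_modules(br, min_size = 3L)$flagged), 0L)
})
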