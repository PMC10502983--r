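test_that("the window ladder partitions 672 h exactly at every level", {
  slabs <- split_ladder(0)
  expect_equal(as.integer(names(slabs)),
               c(672L, 336L, 168L, 84L, 48L, 24L, 12L, 6L, 3L, 1L))
  for (d in names(slabs)) {
    wins <- slabs[[d]]
    expect_equal(nrow(wins) * as.integer(d), 672L)
    expect_equal(wins$end - wins$start, rep(as.integer(d) * 3600, nrow(wins)))
    expect_equal(wins$start[-1], wins$end[-nrow(wins)])  # contiguous
  }
  expect_equal(nrow(slabs[["336"]]), 2)   # two two-week networks
  expect_equal(nrow(slabs[["1"]]), 672)   # 24 h/day x 28 days
  expect_error(split_ladder(0, total_h = 500), "672")
  expect_error(split_ladder(0, durations_h = c(672, 100)), "divide")
})

test_that("excess networks clamp at zero and drop empty edges", {
  real <- make_net(data.frame(a = c("x", "x"), b = c("y", "z"), w = c(5L, 2L)))
  null <- make_net(data.frame(a = c("x", "x"), b = c("y", "z"), w = c(2L, 5L)),
                   nodes = real$nodes)
  ex <- excess_network(real, null)
  expect_equal(ex$edges$weight_count, 3)
  expect_equal(nrow(ex$edges), 1)       # negative excess -> edge absent
  expect_equal(ex$provenance, "excess")
  # empty null -> excess equals real
  ex2 <- excess_network(real, make_net(real$edges[0], nodes = real$nodes))
  expect_equal(ex2$edges[order(b), weight_count], c(5, 2))
  bad <- make_net(real$edges, nodes = real$nodes, window = c(10, 20))
  expect_error(excess_network(real, bad), "mismatch")
})

test_that("community detection resolves planted structure", {
  tri2 <- make_net(data.frame(
    a = c("a1", "a1", "a2", "b1", "b1", "b2"),
    b = c("a2", "a3", "a3", "b2", "b3", "b3"), w = 10L))
  cm <- detect_communities(tri2)
  expect_equal(cm$n_communities, 2L)   # two disjoint triangles
  clique <- make_net(data.frame(t(utils::combn(paste0("n", 1:6), 2)), w = 5L) |>
                       stats::setNames(c("a", "b", "w")))
  expect_equal(detect_communities(clique)$n_communities, 1L)
  # no edges -> zero communities of size >= 3; isolated nodes never counted
  empty <- make_net(clique$edges[0], nodes = paste0("n", 1:6))
  expect_equal(detect_communities(empty)$n_communities, 0L)
})

test_that("a ring of four weakly-linked triangles yields four communities", {
  tri <- function(k) data.frame(
    a = paste0("t", k, c("a", "a", "b")), b = paste0("t", k, c("b", "c", "c")),
    w = 20L)
  bridge <- data.frame(a = paste0("t", 1:4, "a"),
                       b = paste0("t", c(2, 3, 4, 1), "b"), w = 1L)
  net <- make_net(rbind(tri(1), tri(2), tri(3), tri(4), bridge))
  cm <- detect_communities(net)
  expect_equal(cm$n_communities, 4L)
  # independent modularity-based oracle on the same graph
  g <- as_igraph(net)
  set.seed(9)
  lou <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  expect_equal(length(unique(igraph::membership(lou))), 4L)
})

test_that("community detection is deterministic under its seed", {
  set.seed(77)
  ed <- data.frame(a = sample(letters[1:10], 40, TRUE),
                   b = sample(letters[11:20], 40, TRUE), w = sample(1:5, 40, TRUE))
  net <- make_net(ed)
  m1 <- detect_communities(net, seed = 5)$membership
  m2 <- detect_communities(net, seed = 5)$membership
  expect_identical(m1, m2)
})

test_that("memory timescale is the argmax with ties broken long", {
  curve <- data.table::data.table(
    duration_h = c(672L, 336L, 168L, 84L), mean_communities = c(1, 3, 2, 3))
  expect_equal(memory_timescale(curve), 336L)
  mono <- data.table::data.table(duration_h = c(24L, 12L, 6L),
                                 mean_communities = c(1, 2, 3))
  expect_equal(memory_timescale(mono), 6L)   # monotone decreasing -> shortest
  zero <- data.table::data.table(duration_h = c(24L, 12L),
                                 mean_communities = c(0, 0))
  expect_true(is.na(memory_timescale(zero)))
})

test_that("timescale curves aggregate identically to the windowed pipeline", {
  set.seed(55)
  t0 <- 0
  nodes <- sprintf("f%02d", 1:8)
  mk_ev <- function(n) {
    ab <- t(replicate(n, sort(sample(nodes, 2))))
    data.table::data.table(pair = paste(ab[, 1], ab[, 2], sep = "|"),
                           a = ab[, 1], b = ab[, 2],
                           start = runif(n, 0, 672 * 3600),
                           duration_s = 60, period = "all")
  }
  ev <- mk_ev(400); nv <- mk_ev(150)
  cur <- timescale_curve(ev, nv, t0, period = "all", nodes = nodes,
                         durations_h = c(84L, 6L))
  # recompute one level the slow way
  wins <- split_ladder(t0, 84L)[["84"]]
  counts <- edges <- integer(nrow(wins))
  for (w in seq_len(nrow(wins))) {
    ex <- excess_network(
      aggregate_network(ev, wins$start[w], wins$end[w], "all", nodes),
      aggregate_network(nv, wins$start[w], wins$end[w], "all", nodes,
                        provenance = "shuffled"))
    edges[w] <- nrow(ex$edges)
    counts[w] <- detect_communities(ex)$n_communities
  }
  expect_equal(cur[cur$duration_h == 84L]$mean_communities,
               mean(counts[edges > 0]))
  expect_equal(cur[cur$duration_h == 84L]$pct_realized_links,
               100 * mean(edges) / choose(8, 2))
})
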