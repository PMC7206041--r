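toy_itab <- function() itab(c("A", "A", "C", "B"), c("B", "C", "D", "E"),
                            c(800, 750, 900, 650))

test_that("network construction keeps the strict-threshold first shell", {
  net <- buildNetwork(c("A", "B"), toy_itab())
  expect_setequal(nodeIds(net), c("A", "B", "C"))
  el <- igraph::as_data_frame(networkGraph(net))
  expect_equal(nrow(el), 2)
  expect_setequal(el$weight, c(800, 750))   # E dropped (650 <= 700), D 2nd shell
  expect_setequal(seedNodes(net), c("A", "B"))

  net2 <- buildNetwork(c("A", "B"), toy_itab(), expansion = "seeds_only")
  expect_setequal(nodeIds(net2), c("A", "B"))
  expect_equal(igraph::E(networkGraph(net2))$weight, 800)

  # empty interaction table: isolated seeds
  net3 <- buildNetwork(c("X", "Y"), itab(character(), character(), integer()))
  expect_setequal(nodeIds(net3), c("X", "Y"))
  expect_equal(igraph::ecount(networkGraph(net3)), 0)

  # a boundary-score edge is excluded under the strict rule
  net4 <- buildNetwork("A", itab("A", "B", 700))
  expect_equal(igraph::ecount(networkGraph(net4)), 0)

  expect_error(buildNetwork(c("Z1", "Z2"), toy_itab()), "none of the seeds")
})

test_that("evidence-channel filtering and alias mapping apply", {
  tab <- itab(c("A", "A"), c("B", "C"), c(800, 900),
              experiments = c(0, 120), database = c(0, 0))
  net <- buildNetwork("A", tab, evidence_channels = c("experiments", "database"))
  el <- igraph::as_data_frame(networkGraph(net))
  expect_equal(el$weight, 900)   # A-B has no supporting channel
  expect_error(buildNetwork("A", tab, evidence_channels = "textmining"),
               "textmining")

  net2 <- buildNetwork("Mmp9", toy_itab(), alias_map = c(Mmp9 = "A"))
  expect_true("A" %in% seedNodes(net2))
})

test_that("hub calling takes ceil(fraction * n) by degree with id tie-breaks", {
  # 10-node star: single hub is the centre
  star <- itab(rep("hub", 9), paste0("leaf", 1:9), rep(900, 9))
  net <- net_from_itab(star)
  hubs <- findHubs(net)
  expect_equal(nrow(hubs), 1)
  expect_equal(hubs$node_id, "hub")
  expect_equal(hubs$degree, 9)

  # 10 isolated nodes, all degree 0: lexicographically smallest id wins
  g <- igraph::make_empty_graph(10, directed = FALSE)
  igraph::V(g)$name <- sprintf("n%02d", 10:1)
  h0 <- findHubs(g)
  expect_equal(h0$node_id, "n01")

  # scripted degree sequence equals the sort-then-take oracle
  set.seed(4)
  g2 <- igraph::sample_gnp(25, 0.3)
  igraph::V(g2)$name <- sprintf("v%02d", 1:25)
  h <- findHubs(g2, fraction = 0.2)
  deg <- igraph::degree(g2)
  oracle <- igraph::V(g2)$name[order(-deg, igraph::V(g2)$name)][1:ceiling(0.2 * 25)]
  expect_equal(h$node_id, oracle)
  expect_equal(attr(h, "cutoff_degree"), min(h$degree))
})

test_that("cohesiveness matches direct arithmetic", {
  tri <- net_from_itab(itab(c("a", "b", "c"), c("b", "c", "a"), c(1, 1, 1)),
                       unit_weights = TRUE)
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 1)
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 2), 1 / 3)

  tri_plus <- net_from_itab(itab(c("a", "b", "c", "c"), c("b", "c", "a", "d"),
                                 rep(1, 4)), unit_weights = TRUE)
  expect_equal(cohesiveness(tri_plus, c("a", "b", "c"), penalty = 0), 0.75)
  # empty-edge set with positive penalty
  expect_equal(cohesiveness(tri_plus, "d", penalty = 2), 0)
  expect_error(cohesiveness(tri, character()), "non-empty")
  expect_error(cohesiveness(tri, "zz"), "unknown")
})

test_that("greedy growth recovers disjoint cliques exactly", {
  sim <- simulateInteractome(10, 2, 5, p_in = 1, p_out = 0, seed = 3)
  net <- net_from_itab(sim$interactions, unit_weights = TRUE)
  cl <- growClusters(net)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$cohesiveness, c(0.5, 0.5))   # 10/(10 + 0 + 2*5)
  got <- lapply(cl$members, sort)
  want <- lapply(sim$truth$planted_communities, sort)
  expect_setequal(got, want)
  # oracle: connected components
  comp <- igraph::components(networkGraph(net))
  expect_equal(nrow(cl), comp$no)

  # stored cohesiveness matches recomputation
  for (i in seq_len(nrow(cl)))
    expect_equal(cl$cohesiveness[i], cohesiveness(net, cl$members[[i]]),
                 tolerance = 1e-12)

  # a single edge cannot form a cluster at min_size 3
  e1 <- net_from_itab(itab("a", "b", 1), unit_weights = TRUE)
  expect_equal(nrow(growClusters(e1)), 0)

  # determinism
  cl2 <- growClusters(net)
  expect_identical(cl$members, cl2$members)
})

test_that("overlap-score merging unions only highly overlapping clusters", {
  net <- net_from_itab(itab(c("a", "b", "c"), c("b", "c", "a"), rep(1, 3)),
                       unit_weights = TRUE)
  mk <- function(...) {
    m <- list(...)
    structure(data.frame(cluster_id = sprintf("C%03d", seq_along(m)),
                         members = I(m),
                         size = lengths(m), cohesiveness = 0, w_in = 0,
                         w_bound = 0, density = 1),
              class = c("cluster_set", "data.frame"))
  }
  # identical clusters: omega = 1, merged
  m1 <- mergeOverlapping(mk(c("a", "b"), c("a", "b")), net)
  expect_equal(nrow(m1), 1)
  # disjoint: untouched
  m2 <- mergeOverlapping(mk(c("a", "b"), c("c")), net)
  expect_equal(nrow(m2), 2)
  # |A|=|B|=4, overlap 2: omega = 0.25, not merged at 0.8
  net4 <- net_from_itab(itab(rep("a", 5), paste0("x", 1:5), rep(1, 5)),
                        unit_weights = TRUE)
  m3 <- mergeOverlapping(mk(c("a", "x1", "x2", "x3"),
                            c("a", "x1", "x4", "x5")), net4)
  expect_equal(nrow(m3), 2)
  # cohesiveness is recomputed on the merged set
  m4 <- mergeOverlapping(mk(c("a", "b", "c"), c("a", "b", "c")), net)
  expect_equal(m4$cohesiveness, 1 / 3)
})

test_that("cluster significance behaves at separation, equality and tiny sizes", {
  # isolated 8-clique: complete separation, p far below 0.05
  s8 <- simulateInteractome(8, 1, 8, 1, 0, seed = 1)
  n8 <- net_from_itab(s8$interactions, unit_weights = TRUE)
  p8 <- clusterSignificance(n8, nodeIds(n8))
  expect_lt(p8, 0.001)

  # internal equal to boundary for every vertex: no evidence, p >= 0.5
  # path a - b - c - d, cluster {b, c}: each has internal 1, boundary 1
  path <- net_from_itab(itab(c("a", "b", "c"), c("b", "c", "d"), rep(1, 3)),
                        unit_weights = TRUE)
  expect_gte(clusterSignificance(path, c("b", "c")), 0.5)

  # size-3 cluster: exact U test cannot reach p < 0.05 (min is 1/C(6,3))
  s3 <- simulateInteractome(3, 1, 3, 1, 0, seed = 1)
  n3 <- net_from_itab(s3$interactions)
  p3 <- clusterSignificance(n3, nodeIds(n3))
  expect_gte(p3, 0.05)

  expect_warning(p1 <- clusterSignificance(path, "a"), "size < 2")
  expect_equal(p1, 1)
})
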