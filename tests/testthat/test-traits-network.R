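test_that("shortest-path distances match hand and dense oracles", {
  # path root-a-b with unit resistances (length 2, width 2 -> r = 2/1 = 2?
  # no: length 2, width 2 gives resistance 2; use length 1 -> wait, width 2
  # means radius 1, so resistance = length; lengths 1,1 give d(root,b) = 2
  pn <- path_net(c(1, 1), c(2, 2))
  d <- shortest_path_distances(pn, sources = 1)[1, ]
  expect_equal(unname(d["3"]), 2)

  # triangle with resistances 1,1,3: the detour beats the heavy edge
  tr <- tri_net(lengths = c(1, 1, 3), widths = c(2, 2, 2))
  dt <- shortest_path_distances(tr)
  expect_equal(dt["3", "1"], 2)

  for (s in 1:20) {
    net <- random_net(15, extra = 6, seed = s)
    expect_equal(unname(shortest_path_distances(net)),
                 unname(floyd_warshall(net)), tolerance = 1e-10)
  }
})

test_that("root and root-tip efficiencies match hand calculations", {
  pn <- path_net(c(1, 1), c(2, 2))
  expect_equal(root_efficiency(pn), (1 + 1 / 2) / 2)

  st <- star_net(3, length = 2, width = 2)   # three tips at resistance 2
  expect_equal(root_tip_efficiency(st), 0.5)

  # halving widths at alpha = 4 scales efficiency by 1/16
  half <- pn
  half$edges$width <- pn$edges$width / 2
  expect_equal(root_efficiency(half), root_efficiency(pn) / 16)
})

test_that("global efficiency matches closed forms and is edge-monotone", {
  expect_equal(global_efficiency(tri_net()), 1.0)
  expect_equal(global_efficiency(path_net(c(1, 1), c(2, 2), root = FALSE)),
               (1 + 1 + 1 / 2) / 3)
  for (s in 1:10) {
    net <- random_net(10, extra = 2, seed = s, root = FALSE)
    g0 <- global_efficiency(net)
    set.seed(s + 100)
    pair <- sample(net$nodes$id, 2)
    added <- net
    added$edges <- rbind(
      added$edges,
      data.frame(from = pair[1], to = pair[2], length = 5, width = 3,
                 is_root_edge = FALSE, id = max(net$edges$id) + 1L,
                 polyline = I(list(NULL))))
    expect_gte(global_efficiency(added), g0 - 1e-12)
  }
})

test_that("minimum spanning tree is exact, deterministic and idempotent", {
  tr <- tri_net(lengths = c(1, 2, 3), widths = c(2, 2, 2))
  mst <- minimum_spanning_tree(tr)
  expect_equal(sort(mst$edges$length), c(1, 2))

  pn <- path_net(c(1, 2, 3), c(2, 2, 2))
  expect_equal(minimum_spanning_tree(pn)$edges$id, pn$edges$id)

  for (s in 1:10) {
    net <- random_net(6, extra = 4, seed = s)
    expect_equal(total_mst_weight(net), exhaustive_mst_weight(net),
                 tolerance = 1e-10)
  }
  # never beaten by a random spanning tree
  net <- random_net(12, extra = 8, seed = 1)
  w0 <- total_mst_weight(net)
  g <- as_igraph(net, weight = "resistance")
  for (k in 1:50) {
    set.seed(k)
    rt <- igraph::subgraph.edges(
      g, igraph::sample_spanning_tree(g), delete.vertices = FALSE)
    expect_gte(sum(igraph::E(rt)$weight), w0 - 1e-10)
  }
})

test_that("meshedness matches the planar formula and the cycle-rank oracle", {
  expect_equal(meshedness(path_net(c(1, 1, 1), c(2, 2, 2))), 0)

  cyc <- mycelial_network(
    data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
    data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1),
               length = 1, width = 2))
  expect_equal(meshedness(cyc), 1 / 3)

  # maximal planar graph on 5 nodes: E = 3N - 6 = 9
  tri5 <- mycelial_network(
    data.frame(id = 1:5, x = c(0, 4, 2, 1.7, 2.3), y = c(0, 0, 3, 1, 1)),
    data.frame(from = c(1, 2, 3, 1, 1, 2, 3, 4, 3),
               to = c(2, 3, 1, 4, 5, 5, 4, 5, 5),
               length = 1, width = 2))
  expect_equal(meshedness(tri5), 1.0)

  for (s in 1:10) {
    net <- random_net(12, extra = s %% 5, seed = s, root = FALSE)
    e <- measured_edges(net)
    n <- length(unique(c(e$from, e$to)))
    g <- as_igraph(net, include_root_edges = FALSE)
    cyc_rank <- nrow(e) - n + igraph::components(g)$no
    expect_equal(meshedness(net), cyc_rank / (2 * n - 5))
  }
})

test_that("MST-normalized cost and efficiency behave as ratios >= 1", {
  pn <- path_net(c(1, 2), c(2, 3))
  expect_equal(volume_mst(pn), 1.0)
  expect_equal(geff_mst(pn), 1.0)

  tr <- tri_net(lengths = c(1, 1, 1), widths = c(2, 2, 2))
  expect_equal(volume_mst(tr), 1.5)   # 3 cylinders vs 2

  for (s in 1:15) {
    net <- random_net(10, extra = 4, seed = s)
    expect_gte(geff_mst(net), 1 - 1e-12)
    expect_gte(volume_mst(net), 1 - 1e-12)
  }
})

test_that("area normalization divides efficiencies by the hull area", {
  st <- star_net(4, length = 1, width = 2)
  a <- mycelial_area(st)
  expect_equal(a, 2)   # unit square rotated: diagonals 2
  an <- area_normalized_efficiencies(st)
  expect_equal(an$R_eff_area, root_efficiency(st) / a)
  expect_equal(an$RT_eff_area, root_tip_efficiency(st) / a)
})

test_that("removing a non-bridge edge lowers meshedness, not G_eff", {
  for (s in 1:8) {
    net <- random_net(10, extra = 5, seed = s, root = FALSE)
    g <- as_igraph(net, include_root_edges = FALSE)
    bridges <- igraph::E(g)$eid[igraph::bridges(g)]
    nonbridge <- setdiff(net$edges$id, bridges)
    if (!length(nonbridge)) next
    drop <- nonbridge[1]
    cut <- net
    cut$edges <- net$edges[net$edges$id != drop, , drop = FALSE]
    expect_lt(meshedness(cut), meshedness(net))
    expect_lte(global_efficiency(cut), global_efficiency(net) + 1e-12)
  }
})
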