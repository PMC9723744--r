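test_that("edge resistance follows the l / r^alpha law", {
  expect_equal(edge_resistance(2, 2, resistance_params("micro")), 2)
  expect_equal(edge_resistance(1, 2, resistance_params("macro")), 1)
  expect_equal(edge_resistance(10, 4, resistance_params("micro")), 0.625)
  # doubling width divides resistance by 16 (micro) / 4 (macro), exactly
  l <- runif(20, 0.5, 10); w <- runif(20, 0.5, 8)
  expect_equal(edge_resistance(l, w, resistance_params("micro")) /
                 edge_resistance(l, 2 * w, resistance_params("micro")),
               rep(16, 20))
  expect_equal(edge_resistance(l, w, resistance_params("macro")) /
                 edge_resistance(l, 2 * w, resistance_params("macro")),
               rep(4, 20))
  expect_error(edge_resistance(-1, 2), "> 0")
  expect_error(edge_resistance(1, 0), "> 0")
})

test_that("edge lists load with coordinate merging and validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  # 3 rows forming a path over 4 distinct coordinates
  write.csv(data.frame(x1 = c(0, 1, 2), y1 = 0, x2 = c(1, 2, 3), y2 = 0,
                       length = 1, width = 2), f, row.names = FALSE)
  net <- load_network(f)
  expect_equal(nrow(net$nodes), 4)
  expect_equal(nrow(net$edges), 3)

  # invalid width must name the offending row
  write.csv(data.frame(x1 = c(0, 1), y1 = 0, x2 = c(1, 2), y2 = 0,
                       length = 1, width = c(2, 0)), f, row.names = FALSE)
  expect_error(load_network(f), "row\\(s\\): 2")

  # endpoints within the merge tolerance share a node
  write.csv(data.frame(x1 = c(0, 1 + 4e-7), y1 = c(0, 1e-7),
                       x2 = c(1, 2), y2 = c(0, 0),
                       length = 1.01, width = 2), f, row.names = FALSE)
  net <- load_network(f)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
})

test_that("self-loops are dropped with a warning", {
  nodes <- data.frame(id = 1:2, x = 0:1, y = 0)
  edges <- data.frame(from = c(1, 1), to = c(2, 1), length = 1, width = 1)
  expect_warning(net <- mycelial_network(nodes, edges), "self-loop")
  expect_equal(nrow(net$edges), 1)
})

test_that("root attachment uses Euclidean length and maximum width", {
  nodes <- data.frame(id = 1:3, x = c(0, 5, 12), y = 0)
  edges <- data.frame(from = c(1, 2), to = c(2, 3),
                      length = c(5, 7), width = c(3, 1))
  net <- mycelial_network(nodes, edges)
  out <- attach_root(net, c(0, 0), boundary_nodes = c(2, 3))
  re <- out$edges[out$edges$is_root_edge, ]
  expect_equal(sort(re$length), c(5, 12))
  expect_equal(re$width, c(3, 3))
  expect_error(attach_root(out, c(0, 0), 2), "already has a root")
  expect_error(attach_root(net, c(0, 0), integer(0)), "nonempty")

  st <- star_net(4)
  d <- myconet:::node_degree(st)
  expect_equal(unname(d["1"]), 4)
})

test_that("networks round trip through csv and graphml", {
  for (seed in 1:5) {
    net <- random_net(10, extra = 3, seed = seed, root = FALSE)
    net <- attach_root(net, c(50, 50), net$nodes$id[1:2])
    f <- withr::local_tempfile(fileext = ".csv")
    write_network(net, f, "csv")
    back <- load_network(f, columns = c(x1 = "x1", y1 = "y1", x2 = "x2",
                                        y2 = "y2", length = "length",
                                        width = "width",
                                        is_root_edge = "is_root_edge"))
    expect_equal(nrow(back$nodes), nrow(net$nodes))
    expect_equal(nrow(back$edges), nrow(net$edges))
    # edge multiset identical up to node relabelling
    key <- function(n) {
      e <- n$edges
      sort(paste(round(e$length, 9), round(e$width, 9), e$is_root_edge))
    }
    expect_identical(key(back), key(net))
    expect_equal(sum(back$edges$is_root_edge), sum(net$edges$is_root_edge))

    g <- withr::local_tempfile(fileext = ".graphml")
    write_network(net, g, "graphml")
    gg <- igraph::read_graph(g, format = "graphml")
    expect_equal(igraph::vcount(gg), nrow(net$nodes))
    expect_equal(igraph::ecount(gg), nrow(net$edges))
    expect_equal(sum(igraph::E(gg)$is_root_edge), sum(net$edges$is_root_edge))
  }
  expect_error(write_network(star_net(3), tempfile(), "xlsx"), "xlsx")
})

test_that("validation enforces the structural invariants", {
  net <- star_net(4)
  expect_true(validate_network(net))
  expect_error(
    mycelial_network(data.frame(id = 1:2, x = 0:1, y = 0),
                     data.frame(from = 1, to = 3, length = 1, width = 1)),
    "unknown node ids")
  expect_error(
    mycelial_network(data.frame(id = c(1, 1), x = 0:1, y = 0),
                     data.frame(from = 1, to = 1, length = 1, width = 1)),
    "duplicate")
})
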