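# fixture builders used across the suite (built in code, no data files)

# straight path r - a - b - ... with given per-edge lengths/widths;
# first node is the root
path_net <- function(lengths, widths, root = TRUE,
                     scale_class = "micro", root_edge_first = FALSE) {
  n <- length(lengths) + 1
  nodes <- data.frame(id = seq_len(n), x = c(0, cumsum(lengths)), y = 0)
  edges <- data.frame(from = seq_len(n - 1), to = 2:n,
                      length = lengths, width = widths)
  if (root_edge_first) edges$is_root_edge <- c(TRUE, rep(FALSE, n - 2))
  mycelial_network(nodes, edges, root_id = if (root) 1L else NA_integer_,
                   scale_class = scale_class)
}

# star: root at origin, k arms of equal length/width
star_net <- function(k = 4, length = 1, width = 2, scale_class = "micro") {
  ang <- 2 * pi * (seq_len(k) - 1) / k
  nodes <- data.frame(id = seq_len(k + 1),
                      x = c(0, length * cos(ang)),
                      y = c(0, length * sin(ang)))
  edges <- data.frame(from = 1, to = 1 + seq_len(k),
                      length = length, width = width)
  mycelial_network(nodes, edges, root_id = 1L, scale_class = scale_class)
}

# triangle with specified lengths/widths; no root
tri_net <- function(lengths = c(1, 1, 1), widths = c(2, 2, 2),
                    scale_class = "micro") {
  nodes <- data.frame(id = 1:3, x = c(0, 1, 0.5), y = c(0, 0, 1))
  edges <- data.frame(from = c(1, 2, 3), to = c(2, 3, 1),
                      length = lengths, width = widths)
  mycelial_network(nodes, edges, scale_class = scale_class)
}

# random connected spatial network: spanning tree over random points plus
# `extra` chord edges; lengths are Euclidean distances, widths uniform
random_net <- function(n = 15, extra = 5, seed = 1, root = TRUE) {
  set.seed(seed)
  x <- runif(n, 0, 100)
  y <- runif(n, 0, 100)
  from <- integer(0); to <- integer(0)
  for (i in 2:n) {                 # random recursive tree keeps it connected
    from <- c(from, sample(i - 1, 1)); to <- c(to, i)
  }
  for (k in seq_len(extra)) {
    repeat {
      p <- sample(n, 2)
      if (!any((from == p[1] & to == p[2]) | (from == p[2] & to == p[1]))) {
        from <- c(from, p[1]); to <- c(to, p[2]); break
      }
    }
  }
  lens <- sqrt((x[from] - x[to])^2 + (y[from] - y[to])^2) + 0.1
  nodes <- data.frame(id = seq_len(n), x = x, y = y)
  edges <- data.frame(from = from, to = to, length = lens,
                      width = runif(length(from), 1, 6))
  mycelial_network(nodes, edges, root_id = if (root) 1L else NA_integer_,
                   scale_class = "micro")
}

# dense all-pairs shortest path oracle (Floyd-Warshall)
floyd_warshall <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  r <- edge_resistance(net$edges$length, net$edges$width,
                       resistance_params(net$scale_class))
  for (k in seq_len(nrow(net$edges))) {
    i <- match(net$edges$from[k], ids)
    j <- match(net$edges$to[k], ids)
    d[i, j] <- min(d[i, j], r[k])
    d[j, i] <- d[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# exhaustive minimum spanning tree by enumerating edge subsets (tiny n)
exhaustive_mst_weight <- function(net) {
  e <- net$edges
  n <- nrow(net$nodes)
  r <- edge_resistance(e$length, e$width, resistance_params(net$scale_class))
  best <- Inf
  for (comb in utils::combn(nrow(e), n - 1, simplify = FALSE)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(e$from[comb]),
                 to = as.character(e$to[comb])),
      directed = FALSE,
      vertices = data.frame(name = as.character(net$nodes$id)))
    if (igraph::components(g)$no == 1) best <- min(best, sum(r[comb]))
  }
  best
}

total_mst_weight <- function(net) {
  mst <- minimum_spanning_tree(net)
  sum(edge_resistance(mst$edges$length, mst$edges$width,
                      resistance_params(mst$scale_class)))
}
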