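#' Shortest-path resistance distances
#'
#' Dijkstra distances on the transport-resistance-weighted graph (root
#' node and synthetic root edges included: they are the inoculum's
#' connection and legitimate transport paths).
#'
#' @param net a [mycelial_network].
#' @param sources node ids (default: all nodes).
#' @return matrix of distances, rows = sources, dimnames = node ids;
#'   `Inf` for unreachable nodes.
#' @export
shortest_path_distances <- function(net, sources = net$nodes$id) {
  g <- as_igraph(net, weight = "resistance")
  igraph::distances(g, v = as.character(sources), algorithm = "dijkstra")
}

#' Root and root-tip transport efficiency
#'
#' `R_eff` is the mean over all non-root nodes i of `1/d(root, i)` where d
#' is the shortest-path resistance distance; `RT_eff` restricts the mean
#' to tip nodes. Thin, long paths have low efficiency; short, wide paths
#' have high efficiency. Unreachable nodes contribute 0.
#'
#' @param net a root-attached [mycelial_network].
#' @return `root_efficiency`: scalar. `root_tip_efficiency`: scalar (`NA`
#'   when the network has no tips).
#' @export
root_efficiency <- function(net) {
  if (is.na(net$root_id)) stop("no root attached")
  d <- shortest_path_distances(net, sources = net$root_id)[1, ]
  d <- d[names(d) != as.character(net$root_id)]
  mean(ifelse(is.finite(d) & d > 0, 1 / d, 0))
}

#' @rdname root_efficiency
#' @export
root_tip_efficiency <- function(net) {
  if (is.na(net$root_id)) stop("no root attached")
  tips <- net$nodes$id[net$nodes$kind == "tip"]
  if (!length(tips)) return(NA_real_)
  d <- shortest_path_distances(net, sources = net$root_id)[1, ]
  d <- d[as.character(tips)]
  mean(ifelse(is.finite(d) & d > 0, 1 / d, 0))
}

#' Global transport efficiency
#'
#' Mean over all unordered pairs of non-root nodes of the reciprocal
#' shortest-path resistance distance: the expected efficiency of
#' multidirectional transport. Paths may run through the root and its
#' synthetic edges, but the root itself is not an endpoint (it is not
#' measured structure).
#'
#' @param net a [mycelial_network].
#' @return scalar efficiency.
#' @export
global_efficiency <- function(net) {
  ids <- net$nodes$id
  if (!is.na(net$root_id)) ids <- setdiff(ids, net$root_id)
  if (length(ids) < 2) stop("need at least 2 non-root nodes")
  d <- shortest_path_distances(net, sources = ids)
  d <- d[, as.character(ids), drop = FALSE]
  ut <- d[upper.tri(d)]
  mean(ifelse(is.finite(ut) & ut > 0, 1 / ut, 0))
}

#' Minimum spanning tree under transport resistance
#'
#' Kruskal's algorithm with the deterministic tie-break (resistance,
#' length, edge id) ascending. Because edge weights are the predicted
#' resistances, the MST is the lowest-resistance skeleton: the shortest
#' path for flow from the inoculum to the tips, used as the baseline for
#' cost and efficiency normalization.
#'
#' @param net a connected [mycelial_network].
#' @return a [mycelial_network] that is a spanning tree of `net`.
#' @export
minimum_spanning_tree <- function(net) {
  e <- net$edges
  if (!nrow(e)) stop("no edges")
  comp <- igraph::components(as_igraph(net))
  if (comp$no > 1) stop("network is disconnected; MST undefined")
  r <- edge_resistances(net)
  ord <- order(r, e$length, e$id)
  ids <- net$nodes$id
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(e))
  for (k in ord) {
    a <- find(match(e$from[k], ids))
    b <- find(match(e$to[k], ids))
    if (a != b) {
      parent[a] <- b
      keep[k] <- TRUE
    }
  }
  out <- net
  out$edges <- e[keep, , drop = FALSE]
  out$nodes$kind <- node_kinds(out)
  out
}

#' Meshedness coefficient
#'
#' Planar cycle density `(E - N + 1) / (2N - 5)` over the measured
#' structure (root edges and the root excluded): 0 for trees, 1 for
#' maximal planar graphs. E counts measured edges, N the nodes they
#' touch. The numerator is the cycle-space rank, so for a measured
#' structure that is a forest of C components (trunks joined only through
#' the inoculum) it generalizes to `E - N + C` and stays 0 for any
#' cycle-free network.
#'
#' @param net a [mycelial_network].
#' @return scalar in `[0, 1]` (can exceed 1 for non-planar multigraphs).
#' @export
meshedness <- function(net) {
  e <- measured_edges(net)
  n <- length(unique(c(e$from, e$to)))
  if (n < 3) stop("meshedness undefined for fewer than 3 nodes")
  g <- as_igraph(net, include_root_edges = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  cc <- igraph::components(g)$no
  (nrow(e) - n + cc) / (2 * n - 5)
}

#' Construction cost and efficiency relative to the MST
#'
#' `volume_mst` is total built hyphal volume (cylinders, `pi (w/2)^2 l`,
#' root edges excluded) over the same sum for the [minimum_spanning_tree];
#' `geff_mst` is [global_efficiency()] of the network over that of its
#' MST. Both are >= 1; large values mean heavy investment in cross-linking
#' beyond the minimal transport skeleton.
#'
#' @param net a [mycelial_network].
#' @return scalar ratio.
#' @export
volume_mst <- function(net) {
  mst <- minimum_spanning_tree(net)
  edge_volume(net) / edge_volume(mst)
}

edge_volume <- function(net) {
  e <- measured_edges(net)
  sum(pi * (e$width / 2)^2 * e$length)
}

#' @rdname volume_mst
#' @export
geff_mst <- function(net) {
  global_efficiency(net) / global_efficiency(minimum_spanning_tree(net))
}

#' Area-normalized root efficiencies
#'
#' Root efficiencies divided by [mycelial_area()], making them comparable
#' across colonies of different absolute size (the size-corrected variants
#' used when micro- and macro-scale mycelia share one ordination).
#'
#' @param net a root-attached [mycelial_network].
#' @return list with `R_eff_area` and `RT_eff_area`.
#' @export
area_normalized_efficiencies <- function(net) {
  a <- mycelial_area(net)
  if (!is.finite(a) || a <= 0) stop("degenerate mycelial area")
  list(R_eff_area = root_efficiency(net) / a,
       RT_eff_area = root_tip_efficiency(net) / a)
}

#' Network traits (6--10, plus normalized variants)
#'
#' @param net a root-attached [mycelial_network].
#' @return named list: `meshedness`, `R_eff`, `RT_eff`, `G_eff`,
#'   `G_eff_MST`, `volume_MST`, `R_eff_area`, `RT_eff_area`.
#' @export
network_traits <- function(net) {
  an <- area_normalized_efficiencies(net)
  list(meshedness = meshedness(net),
       R_eff = root_efficiency(net),
       RT_eff = root_tip_efficiency(net),
       G_eff = global_efficiency(net),
       G_eff_MST = geff_mst(net),
       volume_MST = volume_mst(net),
       R_eff_area = an$R_eff_area,
       RT_eff_area = an$RT_eff_area)
}
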