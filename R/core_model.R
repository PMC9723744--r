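#' Construct a mycelial network
#'
#' A `mycelial_network` is a spatially embedded weighted multigraph. Nodes
#' are hyphal tips, branching/anastomosis points (and pass-through points),
#' plus at most one designated "root" standing for the inoculum. Edges are
#' hyphal segments carrying a physical `length` and cross-section `width`;
#' synthetic inoculum connections are flagged `is_root_edge` and are
#' excluded from all morphological statistics.
#'
#' Parallel edges between the same node pair are permitted (two hyphae can
#' join the same pair of points); self-loops are dropped with a warning.
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y`
#'   (coordinates; micrometres for `scale_class = "micro"`, millimetres for
#'   `"macro"`), and optionally `kind`.
#' @param edges data.frame with columns `from`, `to` (node ids), `length`,
#'   `width` (both > 0), and optionally `id`, `is_root_edge`, and a
#'   `polyline` list-column of 2-column coordinate matrices tracing each
#'   hypha.
#' @param root_id id of the root node, or `NA` if no root is attached yet.
#' @param scale_class `"micro"` (single hyphae, Poiseuille resistance
#'   exponent 4) or `"macro"` (multi-hyphal cords, exponent 2).
#' @param pixel_size physical size of one pixel, for networks that came
#'   from images; `NA` otherwise.
#' @param metadata named list of free-form labels (species, replicate...).
#' @return object of class `mycelial_network`.
#' @seealso [load_network()], [attach_root()], [edge_resistance()]
#' @export
mycelial_network <- function(nodes, edges, root_id = NA_integer_,
                             scale_class = c("micro", "macro"),
                             pixel_size = NA_real_, metadata = list()) {
  scale_class <- match.arg(scale_class)
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "length", "width") %in% names(edges)))
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (is.null(edges$id)) edges$id <- seq_len(nrow(edges))
  edges$id <- as.integer(edges$id)
  if (nrow(edges) && anyDuplicated(edges$id)) stop("duplicate edge ids")
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (is.null(edges$is_root_edge)) {
    edges$is_root_edge <- rep(FALSE, nrow(edges))
  }
  if (is.null(edges$polyline)) edges$polyline <- replicate(nrow(edges), NULL)
  if (nrow(edges)) {
    bad <- !is.finite(edges$length) | edges$length <= 0 |
      !is.finite(edges$width) | edges$width <= 0
    if (any(bad)) {
      stop("edge(s) ", paste(which(bad), collapse = ", "),
           ": length and width must be finite and > 0")
    }
    loops <- edges$from == edges$to
    if (any(loops)) {
      warning(sum(loops), " self-loop edge(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    miss <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
    if (any(miss)) stop("edge endpoints reference unknown node ids")
  }
  net <- structure(
    list(nodes = nodes, edges = edges, root_id = as.integer(root_id),
         scale_class = scale_class, pixel_size = pixel_size,
         metadata = metadata),
    class = "mycelial_network")
  net$nodes$kind <- node_kinds(net)
  net
}

#' @export
print.mycelial_network <- function(x, ...) {
  nm <- sum(!x$edges$is_root_edge)
  cat(sprintf(
    "<mycelial_network> %d nodes, %d measured edges (+%d root edges), scale=%s, root=%s\n",
    nrow(x$nodes), nm, nrow(x$edges) - nm, x$scale_class,
    ifelse(is.na(x$root_id), "none", x$root_id)))
  invisible(x)
}

# node degrees counting every edge (root edges included unless excluded)
node_degree <- function(net, include_root_edges = TRUE) {
  e <- net$edges
  if (!include_root_edges) e <- e[!e$is_root_edge, , drop = FALSE]
  d <- integer(nrow(net$nodes))
  names(d) <- as.character(net$nodes$id)
  if (nrow(e)) {
    t1 <- table(factor(as.character(c(e$from, e$to)),
                       levels = as.character(net$nodes$id)))
    d <- as.integer(t1)
    names(d) <- as.character(net$nodes$id)
  }
  d
}

# classify nodes: root / tip (degree 1 over measured edges) /
# junction (>= 3) / body (degree 2, pass-through)
node_kinds <- function(net) {
  d <- node_degree(net, include_root_edges = FALSE)
  kind <- ifelse(d >= 3, "junction", ifelse(d == 1, "tip", "body"))
  if (!is.na(net$root_id)) kind[net$nodes$id == net$root_id] <- "root"
  unname(kind)
}

#' Measured (non-root) edges of a network
#'
#' Root edges are synthetic inoculum connections and are excluded from all
#' edge statistics; this accessor returns only the measured structure.
#'
#' @param net a [mycelial_network].
#' @return the edge data.frame restricted to measured edges.
#' @export
measured_edges <- function(net) {
  net$edges[!net$edges$is_root_edge, , drop = FALSE]
}

#' Transport resistance of a hyphal segment
#'
#' Resistance scales with length and inversely with radius to the power
#' `alpha`: `length / (width/2)^alpha`. `alpha = 4` models Poiseuille flow
#' through a single hypha (micro scale); `alpha = 2` models a cord whose
#' capacity grows with the number of constituent hyphae (macro scale).
#' The radius convention is `r = width/2`.
#'
#' @param length physical length(s), > 0.
#' @param width cross-section width(s), > 0.
#' @param params a [resistance_params()] object (or a scale-class string).
#' @return numeric resistance(s), arbitrary consistent units.
#' @examples
#' edge_resistance(2, 2, resistance_params("micro")) # r = 1 -> 2
#' edge_resistance(10, 4, resistance_params("micro")) # 10/2^4 = 0.625
#' @export
edge_resistance <- function(length, width, params = resistance_params("micro")) {
  if (is.character(params)) params <- resistance_params(params)
  if (any(!is.finite(length) | length <= 0) ||
      any(!is.finite(width) | width <= 0)) {
    stop("length and width must be finite and > 0")
  }
  length / (width / 2)^params$alpha
}

#' Resistance model parameters
#'
#' @param scale_class `"micro"` (alpha = 4) or `"macro"` (alpha = 2).
#' @return list with fields `alpha` and `radius_convention`.
#' @export
resistance_params <- function(scale_class = c("micro", "macro")) {
  scale_class <- match.arg(scale_class)
  list(alpha = if (scale_class == "micro") 4 else 2,
       radius_convention = "width/2")
}

# per-edge resistances for a network, using its own scale class
edge_resistances <- function(net) {
  if (!nrow(net$edges)) return(numeric(0))
  edge_resistance(net$edges$length, net$edges$width,
                  resistance_params(net$scale_class))
}

#' Load a mycelial network from an edge-list file
#'
#' Reads a CSV (or XLSX, via the readxl package) edge list with one row per
#' hyphal segment: endpoint coordinates, physical length, and width.
#' Endpoints closer than `merge_tol` are merged into a single node, so rows
#' that share a coordinate share a node.
#'
#' @param path CSV or XLSX file.
#' @param scale_class `"micro"` or `"macro"`.
#' @param columns named character vector mapping the required fields
#'   (`x1, y1, x2, y2, length, width`, optionally `is_root_edge`) to the
#'   file's header names.
#' @param merge_tol coordinate merge tolerance, physical units. Exported
#'   coordinates of shared nodes have identical provenance, so the default
#'   is tight.
#' @param metadata passed to [mycelial_network()].
#' @return a [mycelial_network] (no root node unless an `is_root_edge`
#'   column is present together with a `root_id` attribute convention; use
#'   [attach_root()] to add one).
#' @export
load_network <- function(path, scale_class = c("micro", "macro"),
                         columns = c(x1 = "x1", y1 = "y1", x2 = "x2",
                                     y2 = "y2", length = "length",
                                     width = "width"),
                         merge_tol = 1e-6, metadata = list()) {
  scale_class <- match.arg(scale_class)
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path))
  } else {
    read.csv(path, comment.char = "#", check.names = FALSE)
  }
  req <- c("x1", "y1", "x2", "y2", "length", "width")
  cols <- columns[req]
  if (any(is.na(cols)) || !all(cols %in% names(df))) {
    stop("edge list must contain columns: ",
         paste(cols[!cols %in% names(df)], collapse = ", "))
  }
  n <- nrow(df)
  if (!n) stop("edge list is empty")
  len <- as.numeric(df[[cols[["length"]]]])
  wid <- as.numeric(df[[cols[["width"]]]])
  bad <- which(!is.finite(len) | len <= 0 | !is.finite(wid) | wid <= 0)
  if (length(bad)) {
    stop("invalid length/width (must be > 0) in row(s): ",
         paste(bad, collapse = ", "))
  }
  pts <- rbind(cbind(as.numeric(df[[cols[["x1"]]]]),
                     as.numeric(df[[cols[["y1"]]]])),
               cbind(as.numeric(df[[cols[["x2"]]]]),
                     as.numeric(df[[cols[["y2"]]]])))
  idx <- merge_coordinates(pts, merge_tol)
  uid <- !duplicated(idx)
  nodes <- data.frame(id = seq_len(sum(uid)),
                      x = pts[uid, 1][order(idx[uid])],
                      y = pts[uid, 2][order(idx[uid])])
  edges <- data.frame(from = idx[seq_len(n)], to = idx[n + seq_len(n)],
                      length = len, width = wid)
  rootcol <- if ("is_root_edge" %in% names(columns)) {
    columns[["is_root_edge"]]
  } else {
    NA_character_
  }
  if (!is.na(rootcol) && rootcol %in% names(df)) {
    edges$is_root_edge <- as.logical(df[[rootcol]])
  }
  # polyline-traced lengths may exceed the chord; never the other way round
  chord <- sqrt((pts[seq_len(n), 1] - pts[n + seq_len(n), 1])^2 +
                (pts[seq_len(n), 2] - pts[n + seq_len(n), 2])^2)
  short <- which(len < chord * (1 - 1e-6) - merge_tol)
  if (length(short)) {
    warning("row(s) ", paste(short, collapse = ", "),
            ": length below Euclidean endpoint distance")
  }
  net <- mycelial_network(nodes, edges, scale_class = scale_class,
                          metadata = metadata)
  if (any(net$edges$is_root_edge)) {
    # a saved root column implies the root node is the one all root edges share
    re <- net$edges[net$edges$is_root_edge, ]
    cand <- intersect(unique(c(re$from)), unique(c(re$to)))
    shared <- c(re$from, re$to)[duplicated(c(re$from, re$to))]
    rid <- if (nrow(re) == 1) re$from[1] else unique(shared)[1]
    if (length(rid) == 1 && !is.na(rid)) {
      net$root_id <- as.integer(rid)
      net$nodes$kind <- node_kinds(net)
    }
  }
  net
}

# single-linkage clustering of coordinates within tol (union-find over a
# sliding x-window); returns an integer cluster index per row, clusters
# numbered by first appearance
merge_coordinates <- function(pts, tol) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(pts[, 1], pts[, 2])
  xs <- pts[ord, 1]
  ys <- pts[ord, 2]
  j0 <- 1L
  for (j in seq_len(n)) {
    while (xs[j] - xs[j0] > tol) j0 <- j0 + 1L
    if (j0 < j) {
      cand <- j0:(j - 1L)
      cand <- cand[abs(ys[cand] - ys[j]) <= tol]
      cand <- cand[(xs[cand] - xs[j])^2 + (ys[cand] - ys[j])^2 <= tol^2]
      for (h in cand) {
        a <- find(ord[h])
        b <- find(ord[j])
        if (a != b) parent[a] <- b
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Attach the inoculum (root) node
#'
#' The mycelium inside the inoculum cannot be resolved by imaging, so it is
#' modelled as a single central node connected to each supplied boundary
#' node by a synthetic edge whose length is the Euclidean distance and
#' whose width is the maximum measured edge width — a deliberately strong
#' connection that keeps the network whole without biasing edge statistics
#' (root edges are excluded from those).
#'
#' @param net a [mycelial_network] without a root.
#' @param root_position numeric `c(x, y)` of the inoculum centre.
#' @param boundary_nodes ids of the nodes where hyphae meet the inoculum
#'   rim.
#' @return the network with one root node and flagged root edges.
#' @export
attach_root <- function(net, root_position, boundary_nodes) {
  if (!is.na(net$root_id)) stop("network already has a root node")
  if (!length(boundary_nodes)) stop("boundary_nodes must be nonempty")
  boundary_nodes <- as.integer(boundary_nodes)
  if (!all(boundary_nodes %in% net$nodes$id)) {
    stop("unknown boundary node id(s)")
  }
  me <- measured_edges(net)
  if (!nrow(me)) stop("network has no measured edges")
  wmax <- max(me$width)
  rid <- max(net$nodes$id) + 1L
  bn <- net$nodes[match(boundary_nodes, net$nodes$id), ]
  lens <- sqrt((bn$x - root_position[1])^2 + (bn$y - root_position[2])^2)
  lens <- pmax(lens, 1e-9) # boundary node may sit exactly at the centre
  newe <- data.frame(from = rid, to = boundary_nodes, length = lens,
                     width = wmax, is_root_edge = TRUE,
                     id = max(net$edges$id, 0L) + seq_along(boundary_nodes))
  newe$polyline <- replicate(nrow(newe), NULL)
  nodes <- rbind(net$nodes[, c("id", "x", "y")],
                 data.frame(id = rid, x = root_position[1],
                            y = root_position[2]))
  edges <- rbind(net$edges[, c("from", "to", "length", "width",
                               "is_root_edge", "id", "polyline")],
                 newe[, c("from", "to", "length", "width", "is_root_edge",
                          "id", "polyline")])
  out <- mycelial_network(nodes, edges, root_id = rid,
                          scale_class = net$scale_class,
                          pixel_size = net$pixel_size,
                          metadata = net$metadata)
  comp <- igraph::components(as_igraph(out))
  if (comp$no > 1) {
    rootc <- comp$membership[as.character(out$root_id)]
    orphan <- names(comp$membership)[comp$membership != rootc]
    warning("network not root-connected; ", length(orphan),
            " node(s) in components without a boundary node: ",
            paste(utils::head(orphan, 10), collapse = ", "))
  }
  out
}

#' Convert to an igraph object
#'
#' @param net a [mycelial_network].
#' @param weight `"resistance"` (the transport model), `"length"`, or
#'   `"none"`.
#' @param include_root_edges keep the synthetic inoculum edges (they are
#'   part of the transport path graph) or drop them (topology of the
#'   measured structure only).
#' @return an igraph graph whose vertex names are node ids and with edge
#'   attributes `eid`, `length`, `width`, `is_root_edge` (+ `weight`).
#' @export
as_igraph <- function(net, weight = c("resistance", "length", "none"),
                      include_root_edges = TRUE) {
  weight <- match.arg(weight)
  e <- net$edges
  if (!include_root_edges) e <- e[!e$is_root_edge, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$from), to = as.character(e$to),
               eid = e$id, length = e$length, width = e$width,
               is_root_edge = e$is_root_edge),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$id),
                          x = net$nodes$x, y = net$nodes$y,
                          kind = net$nodes$kind))
  if (weight == "resistance") {
    igraph::E(g)$weight <- edge_resistance(
      e$length, e$width, resistance_params(net$scale_class))
  } else if (weight == "length") {
    igraph::E(g)$weight <- e$length
  }
  g
}

#' Write a network to disk
#'
#' `csv` writes the edge-list schema read by [load_network()] (with a
#' commented metadata header); `graphml` writes an igraph-compatible
#' GraphML file with `length`, `width`, `is_root_edge` edge attributes and
#' `x`, `y`, `kind` node attributes. The csv round trip is lossless up to
#' node id relabelling.
#'
#' @param net a [mycelial_network].
#' @param path output file.
#' @param format `"csv"` or `"graphml"` (no xlsx writer is available).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "graphml", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("unsupported format: xlsx (no xlsx writer available; use csv)")
  }
  if (format == "graphml") {
    g <- as_igraph(net, weight = "none")
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  e <- net$edges
  n <- net$nodes
  i1 <- match(e$from, n$id)
  i2 <- match(e$to, n$id)
  df <- data.frame(node1 = e$from, node2 = e$to,
                   length = e$length, width = e$width,
                   x1 = n$x[i1], y1 = n$y[i1], x2 = n$x[i2], y2 = n$y[i2],
                   is_root_edge = e$is_root_edge)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# myconet edge list; scale_class=%s; root_id=%s",
                     net$scale_class,
                     ifelse(is.na(net$root_id), "NA", net$root_id)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Validate network invariants
#'
#' Checks endpoint integrity, positivity of lengths/widths, the single-root
#' invariant, tip degrees, and (if a root is present) root-connectivity.
#'
#' @param net a [mycelial_network].
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "mycelial_network"))
  e <- net$edges
  if (nrow(e)) {
    stopifnot(all(e$length > 0), all(e$width > 0),
              all(e$from %in% net$nodes$id), all(e$to %in% net$nodes$id))
  }
  if (sum(net$nodes$kind == "root") > 1) stop("more than one root node")
  if (!is.na(net$root_id)) {
    if (!net$root_id %in% net$nodes$id) stop("root_id not a node")
    comp <- igraph::components(as_igraph(net))
    if (comp$no > 1) stop("network is not connected after root attachment")
  }
  d <- node_degree(net, include_root_edges = FALSE)
  tips <- net$nodes$kind == "tip"
  if (any(d[tips] != 1)) stop("tip nodes must have measured degree 1")
  invisible(TRUE)
}
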