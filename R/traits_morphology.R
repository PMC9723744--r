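#' Mycelial area (convex hull)
#'
#' Area of the convex hull of all measured node coordinates. The root node
#' and root-edge geometry are excluded: they are synthetic. The hull is
#' parameter-free and matches the "enclosed area" notion used for length
#' density.
#'
#' @param net a [mycelial_network].
#' @return hull area in squared coordinate units.
#' @export
mycelial_area <- function(net) {
  nd <- net$nodes[net$nodes$kind != "root", , drop = FALSE]
  me <- measured_edges(net)
  nd <- nd[nd$id %in% c(me$from, me$to), , drop = FALSE]
  if (nrow(nd) < 3) stop("need at least 3 measured nodes for an area")
  h <- chull(nd$x, nd$y)
  if (length(h) < 3) stop("nodes are collinear; area undefined")
  polygon_area(cbind(nd$x[h], nd$y[h]))
}

# shoelace; vertices in order, any orientation
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Branching angles
#'
#' For every degree-3 junction the branching angle is the angle between
#' the two daughter edges, i.e. the two incident edges that are *not* the
#' most root-proximal one (the parent, identified as the incident edge
#' whose far endpoint has the smallest resistance distance to the root; if
#' no root is attached, the longest incident edge is taken as parent).
#' Edge directions are chords from the junction towards each edge's first
#' polyline waypoint (or its far endpoint when no polyline is stored).
#' Junctions of degree 4+ contribute their minimum pairwise daughter
#' angle.
#'
#' @param net a [mycelial_network].
#' @return numeric vector of angles in degrees, in (0, 180].
#' @export
branching_angles <- function(net) {
  juncs <- net$nodes$id[net$nodes$kind == "junction"]
  if (!length(juncs)) return(numeric(0))
  e <- measured_edges(net)
  rootdist <- NULL
  if (!is.na(net$root_id)) {
    g <- as_igraph(net, weight = "resistance")
    dmat <- igraph::distances(g, v = as.character(net$root_id))
    rootdist <- setNames(as.numeric(dmat), colnames(dmat))
  }
  nid <- net$nodes$id
  out <- numeric(0)
  for (v in juncs) {
    inc <- which(e$from == v | e$to == v)
    if (length(inc) < 3) next
    far <- ifelse(e$from[inc] == v, e$to[inc], e$from[inc])
    vx <- net$nodes$x[match(v, nid)]
    vy <- net$nodes$y[match(v, nid)]
    dirs <- t(vapply(seq_along(inc), function(q) {
      pl <- e$polyline[[inc[q]]]
      if (!is.null(pl) && nrow(pl) > 2) {
        # orient polyline to start at the junction
        if (sum((pl[1, ] - c(vx, vy))^2) >
            sum((pl[nrow(pl), ] - c(vx, vy))^2)) {
          pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
        }
        p <- pl[2, ]
      } else {
        i <- match(far[q], nid)
        p <- c(net$nodes$x[i], net$nodes$y[i])
      }
      d <- p - c(vx, vy)
      d / max(sqrt(sum(d^2)), 1e-12)
    }, numeric(2)))
    parent <- if (!is.null(rootdist)) {
      which.min(rootdist[as.character(far)])
    } else {
      which.max(e$length[inc])
    }
    dau <- setdiff(seq_along(inc), parent)
    if (length(dau) < 2) next
    prs <- combn(dau, 2)
    angs <- apply(prs, 2, function(pr) {
      cosang <- sum(dirs[pr[1], ] * dirs[pr[2], ])
      acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    })
    out <- c(out, min(angs))
  }
  out[out > 0]
}

#' Morphological traits (1--5)
#'
#' Mean edge (hyphal) length, mean tip-edge width, mean main-edge width,
#' mean branching angle, and edge length density (total measured length
#' over [mycelial_area()]). Tip edges are incident to a tip node; main
#' edges join two non-tip nodes. Root edges never enter any statistic.
#'
#' @param net a [mycelial_network] with widths.
#' @return named list: `mean_edge_length`, `mean_tip_width`,
#'   `mean_main_width`, `mean_branch_angle`, `length_density`. Traits
#'   whose support is empty (e.g. no main edges) are `NA`.
#' @export
morphological_traits <- function(net) {
  e <- measured_edges(net)
  if (!nrow(e)) stop("no measured edges")
  tipids <- net$nodes$id[net$nodes$kind == "tip"]
  istip <- e$from %in% tipids | e$to %in% tipids
  ang <- branching_angles(net)
  area <- tryCatch(mycelial_area(net), error = function(e) NA_real_)
  list(
    mean_edge_length = mean(e$length),
    mean_tip_width = if (any(istip)) mean(e$width[istip]) else NA_real_,
    mean_main_width = if (any(!istip)) mean(e$width[!istip]) else NA_real_,
    mean_branch_angle = if (length(ang)) mean(ang) else NA_real_,
    length_density = sum(e$length) / area  # NA when the hull degenerates
  )
}

#' Per-edge distribution table
#'
#' One row per measured edge with its length, width, and incident-kind
#' classification (`tip` or `main`), for histogram and moment export.
#'
#' @param net a [mycelial_network].
#' @return data.frame with columns `edge_id`, `length`, `width`, `kind`.
#' @export
edge_distributions <- function(net) {
  e <- measured_edges(net)
  tipids <- net$nodes$id[net$nodes$kind == "tip"]
  istip <- e$from %in% tipids | e$to %in% tipids
  data.frame(edge_id = e$id, length = e$length, width = e$width,
             kind = ifelse(istip, "tip", "main"))
}
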