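#' Extraction parameters
#'
#' Controls the image-to-network pipeline: background correction, optional
#' curvilinear ridge enhancement, segmentation, skeletonization, graph
#' tracing, width estimation, and spur pruning.
#'
#' @param pixel_size physical units per pixel (required to produce
#'   physical lengths/widths).
#' @param background_radius structuring-element radius (px) for the
#'   morphological-opening background estimate.
#' @param enhancement `"none"` (threshold the background-corrected
#'   intensity; best for clean, evenly lit images) or `"ridge"`
#'   (multiscale Hessian ridge filter; intensity-independent detection of
#'   curvilinear structures).
#' @param ridge_scales smoothing scales (px) for the ridge filter.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold on the enhanced image when
#'   `threshold_method = "fixed"`.
#' @param invert set when hyphae are dark on a bright background
#'   (bright-field); the image is inverted before processing.
#' @param min_object_px connected foreground components smaller than this
#'   are discarded as noise.
#' @param node_merge_radius px radius within which adjacent junction-pixel
#'   clusters are collapsed into one node.
#' @param min_spur_length physical length below which terminal branches
#'   are pruned (skeletonization artifacts); default 3 pixels.
#' @return an `extraction_params` list.
#' @export
extraction_params <- function(pixel_size = 1, background_radius = 20,
                              enhancement = c("none", "ridge"),
                              ridge_scales = c(1, 2, 3),
                              threshold_method = c("otsu", "fixed"),
                              fixed_threshold = NULL, invert = FALSE,
                              min_object_px = 30, node_merge_radius = 3,
                              min_spur_length = 3 * pixel_size) {
  stopifnot(pixel_size > 0, background_radius > 0, node_merge_radius > 0)
  structure(list(pixel_size = pixel_size,
                 background_radius = background_radius,
                 enhancement = match.arg(enhancement),
                 ridge_scales = ridge_scales,
                 threshold_method = match.arg(threshold_method),
                 fixed_threshold = fixed_threshold, invert = invert,
                 min_object_px = min_object_px,
                 node_merge_radius = node_merge_radius,
                 min_spur_length = min_spur_length),
            class = c("extraction_params", "list"))
}

# shift a matrix by (dr, dc), padding with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Segment hyphae from a grayscale image
#'
#' Background is estimated by a morphological opening with a disc of
#' `background_radius` and subtracted (top-hat), so thin bright structures
#' survive while slow illumination gradients are removed. The corrected
#' image (or its multiscale Hessian ridge response) is thresholded by
#' Otsu's method, floored at median + 5 MAD so that structure-free images
#' yield an empty mask rather than thresholded noise. Components smaller
#' than `min_object_px` are discarded.
#'
#' @param image numeric matrix (any intensity range) or a
#'   [render_image()] result.
#' @param params an [extraction_params()] object.
#' @return logical matrix mask, `TRUE` = hyphae.
#' @export
preprocess <- function(image, params = extraction_params()) {
  img <- if (inherits(image, "myc_render")) image$image else image
  img <- as.matrix(img)
  rng <- range(img)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    stop("constant image: no structure to segment")
  }
  img <- (img - rng[1]) / diff(rng)
  if (isTRUE(params$invert)) img <- 1 - img
  brush <- EBImage::makeBrush(2 * round(params$background_radius) + 1, "disc")
  bg <- as.matrix(EBImage::opening(EBImage::Image(img), brush))
  th <- pmax(img - bg, 0)
  resp <- if (params$enhancement == "ridge") ridge_response(th, params$ridge_scales) else th
  if (params$threshold_method == "fixed") {
    if (is.null(params$fixed_threshold)) stop("fixed_threshold not set")
    level <- params$fixed_threshold
  } else {
    level <- max(EBImage::otsu(EBImage::Image(resp), range = c(0, 1)),
                 median(resp) + 5 * mad(resp))
  }
  mask <- resp > level
  if (!any(mask)) stop("empty mask: no foreground found")
  if (params$min_object_px > 0) {
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (!any(mask)) stop("empty mask: all components below min_object_px")
  mask
}

# gamma-normalized multiscale Hessian ridge response (bright ridges)
ridge_response <- function(img, scales = c(1, 2, 3)) {
  best <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = s))
    dxx <- shift_mat(sm, 0, -1) - 2 * sm + shift_mat(sm, 0, 1)
    dyy <- shift_mat(sm, -1, 0) - 2 * sm + shift_mat(sm, 1, 0)
    dxy <- (shift_mat(sm, 1, 1) + shift_mat(sm, -1, -1) -
            shift_mat(sm, 1, -1) - shift_mat(sm, -1, 1)) / 4
    lmin <- (dxx + dyy) / 2 - sqrt(((dxx - dyy) / 2)^2 + dxy^2)
    best <- pmax(best, s^2 * pmax(-lmin, 0))
  }
  if (max(best) > 0) best <- best / max(best)
  best
}

#' Skeletonize a binary mask
#'
#' Topology-preserving Zhang–Suen thinning to a one-pixel-wide skeleton.
#' The skeleton is always a subset of the mask.
#'
#' @param mask logical matrix.
#' @return logical matrix skeleton.
#' @export
skeletonize_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!any(m == 1)) return(mask & FALSE)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
           (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
           (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1 & b >= 2 & b <= 6 & a == 1
      if (pass == 1) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Convert a skeleton to a network graph
#'
#' Skeleton pixels with one neighbour become tip nodes; pixels with three
#' or more neighbours are junction pixels, clustered (8-connectivity, then
#' single linkage within `node_merge_radius`) and collapsed to their
#' centroid. Pixel chains between nodes become edges whose length is the
#' polyline arc length (diagonal steps count sqrt(2)) times `pixel_size`.
#' Widths are set to a placeholder of 1 until [estimate_widths()] runs.
#'
#' @param skeleton logical matrix from [skeletonize_mask()].
#' @param params an [extraction_params()] object.
#' @return a [mycelial_network] (micro scale) with polylines, no widths.
#' @export
skeleton_to_graph <- function(skeleton, params = extraction_params()) {
  ps <- params$pixel_size
  sk <- skeleton
  if (!any(sk)) stop("empty skeleton")
  nbk <- Reduce(`+`, lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
                            function(d) shift_mat(sk * 1L, d[1], d[2])))
  nb <- matrix(nbk, nrow(sk), ncol(sk))
  iso <- sk & nb == 0
  sk[iso] <- FALSE                      # isolated pixels carry no structure
  tipmask <- sk & nb == 1
  juncmask <- sk & nb >= 3
  if (!any(tipmask) && !any(juncmask)) {
    warning("skeleton is a closed loop with no tips or junctions; ",
            "anchoring one node arbitrarily")
    first <- which(sk)[1]
    juncmask[first] <- TRUE
  }

  nr <- nrow(sk)
  lin <- function(i, j) (j - 1L) * nr + i
  # cluster junction pixels: connected components, then centroid linkage
  jidx <- which(juncmask, arr.ind = TRUE)
  nodemap <- integer(nr * ncol(sk))      # pixel linear index -> node id
  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0))
  nid <- 0L
  if (nrow(jidx)) {
    jl <- lin(jidx[, 1], jidx[, 2])
    g <- igraph::make_empty_graph(n = nrow(jidx), directed = FALSE)
    pairs <- NULL
    for (d in list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
      ri <- jidx[, 1] + d[1]
      ci <- jidx[, 2] + d[2]
      inb <- ri >= 1 & ri <= nr & ci >= 1 & ci <= ncol(sk)
      hit <- rep(NA_integer_, nrow(jidx))
      hit[inb] <- match(lin(ri[inb], ci[inb]), jl)
      ok <- which(!is.na(hit))
      if (length(ok)) pairs <- rbind(pairs, cbind(ok, hit[ok]))
    }
    if (!is.null(pairs)) g <- igraph::add_edges(g, t(pairs))
    comp <- igraph::components(g)$membership
    cx <- tapply(jidx[, 2], comp, mean)
    cy <- tapply(jidx[, 1], comp, mean)
    cl <- merge_coordinates(cbind(as.numeric(cx), as.numeric(cy)),
                            params$node_merge_radius)
    ncl <- max(cl)
    ccx <- tapply(jidx[, 2], cl[comp], mean)
    ccy <- tapply(jidx[, 1], cl[comp], mean)
    for (k in seq_len(ncl)) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, x = ccx[[k]] * ps,
                                       y = ccy[[k]] * ps))
    }
    nodemap[jl] <- cl[comp]
  }
  tidx <- which(tipmask, arr.ind = TRUE)
  if (nrow(tidx)) {
    tl <- lin(tidx[, 1], tidx[, 2])
    for (k in seq_len(nrow(tidx))) {
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, x = tidx[k, 2] * ps,
                                       y = tidx[k, 1] * ps))
      nodemap[tl[k]] <- nid
    }
  }

  # corner-count corrected chain length (Vossepoel-Smeulders): raw chain
  # codes overestimate smooth arcs by up to ~8% on diagonals; weighting
  # axis steps, diagonal steps and direction changes removes the bias
  chain_length <- function(pl) {
    n <- nrow(pl)
    if (n < 2) return(0)
    dx <- diff(pl[, 1]); dy <- diff(pl[, 2])
    adx <- abs(dx); ady <- abs(dy)
    unit <- function(v) v > 0.5 & v < 1.5
    diag <- unit(adx) & unit(ady)
    axis <- (adx < 0.5 & unit(ady)) | (ady < 0.5 & unit(adx))
    other <- !diag & !axis              # centroid-anchor jumps: Euclidean
    corners <- if (n > 2) sum(abs(diff(dx)) + abs(diff(dy)) > 0.5) else 0
    0.980 * sum(axis) + 1.406 * sum(diag) - 0.091 * corners +
      sum(sqrt(dx[other]^2 + dy[other]^2))
  }

  nbrs_of <- function(i, j) {
    di <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dj <- c(-1, 0, 1, -1, 1, -1, 0, 1)
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= ncol(sk)
    ii <- ii[ok]; jj <- jj[ok]
    keep <- sk[cbind(ii, jj)]
    cbind(ii[keep], jj[keep])
  }

  visited <- logical(nr * ncol(sk))
  ef <- integer(0); et <- integer(0)
  plist <- list()
  add_chain <- function(a, b, path) {
    ef[length(ef) + 1L] <<- a
    et[length(et) + 1L] <<- b
    plist[[length(plist) + 1L]] <<- path
  }
  nodepix <- rbind(jidx, tidx)
  for (k in seq_len(nrow(nodepix))) {
    i0 <- nodepix[k, 1]; j0 <- nodepix[k, 2]
    a <- nodemap[lin(i0, j0)]
    for (q in seq_len(nrow(nbrs_of(i0, j0)))) {
      nbq <- nbrs_of(i0, j0)[q, , drop = FALSE]
      i1 <- nbq[1]; j1 <- nbq[2]
      b <- nodemap[lin(i1, j1)]
      if (b > 0L) {
        # direct node-node contact: emit once, skip intra-cluster contacts
        if (b != a && lin(i0, j0) < lin(i1, j1)) {
          add_chain(a, b, cbind(c(j0, j1), c(i0, i1)))
        }
        next
      }
      if (visited[lin(i1, j1)]) next
      path_i <- c(i0, i1); path_j <- c(j0, j1)
      visited[lin(i1, j1)] <- TRUE
      prev_i <- i0; prev_j <- j0; cur_i <- i1; cur_j <- j1
      repeat {
        nxt <- nbrs_of(cur_i, cur_j)
        nxt <- nxt[!(nxt[, 1] == prev_i & nxt[, 2] == prev_j), ,
                   drop = FALSE]
        if (!nrow(nxt)) { b2 <- 0L; break }   # dead end (shouldn't happen)
        isnode <- nodemap[lin(nxt[, 1], nxt[, 2])] > 0L
        if (any(isnode)) {
          w <- which(isnode)[1]
          path_i <- c(path_i, nxt[w, 1]); path_j <- c(path_j, nxt[w, 2])
          b2 <- nodemap[lin(nxt[w, 1], nxt[w, 2])]
          break
        }
        free <- which(!visited[lin(nxt[, 1], nxt[, 2])])
        if (!length(free)) { b2 <- 0L; break }
        w <- free[1]
        prev_i <- cur_i; prev_j <- cur_j
        cur_i <- nxt[w, 1]; cur_j <- nxt[w, 2]
        visited[lin(cur_i, cur_j)] <- TRUE
        path_i <- c(path_i, cur_i); path_j <- c(path_j, cur_j)
      }
      if (b2 > 0L) add_chain(a, b2, cbind(path_j, path_i))
    }
  }
  if (!length(ef)) stop("no edges traced from skeleton")
  # a chain that returns to its own cluster is a real anastomosis loop:
  # split it at its midpoint into a parallel edge pair so neither its
  # length nor its cycle is lost; degenerate few-pixel loops are dropped
  selfch <- which(ef == et)
  dropped <- 0L
  for (k in selfch) {
    pl <- plist[[k]]
    if (nrow(pl) >= 5) {
      mid <- ceiling(nrow(pl) / 2)
      nid <- nid + 1L
      nodes <- rbind(nodes, data.frame(id = nid, x = pl[mid, 1] * ps,
                                       y = pl[mid, 2] * ps))
      add_chain(nid, et[k], pl[mid:nrow(pl), , drop = FALSE])
      et[k] <- nid
      plist[[k]] <- pl[seq_len(mid), , drop = FALSE]
    } else {
      dropped <- dropped + 1L
    }
  }
  if (dropped) warning(dropped, " degenerate skeleton loop(s) dropped")
  keep <- ef != et
  ef <- ef[keep]; et <- et[keep]; plist <- plist[keep]

  lens <- vapply(seq_along(plist), function(k) {
    pl <- plist[[k]]
    # anchor chain ends at the (possibly centroid-averaged) node positions
    pl[1, ] <- c(nodes$x[ef[k]] / ps, nodes$y[ef[k]] / ps)
    pl[nrow(pl), ] <- c(nodes$x[et[k]] / ps, nodes$y[et[k]] / ps)
    plist[[k]] <<- pl * ps
    chain_length(pl) * ps
  }, numeric(1))
  # an arc can never be shorter than the chord between its endpoints
  chord <- sqrt((nodes$x[ef] - nodes$x[et])^2 +
                  (nodes$y[ef] - nodes$y[et])^2)
  lens <- pmax(lens, chord, ps * 1e-3)
  edges <- data.frame(from = ef, to = et, length = lens, width = 1)
  edges$polyline <- plist
  mycelial_network(nodes, edges, scale_class = "micro", pixel_size = ps,
                   metadata = list(widths_estimated = FALSE))
}

#' Estimate edge widths by distance transform
#'
#' Width is a granulometry-style estimate: twice the median Euclidean
#' distance-transform value of the segmentation mask, sampled along each
#' edge's polyline (minus half a pixel, since the transform measures to the
#' nearest background pixel centre), times `pixel_size`. The median is
#' robust to inflation near junctions.
#'
#' @param net network with polylines (from [skeleton_to_graph()]).
#' @param mask the segmentation the skeleton came from.
#' @param pixel_size physical units per pixel.
#' @return the network with measured edge widths filled in.
#' @export
estimate_widths <- function(net, mask, pixel_size = net$pixel_size) {
  edt <- as.matrix(EBImage::distmap(EBImage::Image(mask * 1)))
  nr <- nrow(mask); nc <- ncol(mask)
  wfloor <- 0.5 * pixel_size
  for (k in seq_len(nrow(net$edges))) {
    if (net$edges$is_root_edge[k]) next
    pl <- net$edges$polyline[[k]]
    if (is.null(pl)) next
    jj <- pmin(pmax(round(pl[, 1] / pixel_size), 1), nc)
    ii <- pmin(pmax(round(pl[, 2] / pixel_size), 1), nr)
    v <- edt[cbind(ii, jj)]
    v <- v[v > 0]                        # in-mask samples only
    if (!length(v)) {
      warning("edge ", net$edges$id[k],
              ": polyline outside mask; width floored")
      net$edges$width[k] <- wfloor
    } else {
      net$edges$width[k] <- max((2 * median(v) - 0.5) * pixel_size, wfloor)
    }
  }
  net$metadata$widths_estimated <- TRUE
  net
}

#' Prune spurs and dissolve pass-through nodes
#'
#' Terminal edges shorter than `min_spur_length` (skeletonization
#' artifacts at junctions) are removed iteratively; degree-2 nodes left
#' behind are dissolved by concatenating their two incident edges (lengths
#' summed, widths length-weighted, polylines joined).
#'
#' @param net a [mycelial_network].
#' @param params an [extraction_params()] (only `min_spur_length` is
#'   used).
#' @return the cleaned network.
#' @export
prune_and_clean <- function(net, params = extraction_params()) {
  min_spur <- params$min_spur_length
  repeat {
    e <- net$edges
    d <- node_degree(net, include_root_edges = FALSE)
    rooted <- unique(c(e$from[e$is_root_edge], e$to[e$is_root_edge]))
    isdeg1 <- function(v) d[as.character(v)] == 1 & !(v %in% rooted) &
      !(v %in% net$root_id)
    spur <- !e$is_root_edge & e$length < min_spur &
      (isdeg1(e$from) | isdeg1(e$to)) &
      !(isdeg1(e$from) & isdeg1(e$to))   # keep isolated two-tip edges
    if (!any(spur)) break
    net$edges <- e[!spur, , drop = FALSE]
    net <- drop_orphans(net)
  }
  dissolve_pass_through(net)
}

drop_orphans <- function(net) {
  used <- unique(c(net$edges$from, net$edges$to, net$root_id))
  net$nodes <- net$nodes[net$nodes$id %in% used, , drop = FALSE]
  net$nodes$kind <- node_kinds(net)
  net
}

# dissolve nodes of measured degree 2 with no root edges
dissolve_pass_through <- function(net) {
  repeat {
    e <- net$edges
    d <- node_degree(net, include_root_edges = FALSE)
    dr <- node_degree(net, include_root_edges = TRUE)
    rid <- ifelse(is.na(net$root_id), -1L, net$root_id)
    cand <- net$nodes$id[d == 2 & dr == 2 & net$nodes$id != rid]
    progressed <- FALSE
    for (v in cand) {
      inc <- which(e$from == v | e$to == v)
      if (length(inc) != 2) next       # parallel loop pair at v: leave it
      a <- setdiff(c(e$from[inc[1]], e$to[inc[1]]), v)
      b <- setdiff(c(e$from[inc[2]], e$to[inc[2]]), v)
      if (!length(a) || !length(b)) next
      if (a[1] == b[1]) next   # loop anchor: merging would lose the cycle
      l1 <- e$length[inc[1]]; l2 <- e$length[inc[2]]
      pl <- join_polylines(e$polyline[[inc[1]]], e$polyline[[inc[2]]],
                           net, a[1], v, b[1])
      newrow <- e[inc[1], , drop = FALSE]
      newrow$from <- a[1]; newrow$to <- b[1]
      newrow$length <- l1 + l2
      newrow$width <- (e$width[inc[1]] * l1 + e$width[inc[2]] * l2) /
        (l1 + l2)
      newrow$polyline <- list(pl)
      e <- rbind(e[-inc, , drop = FALSE], newrow)
      if (newrow$from == newrow$to) e <- e[-nrow(e), , drop = FALSE]
      net$edges <- e
      net <- drop_orphans(net)
      progressed <- TRUE
      break
    }
    if (!progressed) break
  }
  net$nodes$kind <- node_kinds(net)
  net
}

join_polylines <- function(p1, p2, net, a, v, b) {
  pt <- function(id) {
    i <- match(id, net$nodes$id)
    c(net$nodes$x[i], net$nodes$y[i])
  }
  if (is.null(p1)) p1 <- rbind(pt(a), pt(v))
  if (is.null(p2)) p2 <- rbind(pt(v), pt(b))
  # orient both a -> v -> b
  if (sum((p1[1, ] - pt(a))^2) > sum((p1[nrow(p1), ] - pt(a))^2)) {
    p1 <- p1[rev(seq_len(nrow(p1))), , drop = FALSE]
  }
  if (sum((p2[nrow(p2), ] - pt(b))^2) > sum((p2[1, ] - pt(b))^2)) {
    p2 <- p2[rev(seq_len(nrow(p2))), , drop = FALSE]
  }
  rbind(p1, p2[-1, , drop = FALSE])
}

#' Extract a network from an image
#'
#' Full pipeline: [preprocess()] (background correction, optional ridge
#' enhancement, segmentation), [skeletonize_mask()],
#' [skeleton_to_graph()], [estimate_widths()], [prune_and_clean()].
#' If `inoculum` is given (list with `center` = physical `c(x, y)` and
#' `radius`), the unresolvable inoculum disk is masked out of the graph
#' and the root node is attached at its centre to the edges that touched
#' it.
#'
#' @param image numeric matrix or [render_image()] result.
#' @param params an [extraction_params()] object (set `pixel_size`!).
#' @param inoculum optional list(center = c(x, y), radius = r), physical
#'   units.
#' @return a [mycelial_network].
#' @export
extract_network <- function(image, params = extraction_params(),
                            inoculum = NULL) {
  mask <- preprocess(image, params)
  sk <- skeletonize_mask(mask)
  net <- skeleton_to_graph(sk, params)
  net <- estimate_widths(net, mask, params$pixel_size)
  net <- prune_and_clean(net, params)
  net <- extend_tip_edges(net)
  net <- junction_merge_correction(net)
  if (!is.null(inoculum)) {
    net <- mask_inoculum(net, inoculum$center, inoculum$radius)
  }
  net
}

# thinning retracts each free hyphal end by about half the local width;
# compensate by extending tip edges outward along their end direction
extend_tip_edges <- function(net) {
  tips <- net$nodes$id[net$nodes$kind == "tip"]
  for (v in tips) {
    k <- which((net$edges$from == v | net$edges$to == v) &
                 !net$edges$is_root_edge)
    if (length(k) != 1) next
    ext <- net$edges$width[k] / 2
    i <- match(v, net$nodes$id)
    pl <- net$edges$polyline[[k]]
    if (!is.null(pl) && nrow(pl) >= 2) {
      # direction of the last polyline step pointing out of the colony
      endfirst <- sum((pl[1, ] - c(net$nodes$x[i], net$nodes$y[i]))^2) <
        sum((pl[nrow(pl), ] - c(net$nodes$x[i], net$nodes$y[i]))^2)
      d <- if (endfirst) pl[1, ] - pl[2, ] else
        pl[nrow(pl), ] - pl[nrow(pl) - 1, ]
    } else {
      u <- setdiff(c(net$edges$from[k], net$edges$to[k]), v)
      j <- match(u, net$nodes$id)
      d <- c(net$nodes$x[i] - net$nodes$x[j], net$nodes$y[i] - net$nodes$y[j])
    }
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) next
    net$nodes$x[i] <- net$nodes$x[i] + ext * d[1] / nd
    net$nodes$y[i] <- net$nodes$y[i] + ext * d[2] / nd
    net$edges$length[k] <- net$edges$length[k] + ext
  }
  net
}

# near a branch point two diverging hyphae overlap for roughly
# r / tan(theta/2) before they are optically separable, so the skeleton
# fuses them and one daughter's initial stretch is lost; credit that
# length back to the closest-direction edge pair at each junction
junction_merge_correction <- function(net) {
  juncs <- net$nodes$id[net$nodes$kind == "junction"]
  nid <- net$nodes$id
  for (v in juncs) {
    inc <- which((net$edges$from == v | net$edges$to == v) &
                   !net$edges$is_root_edge)
    if (length(inc) < 3) next
    dirs <- t(vapply(inc, function(k) {
      pl <- net$edges$polyline[[k]]
      vi <- match(v, nid)
      p0 <- c(net$nodes$x[vi], net$nodes$y[vi])
      if (!is.null(pl) && nrow(pl) > 2) {
        if (sum((pl[1, ] - p0)^2) > sum((pl[nrow(pl), ] - p0)^2)) {
          pl <- pl[rev(seq_len(nrow(pl))), , drop = FALSE]
        }
        d <- pl[min(3, nrow(pl)), ] - p0
      } else {
        u <- setdiff(c(net$edges$from[k], net$edges$to[k]), v)
        ui <- match(u, nid)
        d <- c(net$nodes$x[ui], net$nodes$y[ui]) - p0
      }
      d / max(sqrt(sum(d^2)), 1e-12)
    }, numeric(2)))
    prs <- utils::combn(seq_along(inc), 2)
    angs <- apply(prs, 2, function(pr) {
      acos(pmin(pmax(sum(dirs[pr[1], ] * dirs[pr[2], ]), -1), 1))
    })
    b <- which.min(angs)
    theta <- max(angs[b], 0.2)           # guard against parallel contacts
    pair <- inc[prs[, b]]
    r <- mean(net$edges$width[pair]) / 2
    ell <- min(r / tan(theta / 2), 4 * r)
    net$edges$length[pair] <- net$edges$length[pair] + ell / 2
  }
  net
}

# remove structure inside the inoculum disk and attach the root there
mask_inoculum <- function(net, center, radius) {
  dn <- sqrt((net$nodes$x - center[1])^2 + (net$nodes$y - center[2])^2)
  inside <- net$nodes$id[dn <= radius]
  e <- net$edges
  both_in <- e$from %in% inside & e$to %in% inside
  net$edges <- e[!both_in, , drop = FALSE]
  net <- drop_orphans(net)
  d <- sqrt((net$nodes$x - center[1])^2 + (net$nodes$y - center[2])^2)
  boundary <- net$nodes$id[d <= radius * 1.5]
  if (!length(boundary)) {
    warning("no nodes near the inoculum; root not attached")
    return(net)
  }
  attach_root(net, center, boundary)
}
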