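#' Parameters for the synthetic mycelium generator
#'
#' The generator emulates a foraging colony growing out of a central
#' inoculum: tips advance stepwise with persistent headings plus Gaussian
#' angular noise, branch with a fixed per-step probability, and may fuse
#' (anastomose) with an existing hypha when they come within capture
#' distance. Low branching and no fusion give sparse tree-like
#' ("guerrilla") colonies; frequent branching and fusion give densely
#' cross-linked ("phalanx") colonies.
#'
#' Units are micrometres throughout (scale class "micro").
#'
#' @param n_steps growth iterations.
#' @param step_length_mu,step_length_sigma log-normal step length
#'   (meanlog/sdlog, step in micrometres).
#' @param branch_prob per-tip per-step probability of spawning a lateral
#'   branch.
#' @param branch_angle_mu,branch_angle_sigma branch angle from the parent
#'   heading, degrees (Gaussian).
#' @param heading_noise_sd per-step heading jitter, degrees.
#' @param fuse_radius capture distance for anastomosis, micrometres.
#' @param fuse_prob probability of fusing when within capture distance; a
#'   tip that declines to fuse stops growing at the obstacle (hyphae are
#'   not allowed to cross without creating a node, keeping the graph
#'   planar).
#' @param width_tip,width_main mean widths (micrometres) for tip-incident
#'   and internal edges; sampled Gaussian with 10% relative sd, clipped
#'   positive.
#' @param arena_radius growth limit from the inoculum centre, micrometres.
#' @param n_trunks number of initial hyphae leaving the inoculum.
#' @param inoculum_radius radius of the unresolvable inoculum disk; trunk
#'   start nodes sit on its rim and become the root's boundary nodes.
#' @param seed RNG seed; identical parameters + seed reproduce the network
#'   exactly.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_steps = 45,
                         step_length_mu = log(20), step_length_sigma = 0.35,
                         branch_prob = 0.12,
                         branch_angle_mu = 55, branch_angle_sigma = 12,
                         heading_noise_sd = 9,
                         fuse_radius = 4, fuse_prob = 0.15,
                         width_tip = 3, width_main = 5,
                         arena_radius = 400, n_trunks = 4,
                         inoculum_radius = 15, seed = 1L) {
  p <- list(n_steps = n_steps, step_length_mu = step_length_mu,
            step_length_sigma = step_length_sigma, branch_prob = branch_prob,
            branch_angle_mu = branch_angle_mu,
            branch_angle_sigma = branch_angle_sigma,
            heading_noise_sd = heading_noise_sd, fuse_radius = fuse_radius,
            fuse_prob = fuse_prob, width_tip = width_tip,
            width_main = width_main, arena_radius = arena_radius,
            n_trunks = n_trunks, inoculum_radius = inoculum_radius,
            seed = as.integer(seed))
  stopifnot(p$branch_prob >= 0, p$branch_prob <= 1,
            p$fuse_prob >= 0, p$fuse_prob <= 1,
            p$fuse_radius > 0, p$width_tip > 0, p$width_main > 0,
            p$arena_radius > 0, p$n_trunks >= 1, p$inoculum_radius > 0)
  class(p) <- c("synth_params", "list")
  p
}

#' Preset phenotype parameters
#'
#' Three anchor points on the guerrilla--phalanx connectivity gradient:
#' `"guerrilla"` (sparse, long steps, rare branching, essentially no
#' anastomosis), `"phalanx"` (short steps, frequent branching and fusion),
#' and `"intermediate"`.
#'
#' @param phenotype one of `"guerrilla"`, `"phalanx"`, `"intermediate"`.
#' @param seed RNG seed stored in the returned parameters.
#' @return a [synth_params()] object.
#' @export
preset_params <- function(phenotype = c("guerrilla", "phalanx",
                                        "intermediate"), seed = 1L) {
  phenotype <- match.arg(phenotype)
  # anchored so that colonies reach comparable edge counts (hundreds of
  # hyphal segments) while differing in branching, step length, widths
  # and above all anastomosis - the connectivity gradient of real sparse
  # vs dense foragers
  switch(phenotype,
    guerrilla = synth_params(
      n_steps = 45, step_length_mu = log(22), step_length_sigma = 0.4,
      branch_prob = 0.18, heading_noise_sd = 7,
      fuse_radius = 8, fuse_prob = 0, width_tip = 3.5, width_main = 6,
      arena_radius = 420, n_trunks = 5, seed = seed),
    phalanx = synth_params(
      n_steps = 40, step_length_mu = log(14), step_length_sigma = 0.3,
      branch_prob = 0.30, heading_noise_sd = 16,
      fuse_radius = 7, fuse_prob = 0.85, width_tip = 2.5, width_main = 4,
      arena_radius = 300, n_trunks = 6, seed = seed),
    intermediate = synth_params(
      n_steps = 42, step_length_mu = log(18), step_length_sigma = 0.35,
      branch_prob = 0.24, heading_noise_sd = 11,
      fuse_radius = 5, fuse_prob = 0.35, width_tip = 3, width_main = 5,
      arena_radius = 350, n_trunks = 5, seed = seed))
}

# evaluate expr under a local RNG stream, restoring global state after
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# distance from point (px,py) to segments (x1,y1)-(x2,y2), vectorized over
# segments; returns list(d = distances, t = projection fractions)
point_seg_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- ((px - x1) * dx + (py - y1) * dy) / pmax(l2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx
  qy <- y1 + t * dy
  list(d = sqrt((px - qx)^2 + (py - qy)^2), t = t, qx = qx, qy = qy)
}

# do segments p1-p2 and (x1,y1)-(x2,y2) properly intersect? vectorized
seg_seg_cross <- function(p1, p2, x1, y1, x2, y2) {
  o <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  o1 <- o(p1[1], p1[2], p2[1], p2[2], x1, y1)
  o2 <- o(p1[1], p1[2], p2[1], p2[2], x2, y2)
  o3 <- o(x1, y1, x2, y2, p1[1], p1[2])
  o4 <- o(x1, y1, x2, y2, p2[1], p2[2])
  o1 != o2 & o3 != o4 & o1 != 0 & o2 != 0
}

#' Grow a synthetic mycelium
#'
#' Runs the tip-based growth model of [synth_params()] and returns a
#' root-attached [mycelial_network] (micro scale, micrometre units). The
#' graph stays planar: a tip that would cross an existing hypha either
#' fuses with it (probability `fuse_prob`), creating an anastomosis node
#' that splits the target edge, or stops at the obstacle.
#'
#' @param params a [synth_params()] object.
#' @return a [mycelial_network] with the inoculum root at the arena centre.
#' @examples
#' net <- grow_network(preset_params("guerrilla", seed = 7))
#' net
#' @export
grow_network <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  if (params$n_steps < 1) stop("n_steps must be >= 1 (empty network)")
  with_local_seed(params$seed, grow_network_impl(params))
}

grow_network_impl <- function(p) {
  # node store
  nx <- numeric(0); ny <- numeric(0)
  add_node <- function(x, y) {
    nx[length(nx) + 1L] <<- x
    ny[length(ny) + 1L] <<- y
    length(nx)
  }
  # edge store (straight segments)
  ef <- integer(0); et <- integer(0)
  add_edge <- function(a, b) {
    ef[length(ef) + 1L] <<- a
    et[length(et) + 1L] <<- b
    length(ef)
  }
  trunk_heads <- (seq_len(p$n_trunks) - 1) * 2 * pi / p$n_trunks +
    runif(1, 0, 2 * pi)
  trunk_ids <- vapply(trunk_heads, function(h) {
    add_node(p$inoculum_radius * cos(h), p$inoculum_radius * sin(h))
  }, integer(1))
  tips <- data.frame(node = trunk_ids, heading = trunk_heads)

  deg2rad <- pi / 180
  for (step in seq_len(p$n_steps)) {
    if (!nrow(tips)) break
    keep <- rep(TRUE, nrow(tips))
    newtips <- list()
    for (ti in seq_len(nrow(tips))) {
      nd <- tips$node[ti]
      h <- tips$heading[ti] + rnorm(1, 0, p$heading_noise_sd * deg2rad)
      L <- rlnorm(1, p$step_length_mu, p$step_length_sigma)
      x1 <- nx[nd]; y1 <- ny[nd]
      x2 <- x1 + L * cos(h); y2 <- y1 + L * sin(h)
      if (sqrt(x2^2 + y2^2) > p$arena_radius ||
          sqrt(x2^2 + y2^2) < p$inoculum_radius) {
        keep[ti] <- FALSE   # hit the arena rim or grew back into inoculum
        next
      }
      hit <- NA_integer_
      if (length(ef)) {
        cand <- which(ef != nd & et != nd)
        if (length(cand)) {
          # true segment-segment proximity: for non-crossing segments the
          # minimum distance is attained at one of the four endpoints
          ps <- point_seg_dist(x2, y2, nx[ef[cand]], ny[ef[cand]],
                               nx[et[cand]], ny[et[cand]])
          da <- point_seg_dist(nx[ef[cand]], ny[ef[cand]],
                               x1, y1, x2, y2)$d
          db <- point_seg_dist(nx[et[cand]], ny[et[cand]],
                               x1, y1, x2, y2)$d
          crossing <- seg_seg_cross(c(x1, y1), c(x2, y2),
                                    nx[ef[cand]], ny[ef[cand]],
                                    nx[et[cand]], ny[et[cand]])
          dmin <- pmin(ps$d, da, db)
          close <- dmin <= p$fuse_radius | crossing
          if (any(close)) hit <- cand[which(close)[which.min(dmin[close])]]
        }
      }
      if (!is.na(hit)) {
        if (runif(1) <= p$fuse_prob) {
          # anastomose: split the target edge at the capture point,
          # snapping to an endpoint when the capture lands on one
          a <- ef[hit]; b <- et[hit]
          ps <- point_seg_dist(x2, y2, nx[a], ny[a], nx[b], ny[b])
          da <- sqrt((ps$qx - nx[a])^2 + (ps$qy - ny[a])^2)
          db <- sqrt((ps$qx - nx[b])^2 + (ps$qy - ny[b])^2)
          if (da < 1e-3) {
            qid <- a
          } else if (db < 1e-3) {
            qid <- b
          } else {
            qid <- add_node(ps$qx, ps$qy)
            et[hit] <- qid
            add_edge(qid, b)
          }
          if (qid != nd) add_edge(nd, qid)
        }
        keep[ti] <- FALSE   # fused or blocked; either way the tip stops
        next
      }
      nid <- add_node(x2, y2)
      add_edge(nd, nid)
      tips$node[ti] <- nid
      tips$heading[ti] <- h
      if (runif(1) <= p$branch_prob) {
        ang <- rnorm(1, p$branch_angle_mu, p$branch_angle_sigma) * deg2rad
        side <- sample(c(-1, 1), 1)
        newtips[[length(newtips) + 1L]] <-
          data.frame(node = nid, heading = h + side * ang)
      }
    }
    tips <- rbind(tips[keep, , drop = FALSE], do.call(rbind, newtips))
  }
  if (!length(ef)) stop("growth produced no edges; parameters degenerate")

  lens <- sqrt((nx[ef] - nx[et])^2 + (ny[ef] - ny[et])^2)
  ok <- lens > 1e-9
  ef <- ef[ok]; et <- et[ok]; lens <- lens[ok]
  # drop nodes that ended up with no incident edge (dead growth starts)
  used <- sort(unique(c(ef, et, trunk_ids)))
  remap <- match(seq_along(nx), used)
  nx <- nx[used]; ny <- ny[used]
  ef <- remap[ef]; et <- remap[et]
  trunk_ids <- remap[trunk_ids]

  nodes <- data.frame(id = seq_along(nx), x = nx, y = ny)
  edges <- data.frame(from = ef, to = et, length = lens, width = 1)
  net <- mycelial_network(nodes, edges, scale_class = "micro",
                          metadata = list(generator = "myconet-synth",
                                          seed = p$seed))
  net <- attach_root(net, c(0, 0), trunk_ids)
  # growth steps leave degree-2 waypoints; real network nodes are tips,
  # branch and anastomosis points only, so dissolve the pass-throughs
  # (polylines keep the traced geometry)
  net <- dissolve_pass_through(net)
  # widths per whole hyphal segment: tip-incident edges thinner than main
  e <- net$edges
  tipids <- net$nodes$id[net$nodes$kind == "tip"]
  measured <- !e$is_root_edge
  tipedge <- (e$from %in% tipids | e$to %in% tipids) & measured
  wmu <- ifelse(tipedge, p$width_tip, p$width_main)
  w <- pmax(rnorm(nrow(e), wmu, 0.1 * wmu), 0.2 * wmu)
  net$edges$width[measured] <- w[measured]
  net$edges$width[!measured] <- max(w[measured])   # root-edge convention
  net
}

#' Render a network to a grayscale image
#'
#' Draws every measured edge as an anti-aliased thick line (capsule of
#' radius width/2), then applies optional Gaussian blur and additive
#' Gaussian noise. By default hyphae are bright on a dark background;
#' `invert = TRUE` emulates bright-field images (dark hyphae on a bright
#' background).
#'
#' @param net a [mycelial_network].
#' @param pixel_size physical units per pixel.
#' @param blur_sigma Gaussian blur sd in pixels (0 = none).
#' @param noise_sd additive noise sd on the 0..1 intensity scale.
#' @param invert render dark-on-bright.
#' @param seed RNG seed for the noise.
#' @param pad margin in pixels around the colony bounding box.
#' @return list of class `myc_render`: `image` (numeric matrix, rows = y,
#'   values 0..1), `pixel_size`, `origin` (physical coordinates of the
#'   image corner), and `truth` (the input network, for round-trip
#'   scoring).
#' @export
render_image <- function(net, pixel_size = 1, blur_sigma = 0, noise_sd = 0,
                         invert = FALSE, seed = 1L, pad = 5L) {
  me <- measured_edges(net)
  if (nrow(me) && max(me$width) < pixel_size) {
    stop("pixel_size too coarse: maximum edge width is below one pixel")
  }
  nid <- net$nodes$id
  if (nrow(me)) {
    xs <- c(net$nodes$x[match(me$from, nid)], net$nodes$x[match(me$to, nid)])
    ys <- c(net$nodes$y[match(me$from, nid)], net$nodes$y[match(me$to, nid)])
    wmax <- max(me$width)
  } else {
    xs <- 0; ys <- 0; wmax <- 0
  }
  x0 <- min(xs) - wmax - pad * pixel_size
  y0 <- min(ys) - wmax - pad * pixel_size
  ncol_ <- ceiling((max(xs) + wmax + pad * pixel_size - x0) / pixel_size) + 1L
  nrow_ <- ceiling((max(ys) + wmax + pad * pixel_size - y0) / pixel_size) + 1L
  img <- matrix(0, nrow_, ncol_)
  if (nrow(me)) {
    for (k in seq_len(nrow(me))) {
      ax <- net$nodes$x[match(me$from[k], nid)]
      ay <- net$nodes$y[match(me$from[k], nid)]
      bx <- net$nodes$x[match(me$to[k], nid)]
      by <- net$nodes$y[match(me$to[k], nid)]
      r <- me$width[k] / 2
      jlo <- max(1L, floor((min(ax, bx) - r - x0) / pixel_size))
      jhi <- min(ncol_, ceiling((max(ax, bx) + r - x0) / pixel_size) + 1L)
      ilo <- max(1L, floor((min(ay, by) - r - y0) / pixel_size))
      ihi <- min(nrow_, ceiling((max(ay, by) + r - y0) / pixel_size) + 1L)
      if (jlo > jhi || ilo > ihi) next
      jj <- jlo:jhi
      ii <- ilo:ihi
      px <- x0 + (jj - 0.5) * pixel_size
      py <- y0 + (ii - 0.5) * pixel_size
      gx <- matrix(px, length(ii), length(jj), byrow = TRUE)
      gy <- matrix(py, length(ii), length(jj))
      d <- point_seg_dist(gx, gy, ax, ay, bx, by)$d
      cov <- pmin(pmax((r - d) / pixel_size + 0.5, 0), 1)
      img[ii, jj] <- pmax(img[ii, jj], cov)
    }
  }
  if (blur_sigma > 0) {
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  }
  if (noise_sd > 0) {
    img <- with_local_seed(seed, img + rnorm(length(img), 0, noise_sd))
  }
  img <- pmin(pmax(img, 0), 1)
  if (invert) img <- 1 - img
  structure(list(image = img, pixel_size = pixel_size,
                 origin = c(x0, y0), truth = net),
            class = "myc_render")
}

#' Write a rendered image to PNG or TIFF
#'
#' @param render a [render_image()] result (or a plain numeric matrix).
#' @param path output file; extension selects the writer (.png or .tif).
#' @return `path`, invisibly.
#' @export
write_render <- function(render, path) {
  img <- if (inherits(render, "myc_render")) render$image else render
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) stop("png package needed")
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("tiff package needed")
    tiff::writeTIFF(img, path)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}
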