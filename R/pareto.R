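#' First two principal-component scores
#'
#' Ordination plane for archetype analysis: PCA scores (covariance of the
#' standardized trait matrix) on the first two axes.
#'
#' @param Y standardized trait matrix (size-free traits; see
#'   [select_traits()] model 3).
#' @return n x 2 matrix of scores, columns `PC1`, `PC2`, centred at the
#'   origin.
#' @export
ordinate_2d <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 3) stop("need at least 3 colonies")
  pc <- prcomp(Y, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("trait matrix has rank < 2; no 2D ordination plane")
  }
  sc <- pc$x[, 1:2, drop = FALSE]
  colnames(sc) <- c("PC1", "PC2")
  sc
}

# polygon (vertex matrix) from k support-line angles; Inf area if the
# half-plane intersection is not a bounded k-gon
support_polygon <- function(theta, hx, hy) {
  k <- length(theta)
  theta <- sort(theta %% (2 * pi))
  gaps <- diff(c(theta, theta[1] + 2 * pi))
  if (any(gaps >= pi - 1e-12)) return(NULL)
  cs <- cos(theta); sn <- sin(theta)
  h <- vapply(seq_len(k), function(i) max(cs[i] * hx + sn[i] * hy),
              numeric(1))
  nxt <- c(2:k, 1)
  det <- cs * sn[nxt] - sn * cs[nxt]
  if (any(abs(det) < 1e-12)) return(NULL)
  vx <- (h * sn[nxt] - sn * h[nxt]) / det
  vy <- (cs * h[nxt] - h * cs[nxt]) / det
  # every vertex must respect every half-plane, else a line is redundant
  for (i in seq_len(k)) {
    if (any(cs[i] * vx + sn[i] * vy > h[i] + 1e-9)) return(NULL)
  }
  cbind(vx, vy)
}

support_area <- function(theta, hx, hy) {
  v <- support_polygon(theta, hx, hy)
  if (is.null(v)) return(Inf)
  polygon_area(v)
}

#' Minimal-area enclosing convex k-gon
#'
#' Sides are support lines of the point cloud, so containment is exact by
#' construction. The k side directions are found by exhaustive search over
#' a candidate set (all convex-hull edge normals plus a uniform angular
#' grid) followed by Nelder-Mead refinement. For k = 3 the optimal
#' enclosing triangle has at least one side flush with a hull edge, which
#' the candidate set contains, so the search starts at (and refines from)
#' the right basin; for k > 3 the same procedure is an effective
#' heuristic.
#'
#' @param points n x 2 matrix, at least 3 non-collinear points.
#' @param k number of polygon sides (>= 3).
#' @param n_grid uniform candidate angles added to the hull-edge normals.
#' @param refine run Nelder-Mead refinement after the grid search.
#' @return k x 2 matrix of polygon vertices (some may coincide if fewer
#'   than k sides are active).
#' @export
min_enclosing_polygon <- function(points, k = 3, n_grid = 24,
                                  refine = TRUE) {
  points <- as.matrix(points)
  stopifnot(k >= 3)
  hull <- chull(points[, 1], points[, 2])
  if (length(hull) < 3) stop("points are collinear; no enclosing polygon")
  hx <- points[, 1]; hy <- points[, 2]
  hp <- points[hull, , drop = FALSE]
  m <- nrow(hp)
  ex <- hp[c(2:m, 1), 1] - hp[, 1]
  ey <- hp[c(2:m, 1), 2] - hp[, 2]
  # outward normals of hull edges (chull returns clockwise order)
  normals <- atan2(ex, -ey)
  cand <- sort(unique(round(c(normals %% (2 * pi),
                              seq(0, 2 * pi, length.out = n_grid + 1)[-1]),
                            10)))
  best <- NULL
  besta <- Inf
  if (k == 3) {
    cs <- cos(cand); sn <- sin(cand)
    h <- as.numeric(apply(cbind(hx, hy) %*% rbind(cs, sn), 2, max))
    trip <- combn(length(cand), 3)
    ia <- trip[1, ]; ib <- trip[2, ]; ic <- trip[3, ]
    ok <- (cand[ib] - cand[ia] < pi - 1e-12) &
      (cand[ic] - cand[ib] < pi - 1e-12) &
      (cand[ia] + 2 * pi - cand[ic] < pi - 1e-12)
    ia <- ia[ok]; ib <- ib[ok]; ic <- ic[ok]
    vtx <- function(i, j) {
      dt <- cs[i] * sn[j] - sn[i] * cs[j]
      cbind((h[i] * sn[j] - sn[i] * h[j]) / dt,
            (cs[i] * h[j] - h[i] * cs[j]) / dt)
    }
    vab <- vtx(ia, ib); vbc <- vtx(ib, ic); vca <- vtx(ic, ia)
    valid <- (cs[ic] * vab[, 1] + sn[ic] * vab[, 2] <= h[ic] + 1e-9) &
      (cs[ia] * vbc[, 1] + sn[ia] * vbc[, 2] <= h[ia] + 1e-9) &
      (cs[ib] * vca[, 1] + sn[ib] * vca[, 2] <= h[ib] + 1e-9)
    area <- abs((vbc[, 1] - vab[, 1]) * (vca[, 2] - vab[, 2]) -
                  (vca[, 1] - vab[, 1]) * (vbc[, 2] - vab[, 2])) / 2
    area[!valid] <- Inf
    if (any(is.finite(area))) {
      q <- which.min(area)
      besta <- area[q]
      best <- cand[c(ia[q], ib[q], ic[q])]
    }
  } else {
    # seed: evenly spaced angles rotated to each hull normal
    for (off in cand) {
      th <- (off + seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]) %% (2 * pi)
      a <- support_area(th, hx, hy)
      if (a < besta) {
        besta <- a
        best <- th
      }
    }
  }
  if (!is.finite(besta)) stop("no valid enclosing polygon found")
  if (refine) {
    obj <- function(th) {
      a <- support_area(th, hx, hy)
      if (is.finite(a)) a else 1e18
    }
    for (scale in c(0.2, 0.02)) {
      op <- optim(best, obj, method = "Nelder-Mead",
                  control = list(maxit = 400, reltol = 1e-12,
                                 parscale = rep(scale, k)))
      if (op$value < besta) {
        besta <- op$value
        best <- op$par
      }
    }
  }
  support_polygon(best, hx, hy)
}

#' Triangularity ratio
#'
#' Area of the convex hull of the points divided by the area of the
#' enclosing polygon. Values near 1 mean the cloud itself is nearly a
#' k-gon (for k = 3: strongly triangular data, the Pareto-front
#' signature); the ratio is always in (0, 1].
#'
#' @param points n x 2 score matrix.
#' @param polygon k x 2 vertex matrix from [min_enclosing_polygon()].
#' @return scalar ratio.
#' @export
t_ratio <- function(points, polygon) {
  pa <- polygon_area(polygon)
  if (pa <= 0) stop("degenerate polygon with zero area")
  hull <- chull(points[, 1], points[, 2])
  polygon_area(points[hull, , drop = FALSE]) / pa
}

#' Archetype analysis with a randomization test
#'
#' Ordinates the standardized trait matrix into its first two principal
#' components, fits the minimal enclosing k-gon, and measures the
#' [t_ratio()]. The null distribution permutes each trait column
#' independently (destroying trait correlations while preserving
#' marginals), redoing the full ordination + polygon fit each time;
#' `p_random = (1 + #(t_rand >= t_obs)) / (1 + n_rand)`. Each polygon
#' vertex is an archetype; the colony nearest to it in score space is
#' reported.
#'
#' @param Y standardized size-free trait matrix.
#' @param k number of archetypes (default 3).
#' @param n_rand randomizations.
#' @param seed RNG seed.
#' @param n_grid angular grid resolution passed down (the same statistic
#'   definition is used for observed and null datasets).
#' @param refine Nelder-Mead refinement of the polygon fit. Off by
#'   default here: the grid statistic is cheaper and, being identical for
#'   observed and null datasets, the comparison is unbiased.
#' @return list of class `archetype_result`: `scores`, `k`, `polygon`,
#'   `t_ratio`, `p_random`, `n_rand`, `seed`, `nearest` (data.frame of
#'   vertex coordinates, nearest colony row and distance), `t_null`.
#' @export
archetype_analysis <- function(Y, k = 3, n_rand = 10000, seed = 1L,
                               n_grid = 24, refine = FALSE) {
  if (n_rand < 1) stop("n_rand must be >= 1")
  Y <- as.matrix(Y)
  stat <- function(M) {
    sc <- ordinate_2d(M)
    poly <- min_enclosing_polygon(sc, k = k, n_grid = n_grid,
                                  refine = refine)
    list(sc = sc, poly = poly, t = t_ratio(sc, poly))
  }
  obs <- stat(Y)
  tn <- with_local_seed(seed, vapply(seq_len(n_rand), function(i) {
    Yp <- apply(Y, 2, sample)
    stat(Yp)$t
  }, numeric(1)))
  p <- (1 + sum(tn >= obs$t)) / (1 + n_rand)
  dmat <- as.matrix(dist(rbind(obs$poly, obs$sc)))
  kk <- nrow(obs$poly)
  nearest <- data.frame(
    vertex = seq_len(kk),
    x = obs$poly[, 1], y = obs$poly[, 2],
    nearest_row = vapply(seq_len(kk), function(i) {
      which.min(dmat[i, -(seq_len(kk))])
    }, integer(1)),
    distance = vapply(seq_len(kk), function(i) {
      min(dmat[i, -(seq_len(kk))])
    }, numeric(1)))
  if (!is.null(rownames(Y))) {
    nearest$nearest_label <- rownames(Y)[nearest$nearest_row]
  }
  structure(list(scores = obs$sc, k = k, polygon = obs$poly,
                 t_ratio = obs$t, p_random = p, n_rand = n_rand,
                 seed = seed, nearest = nearest, t_null = tn),
            class = "archetype_result")
}

#' @export
print.archetype_result <- function(x, ...) {
  cat(sprintf(
    "<archetype_result> k=%d, t-ratio=%.3f, p=%.4g (%d randomizations)\n",
    x$k, x$t_ratio, x$p_random, x$n_rand))
  invisible(x)
}
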