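#' Attack scheme specification
#'
#' Five edge-removal patterns mimic attack by distinct fungivores:
#' `random_single` (uniform random edges), `random_chunk` (a random bite
#' of `chunk_k` spatially adjacent edges at a time), `ascending_width`
#' (thinnest first; grazers of fine hyphae), `descending_width` (widest
#' first), and `descending_length` (longest first). Root edges are never
#' attacked.
#'
#' @param name one of the five scheme names.
#' @param chunk_k edges per bite for `random_chunk`; default
#'   `max(2, round(0.02 E))` at attack time.
#' @param replicates replicate removal sequences for the stochastic
#'   schemes.
#' @param seed RNG seed for the stochastic schemes.
#' @return an `attack_scheme` list.
#' @export
attack_scheme <- function(name = c("random_single", "random_chunk",
                                   "ascending_width", "descending_width",
                                   "descending_length"),
                          chunk_k = NULL, replicates = 100, seed = 1L) {
  name <- match.arg(name)
  if (!is.null(chunk_k) && chunk_k < 2) stop("chunk_k must be >= 2")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(name = name, chunk_k = chunk_k,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = c("attack_scheme", "list"))
}

#' Edge-removal order under an attack scheme
#'
#' Deterministic schemes use the tie-break (width, length, id) ascending
#' within equal primary keys. Stochastic schemes return one order per
#' replicate.
#'
#' @param net a root-attached [mycelial_network].
#' @param scheme an [attack_scheme()].
#' @return for deterministic schemes, an integer vector of edge ids; for
#'   stochastic schemes, a list of such vectors (one per replicate). For
#'   `random_chunk` each element keeps a `chunks` attribute giving the
#'   bite index of every removed edge.
#' @export
attack_order <- function(net, scheme) {
  e <- measured_edges(net)
  if (!nrow(e)) stop("no measured edges to attack")
  switch(scheme$name,
    ascending_width = e$id[order(e$width, e$length, e$id)],
    descending_width = e$id[order(-e$width, e$length, e$id)],
    descending_length = e$id[order(-e$length, e$width, e$id)],
    random_single = with_local_seed(scheme$seed, {
      lapply(seq_len(scheme$replicates), function(r) sample(e$id))
    }),
    random_chunk = with_local_seed(scheme$seed, {
      k <- if (is.null(scheme$chunk_k)) {
        max(2L, round(0.02 * nrow(e)))
      } else {
        as.integer(scheme$chunk_k)
      }
      mid <- edge_midpoints(net, e)
      lapply(seq_len(scheme$replicates), function(r) {
        remaining <- seq_len(nrow(e))
        ord <- integer(0)
        bite <- integer(0)
        ci <- 0L
        while (length(remaining)) {
          ci <- ci + 1L
          pick <- remaining[sample.int(length(remaining), 1)]
          dd <- (mid[remaining, 1] - mid[pick, 1])^2 +
            (mid[remaining, 2] - mid[pick, 2])^2
          take <- remaining[order(dd)][seq_len(min(k, length(remaining)))]
          ord <- c(ord, e$id[take])
          bite <- c(bite, rep(ci, length(take)))
          remaining <- setdiff(remaining, take)
        }
        attr(ord, "chunks") <- bite
        ord
      })
    }))
}

edge_midpoints <- function(net, e = measured_edges(net)) {
  i1 <- match(e$from, net$nodes$id)
  i2 <- match(e$to, net$nodes$id)
  cbind((net$nodes$x[i1] + net$nodes$x[i2]) / 2,
        (net$nodes$y[i1] + net$nodes$y[i2]) / 2)
}

#' Fraction of mycelium still connected to the root
#'
#' Measured-edge *length* (the natural biomass proxy) in the component
#' containing the root after removing `removed_ids`, divided by the total
#' measured length before any removal. Root edges count in neither sum.
#'
#' @param net a root-attached [mycelial_network].
#' @param removed_ids edge ids already removed.
#' @return fraction in `[0, 1]`.
#' @export
connected_fraction <- function(net, removed_ids = integer(0)) {
  if (is.na(net$root_id)) stop("no root attached")
  total <- sum(measured_edges(net)$length)
  e <- net$edges[!net$edges$id %in% removed_ids, , drop = FALSE]
  sub <- net
  sub$edges <- e
  g <- as_igraph(sub)
  comp <- igraph::components(g)$membership
  rc <- comp[as.character(net$root_id)]
  me <- e[!e$is_root_edge, , drop = FALSE]
  inroot <- comp[as.character(me$from)] == rc &
    comp[as.character(me$to)] == rc
  sum(me$length[inroot]) / total
}

# root-connected length fraction after removing the first m edges of
# `ord`, for every m in 0..E, via reverse edge addition with union-find
removal_trajectory <- function(net, ord) {
  ids <- net$nodes$id
  e <- net$edges
  me <- e[!e$is_root_edge, , drop = FALSE]
  total <- sum(me$length)
  pos <- match(ord, me$id)
  parent <- seq_along(ids)
  clen <- numeric(length(ids))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(a, b, len) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <<- rb
      clen[rb] <<- clen[rb] + clen[ra]
      clen[ra] <<- 0
    }
    clen[find(b)] <<- clen[find(b)] + len
  }
  re <- e[e$is_root_edge, , drop = FALSE]
  for (k in seq_len(nrow(re))) {
    link(match(re$from[k], ids), match(re$to[k], ids), 0)
  }
  rooti <- match(net$root_id, ids)
  E <- length(ord)
  f <- numeric(E + 1)             # f[m + 1] = fraction after removing m
  f[E + 1] <- 0
  for (m in E:1) {
    k <- pos[m]
    link(match(me$from[k], ids), match(me$to[k], ids), me$length[k])
    f[m] <- clen[find(rooti)] / total
  }
  f[-1]                            # m = 1..E
}

#' Robustness to an attack scheme
#'
#' Edges are removed in attack order (per bite for `random_chunk`),
#' re-evaluating the root-connected fraction after each removal; the
#' robustness is the fraction of measured edges removed when the
#' connected fraction first drops to <= 0.5. Stochastic schemes report
#' the mean over replicates (per-replicate values retained). Large values
#' mean many edges must be destroyed before half the mycelium is cut off
#' from the inoculum.
#'
#' @param net a root-attached [mycelial_network].
#' @param scheme an [attack_scheme()].
#' @return list of class `robustness_result`: `scheme`, `robustness`
#'   (mean fraction), `n_removed` (mean count), `per_replicate`,
#'   `trajectory` (first replicate: connected fraction after each
#'   evaluation point).
#' @export
robustness <- function(net, scheme) {
  if (is.na(net$root_id)) stop("no root attached")
  orders <- attack_order(net, scheme)
  if (!is.list(orders)) orders <- list(orders)
  ne <- nrow(measured_edges(net))
  res <- lapply(orders, function(ord) {
    f <- removal_trajectory(net, ord)
    bites <- attr(ord, "chunks")
    if (is.null(bites)) bites <- seq_along(ord)
    # evaluation points: after each removal, or after each full bite
    evalm <- which(bites != c(bites[-1], -1L))
    fe <- f[evalm]
    hit <- which(fe <= 0.5)
    if (!length(hit)) stop("connected fraction never crossed 0.5")
    m <- evalm[hit[1]]
    list(frac = m / ne, n = m, traj = fe[seq_len(hit[1])])
  })
  structure(list(
    scheme = scheme$name,
    robustness = mean(vapply(res, `[[`, numeric(1), "frac")),
    n_removed = mean(vapply(res, `[[`, numeric(1), "n")),
    per_replicate = vapply(res, `[[`, numeric(1), "frac"),
    trajectory = res[[1]]$traj), class = "robustness_result")
}

#' All five robustness traits (11--15)
#'
#' @param net a root-attached [mycelial_network].
#' @param chunk_k,replicates,seed passed to the stochastic schemes.
#' @return named list `rob_random_single`, `rob_random_chunk`,
#'   `rob_asc_width`, `rob_desc_width`, `rob_desc_length`.
#' @export
robustness_traits <- function(net, chunk_k = NULL, replicates = 100,
                              seed = 1L) {
  schemes <- c("random_single", "random_chunk", "ascending_width",
               "descending_width", "descending_length")
  vals <- lapply(seq_along(schemes), function(i) {
    robustness(net, attack_scheme(schemes[i], chunk_k = chunk_k,
                                  replicates = replicates,
                                  seed = seed + i))$robustness
  })
  names(vals) <- c("rob_random_single", "rob_random_chunk",
                   "rob_asc_width", "rob_desc_width", "rob_desc_length")
  vals
}
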