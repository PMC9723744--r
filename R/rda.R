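#' Standardize a trait matrix
#'
#' Each column is centred and scaled to unit variance (denominator n-1),
#' putting traits with different units and magnitudes on a common scale.
#' The total inertia of a standardized p-column matrix is exactly p.
#'
#' @param Y numeric matrix or data.frame, rows = colonies.
#' @return standardized matrix.
#' @export
standardize <- function(Y) {
  Y <- as.matrix(Y)
  v <- apply(Y, 2, sd)
  if (any(!is.finite(v) | v == 0)) {
    bad <- colnames(Y)[!is.finite(v) | v == 0]
    stop("zero-variance or non-finite trait column(s): ",
         paste(bad, collapse = ", "))
  }
  scale(Y)
}

# centred dummy design for a factor; NULL for NULL input
factor_design <- function(f) {
  if (is.null(f)) return(NULL)
  f <- as.factor(f)
  m <- stats::model.matrix(~ 0 + f)
  scale(m, scale = FALSE)
}

# orthonormal basis of the column space (rank-revealing); columns that are
# numerically zero (e.g. a design fully absorbed by the conditioning
# variable) are discarded outright so they cannot fake a rank direction
ortho_basis <- function(M) {
  if (is.null(M)) return(NULL)
  M <- as.matrix(M)
  keep <- sqrt(colSums(M^2)) > 1e-8
  if (!any(keep)) return(NULL)
  q <- qr(M[, keep, drop = FALSE])
  if (q$rank == 0) return(NULL)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

#' Fit a (partial) redundancy analysis
#'
#' Constrained ordination of a standardized trait matrix on a species
#' factor, optionally conditioning out a phylum factor first (partial
#' RDA): `traits ~ species + Condition(phylum)`. Implemented directly via
#' orthogonal projections and SVD: the conditional step residualizes both
#' the traits and the species design on the covariate; the constrained
#' step projects the residualized traits onto the residualized design;
#' the leftover is the unconstrained (residual PCA) part. Inertias are
#' sums of squares divided by n-1 and satisfy total = conditional +
#' constrained + unconstrained.
#'
#' @param Y standardized trait matrix (see [standardize()]).
#' @param species factor (or design matrix) of the constraining variable.
#' @param phylum optional factor (or design matrix) to condition on.
#' @return object of class `rda_fit`: variance partition (inertias and
#'   proportions), constrained eigenvalues with axis-wise proportions,
#'   unit-norm trait loadings, site scores (`sites` = weighted-average
#'   scores of the residualized traits, `sites_lc` = linear-constraint
#'   scores), ranks/degrees of freedom, and the pseudo-F statistic.
#' @export
rda_fit <- function(Y, species, phylum = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- scale(Y, scale = FALSE)
  X <- if (is.factor(species) || is.character(species)) {
    factor_design(species)
  } else {
    scale(as.matrix(species), scale = FALSE)
  }
  Z <- if (is.null(phylum)) NULL else if (is.factor(phylum) ||
                                          is.character(phylum)) {
    factor_design(phylum)
  } else {
    scale(as.matrix(phylum), scale = FALSE)
  }
  Qz <- ortho_basis(Z)
  rank_z <- if (is.null(Qz)) 0L else ncol(Qz)
  if (is.null(Qz)) {
    Yz_fit <- matrix(0, n, ncol(Yc))
    Yres <- Yc
    Xres <- X
  } else {
    Yz_fit <- Qz %*% crossprod(Qz, Yc)
    Yres <- Yc - Yz_fit
    Xres <- X - Qz %*% crossprod(Qz, X)
  }
  Qx <- ortho_basis(Xres)
  rank_x <- if (is.null(Qx)) 0L else ncol(Qx)
  if (rank_x < qr(X)$rank) {
    warning("constraint rank reduced from ", qr(X)$rank, " to ", rank_x,
            " after conditioning")
  }
  Yfit <- if (rank_x) Qx %*% crossprod(Qx, Yres) else 0 * Yres
  Yunc <- Yres - Yfit
  nm1 <- n - 1
  inertia <- c(total = sum(Yc^2), conditional = sum(Yz_fit^2),
               constrained = sum(Yfit^2), unconstrained = sum(Yunc^2)) / nm1
  sv <- svd(Yfit / sqrt(nm1))
  keep <- which(sv$d^2 > max(sv$d^2, 0) * 1e-12)
  eig <- sv$d[keep]^2
  loadings <- sv$v[, keep, drop = FALSE]
  # sign convention: largest-magnitude loading on each axis is positive
  for (a in seq_along(keep)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) loadings[, a] <- -loadings[, a]
  }
  rownames(loadings) <- colnames(Y)
  if (length(keep)) colnames(loadings) <- paste0("RDA", seq_along(keep))
  sites <- Yres %*% loadings
  sites_lc <- Yfit %*% loadings
  df_res <- n - 1 - rank_z - rank_x
  pseudo_f <- if (rank_x && df_res > 0 && inertia["unconstrained"] > 0) {
    (inertia[["constrained"]] / rank_x) /
      (inertia[["unconstrained"]] / df_res)
  } else {
    NA_real_
  }
  structure(list(
    inertia = inertia,
    proportion = inertia / inertia[["total"]],
    eig = eig,
    axis_proportion = if (length(eig)) eig / inertia[["total"]] else
      numeric(0),
    loadings = loadings,
    sites = sites, sites_lc = sites_lc,
    rank_x = rank_x, rank_z = rank_z, df_res = df_res,
    pseudo_f = pseudo_f, n = n,
    Yres = Yres, Qx = Qx, Qz = Qz), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("Partial RDA fit\n")
  part <- data.frame(Inertia = round(x$inertia, 4),
                     Proportion = round(x$proportion, 4))
  print(part)
  cat("Constrained eigenvalues:", paste(round(x$eig, 4), collapse = ", "),
      "\npseudo-F =", round(x$pseudo_f, 3), "\n")
  invisible(x)
}

#' Permutation test for the constrained fraction
#'
#' Reduced-model permutation: rows of the covariate-residualized trait
#' matrix are permuted, re-residualized, and the pseudo-F recomputed.
#' The p-value uses the add-one convention,
#' `(1 + #(F_perm >= F_obs)) / (1 + n_perm)`, so 9999 permutations give a
#' minimum p of 1e-4.
#'
#' @param fit an [rda_fit()] result.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list: `pseudo_f`, `p_value`, `n_perm`, `seed`,
#'   `f_permuted` (the null draws).
#' @export
permutation_test <- function(fit, n_perm = 9999, seed = 1L) {
  stopifnot(inherits(fit, "rda_fit"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  Yres <- fit$Yres
  Qx <- fit$Qx
  Qz <- fit$Qz
  n <- nrow(Yres)
  rx <- fit$rank_x
  dfr <- fit$df_res
  fperm <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    Yp <- Yres[sample.int(n), , drop = FALSE]
    if (!is.null(Qz)) Yp <- Yp - Qz %*% crossprod(Qz, Yp)
    con <- sum((crossprod(Qx, Yp))^2)
    res <- sum(Yp^2) - con
    (con / rx) / (res / dfr)
  }, numeric(1)))
  p <- (1 + sum(fperm >= fit$pseudo_f)) / (1 + n_perm)
  list(pseudo_f = fit$pseudo_f, p_value = p, n_perm = n_perm, seed = seed,
       f_permuted = fperm)
}

# canonical trait column sets
morph_trait_names <- function() {
  c("mean_edge_length", "mean_tip_width", "mean_main_width",
    "mean_branch_angle", "length_density")
}

network_trait_names <- function() {
  c("meshedness", "R_eff", "RT_eff", "G_eff", "volume_MST",
    robustness_trait_names())
}

robustness_trait_names <- function() {
  c("rob_random_single", "rob_random_chunk", "rob_asc_width",
    "rob_desc_width", "rob_desc_length")
}

size_free_trait_names <- function() {
  c("meshedness", "G_eff_MST", "volume_MST", "R_eff_area", "RT_eff_area",
    robustness_trait_names())
}

#' Select the trait set for an RDA model
#'
#' Models 1 (micro-scale colonies) and 2 (macro-scale colonies) use all
#' 15 traits; model 3 (all colonies together) uses only the 10
#' size-independent or size-normalized network traits: meshedness,
#' MST-normalized global efficiency, volume-MST, area-normalized root and
#' root-tip efficiencies, and the five robustness fractions.
#'
#' @param table trait data.frame (as from [compute_traits()], with any
#'   factor columns).
#' @param model `"model1_micro"`, `"model2_macro"`, or `"model3_all"`.
#' @return the table restricted to that model's trait columns.
#' @export
select_traits <- function(table, model = c("model1_micro", "model2_macro",
                                           "model3_all")) {
  model <- match.arg(model)
  want <- if (model == "model3_all") {
    size_free_trait_names()
  } else {
    c(morph_trait_names(), network_trait_names())
  }
  miss <- setdiff(want, names(table))
  if (length(miss)) {
    stop("trait table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  table[, want, drop = FALSE]
}

#' Run one of the three standard RDA models on a trait table
#'
#' Convenience wrapper: selects the model's trait set and rows (model 1 =
#' micro colonies, model 2 = macro colonies, model 3 = all), standardizes,
#' fits `traits ~ species + Condition(phylum)` (the condition is dropped
#' automatically when the subset has a single phylum), and runs the
#' permutation test.
#'
#' @param table trait data.frame with `species`, `phylum` and (for model
#'   filtering) `scale_class` columns.
#' @param model model id, see [select_traits()].
#' @param n_perm,seed passed to [permutation_test()].
#' @return list: `fit` ([rda_fit]), `test` ([permutation_test] output),
#'   `traits` (columns used), `rows` (row indices used).
#' @export
rda_model <- function(table, model = c("model1_micro", "model2_macro",
                                       "model3_all"),
                      n_perm = 9999, seed = 1L) {
  model <- match.arg(model)
  rows <- seq_len(nrow(table))
  if (!is.null(table$scale_class)) {
    if (model == "model1_micro") rows <- which(table$scale_class == "micro")
    if (model == "model2_macro") rows <- which(table$scale_class == "macro")
  }
  sub <- table[rows, , drop = FALSE]
  Y <- standardize(select_traits(sub, model))
  phy <- if (!is.null(sub$phylum) && length(unique(sub$phylum)) > 1) {
    sub$phylum
  } else {
    NULL
  }
  fit <- rda_fit(Y, species = sub$species, phylum = phy)
  test <- permutation_test(fit, n_perm = n_perm, seed = seed)
  list(fit = fit, test = test, traits = colnames(Y), rows = rows)
}
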