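make_trait_data <- function(n_per = 5, n_sp = 6, p = 15, sd = 0.8,
                            seed = 42) {
  set.seed(seed)
  species <- factor(rep(letters[seq_len(n_sp)], each = n_per))
  phylum <- factor(rep(rep(c("P1", "P2"), length.out = n_sp), each = n_per))
  mu <- matrix(rnorm(n_sp * p), n_sp, p)
  Y <- mu[as.integer(species), ] + matrix(rnorm(n_per * n_sp * p, sd = sd),
                                          n_per * n_sp, p)
  colnames(Y) <- paste0("t", seq_len(p))
  list(Y = Y, species = species, phylum = phylum)
}

test_that("standardization yields unit-variance columns, idempotently", {
  m <- standardize(cbind(a = c(1, 2, 3), b = c(10, 30, 20)))
  expect_equal(colMeans(m), c(a = 0, b = 0))
  expect_equal(apply(m, 2, sd), c(a = 1, b = 1))
  expect_equal(standardize(m), m, ignore_attr = TRUE)
  expect_error(standardize(cbind(a = c(1, 1, 1), b = 1:3)), "a")

  d <- make_trait_data()
  Ys <- standardize(d$Y)
  expect_equal(sum(Ys^2) / (nrow(Ys) - 1), 15)
})

test_that("degenerate designs give the expected variance partitions", {
  d <- make_trait_data(sd = 1)
  # Y exactly the species means: perfect constrained fit
  mu <- apply(d$Y, 2, function(col) ave(col, d$species))
  Ys <- standardize(mu)
  fit <- rda_fit(Ys, d$species)
  expect_equal(fit$proportion[["constrained"]], 1.0, tolerance = 1e-10)
  expect_equal(fit$inertia[["unconstrained"]], 0, tolerance = 1e-8)

  # condition identical to the predictor absorbs everything
  fit2 <- suppressWarnings(rda_fit(standardize(d$Y), d$species,
                                   phylum = d$species))
  expect_equal(fit2$inertia[["constrained"]], 0, tolerance = 1e-8)
})

test_that("axis extraction matches a direct SVD on a tiny fixture", {
  Y <- matrix(c(1, 2, 3, 4, 1.5, 1, 2.5, 2), 4, 2)
  grp <- factor(c("a", "a", "b", "b"))
  Ys <- standardize(Y)
  fit <- rda_fit(Ys, grp)
  X <- scale(stats::model.matrix(~ 0 + grp), scale = FALSE)
  H <- X %*% MASS::ginv(crossprod(X)) %*% t(X)
  Fhat <- H %*% Ys
  sv <- svd(Fhat / sqrt(3))
  expect_equal(fit$eig, sv$d[sv$d^2 > 1e-12]^2, tolerance = 1e-10)
  expect_equal(abs(fit$loadings[, 1]), abs(sv$v[, 1]), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("the partition and statistics agree with an independent RDA", {
  skip_if_not_installed("vegan")
  d <- make_trait_data()
  Ys <- standardize(d$Y)
  fit <- rda_fit(Ys, d$species, d$phylum)
  v <- vegan::rda(Ys ~ species + Condition(phylum),
                  data = data.frame(species = d$species,
                                    phylum = d$phylum))
  expect_equal(fit$inertia[["total"]], v$tot.chi, tolerance = 1e-6)
  expect_equal(fit$inertia[["conditional"]], v$pCCA$tot.chi,
               tolerance = 1e-6)
  expect_equal(fit$inertia[["constrained"]], v$CCA$tot.chi,
               tolerance = 1e-6)
  expect_equal(fit$inertia[["unconstrained"]], v$CA$tot.chi,
               tolerance = 1e-6)
  expect_equal(unname(fit$eig),
               unname(v$CCA$eig[seq_along(fit$eig)]), tolerance = 1e-6)
  a <- vegan::anova.cca(v, permutations = 199)
  expect_equal(fit$pseudo_f, a$F[1], tolerance = 1e-6)
})

test_that("inertia conservation holds on arbitrary trait tables", {
  for (s in 1:10) {
    d <- make_trait_data(n_per = 3, n_sp = 5, p = 8, sd = 2, seed = s)
    fit <- rda_fit(standardize(d$Y), d$species, d$phylum)
    expect_lt(abs(fit$inertia[["total"]] -
                    sum(fit$inertia[c("conditional", "constrained",
                                      "unconstrained")])), 1e-8)
    expect_equal(sum(fit$proportion[2:4]), 1, tolerance = 1e-8)
    # loadings are unit-norm with positive dominant entries
    nrm <- sqrt(colSums(fit$loadings^2))
    expect_equal(unname(nrm), rep(1, length(nrm)), tolerance = 1e-8)
    for (a in seq_len(ncol(fit$loadings))) {
      expect_gt(fit$loadings[which.max(abs(fit$loadings[, a])), a], 0)
    }
  }
})

test_that("permutation p-values behave at the boundaries and reproduce", {
  d <- make_trait_data(sd = 0.01)   # essentially perfect separation
  fit <- rda_fit(standardize(d$Y), d$species, d$phylum)
  pt <- permutation_test(fit, n_perm = 999, seed = 4)
  expect_equal(pt$p_value, 1 / 1000)
  pt2 <- permutation_test(fit, n_perm = 999, seed = 4)
  expect_identical(pt$p_value, pt2$p_value)
  expect_error(permutation_test(fit, n_perm = 0), "n_perm")
})

test_that("model trait sets are selected and validated", {
  cols <- c(myconet:::morph_trait_names(), myconet:::network_trait_names(),
            "G_eff_MST", "R_eff_area", "RT_eff_area")
  tab <- as.data.frame(matrix(rnorm(5 * length(cols)), 5,
                              dimnames = list(NULL, cols)))
  m3 <- select_traits(tab, "model3_all")
  expect_equal(ncol(m3), 10)
  expect_false("mean_edge_length" %in% names(m3))
  m1 <- select_traits(tab, "model1_micro")
  expect_equal(ncol(m1), 15)
  expect_error(select_traits(tab[, -1], "model1_micro"),
               "mean_edge_length")
})
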