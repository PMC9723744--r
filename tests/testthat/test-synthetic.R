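test_that("growth without anastomosis yields a tree", {
  for (s in 1:5) {
    p <- preset_params("guerrilla", seed = s)   # fuse_prob = 0
    net <- grow_network(p)
    # tree including the root: E = N - 1
    expect_equal(nrow(net$edges), nrow(net$nodes) - 1)
    expect_equal(meshedness(net), 0)
    expect_true(validate_network(net))
  }
})

test_that("identical parameters and seed reproduce the network exactly", {
  a <- grow_network(preset_params("phalanx", seed = 11))
  b <- grow_network(preset_params("phalanx", seed = 11))
  expect_identical(a$edges[, c("from", "to", "length", "width")],
                   b$edges[, c("from", "to", "length", "width")])
  expect_identical(a$nodes, b$nodes)
})

test_that("generated networks validate and stay root-connected", {
  for (ph in c("guerrilla", "intermediate", "phalanx")) {
    net <- grow_network(preset_params(ph, seed = 2))
    expect_true(validate_network(net))
    expect_false(is.na(net$root_id))
  }
})

test_that("anastomosis frequency drives meshedness monotonically", {
  mesh_at <- function(fp, s) {
    p <- synth_params(fuse_prob = fp, fuse_radius = 5, branch_prob = 0.18,
                      n_steps = 35, seed = s)
    meshedness(grow_network(p))
  }
  seeds <- 1:10
  m0 <- vapply(seeds, function(s) mesh_at(0, s), numeric(1))
  m1 <- vapply(seeds, function(s) mesh_at(0.4, s), numeric(1))
  m2 <- vapply(seeds, function(s) mesh_at(0.9, s), numeric(1))
  expect_true(all(m0 == 0))
  # paired sign test: high fusion beats no fusion
  expect_gt(mean(m2 > m0), 0.8)
  expect_lt(mean(m0), mean(m1))
  expect_lt(mean(m1), mean(m2))
})

test_that("preset phenotypes order as a connectivity gradient", {
  seeds <- 1:12
  stats <- function(ph) {
    t(vapply(seeds, function(s) {
      net <- grow_network(preset_params(ph, seed = s))
      c(mesh = meshedness(net),
        dens = sum(measured_edges(net)$length) / mycelial_area(net))
    }, numeric(2)))
  }
  g <- stats("guerrilla"); i <- stats("intermediate"); p <- stats("phalanx")
  expect_lt(mean(g[, "mesh"]), mean(p[, "mesh"]))
  expect_lt(mean(g[, "dens"]), mean(p[, "dens"]))
  expect_gt(mean(i[, "mesh"]), mean(g[, "mesh"]))
  expect_lt(mean(i[, "mesh"]), mean(p[, "mesh"]))
})

test_that("hyphal segment lengths follow the configured log-normal family", {
  # branch at every step in a wide arena so most edges are single raw
  # log-normal step draws; edges merged from several steps (branches that
  # stopped immediately and were dissolved) are sums and are excluded
  p <- synth_params(n_steps = 7, branch_prob = 1, fuse_prob = 0,
                    fuse_radius = 0.1, heading_noise_sd = 15,
                    branch_angle_mu = 60, branch_angle_sigma = 8,
                    arena_radius = 1e6, n_trunks = 40,
                    inoculum_radius = 2000, step_length_mu = log(20),
                    step_length_sigma = 0.35, seed = 42)
  net <- grow_network(p)
  e <- measured_edges(net)
  single <- vapply(e$polyline, function(pl) is.null(pl) || nrow(pl) <= 2,
                   logical(1))
  lens <- e$length[single]
  expect_gt(length(lens), 1000)
  ks <- suppressWarnings(stats::ks.test(lens, stats::plnorm,
                                        meanlog = log(20), sdlog = 0.35))
  expect_gt(ks$p.value, 0.01)
})

test_that("rendering produces the expected raster geometry", {
  nodes <- data.frame(id = 1:2, x = c(10.2, 90.2), y = c(20.3, 20.3))
  edges <- data.frame(from = 1, to = 2, length = 80, width = 5)
  net <- mycelial_network(nodes, edges)
  rd <- render_image(net, pixel_size = 1)
  # with anti-aliasing the foreground mass is the summed coverage; it
  # equals length x width plus the rounded end caps
  fg <- sum(rd$image)
  expect_lt(abs(fg - 80 * 5) / (80 * 5), 0.15)

  # determinism of the noisy render
  r1 <- render_image(net, pixel_size = 1, noise_sd = 0.1, seed = 7)
  r2 <- render_image(net, pixel_size = 1, noise_sd = 0.1, seed = 7)
  expect_identical(r1$image, r2$image)

  # empty network renders a uniform background
  empty <- mycelial_network(
    data.frame(id = 1, x = 0, y = 0),
    data.frame(from = integer(0), to = integer(0),
               length = numeric(0), width = numeric(0)))
  expect_true(all(render_image(empty, pixel_size = 1)$image == 0))

  # too-coarse pixels are refused
  expect_error(render_image(net, pixel_size = 10), "coarse")
})
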