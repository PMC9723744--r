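# raster fixture helpers ----------------------------------------------------

ribbon_image <- function(width = 5, nrow_ = 40, ncol_ = 100) {
  img <- matrix(0, nrow_, ncol_)
  r0 <- round(nrow_ / 2)
  img[(r0 - (width - 1) / 2):(r0 + (width - 1) / 2), 10:(ncol_ - 10)] <- 1
  img
}

plus_image <- function(width = 5, size = 81) {
  img <- matrix(0, size, size)
  c0 <- (size + 1) / 2
  half <- (width - 1) / 2
  img[(c0 - half):(c0 + half), 10:(size - 10)] <- 1
  img[10:(size - 10), (c0 - half):(c0 + half)] <- 1
  img
}

test_that("preprocess segments clean structures and rejects junk", {
  img <- ribbon_image(5)
  par <- extraction_params(pixel_size = 1, background_radius = 15)
  mask <- preprocess(img, par)
  expect_gte(sum(mask & img > 0.5) / sum(img > 0.5), 0.95)

  # inverted contrast with the invert flag gives the same mask
  pari <- extraction_params(pixel_size = 1, background_radius = 15,
                            invert = TRUE)
  expect_identical(preprocess(1 - img, pari), mask)

  expect_error(preprocess(matrix(0.4, 50, 50), par), "constant image")

  # pure noise: tiny or empty mask
  set.seed(5)
  noise <- matrix(abs(rnorm(200 * 200, 0, 0.05)), 200, 200)
  area <- tryCatch(mean(preprocess(noise, par)), error = function(e) 0)
  expect_lt(area, 0.05)
})

test_that("rendered colonies are covered by their segmentation", {
  net <- grow_network(preset_params("guerrilla", seed = 4))
  rd <- render_image(net, pixel_size = 1)
  mask <- preprocess(rd, extraction_params(pixel_size = 1))
  truth <- rd$image > 0.5
  expect_gte(sum(mask & truth) / sum(truth), 0.95)
})

test_that("thinning produces one-pixel skeletons inside the mask", {
  img <- ribbon_image(5) > 0.5
  sk <- skeletonize_mask(img)
  expect_true(all(img[sk]))                       # subset of the mask
  expect_lte(max(colSums(sk[, 12:88])), 1)        # 1 px wide
  # thinning erodes each free end by about half the ribbon width
  expect_lt(abs(sum(sk) - 81), 6)

  plus <- plus_image(5) > 0.5
  skp <- skeletonize_mask(plus)
  nb <- myconet:::shift_mat(skp * 1, -1, 0) + myconet:::shift_mat(skp * 1, 1, 0) +
    myconet:::shift_mat(skp * 1, 0, -1) + myconet:::shift_mat(skp * 1, 0, 1) +
    myconet:::shift_mat(skp * 1, -1, -1) + myconet:::shift_mat(skp * 1, 1, 1) +
    myconet:::shift_mat(skp * 1, -1, 1) + myconet:::shift_mat(skp * 1, 1, -1)
  junc <- skp & nb >= 3
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(junc * 1)))
  expect_equal(max(lab), 1)                       # one junction cluster

  disk <- (row(matrix(0, 41, 41)) - 21)^2 +
    (col(matrix(0, 41, 41)) - 21)^2 <= 15^2
  expect_lte(sum(skeletonize_mask(disk)), 12)     # blob degenerates
})

test_that("skeletons convert to graphs with correct topology", {
  par <- extraction_params(pixel_size = 1)

  line <- matrix(FALSE, 20, 60)
  line[10, 10:50] <- TRUE
  net <- skeleton_to_graph(line, par)
  expect_equal(sum(net$nodes$kind == "tip"), 2)
  expect_equal(nrow(net$edges), 1)
  expect_lt(abs(net$edges$length - 40), 1.01)

  plus <- skeletonize_mask(plus_image(5) > 0.5)
  netp <- skeleton_to_graph(plus, par)
  expect_equal(sum(netp$nodes$kind == "junction"), 1)
  expect_equal(sum(netp$nodes$kind == "tip"), 4)
  expect_equal(nrow(netp$edges), 4)

  y <- matrix(FALSE, 50, 50)
  y[25, 5:25] <- TRUE
  for (k in 1:15) { y[25 - k, 25 + k] <- TRUE; y[25 + k, 25 + k] <- TRUE }
  nety <- skeleton_to_graph(y, par)
  expect_equal(sum(nety$nodes$kind == "junction"), 1)
  expect_equal(sum(nety$nodes$kind == "tip"), 3)
  jid <- nety$nodes$id[nety$nodes$kind == "junction"]
  expect_equal(sum(nety$edges$from == jid | nety$edges$to == jid), 3)
})

test_that("width estimation recovers ribbon widths and their order", {
  par <- extraction_params(pixel_size = 1, background_radius = 15)
  img <- ribbon_image(5)
  mask <- preprocess(img, par)
  net <- estimate_widths(skeleton_to_graph(skeletonize_mask(mask), par),
                         mask, 1)
  expect_lt(abs(measured_edges(net)$width[1] - 5), 1.01)

  two <- matrix(0, 60, 100)
  two[10:12, 10:90] <- 1          # width 3
  two[40:48, 10:90] <- 1          # width 9
  mask2 <- preprocess(two, par)
  net2 <- estimate_widths(skeleton_to_graph(skeletonize_mask(mask2), par),
                          mask2, 1)
  w <- sort(measured_edges(net2)$width)
  expect_lt(abs(w[1] - 3), 1.01)
  expect_lt(abs(w[length(w)] - 9), 1.01)

  # intensity rescaling leaves the mask, hence the widths, unchanged
  mask3 <- preprocess(two * 0.3, par)
  expect_identical(mask3, mask2)
})

test_that("pruning removes short spurs and dissolves pass-throughs", {
  # path with a 2 px spur hanging off its middle
  sk <- matrix(FALSE, 30, 60)
  sk[15, 5:55] <- TRUE
  sk[14, 30] <- TRUE
  sk[13, 31] <- TRUE
  par <- extraction_params(pixel_size = 1, min_spur_length = 5)
  net <- skeleton_to_graph(sk, par)
  expect_equal(nrow(net$edges), 3)
  clean <- prune_and_clean(net, par)
  expect_equal(nrow(clean$edges), 1)
  expect_equal(sum(clean$nodes$kind == "tip"), 2)

  # a clean network (junctions only, no spurs) passes through unchanged
  net2 <- mycelial_network(
    data.frame(id = 1:4, x = c(0, 10, -5, -5), y = c(0, 0, 8, -8)),
    data.frame(from = 1, to = 2:4, length = c(10, 9.5, 9.5),
               width = c(3, 2, 2)))
  clean2 <- prune_and_clean(net2, extraction_params(min_spur_length = 1))
  expect_equal(sort(clean2$edges$length), sort(net2$edges$length))

  # pruning never disconnects the root component
  for (s in 1:6) {
    net3 <- grow_network(preset_params("intermediate", seed = s))
    cl <- prune_and_clean(net3, extraction_params(min_spur_length = 6))
    expect_true(validate_network(cl))
  }
})

test_that("noise-free colonies survive the render-extract round trip", {
  for (s in 1:5) {
    net <- grow_network(preset_params("guerrilla", seed = s))
    rd <- render_image(net, pixel_size = 1)
    ext <- suppressWarnings(
      extract_network(rd, extraction_params(pixel_size = 1)))
    lt <- sum(measured_edges(net)$length)
    le <- sum(measured_edges(ext)$length)
    expect_lt(abs(le / lt - 1), 0.05)
    expect_lt(abs(nrow(measured_edges(ext)) / nrow(measured_edges(net)) - 1),
              0.10)
    expect_lt(abs(mean(measured_edges(ext)$width) /
                    mean(measured_edges(net)$width) - 1), 0.10)
    # arc lengths at least the chord between endpoints
    e <- measured_edges(ext)
    i1 <- match(e$from, ext$nodes$id); i2 <- match(e$to, ext$nodes$id)
    chord <- sqrt((ext$nodes$x[i1] - ext$nodes$x[i2])^2 +
                    (ext$nodes$y[i1] - ext$nodes$y[i2])^2)
    expect_true(all(e$length >= chord - 1e-6))
  }
})
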