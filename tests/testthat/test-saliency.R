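test_that("affinity graph weights and degrees obey their contracts", {
  sc <- disc_fixture(seed = 2, size = 80)
  sp <- compute_superpixels(sc$image, n_target = 40)
  g <- build_closed_loop_graph(sp, sigma_c = 0.1)
  expect_true(isSymmetric(g$W))
  expect_true(all(diag(g$W) == 0))
  expect_true(all(g$W >= 0))
  # degree equals row sums (independent summation)
  expect_equal(diag(g$D), apply(g$W, 1, sum), tolerance = 1e-15)
  # identical mean colors on a connected pair give weight exp(0) = 1
  sp2 <- sp
  sp2$mean_color[1:2, ] <- rep(sp$mean_color[1, ], each = 2)
  g2 <- build_closed_loop_graph(sp2, sigma_c = 0.1)
  pair <- which(g2$edges[1, ])[1]
  if (g2$edges[1, 2]) expect_equal(g2$W[1, 2], 1)
  expect_error(build_closed_loop_graph(sp, sigma_c = 0), "sigma_c")
})

test_that("boundary closure connects opposite corners of a block layout", {
  # 3x3 block layout built from a synthetic label raster
  img <- matrix(0, 90, 90)
  for (i in 0:2) for (j in 0:2)
    img[i * 30 + 1:30, j * 30 + 1:30] <- (i * 3 + j) * 25
  sp <- compute_superpixels(img, n_target = 9, compactness = 40)
  g <- build_closed_loop_graph(sp)
  corner_ids <- c(sp$labels[1, 1], sp$labels[90, 90],
                  sp$labels[1, 90], sp$labels[90, 1]) + 1
  for (a in corner_ids) for (b in corner_ids)
    if (a != b) expect_true(g$edges[a, b])
})

test_that("manifold ranking matches hand and iterative oracles", {
  # all-zero query maps to all-zero ranking
  W <- matrix(c(0, 1, 1, 0), 2)
  g <- graph_from_W(W)
  expect_warning(r0 <- manifold_rank(g, c(0, 0), 0.5), "constant")
  expect_equal(r0$f, c(0, 0))
  # 2-node hand example: f = (1-a)(D-aW)^-1 y = [2/3, 1/3]
  f <- manifold_rank(g, c(1, 0), 0.5)$f
  expect_equal(f, c(2 / 3, 1 / 3), tolerance = 1e-12)
  # random connected graphs against the independent Jacobi fixed-point solve
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    W <- random_connected_graph(n)
    alpha <- runif(1, 0.3, 0.9)
    y <- as.numeric(seq_len(n) %in% sample(n, sample(1:3, 1)))
    g <- graph_from_W(W)
    expect_equal(manifold_rank(g, y, alpha)$f,
                 jacobi_rank_oracle(W, y, alpha), tolerance = 1e-10)
  }
  expect_error(manifold_rank(g, y, 1.5), "alpha")
})

test_that("boundary-stage saliency is the product of four side maps", {
  sc <- disc_fixture(seed = 4, size = 100)
  sp <- compute_superpixels(sc$image, n_target = 80)
  g <- build_closed_loop_graph(sp)
  s1 <- boundary_stage_saliency(g, sp)
  expect_true(all(s1$scores >= 0 & s1$scores <= 1))
  # product is bounded by each factor pointwise
  for (side in s1$sides)
    expect_true(all(s1$scores <= side + 1e-12))
  # a node whose normalized rank is 1 on some side scores 0 overall
  top_rank1 <- which(s1$sides$top == 0)
  expect_true(all(s1$scores[top_rank1] == 0))
  # object superpixels outrank background ones on the fixture
  inobj <- tapply(c(sc$mask), c(sp$labels + 1L), mean) > 0.5
  expect_gt(mean(s1$scores[inobj]), mean(s1$scores[!inobj]))
})

test_that("foreground-query stage sharpens the object/background contrast", {
  sc <- disc_fixture(seed = 6, size = 100)
  sal <- saliency_map(sc$image, n_target = 80)
  sp <- sal$sp
  inobj <- tapply(c(sc$mask), c(sp$labels + 1L), mean) > 0.5
  sep1 <- mean(sal$stage1$scores[inobj]) - mean(sal$stage1$scores[!inobj])
  sep2 <- mean(sal$stage2$scores[inobj]) - mean(sal$stage2$scores[!inobj])
  expect_gte(sep2, sep1 - 0.05)
  expect_gt(sep2, 0.5)
  # constant stage-one map is degenerate
  g <- sal$graph
  const <- structure(list(scores = rep(0.5, g$n)), class = "saliency_field")
  expect_error(foreground_query_saliency(g, const), "degenerate")
})

test_that("all-node query reproduces the iterative solve of (D-aW)^-1 1", {
  set.seed(55)
  W <- random_connected_graph(12)
  g <- graph_from_W(W)
  f <- manifold_rank(g, rep(1, 12), 0.7)$f
  expect_equal(f, jacobi_rank_oracle(W, rep(1, 12), 0.7), tolerance = 1e-10)
  # seed selection: scores >= mean(S) become queries
  s1 <- structure(list(scores = c(rep(0.2, 6), rep(0.9, 6))),
                  class = "saliency_field")
  out <- foreground_query_saliency(g, s1, alpha = 0.7)
  expect_equal(out$seeds, c(rep(0, 6), rep(1, 6)))
})

test_that("upsampling maps scores onto pixels by label", {
  sc <- disc_fixture(seed = 8, size = 60)
  sp <- compute_superpixels(sc$image, n_target = 30)
  up <- upsample_saliency(rep(0.5, sp$n), sp)
  expect_true(all(up == 0.5))
  scores <- runif(sp$n)
  up <- upsample_saliency(scores, sp)
  # histogram equals the score multiset weighted by superpixel areas
  cnt <- table(factor(c(up), levels = sort(unique(scores))))
  expect_equal(as.integer(cnt), sp$area[order(scores)])
  expect_error(upsample_saliency(scores[-1], sp), "match")
})
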