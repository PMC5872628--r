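test_that("block amplitudes are tile means", {
  img <- matrix(77, 32, 32)
  g <- block_amplitudes(img, 4)
  expect_true(all(g$amplitudes == 77))
  # 4x4 image of 2x2 blocks
  img2 <- rbind(cbind(matrix(0, 2, 2), matrix(255, 2, 2)),
                cbind(matrix(255, 2, 2), matrix(0, 2, 2)))
  g2 <- block_amplitudes(img2, 2)
  expect_equal(g2$amplitudes, matrix(c(0, 255, 255, 0), 2))
  # equal tiles: grand mean preserved
  set.seed(4)
  img3 <- matrix(runif(64 * 64, 0, 255), 64, 64)
  g3 <- block_amplitudes(img3, 8)
  expect_equal(mean(g3$amplitudes), mean(img3), tolerance = 1e-12)
  expect_error(block_amplitudes(img, 64), "resolution")
})

test_that("phosphenes render as truncated peak-normalized gaussians", {
  img <- matrix(0, 60, 60)
  g <- block_amplitudes(img, 4)
  expect_true(all(render_phosphenes(g)$raster == 0))
  g$amplitudes[2, 3] <- 255
  sigma <- 4
  p <- render_phosphenes(g, sigma = sigma)
  cr <- g$centers_row[2]; cc <- g$centers_col[3]
  expect_equal(p$raster[cr, cc], 255)
  expect_equal(max(p$raster), 255)
  # closed-form value at radius sigma
  expect_equal(p$raster[cr + sigma, cc], 255 * exp(-0.5), tolerance = 1e-9)
  # zero beyond the 3-sigma truncation radius
  rr <- row(p$raster) - cr; cc2 <- col(p$raster) - cc
  expect_true(all(p$raster[rr^2 + cc2^2 > (3 * sigma)^2] == 0))
  expect_error(render_phosphenes(g, sigma = -1), "sigma")
})

test_that("LRG percepts respect pitch, constancy, and monotonicity", {
  img <- matrix(180, 64, 64)
  p <- lrg(img, 8)
  expect_equal(max(p$raster), 180)
  # doubling resolution halves pitch and sigma at fixed ratio
  p2 <- lrg(img, 16)
  expect_equal(p2$grid$pitch, p$grid$pitch / 2)
  expect_equal(p2$sigma, p$sigma / 2)
  # non-overlapping dots reproduce tile amplitudes exactly at centers
  set.seed(6)
  img3 <- matrix(runif(64 * 64, 0, 255), 64, 64)
  g <- block_amplitudes(img3, 8)
  p3 <- render_phosphenes(g, sigma = g$pitch / 6)
  expect_equal(p3$raster[cbind(rep(g$centers_row, 8),
                               rep(g$centers_col, each = 8))],
               c(g$amplitudes), tolerance = 1e-12)
  # raising an amplitude never lowers any raster pixel
  g_hi <- g; g_hi$amplitudes[3, 3] <- min(255, g$amplitudes[3, 3] + 50)
  p_hi <- render_phosphenes(g_hi, sigma = g$pitch / 2)
  p_lo <- render_phosphenes(g, sigma = g$pitch / 2)
  expect_true(all(p_hi$raster >= p_lo$raster - 1e-12))
})

test_that("batch rendering emits one percept per configured resolution", {
  img <- matrix(128, 96, 96)
  ps <- lrg_batch(img)
  expect_named(ps, c("8", "16", "24", "32", "48", "64"))
  expect_length(ps, 6)
  for (p in ps) expect_true(all(p$raster >= 0 & p$raster <= 255))
})

test_that("density normalization dims wide dots", {
  img <- matrix(200, 48, 48)
  g <- block_amplitudes(img, 4)
  pk <- render_phosphenes(g, sigma = 3, normalize = "peak")
  dn <- render_phosphenes(g, sigma = 3, normalize = "density")
  expect_equal(max(dn$raster), max(pk$raster) / (2 * pi * 9), tolerance = 1e-9)
})
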