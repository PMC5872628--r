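test_that("sobel gradients obey closed-form and symmetry oracles", {
  expect_equal(max(sobel_gradient(matrix(5, 10, 10), 3)$magnitude), 0)
  # vertical 0/255 step: |Gx| = 255 * (1+2+1) = 1020 beside the step
  img <- matrix(0, 16, 16); img[, 9:16] <- 255
  g <- sobel_gradient(img, 3)
  expect_equal(unique(abs(g$Gx[, 8])), 1020)
  expect_equal(unique(abs(g$Gx[, 9])), 1020)
  expect_equal(max(abs(g$Gx[, c(1:6, 11:16)])), 0)
  expect_equal(max(abs(g$Gy)), 0)
  # transposition swaps Gx and Gy and transposes the magnitude
  set.seed(5)
  r <- matrix(runif(256, 0, 255), 16, 16)
  a <- sobel_gradient(r, 3); b <- sobel_gradient(t(r), 3)
  expect_equal(b$Gx, t(a$Gy), tolerance = 1e-12)
  expect_equal(b$Gy, t(a$Gx), tolerance = 1e-12)
  expect_equal(b$magnitude, t(a$magnitude), tolerance = 1e-12)
  # magnitude invariant to a constant offset
  a2 <- sobel_gradient(r + 40, 3)
  expect_equal(a2$magnitude, a$magnitude, tolerance = 1e-9)
  expect_error(sobel_gradient(r, 5), "kernel_size")
})

test_that("7x7 kernel is the binomially smoothed 3x3 derivative", {
  k <- prosthvis:::sobel_vectors(7L)
  expect_equal(k$smooth, choose(6, 0:6))
  expect_equal(k$deriv, c(-1, -4, -5, 0, 5, 4, 1))
  # consistency: both scales respond at the same step location
  img <- matrix(0, 20, 20); img[, 11:20] <- 100
  g7 <- sobel_gradient(img, 7)
  expect_lte(abs(which.max(g7$magnitude[10, ]) - 10.5), 1)
})

test_that("geometric-mean fusion matches pointwise arithmetic", {
  m <- matrix(3, 4, 4)
  expect_equal(multiscale_magnitude(list(m, m)), m)
  expect_equal(multiscale_magnitude(list(matrix(4, 2, 2), matrix(9, 2, 2))),
               matrix(6, 2, 2))
  expect_equal(multiscale_magnitude(list(m, m * 0)), m * 0)
  # bounded by per-scale min and max pointwise
  set.seed(9)
  a <- matrix(runif(100, 0, 10), 10); b <- matrix(runif(100, 0, 10), 10)
  fused <- multiscale_magnitude(list(a, b))
  expect_true(all(fused >= pmin(a, b) - 1e-12))
  expect_true(all(fused <= pmax(a, b) + 1e-12))
  expect_error(multiscale_magnitude(list(a, matrix(1, 2, 2))), "shape")
})

test_that("edge thresholding covers otsu, fixed, and degenerate cases", {
  z <- matrix(0, 8, 8)
  expect_equal(sum(threshold_edges(z, "otsu")), 0)
  m <- matrix(c(0, 2, 0, 5), 2, 2)
  expect_equal(threshold_edges(m, "fixed", value = 0), (m > 0) * 1)
  expect_error(threshold_edges(m, "fixed"), "value")
  expect_error(threshold_edges(m - 3, "otsu"), "nonnegative")
})

test_that("multiscale fusion suppresses noise-driven spurious edges", {
  set.seed(11)
  H <- 128; W <- 128; stepc <- 64
  img <- matrix(0, H, W); img[, (stepc + 1):W] <- 255
  img <- img + matrix(rnorm(H * W, 0, 10), H)
  g3 <- sobel_gradient(img, 3)$magnitude
  fused <- multiscale_magnitude(list(g3, sobel_gradient(img, 7)$magnitude))
  band <- abs(col(img) - (stepc + 0.5)) <= 3
  # matched relative thresholds: same fraction of each map's own maximum
  m3 <- threshold_edges(g3, "fixed", value = 0.1 * max(g3))
  mf <- threshold_edges(fused, "fixed", value = 0.1 * max(fused))
  expect_lt(sum(mf[!band]), sum(m3[!band]))
  # both still detect the true edge
  expect_gt(sum(mf[band]), H)
})
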