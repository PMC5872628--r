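test_that("foreground/background split partitions the image", {
  set.seed(2)
  img <- matrix(sample(0:255, 64, TRUE), 8, 8)
  mask <- matrix(0, 8, 8); mask[3:6, 3:6] <- 1
  fb <- split_foreground_background(img, mask)
  expect_equal(fb$f_F + fb$f_B, img)
  expect_true(all(fb$f_F[mask == 0] == 0))
  expect_true(all(fb$f_B[mask == 1] == 0))
  expect_equal(split_foreground_background(img, mask * 0)$f_F, img * 0)
  expect_error(split_foreground_background(img, mask[1:4, ]), "mismatch")
})

test_that("FEBR halves the background and binarizes foreground edges", {
  img <- matrix(255, 20, 20)
  mask <- matrix(0, 20, 20); mask[6:15, 6:15] <- 1
  out <- febr(img, mask, threshold = 1)
  # background pixel 255 -> 127 (floor halving keeps 0..127)
  expect_true(all(out[mask == 0] == 127))
  expect_true(all(out[mask == 0] == floor(img[mask == 0] / 2)))
  expect_true(all(out[mask == 1] %in% c(0, 255)))
  # empty mask: warn and return the halved image
  expect_warning(out0 <- febr(img, mask * 0), "empty")
  expect_equal(out0, floor(img / 2))
})

test_that("FEBR foreground edges trace a step inside the object", {
  # 8x8 toy: foreground square holding a vertical 0/255 step
  img <- matrix(0, 8, 8); img[, 5:8] <- 255
  mask <- matrix(0, 8, 8); mask[2:7, 2:7] <- 1
  out <- febr(img, mask, threshold = 500)
  expect_true(all(out[mask == 1] %in% c(0, 255)))
  # the step band (cols 4-5) inside the mask must light up
  expect_true(all(out[3:6, 4:5] == 255))
  # hand-halved background
  expect_equal(out[1, ], floor(img[1, ] / 2))
})

test_that("zoom window is the padded tight bounding box", {
  m <- matrix(1, 12, 15)
  zw <- zoom_window(m, 0)
  expect_equal(unlist(zw[c("top", "left", "bottom", "right")]),
               c(top = 1, left = 1, bottom = 12, right = 15))
  m2 <- matrix(0, 30, 30); m2[10, 20] <- 1
  expect_equal(unlist(zoom_window(m2, 0)),
               c(top = 10, left = 20, bottom = 10, right = 20))
  # L-shaped mask vs brute-force min/max scan
  m3 <- matrix(0, 40, 40)
  m3[5:30, 8] <- 1; m3[30, 8:22] <- 1
  zw3 <- zoom_window(m3, 0)
  idx <- which(m3 == 1, arr.ind = TRUE)
  expect_equal(c(zw3$top, zw3$bottom, zw3$left, zw3$right),
               c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2])))
  expect_error(zoom_window(m3 * 0), "empty")
})

test_that("FZE zooms the object to fill the field and removes background", {
  sc <- disc_fixture(seed = 13, size = 120, bg = "flat")
  # off-center small object
  spec <- scene_spec(size = c(320, 320), object_shape = "square",
                     object_gray = 220, center = c(90, 230), radius = 20,
                     background = list(type = "flat", gray = 60), seed = 1)
  s <- generate_scene(spec)
  out <- fze(s$image, s$mask, pad_frac = 0.05)
  expect_true(all(out %in% c(0, 255)))
  # rescaled object's bounding box covers >= 80% of the shorter field side
  lit <- which(out == 255, arr.ind = TRUE)
  span <- max(max(lit[, 1]) - min(lit[, 1]), max(lit[, 2]) - min(lit[, 2]))
  expect_gte(span + 1, 0.8 * min(dim(out)))
  expect_error(fze(s$image, s$mask * 0), "degenerate")
})

test_that("full-field mask makes FZE pure edge detection", {
  set.seed(3)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  full <- matrix(1, 64, 64)
  out <- fze(img, full, pad_frac = 0)
  expect_equal(out, 255 * multiscale_edges(img))
})
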