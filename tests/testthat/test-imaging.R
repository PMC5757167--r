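test_that("grayscale conversion is identity on gray and luminance on color", {
  g <- matrix(runif(64, 0, 255), 8, 8)
  expect_identical(to_grayscale(g), g)
  rgb_flat <- array(123, dim = c(8, 8, 3))
  expect_equal(to_grayscale(rgb_flat), matrix(123, 8, 8), tolerance = 1e-12)
  set.seed(7)
  rgb <- array(runif(8 * 8 * 3, 0, 255), dim = c(8, 8, 3))
  expected <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    expected[i, j] <- 0.299 * rgb[i, j, 1] + 0.587 * rgb[i, j, 2] +
      0.114 * rgb[i, j, 3]
  }
  expect_equal(to_grayscale(rgb), expected, tolerance = 1e-12)
  expect_error(to_grayscale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("background removal zeroes only sub-threshold pixels", {
  img <- matrix(c(10, 29, 30, 200), 2, 2)
  expect_equal(remove_background(img, 30), matrix(c(0, 0, 30, 200), 2, 2))
  z <- matrix(0, 4, 4)
  expect_identical(remove_background(z, 30), z)
  img2 <- matrix(runif(16, 0, 255), 4, 4)
  expect_identical(remove_background(img2, 0), img2)
})

test_that("median denoising equals the brute-force windowed median", {
  const <- matrix(80, 30, 30)
  expect_equal(denoise(const, 3), const)
  salt <- matrix(100, 40, 40); salt[20, 20] <- 255
  expect_equal(denoise(salt, 3), matrix(100, 40, 40))
  set.seed(9)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  r <- 2
  naive <- img
  clampi <- function(i, n) pmin(pmax(i, 1), n)   # replicate padding
  for (i in 1:64) for (j in 1:64) {
    naive[i, j] <- median(img[clampi((i - r):(i + r), 64),
                              clampi((j - r):(j + r), 64)])
  }
  expect_equal(denoise(img, r), naive, tolerance = 1e-9)
  expect_error(denoise(img, 0), "positive")
  # the radius is capped on tiny images instead of destroying them
  tiny <- matrix(c(0, 255), 12, 12)
  expect_message(denoise(tiny, 10), "capped")
})

test_that("footstalk removal cuts the longest thin chain and only it", {
  ell <- ellipse_mask()
  expect_identical(remove_footstalk(ell), ell)     # nothing thin to cut
  with_stalk <- ell
  with_stalk[90:129, 59:61] <- 255                 # 3 px wide, 40 px long
  rec <- remove_footstalk(with_stalk)
  expect_lt(abs(sum(rec > 0) - sum(ell > 0)) / sum(ell > 0), 0.05)
  two <- ell
  two[90:129, 59:61] <- 255                        # length 40
  two[25:44, 95:97] <- 255                         # length 20
  rec2 <- remove_footstalk(two)
  expect_identical(sum(rec2[91:129, 59:61] > 0), 0L)   # longest removed
  expect_gt(sum(rec2[25:44, 95:97] > 0), 0)            # shorter kept
  expect_error(remove_footstalk(matrix(0, 10, 10)), "foreground")
})

test_that("major-axis alignment brings any rotation within 2 degrees of vertical", {
  fam <- leaf_families()$family[[1]]
  for (theta in seq(0, 170, by = 10)) {
    img <- render_leaf(fam, 120, rotation = theta)
    al <- suppressMessages(align_major_axis(img))
    dev <- abs(leafsrc:::principal_axis(al > 1)$deviation)
    expect_lt(dev, 2)
  }
})

test_that("alignment crops tightly and skips isotropic shapes", {
  ell <- ellipse_mask()
  al <- suppressMessages(align_major_axis(ell))
  px <- which(al > 1, arr.ind = TRUE)
  expect_equal(min(px[, 1]), 1)
  expect_equal(min(px[, 2]), 1)
  expect_equal(max(px[, 1]), nrow(al))
  expect_equal(max(px[, 2]), ncol(al))
  disk <- ellipse_mask(120, 120, 60, 60, 30, 30)
  expect_message(align_major_axis(disk), "isotropic")
  al2 <- suppressMessages(align_major_axis(disk))
  expect_equal(dim(al2), c(61, 61))   # tight crop of the unrotated disk
  expect_error(align_major_axis(matrix(0, 10, 10)), "foreground")
})

test_that("contour extraction yields a thin boundary of the right length", {
  rect <- matrix(0, 40, 40); rect[10:30, 8:25] <- 255
  e <- extract_contour(rect)
  expect_true(all(e %in% c(0, 255)))
  perim <- 2 * (21 + 18)
  expect_lt(abs(sum(e > 0) - perim) / perim, 0.15)
  for (r in c(10, 15, 20)) {
    m <- ellipse_mask(64, 64, 32.5, 32.5, r, r)
    e <- extract_contour(m)
    expect_lt(abs(sum(e > 0) - 2 * pi * r) / (2 * pi * r), 0.15)
    # every edge pixel lies within 2 px of the true circle
    px <- which(e > 0, arr.ind = TRUE)
    dist_to_circle <- abs(sqrt((px[, 1] - 32.5)^2 + (px[, 2] - 32.5)^2) - r)
    expect_lt(max(dist_to_circle), 2)
  }
  expect_equal(extract_contour(matrix(50, 20, 20)), matrix(0, 20, 20))
  expect_error(extract_contour(matrix(0, 20, 20)), "foreground")
})

test_that("raster normalization is 32x32, [0,1], and translation invariant", {
  full <- matrix(runif(1024, 0, 255), 32, 32)
  full[1, 1] <- 255; full[32, 32] <- 255    # full-extent foreground
  expect_equal(normalize_raster(full), full / 255, tolerance = 1e-9)
  big <- matrix(0, 64, 64); big[10:50, 20:40] <- 200
  out <- normalize_raster(big)
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(out >= 0 & out <= 1))
  blob <- ellipse_mask(40, 30, 20, 15, 12, 8)
  pad1 <- matrix(0, 100, 100); pad1[3:42, 5:34] <- blob
  pad2 <- matrix(0, 100, 100); pad2[55:94, 63:92] <- blob
  expect_equal(normalize_raster(pad1), normalize_raster(pad2))
  expect_error(normalize_raster(matrix(0, 10, 10)), "foreground")
})

test_that("the full chain returns a valid raster and tolerates rotation", {
  fam <- leaf_families()$family[[1]]
  leaf <- render_leaf(fam, 160, rotation = 25,
                      stalk = list(width = 3, length = 20))
  out <- suppressMessages(preprocess(leaf))
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(out >= 0 & out <= 1))
  expect_gt(sum(out > 0), 0)
  r0 <- suppressMessages(preprocess(render_leaf(fam, 160, rotation = 0)))
  r90 <- suppressMessages(preprocess(render_leaf(fam, 160, rotation = 90)))
  diff_frac <- sum((r0 > 0.5) != (r90 > 0.5)) / sum(r0 > 0.5)
  expect_lt(diff_frac, 0.10)
  expect_error(suppressMessages(preprocess(matrix(0, 50, 50))),
               "stage '")
})

test_that("re-normalizing a preprocessed raster is stable", {
  fam <- leaf_families()$family[[4]]
  r1 <- suppressMessages(preprocess(render_leaf(fam, 160, rotation = 40)))
  r2 <- normalize_raster(suppressMessages(align_major_axis(r1 * 255)), 32)
  expect_lt(mean(abs(r2 - r1) > 0.5), 0.05)
})

test_that("preprocessing settings round-trip through JSON", {
  cfg <- preprocess_config(bg_thresh = 25, median_radius = 7, out_size = 24,
                           atom = "contour")
  path <- withr::local_tempfile(fileext = ".json")
  write_preprocess_config(cfg, path)
  cfg2 <- read_preprocess_config(path)
  expect_equal(cfg2[names(cfg2) != "out_size"], cfg[names(cfg) != "out_size"])
  expect_equal(cfg2$out_size, cfg$out_size)
})
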