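test_that("8-bit PNG values scale to [0,1] by 255 and round-trip exactly", {
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 1, ] <- c(255, 0, 0) / 255
  arr[1, 2, ] <- c(17, 204, 51) / 255
  arr[2, 1, ] <- c(255, 255, 255) / 255
  arr[2, 2, ] <- c(128, 128, 128) / 255
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  img <- load_image(path)
  expect_s3_class(img, "rgb_image")
  expect_identical(dim(img$pixels), c(2L, 2L, 3L))
  expect_equal(img$pixels, arr) # bit-exact round trip
  expect_equal(img$pixels[1, 1, ], c(1, 0, 0))
  expect_equal(img$pixels[2, 2, ], rep(128 / 255, 3), tolerance = 1e-12)
})

test_that("grayscale and missing files are rejected with clear errors", {
  gray <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16), 4, 4), gray)
  expect_error(load_image(gray), "not RGB")
  expect_error(load_image("no/such/file.png"), "does not exist")
  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(load_image(txt), "unsupported image format")
})

test_that("JPEG input decodes to the same container as PNG", {
  arr <- array(0, dim = c(16, 16, 3))
  arr[, , 1] <- 0.8; arr[, , 2] <- 0.4; arr[, , 3] <- 0.2
  path <- withr::local_tempfile(fileext = ".jpg")
  EBImage::writeImage(EBImage::Image(aperm(arr, c(2, 1, 3)),
                                     colormode = "Color"), path, quality = 95)
  img <- load_image(path)
  expect_identical(dim(img$pixels), c(16L, 16L, 3L))
  expect_equal(img$pixels, arr, tolerance = 0.02) # lossy codec, loose check
})

test_that("ROI channel means equal a brute-force pixel loop over the union", {
  img <- gradient_image(64, 64)
  roi1 <- rect_mask(64, 64, 5:40, 10:30)
  roi2 <- rect_mask(64, 64, 30:60, 20:50) # overlaps roi1
  got <- roi_channel_means(img, list(roi1, roi2))
  union <- roi1 | roi2
  for (c in 1:3) {
    vals <- numeric(0)
    for (i in 1:64) for (j in 1:64) {
      if (union[i, j]) vals <- c(vals, img$pixels[i, j, c])
    }
    expect_equal(unname(got$mean[c]), mean(vals), tolerance = 1e-12)
    expect_equal(unname(got$sem[c]), sd(vals) / sqrt(length(vals)),
                 tolerance = 1e-12)
  }
  expect_equal(got$n_pixels, sum(union))
  # permutation invariance in ROI order
  swapped <- roi_channel_means(img, list(roi2, roi1))
  expect_identical(got$mean, swapped$mean)
})

test_that("ROI means on uniform and two-pixel fixtures are exact", {
  img <- uniform_image(8, 8, c(0.6, 0.5, 0.4))
  got <- roi_channel_means(img, rect_mask(8, 8, 2:5, 3:6))
  expect_equal(unname(got$mean), c(0.6, 0.5, 0.4))
  two <- uniform_image(2, 2, c(0, 0, 0))
  two$pixels[1, 1, 1] <- 0.2
  two$pixels[1, 2, 1] <- 0.4
  m <- roi_channel_means(two, rect_mask(2, 2, 1, 1:2))
  expect_equal(unname(m$mean[1]), 0.3)
  expect_error(roi_channel_means(img, matrix(FALSE, 8, 8)), "degenerate")
  expect_error(roi_channel_means(img, list()), "at least one ROI")
})

test_that("polygon ROIs rasterize by pixel-center even-odd inclusion", {
  # unit square from (1,1) to (4,4): centers at x,y in 2..3 are inside
  sq <- rbind(c(1.5, 1.5), c(3.5, 1.5), c(3.5, 3.5), c(1.5, 3.5))
  m <- polygon_to_mask(sq, height = 6, width = 6)
  expect_equal(sum(m), 4)
  expect_true(all(m[3:4, 3:4])) # rows/cols are 1-based; centers (2,2)..(3,3)
  # round trip through the JSON polygon file format
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(image_id = "x", polygons = list(sq)), path)
  m2 <- load_roi_mask(path, height = 6, width = 6)
  expect_identical(m, m2)
})

test_that("quality screening scores glare, blur and blood as specified", {
  flat <- uniform_image(32, 32, c(0.5, 0.5, 0.5))
  roi <- rect_mask(32, 32, 8:24, 8:24)
  rep1 <- qc_screen(flat, roi)
  expect_equal(rep1$glare_fraction, 0)
  expect_equal(rep1$blood_fraction, 0)
  expect_false(rep1$pass) # flat field has zero Laplacian variance
  expect_identical(rep1$reasons, "blur")

  # 10% of the ROI saturated -> glare failure at glare_max = 0.05
  img <- gradient_image(32, 32)
  sat <- img
  idx <- which(roi)
  n_sat <- ceiling(0.10 * length(idx))
  for (c in 1:3) {
    layer <- sat$pixels[, , c]
    layer[idx[seq_len(n_sat)]] <- 1
    sat$pixels[, , c] <- layer
  }
  rep2 <- qc_screen(rgb_image(sat$pixels), roi)
  expect_true("glare" %in% rep2$reasons)
  expect_gte(rep2$glare_fraction, 0.05)

  # textured in-focus render passes; a strong Gaussian blur fails on focus
  rw <- render_wound_image(0.7, seed = 5, size = 64)
  expect_true(qc_screen(rw$image, rw$mask)$pass)
  blurred <- inject_artifacts(rw$image, "blur", severity = 5 / 6,
                              seed = 1, roi = rw$mask)
  rep3 <- qc_screen(blurred, rw$mask)
  expect_false(rep3$pass)
  expect_true("blur" %in% rep3$reasons)
  expect_lt(rep3$blur_score, qc_screen(rw$image, rw$mask)$blur_score)
})

test_that("adding saturated pixels never flips glare from fail to pass", {
  img <- gradient_image(32, 32)
  roi <- rect_mask(32, 32, 4:28, 4:28)
  idx <- which(roi)
  fracs <- numeric(0)
  failed <- logical(0)
  for (n_sat in seq(0, length(idx), by = 60)) {
    cur <- img$pixels
    if (n_sat > 0) {
      for (c in 1:3) {
        layer <- cur[, , c]
        layer[idx[seq_len(n_sat)]] <- 1
        cur[, , c] <- layer
      }
    }
    rep_i <- qc_screen(rgb_image(cur), roi)
    fracs <- c(fracs, rep_i$glare_fraction)
    failed <- c(failed, "glare" %in% rep_i$reasons)
  }
  expect_true(all(diff(fracs) >= 0))
  expect_true(all(diff(failed) >= 0)) # once failing, stays failing
})

test_that("index maps render constant fields mid-gray and track oxygenation", {
  uni <- uniform_image(16, 16, c(0.6, 0.5, 0.4))
  expect_true(all(render_index_map(uni, "r_minus_b") == 0.5))
  expect_true(all(render_index_map(uni, "g") == 0.5))
  expect_error(render_index_map(uni, "chroma"), "should be one of")

  # two-region image: high-StO2 bed brighter than low-StO2 bed in R-B map
  hi <- wound3ccd:::wound_reflectance(0.85, optical_params())
  lo <- wound3ccd:::wound_reflectance(0.35, optical_params())
  arr <- array(0, dim = c(16, 16, 3))
  for (c in 1:3) {
    arr[, 1:8, c] <- hi[c]
    arr[, 9:16, c] <- lo[c]
  }
  arr <- arr + array(runif(length(arr), -0.01, 0.01), dim = dim(arr))
  m <- render_index_map(rgb_image(pmin(pmax(arr, 0), 1)), "r_minus_b")
  expect_gt(mean(m[, 1:8]), mean(m[, 9:16]))
})

test_that("scale-invariant index maps ignore uniform brightness rescaling", {
  img <- gradient_image(24, 24)
  dimmed <- rgb_image(img$pixels * 0.6)
  expect_equal(render_index_map(img, "rb_over_g"),
               render_index_map(dimmed, "rb_over_g"), tolerance = 1e-10)
  # the underlying per-pixel index is scale-invariant only for (R-B)/G
  expect_equal(wound3ccd:::pixel_index(dimmed$pixels, "rb_over_g"),
               wound3ccd:::pixel_index(img$pixels, "rb_over_g"),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    wound3ccd:::pixel_index(dimmed$pixels, "rb_over_r2b2"),
    wound3ccd:::pixel_index(img$pixels, "rb_over_r2b2"),
    tolerance = 1e-10)))
})
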