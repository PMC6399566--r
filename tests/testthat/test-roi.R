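test_that("quarter downscaling follows the block-average rule", {
  expect_equal(dim(downscale_quarter(matrix(0, 3000, 5000))), c(750, 1250))
  expect_error(downscale_quarter(matrix(0, 3, 3)), "at least 4x4")
  cst <- downscale_quarter(matrix(7.5, 8, 12))
  expect_true(all(cst == 7.5))
  # 8x8 checkerboard: every 4x4 block holds 8 ones and 8 zeros -> mean 0.5
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(downscale_quarter(cb), matrix(0.5, 2, 2))
  # hand-computed non-uniform block means
  m <- matrix(0, 4, 8)
  m[1, 1] <- 16
  m[, 5:8] <- 2
  expect_equal(downscale_quarter(m), matrix(c(1, 2), 1, 2))
})

test_that("projection profiles sum along the orthogonal axis", {
  img <- matrix(1, 3, 4)
  expect_equal(project_profile(img, "column")$values, rep(3, 4))
  expect_equal(project_profile(img, "row")$values, rep(4, 3))
  z <- matrix(0, 5, 6)
  z[, 4] <- 2
  p <- project_profile(z, "column")$values
  expect_equal(which(p != 0), 4L)
})

test_that("column band follows the mean-plus-sd threshold rule", {
  pr <- structure(list(values = c(0, 0, 10, 10, 10, 0, 0),
                       axis = "column"), class = "projection_profile")
  # mu = 4.286, population sd = 4.949 -> threshold 9.23: run = columns 3..5
  expect_equal(select_column_band(pr), c(3L, 5L))
  cst <- structure(list(values = rep(4, 9), axis = "column"),
                   class = "projection_profile")
  expect_warning(band <- select_column_band(cst), "zero-variance")
  expect_equal(band, c(1L, 9L))
  # band is always a contiguous interval containing the maximum
  set.seed(4)
  for (k in 1:20) {
    v <- stats::runif(40)
    v[15:20] <- v[15:20] + 3
    b <- select_column_band(structure(list(values = v, axis = "column"),
                                      class = "projection_profile"))
    expect_true(b[1] <= which.max(v) && which.max(v) <= b[2])
  }
})

test_that("row band finds the inter-structure dip and the pelvis jump", {
  # V down to a nadir, plateau, then a cliff in the lower half
  v <- c(seq(300, 100, length.out = 15), seq(110, 280, length.out = 10),
         rep(290, 20), rep(300, 5), rep(800, 10))
  pr <- structure(list(values = v, axis = "row"),
                  class = "projection_profile")
  b <- select_row_band(pr)
  expect_true(abs(b[1] - 15) <= 2)    # nadir of the V
  expect_true(abs(b[2] - 50) <= 3)    # cliff into the bright region
  mono <- structure(list(values = seq_len(30) * 10, axis = "row"),
                    class = "projection_profile")
  expect_warning(bm <- select_row_band(mono), "no local minimum")
  expect_equal(bm[1], 1L)
})

test_that("ROI isolation is deterministic and recalls phantom vertebrae", {
  sm <- cached_phantom(cobb_deg = 20, seed = 3)
  r1 <- isolate_spine_roi(sm$image)
  r2 <- isolate_spine_roi(sm$image)
  expect_identical(r1$box, r2$box)
  # crop equals image content within the box, bit-exact
  q <- downscale_quarter(sm$image)
  expect_identical(r1$image,
                   q[r1$box$top:r1$box$bottom, r1$box$left:r1$box$right])
  # pure noise: warning-flagged full frame
  set.seed(8)
  noise <- matrix(stats::runif(200 * 160, 0, 255), 200, 160)
  expect_warning(rn <- isolate_spine_roi(noise), "full frame")
  expect_equal(unlist(rn$box), c(top = 1, bottom = 50, left = 1,
                                 right = 40))
})

test_that("ROI contains all vertebra centroids across phantoms", {
  cobbs <- c(5, 12, 20, 28, 35, 42)
  for (k in seq_along(cobbs)) {
    spec <- phantom_spec(cobb_deg = cobbs[k],
                         direction = ifelse(k %% 2 == 0, "left", "right"),
                         seed = 100 + k)
    sm <- generate_phantom(spec)
    roi <- isolate_spine_roi(sm$image)
    cr <- spec$centers / 4
    cc <- spec$centerline[round(spec$centers)] / 4
    inside <- cr >= roi$box$top & cr <= roi$box$bottom &
              cc >= roi$box$left & cc <= roi$box$right
    expect_equal(mean(inside), 1,
                 label = sprintf("centroid recall at %g deg", cobbs[k]))
  }
})
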