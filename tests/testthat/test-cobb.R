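test_that("minimum bounding rectangle of an axis-aligned rectangle", {
  mask <- matrix(0, 50, 70)
  mask[10:39, 20:59] <- 1
  mb <- min_bounding_rect(mask)
  expect_equal(mb$upper_slope, 0)
  expect_equal(mb$lower_slope, 0)
  # pixel-centre extent: 29 x 39
  expect_equal(mb$area, 29 * 39)
  expect_error(min_bounding_rect(matrix(0, 5, 5)), "empty mask")
  expect_warning(min_bounding_rect(diag(5)), "border")
})

test_that("rotating the point set rotates the recovered slope", {
  # analytic rotation of a rectangle's pixel corner set
  g <- expand.grid(x = seq(0, 40, by = 0.5), y = seq(0, 12, by = 0.5))
  for (deg in c(10, -7, 25)) {
    a <- deg * pi / 180
    x <- g$x * cos(a) - g$y * sin(a)
    y <- g$x * sin(a) + g$y * cos(a)
    mb <- spinecobb:::mbr_points(x, y)
    expect_equal(mb$upper_slope, tan(a), tolerance = 1e-3)
    expect_equal(mb$area, 40 * 12, tolerance = 1e-6)
  }
  # rasterised tilted rectangle: slope still recovered closely
  mb <- min_bounding_rect(tilted_rect_mask(tilt = 10))
  expect_equal(mb$upper_slope, tan(10 * pi / 180), tolerance = 0.01)
})

test_that("MBR area never exceeds the axis-aligned bounding box", {
  for (s in 1:8) {
    blob <- random_blob(50, seed = s)
    mb <- suppressWarnings(min_bounding_rect(blob))
    idx <- which(blob != 0, arr.ind = TRUE)
    aabb <- diff(range(idx[, 1])) * diff(range(idx[, 2]))
    expect_lte(mb$area, aabb + 1e-9)
  }
})

test_that("endplate slopes require ordered rectangles", {
  mbrs <- lapply(c(10, 30, 50), function(r0) {
    m <- matrix(0, 80, 40)
    m[r0:(r0 + 10), 10:30] <- 1
    min_bounding_rect(m)
  })
  sl <- endplate_slopes(mbrs)
  expect_equal(sl$upper, rep(0, 3))
  expect_error(endplate_slopes(rev(mbrs)), "ordered")
  expect_error(endplate_slopes(mbrs[1:2]), "at least 3")
})

test_that("Cobb angle obeys the maximum-pair rule and sign convention", {
  r <- cobb_angle(c(0, 0, 1), c(0, 0, 1))
  expect_equal(r$magnitude, 45)
  expect_equal(c(r$upper_index, r$lower_index), c(1, 3))
  expect_equal(r$phi, -45)  # upper slope < lower slope: right-bending
  r2 <- cobb_angle(c(1, 0, 0), c(1, 0, 0))
  expect_equal(r2$phi, 45)
  # equal slopes: zero angle, tie broken to the smallest pair
  r0 <- cobb_angle(rep(0.3, 5), rep(0.3, 5))
  expect_equal(r0$phi, 0)
  expect_equal(c(r0$upper_index, r0$lower_index), c(1, 3))
  expect_error(cobb_angle(c(0, 1), c(0, 1)), "at least 3")
  # perpendicular pair is skipped with a warning
  expect_warning(rp <- cobb_angle(c(2, 0, 0, 1), c(1, 0, 0, -0.5)),
                 "perpendicular")
  expect_true(is.finite(rp$phi))
})

test_that("severity bands follow the clinical grading", {
  expect_equal(severity(5), "spinal curve")
  expect_equal(severity(10), "mild scoliosis")
  expect_equal(severity(15), "mild scoliosis")
  expect_equal(severity(20), "moderate scoliosis")
  expect_equal(severity(40), "moderate scoliosis")
  expect_equal(severity(40.5), "severe scoliosis")
  expect_equal(severity(45), "severe scoliosis")
  expect_equal(severity(-25), "moderate scoliosis")  # magnitude rule
})

test_that("severity of the Cobb result is mirror-symmetric", {
  set.seed(17)
  for (k in 1:20) {
    up <- tan(stats::runif(6, -0.4, 0.4))
    lo <- tan(stats::runif(6, -0.4, 0.4))
    a <- cobb_angle(up, lo)
    b <- cobb_angle(-up, -lo)
    expect_equal(a$magnitude, b$magnitude, tolerance = 1e-10)
    expect_equal(a$severity, b$severity)
    expect_equal(a$phi, -b$phi, tolerance = 1e-10)
  }
})

test_that("vertebra labels follow T1..T12, L1..L5", {
  expect_equal(vertebra_label(1), "T1")
  expect_equal(vertebra_label(12), "T12")
  expect_equal(vertebra_label(13), "L1")
  expect_equal(vertebra_label(17), "L5")
})

test_that("a straight phantom measures as (near) zero curvature", {
  sm <- generate_phantom(phantom_spec(cobb_deg = 0,
                                      tilt_deg = rep(0, 17), seed = 44))
  m <- suppressWarnings(measure_spine(sm$image))
  expect_lte(abs(m$cobb$phi), 2)
  expect_equal(m$cobb$severity, "spinal curve")
})
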