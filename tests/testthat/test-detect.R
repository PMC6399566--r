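test_that("window parameter defaults match the published operating point", {
  p <- window_params()
  expect_equal(unlist(p[c("H", "W", "p", "q", "r", "n")]),
               c(H = 51, W = 13, p = 12, q = 10, r = 40, n = 6))
  expect_equal(c(p$sibling_h, p$sibling_w), c(11, 5))
  expect_equal(p$gamma_step * seq_len(p$n_thresholds), 16 * (1:15))
  expect_error(window_params(W = 12), "odd")
  expect_error(window_params(H = 0), "positive")
})

test_that("reference points follow a bright strip and tie-break leftmost", {
  img <- matrix(0, 120, 80)
  img[, 34:46] <- 100           # bright strip of exactly W = 13 columns
  seg <- find_reference_points(img)
  expect_equal(nrow(seg$points), 6)
  expect_equal(seg$points[, 2], rep(40, 6))   # strip centre column
  expect_equal(seg$points[, 1], 1 + 12 * (0:5))  # spans 5 * p = 60 rows
  # all-zero image: every window ties, the leftmost must win
  z <- matrix(0, 120, 50)
  segz <- find_reference_points(z)
  expect_equal(segz$points[1, 2], 7)  # left window, top-middle column
  expect_error(find_reference_points(matrix(0, 120, 9)), "columns wide")
})

test_that("reference points agree with an exhaustive window search", {
  set.seed(77)
  p <- window_params()
  for (trial in 1:5) {
    img <- matrix(stats::runif(150 * 90, 0, 255), 150, 90)
    seg <- find_reference_points(img, p)
    # oracle: direct summation over all candidate windows
    centre <- NULL
    half <- (p$W - 1) / 2
    for (k in 1:6) {
      row <- 1 + (k - 1) * p$p
      cand <- if (is.null(centre)) seq_len(90 - p$W + 1) else
        max(1, centre - half - p$q):min(90 - p$W + 1, centre - half + p$q)
      sums <- vapply(cand, function(lc)
        sum(img[row:(row + p$H - 1), lc:(lc + p$W - 1)]), numeric(1))
      centre <- cand[which.max(sums)] + half
      expect_equal(unname(seg$points[k, ]), c(row, centre),
                   label = sprintf("trial %d point %d", trial, k))
    }
  }
})

test_that("boundary tracing recovers the edges of a bright rectangle", {
  img <- matrix(10, 200, 100)
  img[, 31:70] <- 200           # width-40 bright band
  b <- trace_boundaries(img)
  lcol <- mean(b$left$points[, "col"])
  rcol <- mean(b$right$points[, "col"])
  expect_lt(abs(lcol - 30.5), 1.5)
  expect_lt(abs(rcol - 70.5), 1.5)
  # symmetric image: offsets symmetric about the central line
  expect_lt(abs((lcol + rcol) / 2 - 50.5), 1)
})

test_that("the central spinal curve is the boundary midpoint", {
  fake <- list(left = list(coeffs = 10), right = list(coeffs = 30),
               rows = 1:40)
  csc <- build_csc(fake)
  expect_true(all(csc$col == 20))
  expect_equal(csc$beta, 40)
  crossed <- list(left = list(coeffs = 35), right = list(coeffs = 30),
                  rows = 1:40)
  expect_error(build_csc(crossed), "cross at row 1")
})

test_that("progressive thresholding obeys the vote identities", {
  # uniform foreground 100: gamma_t <= 96 keeps pixels (f = 0) up to t = 6,
  # gamma_t >= 112 empties the histogram (f = 1) from t = 7
  img <- matrix(100, 60, 50)
  csc <- structure(list(rows = 1:60, col = rep(25, 60),
                        slope = rep(0, 60), left = rep(5, 60),
                        right = rep(45, 60), beta = 60),
                   class = "csc_line")
  v <- progressive_threshold(img, csc)
  expect_true(all(v$f[1:6, ] == 0))
  expect_true(all(v$f[7:15, ] == 1))
  expect_true(all(v$P == 9))
  # identities (also asserted inside the call)
  expect_true(all(v$f %in% c(0, 1)))
  expect_equal(v$P, colSums(v$f))
  expect_true(all(v$P >= 0 & v$P <= 15))
  expect_true(all((v$p > 0) == (v$f == 0)))
  expect_error(progressive_threshold(matrix(0, 5, 5),
    structure(list(rows = 1:5, col = rep(3, 5), slope = rep(0, 5),
                   left = rep(3, 5), right = rep(3, 5), beta = 5),
              class = "csc_line")), "empty spine foreground")
})

test_that("vote-histogram cuts land at vertebra-to-disc transitions", {
  # alternating blocks: 20 vertebra bins (P = 0), 20 disc bins (P = 15)
  P <- rep(c(rep(0L, 20), rep(15L, 20)), 6)
  votes <- structure(list(P = P), class = "vote_histogram")
  csc <- structure(list(rows = seq_along(P), col = rep(30, length(P)),
                        slope = rep(0, length(P)),
                        left = rep(10, length(P)),
                        right = rep(50, length(P)), beta = length(P)),
                   class = "csc_line")
  img <- matrix(100, length(P), 60)
  expect_warning(
    boxes <- locate_vertebrae(votes, csc, img,
                              window_params(expected = 17L)),
    "detected 6")
  # one cut per 0 -> 15 transition, at the first disc bin
  lowers <- vapply(boxes, `[[`, numeric(1), "lower_row")
  expect_equal(lowers, 21 + 40 * (0:5))
  expect_equal(length(boxes), 6)
  expect_true(all(vapply(boxes, function(b) b$upper_row < b$lower_row,
                         logical(1))))
  expect_equal(dim(boxes[[1]]$chip), c(256, 128))
  # monotone histogram without a drastic rise: failure path
  flat <- structure(list(P = c(rep(0L, 30), 1L, 2L, 3L, rep(4L, 30))),
                    class = "vote_histogram")
  expect_error(locate_vertebrae(flat, csc, img), "Cobb angle undefined")
})

test_that("detection finds 17 ordered vertebrae on phantoms", {
  hits <- 0
  for (k in 1:4) {
    sm <- generate_phantom(phantom_spec(cobb_deg = c(8, 18, 28, 38)[k],
                                        direction = "right", seed = 30 + k))
    roi <- isolate_spine_roi(sm$image)
    det <- tryCatch(suppressWarnings(detect_vertebrae(roi)),
                    error = function(e) NULL)
    if (is.null(det)) next
    if (length(det$boxes) == 17) hits <- hits + 1
    # boxes ordered and non-overlapping along the central curve
    up <- vapply(det$boxes, `[[`, numeric(1), "upper_row")
    lo <- vapply(det$boxes, `[[`, numeric(1), "lower_row")
    expect_true(all(diff(up) > 0))
    expect_true(all(up < lo))
    expect_true(all(up[-1] >= lo[-length(lo)]))
  }
  expect_gte(hits, 3)
})
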