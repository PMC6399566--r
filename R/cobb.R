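#' Minimum bounding rectangle of a binary vertebra mask
#'
#' Computes the minimum-area enclosing rectangle of the mask's pixel
#' centres via the rotating-calipers property: the optimal rectangle has a
#' side collinear with an edge of the convex hull, so the search evaluates
#' the axis-aligned extent of the hull rotated by each hull-edge angle.
#' The two rectangle edges whose direction is closest to horizontal are
#' labelled the upper and lower borders (the endplate stand-ins); their
#' shared slope is reported as rise/run with the vertical axis pointing
#' up, so a border rising towards the right image border has positive
#' slope.
#'
#' @param mask logical or 0/1 matrix.
#' @return object of class `mbr`: list with `corners` (4 x 2 matrix of
#'   (row, col) points, ordered around the rectangle), `upper_slope`,
#'   `lower_slope` (equal, rectangle sides being parallel), `angle_deg`
#'   (endplate tilt, degrees), `area`, and `long_axis_deg`.  Warns when the
#'   mask touches the matrix border (possible truncation).
#' @export
min_bounding_rect <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask: no minimum bounding rectangle")
  if (any(idx[, 1] %in% c(1L, nrow(mask))) ||
      any(idx[, 2] %in% c(1L, ncol(mask))))
    warning("mask touches the image border; rectangle may be truncated")
  # Cartesian frame: x = col, y = -row
  mbr_points(x = idx[, 2], y = -idx[, 1])
}

# minimum-area rectangle of a point set in a y-up Cartesian frame
mbr_points <- function(x, y) {
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  nh <- length(hull)
  if (nh == 1) {
    corners <- matrix(rep(c(-hy[1], hx[1]), 4), 4, 2, byrow = TRUE)
    colnames(corners) <- c("row", "col")
    return(structure(list(corners = corners, upper_slope = 0,
                          lower_slope = 0, angle_deg = 0, area = 0,
                          long_axis_deg = 0), class = "mbr"))
  }
  ex <- hx[c(2:nh, 1)] - hx
  ey <- hy[c(2:nh, 1)] - hy
  angs <- unique(atan2(ey, ex) %% (pi / 2))
  best <- NULL
  for (a in angs) {
    ca <- cos(a); sa <- sin(a)
    rx <- ca * hx + sa * hy
    ry <- -sa * hx + ca * hy
    area <- (max(rx) - min(rx)) * (max(ry) - min(ry))
    if (is.null(best) || area < best$area - 1e-12)
      best <- list(a = a, area = area, rx = range(rx), ry = range(ry))
  }
  ca <- cos(best$a); sa <- sin(best$a)
  cs <- rbind(c(best$rx[1], best$ry[1]), c(best$rx[2], best$ry[1]),
              c(best$rx[2], best$ry[2]), c(best$rx[1], best$ry[2]))
  cx <- ca * cs[, 1] - sa * cs[, 2]
  cy <- sa * cs[, 1] + ca * cs[, 2]
  # edge directions of the rectangle: angle a (x'-axis) and a + pi/2
  cand <- c(best$a, best$a + pi / 2)
  horiz <- cand[which.min(abs(sin(cand)))]
  slope <- tan(horiz)           # dy/dx in the y-up frame
  long_axis <- if ((best$rx[2] - best$rx[1]) >= (best$ry[2] - best$ry[1]))
    best$a else best$a + pi / 2
  corners <- cbind(row = -cy, col = cx)
  structure(list(corners = corners, upper_slope = slope,
                 lower_slope = slope,
                 angle_deg = 180 / pi * atan(slope),
                 area = best$area,
                 long_axis_deg = 180 / pi * ((long_axis + pi / 2) %%
                                             pi - pi / 2)),
            class = "mbr")
}

#' Endplate slopes from a top-to-bottom sequence of bounding rectangles
#'
#' @param mbrs list of [min_bounding_rect()] results ordered from the
#'   uppermost (T1) to the lowest (L5) vertebra; the ordering is checked
#'   against the rectangle centroids.
#' @return list with `upper` and `lower` slope vectors (rise/run, vertical
#'   axis up, image-coordinate frame).
#' @export
endplate_slopes <- function(mbrs) {
  if (length(mbrs) < 3) stop("need at least 3 vertebrae for a Cobb angle")
  centres <- vapply(mbrs, function(m) mean(m$corners[, "row"]), numeric(1))
  if (any(diff(centres) <= 0))
    stop("bounding rectangles are not ordered top to bottom")
  list(upper = vapply(mbrs, `[[`, numeric(1), "upper_slope"),
       lower = vapply(mbrs, `[[`, numeric(1), "lower_slope"))
}

#' Cobb angle as the maximum curvature over vertebra pairs
#'
#' Evaluates `atan(|(m_i - m_j) / (1 + m_i * m_j)|)` -- the angle between
#' the two endplate lines -- for every pair of an upper vertebra `a` and a
#' lower vertebra `b` with `b - a >= 2` (at least one vertebra in
#' between), where `m_i` is the slope of the upper border of `a` and `m_j`
#' the slope of the lower border of `b`.  The maximum over all admissible
#' pairs is the Cobb angle; ties are broken to the smallest `(a, b)`.
#' The sign is negative when the curve bends to the right, i.e. when the
#' maximising upper slope is smaller than the lower slope.
#'
#' Near-perpendicular endplate pairs (`1 + m_i * m_j` close to 0), for
#' which the tangent quotient is undefined, are skipped with a warning.
#'
#' @param upper_slopes,lower_slopes per-vertebra border slopes, length N.
#' @param N number of vertebrae counted (defaults to the slope length).
#' @return object of class `cobb_result`: list with `phi` (signed
#'   degrees), `magnitude`, `upper_index` (a), `lower_index` (b),
#'   `severity` (see [severity()]) and `N`.
#' @export
cobb_angle <- function(upper_slopes, lower_slopes,
                       N = length(upper_slopes)) {
  if (N < 3) stop("Cobb angle needs at least 3 vertebrae (b - a >= 2)")
  if (length(upper_slopes) != N || length(lower_slopes) != N)
    stop("slope vectors must have length N")
  best <- -1
  besti <- NA_integer_; bestj <- NA_integer_
  skipped <- FALSE
  for (i in seq_len(N - 2)) {
    for (j in (i + 2):N) {
      den <- 1 + upper_slopes[i] * lower_slopes[j]
      if (abs(den) < 1e-9) { skipped <- TRUE; next }
      ang <- atan(abs((upper_slopes[i] - lower_slopes[j]) / den))
      if (ang > best + 1e-12) {
        best <- ang; besti <- i; bestj <- j
      }
    }
  }
  if (skipped)
    warning("perpendicular endplate pair skipped (undefined tangent quotient)")
  if (best < 0) stop("no admissible vertebra pair")
  mag <- 180 / pi * best
  phi <- if (upper_slopes[besti] < lower_slopes[bestj]) -mag else mag
  structure(list(phi = phi, magnitude = mag, upper_index = besti,
                 lower_index = bestj, severity = severity(phi), N = N),
            class = "cobb_result")
}

#' @export
print.cobb_result <- function(x, ...) {
  cat(sprintf("Cobb angle: %.1f deg (|phi| = %.1f, %s)\n",
              x$phi, x$magnitude, x$severity))
  cat(sprintf("End vertebrae: %s to %s (of %d)\n",
              vertebra_label(x$upper_index), vertebra_label(x$lower_index),
              x$N))
  invisible(x)
}

#' Clinical severity grade of a Cobb angle
#'
#' Grades the magnitude: below 10 degrees "spinal curve" (not scoliosis),
#' 10 up to but excluding 20 "mild", 20 through 40 "moderate", above 40
#' "severe".  Band edges are lower-inclusive.
#'
#' @param phi Cobb angle, degrees (sign ignored).
#' @return character grade.
#' @export
severity <- function(phi) {
  stopifnot(is.finite(phi))
  a <- abs(phi)
  if (a < 10) "spinal curve"
  else if (a < 20) "mild scoliosis"
  else if (a <= 40) "moderate scoliosis"
  else "severe scoliosis"
}

#' T1..L5 label of a vertebra index
#'
#' @param i index 1..17, counted from the top.
#' @return character label.
#' @export
vertebra_label <- function(i) {
  ifelse(i <= 12, paste0("T", i), paste0("L", i - 12))
}

#' Measure the spine curvature of a radiograph end to end
#'
#' Runs the full pipeline: spine ROI isolation, vertebra detection,
#' per-vertebra segmentation (a trained network or the training-free
#' classical segmenter), minimum bounding rectangles, and the maximum-pair
#' Cobb angle.  Chip masks are reconstructed in ROI coordinates (through
#' each box's transform) before the rectangles are fitted: the anisotropic
#' 256 x 128 chip rescale does not preserve right angles, so endplate
#' slopes are only meaningful in the image frame.
#'
#' @param image full-resolution numeric matrix.
#' @param segmenter `"classical"` or a trained network from
#'   [train_network()].
#' @param params a [window_params()].
#' @param threshold probability cutoff for network masks.
#' @param roi_args extra arguments for [isolate_spine_roi()].
#' @return object of class `spine_measurement`: list with `cobb` (a
#'   `cobb_result`), `roi`, `boxes`, `masks`, `mbrs`, `slopes`.
#' @export
measure_spine <- function(image, segmenter = "classical",
                          params = window_params(), threshold = 0.5,
                          roi_args = list()) {
  roi <- do.call(isolate_spine_roi, c(list(image), roi_args))
  det <- detect_vertebrae(roi, params)
  use_net <- inherits(segmenter, "spine_network")
  masks <- vector("list", length(det$boxes))
  mbrs <- list()
  keep <- logical(length(det$boxes))
  for (i in seq_along(det$boxes)) {
    box <- det$boxes[[i]]
    chip <- box$chip
    if (use_net) {
      m <- predict_mask(segmenter, chip, threshold = threshold)
    } else {
      m <- classical_segment(chip)
    }
    masks[[i]] <- m
    if (!any(m != 0)) next
    # reconstruct the mask in ROI coordinates before fitting: the
    # anisotropic 256x128 rescale does not preserve right angles, so the
    # rectangle must be fitted in the image frame
    nr <- box$lower_row - box$upper_row + 1
    nc <- box$right_col - box$left_col + 1
    mroi <- resize_matrix(m, nr, nc) >= 0.5
    if (!any(mroi)) next
    mb <- suppressWarnings(min_bounding_rect(mroi))
    # centroid in ROI coordinates for ordering
    mb$centre_row <- box$upper_row + mean(mb$corners[, "row"]) - 1
    mbrs[[length(mbrs) + 1]] <- mb
    keep[i] <- TRUE
  }
  if (length(mbrs) < 3)
    stop(sprintf(paste0("pipeline failure: only %d vertebrae segmented ",
                        "(detected boxes: %d); Cobb angle undefined"),
                 length(mbrs), length(det$boxes)))
  ord <- order(vapply(mbrs, `[[`, numeric(1), "centre_row"))
  mbrs <- mbrs[ord]
  slopes <- list(upper = vapply(mbrs, `[[`, numeric(1), "upper_slope"),
                 lower = vapply(mbrs, `[[`, numeric(1), "lower_slope"))
  cobb <- cobb_angle(slopes$upper, slopes$lower)
  structure(list(cobb = cobb, roi = roi, boxes = det$boxes,
                 masks = masks, mbrs = mbrs, slopes = slopes,
                 votes = det$votes),
            class = "spine_measurement")
}
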