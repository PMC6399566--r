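#' @useDynLib spinecobb, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# block-average downscale by integer factor k (anti-aliased)
downscale_block <- function(image, k) {
  h <- nrow(image) %/% k
  w <- ncol(image) %/% k
  x <- image[seq_len(h * k), seq_len(w * k), drop = FALSE]
  dim(x) <- c(k, h, w * k)
  x <- colMeans(x)         # (h, w*k): row blocks averaged
  dim(x) <- c(h, k, w)     # column runs of k
  colMeans(aperm(x, c(2, 1, 3)))
}

#' Downscale an image to a quarter of its size
#'
#' Reduces each dimension by a factor of 4 using 4x4 block averaging
#' (anti-aliased, so the projection profiles computed downstream are
#' smooth).  The intensity range is preserved.
#'
#' @param image numeric matrix (rows x columns) of grayscale intensities.
#' @return matrix of size `floor(dim/4)`.
#' @export
downscale_quarter <- function(image) {
  if (nrow(image) < 4 || ncol(image) < 4)
    stop("image must be at least 4x4 to downscale to a quarter")
  downscale_block(image, 4L)
}

#' Intensity projection profile
#'
#' Sums image intensities along one axis: the `"column"` profile has one
#' value per image column (summed over rows, the vertical projection used
#' to find the lateral spine extent), the `"row"` profile one value per row.
#'
#' @param image numeric matrix.
#' @param axis `"column"` or `"row"`.
#' @return object of class `projection_profile`: list with `values`, `axis`.
#' @export
project_profile <- function(image, axis = c("column", "row")) {
  axis <- match.arg(axis)
  values <- if (axis == "column") colSums(image) else rowSums(image)
  structure(list(values = unname(values), axis = axis),
            class = "projection_profile")
}

#' Lateral (column) band of the spine from a vertical projection
#'
#' Finds the contiguous run of columns containing the profile maximum and
#' expands it outwards while values stay at or above the threshold
#' `mean + c * sd` (population sd) of the profile.  Returns 1-based
#' inclusive column indices.
#'
#' @param profile a column-axis [project_profile()].
#' @param c threshold multiplier (default 1, i.e. mean plus one standard
#'   deviation).
#' @return integer `c(left, right)`, inclusive.
#' @export
select_column_band <- function(profile, c = 1) {
  stopifnot(inherits(profile, "projection_profile"),
            profile$axis == "column")
  v <- profile$values
  n <- length(v)
  if (n < 3) stop("column profile must have length >= 3")
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2))
  if (sdv == 0) {
    warning("zero-variance column profile; returning full width")
    return(c(1L, n))
  }
  thr <- mu + c * sdv
  peak <- which.max(v)
  left <- peak
  while (left > 1 && v[left - 1] >= thr) left <- left - 1
  right <- peak
  while (right < n && v[right + 1] >= thr) right <- right + 1
  c(as.integer(left), as.integer(right))
}

#' Vertical (row) band of the spine from a horizontal projection
#'
#' The upper boundary is the deepest local minimum in the upper half of the
#' profile (the dim band between the skull and the first thoracic
#' vertebra); the lower boundary is the row of the largest discontinuity
#' (absolute first difference) in the lower half (the jump where the bright
#' pelvis begins).  The profile is lightly smoothed (moving average, window
#' 5) before extrema detection.
#'
#' @param profile a row-axis [project_profile()].
#' @return integer `c(top, bottom)`, inclusive row indices.
#' @export
select_row_band <- function(profile) {
  stopifnot(inherits(profile, "projection_profile"), profile$axis == "row")
  v <- profile$values
  n <- length(v)
  if (n < 5) stop("row profile must have length >= 5")
  s <- stats::filter(v, rep(1 / 5, 5), sides = 2)
  s[is.na(s)] <- v[is.na(s)]
  s <- as.numeric(s)
  half <- n %/% 2
  iu <- 2:(half - 1)
  locmin <- iu[s[iu] < s[iu - 1] & s[iu] <= s[iu + 1]]
  if (!length(locmin)) {
    warning("no local minimum in the upper half; using row 1 as top")
    top <- 1L
  } else {
    top <- locmin[which.min(s[locmin])]
  }
  il <- max(half, top + 1):(n - 1)
  jumps <- abs(s[il + 1] - s[il])
  bottom <- il[which.max(jumps)]
  if (top >= bottom) {
    warning("degenerate row band (top >= bottom); returning full height")
    return(c(1L, n))
  }
  c(as.integer(top), as.integer(bottom))
}

#' Isolate the spine region of interest
#'
#' Composes the ROI-isolation stage: quarter downscaling, vertical and
#' horizontal projection profiles, column- and row-band selection, and the
#' crop.  The column band is padded laterally by `pad` pixels (clipped to
#' the image) so that the boundary-tracing stage, whose sibling windows
#' search up to `r` pixels beyond the spine edge, retains context.
#'
#' An optional pre-rotation aligning the principal axis of the
#' Otsu-thresholded foreground with the vertical is available via
#' `align = TRUE`; it is off by default (upright acquisitions).
#'
#' @param image full-resolution numeric matrix.
#' @param c column-band threshold multiplier, see [select_column_band()].
#' @param pad lateral padding of the column band, quarter-scale pixels
#'   (default 60: the boundary search range plus the spine half-width, so
#'   a laterally displaced curve apex keeps its edges inside the crop).
#' @param align logical; pre-rotate to vertical principal axis.
#' @return object of class `spine_roi`: list with `box` (list
#'   `top/bottom/left/right`, 1-based inclusive indices into the
#'   quarter-scale image), `image` (the cropped quarter-scale matrix),
#'   `scale` (4) and `full_dim`.
#' @export
isolate_spine_roi <- function(image, c = 1, pad = 60, align = FALSE) {
  if (align) image <- align_principal_axis(image)
  q <- downscale_quarter(image)
  degenerate <- FALSE
  cb <- withCallingHandlers(
    select_column_band(project_profile(q, "column"), c = c),
    warning = function(w) {
      degenerate <<- TRUE; invokeRestart("muffleWarning")
    })
  rb <- withCallingHandlers(
    select_row_band(project_profile(q, "row")),
    warning = function(w) {
      degenerate <<- TRUE; invokeRestart("muffleWarning")
    })
  if (cb[2] - cb[1] + 1 < max(3, 0.02 * ncol(q))) degenerate <- TRUE
  if (degenerate) {
    warning("no clear spine structure found; using the full frame as ROI")
    box <- list(top = 1L, bottom = nrow(q), left = 1L, right = ncol(q))
  } else {
    box <- list(top = rb[1], bottom = rb[2],
                left = max(1L, cb[1] - as.integer(pad)),
                right = min(ncol(q), cb[2] + as.integer(pad)))
  }
  structure(list(box = box,
                 image = q[box$top:box$bottom, box$left:box$right],
                 scale = 4L, full_dim = dim(image),
                 degenerate = degenerate),
            class = "spine_roi")
}

# rotate so the foreground principal axis is vertical (bilinear resample)
align_principal_axis <- function(image) {
  q <- image
  thr <- otsu_threshold(q)
  idx <- which(q >= thr, arr.ind = TRUE)
  if (nrow(idx) < 10) return(image)
  cv <- stats::cov(idx)
  ev <- eigen(cv)$vectors[, 1]
  ang <- atan2(ev[2], ev[1]) * 180 / pi   # angle of axis vs row direction
  rot <- ang - ifelse(ang > 90, 180, 0)
  if (abs(rot) < 0.5) return(image)
  warp_matrix(image, angle = -rot, fill = stats::median(image))
}
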