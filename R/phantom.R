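#' Specification of a synthetic AP-view spine radiograph phantom
#'
#' Builds the parameter set for [generate_phantom()].  The phantom emulates
#' the gross radiographic appearance an AP-view spine X-ray presents to the
#' measurement pipeline: a bright column of 17 stacked vertebra-like
#' quadrilaterals (12 thoracic + 5 lumbar) separated by darker
#' intervertebral gaps, an intensity ramp making the lumbar region brighter
#' than the thoracic region, a soft-tissue background, optional bright
#' head/hip structures at the top and bottom, and additive Gaussian noise.
#' Endplate slopes and the resulting Cobb angle are known analytically.
#'
#' The default curvature model is a smooth S-shaped lateral curve: the
#' centerline tangent (column change per row) carries two opposite Gaussian
#' bumps of amplitude `tan(cobb_deg/2)` centred on vertebrae `apex_upper`
#' and `apex_lower`, so the angle between the steepest upward- and
#' downward-tilted endplates equals `cobb_deg`.  Each vertebra is tilted to
#' follow the local centerline tangent, as vertebral bodies do in a
#' scoliotic spine.  Explicit `tilt_deg` and `centerline` vectors override
#' this model.
#'
#' Intensities are on an 8-bit 0-255 grayscale.  Intervertebral gap rows
#' are rendered at 1.5 x `background_level` (background plus half of it),
#' dimmer than any vertebra but brighter than soft tissue.
#'
#' @param image_height,image_width image size in pixels (full resolution).
#' @param n_vertebrae number of vertebrae (default 17: T1-T12, L1-L5).
#' @param vertebra_height,gap_height,vertebra_width vertebra body height,
#'   intervertebral gap height and body width, pixels.
#' @param top_margin row of the upper endplate of the first vertebra.
#' @param cobb_deg target Cobb angle magnitude, degrees.
#' @param direction `"left"` or `"right"`; a right-bending curve yields a
#'   negative Cobb angle under the sign convention of [cobb_angle()].
#' @param apex_upper,apex_lower vertebra indices carrying the two tangent
#'   bumps of the S-curve.
#' @param bump_sigma width (rows) of each tangent bump; defaults to one
#'   vertebra period, a compact clinical-looking curve whose lateral
#'   displacement stays modest even at severe angles.
#' @param tilt_deg optional explicit per-vertebra endplate tilt (degrees,
#'   positive = endplate rising towards the right image border).
#' @param centerline optional explicit column of the spine axis per row
#'   (numeric vector of length `image_height`).
#' @param intensity_spine vertebra intensity at the lumbar (bottom) end.
#' @param intensity_gradient multiplier applied at the thoracic (top) end;
#'   intensities ramp linearly in between.
#' @param background_level soft-tissue background intensity.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param include_head_hips render bright head/hip structures so the
#'   ROI-isolation stage has structures to exclude.
#' @param seed integer seed making the rendering deterministic.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [make_dataset()]
#' @export
phantom_spec <- function(image_height = 4736, image_width = 1200,
                         n_vertebrae = 17,
                         vertebra_height = 192, gap_height = 32,
                         vertebra_width = 176, top_margin = 480,
                         cobb_deg = 20, direction = c("left", "right"),
                         apex_upper = 5, apex_lower = 11,
                         bump_sigma = NULL,
                         tilt_deg = NULL, centerline = NULL,
                         intensity_spine = 250, intensity_gradient = 0.86,
                         background_level = 50, noise_sd = 5,
                         include_head_hips = TRUE, seed = 1L) {
  direction <- match.arg(direction)
  if (n_vertebrae < 3)
    stop("n_vertebrae must be at least 3 (the Cobb angle needs b - a >= 2)")
  if (vertebra_height <= 0 || vertebra_width <= 0)
    stop("vertebra dimensions must be positive")
  if (gap_height < 1) stop("gap_height must be at least 1")
  ints <- c(intensity_spine, intensity_spine * intensity_gradient,
            background_level)
  if (any(ints < 0) || any(ints > 255))
    stop("intensities must lie in [0, 255]")
  if (!is.null(tilt_deg) && (length(tilt_deg) != n_vertebrae ||
                             any(!is.finite(tilt_deg))))
    stop("tilt_deg must be a finite vector of length n_vertebrae")

  period <- vertebra_height + gap_height
  stack_bottom <- top_margin + n_vertebrae * period - gap_height
  if (stack_bottom > image_height)
    stop(sprintf(paste0("vertebra stack exceeds the image: last vertebra ",
                        "ends at row %d but image_height is %d"),
                 stack_bottom, image_height))
  centers <- top_margin + (seq_len(n_vertebrae) - 1) * period +
    vertebra_height / 2

  if (is.null(bump_sigma)) bump_sigma <- period
  sgn <- if (direction == "left") 1 else -1
  rows <- seq_len(image_height)
  if (is.null(centerline)) {
    amp <- sgn * tan(pi / 180 * cobb_deg / 2)
    bump <- function(r0) exp(-((rows - r0)^2) / (2 * bump_sigma^2))
    tangent <- amp * (bump(centers[apex_upper]) - bump(centers[apex_lower]))
    centerline <- image_width / 2 + cumsum(tangent) - tangent[1]
    # keep the spine horizontally centred over its own extent
    span <- range(centerline[rows >= top_margin & rows <= stack_bottom])
    centerline <- centerline - (mean(span) - image_width / 2)
  } else {
    if (length(centerline) != image_height)
      stop("centerline must have one column value per image row")
    tangent <- c(diff(centerline), 0)
  }
  if (is.null(tilt_deg))
    tilt_deg <- 180 / pi * atan(tangent[round(centers)])

  # polynomial record of the centerline (degree 8, normalised row variable)
  u <- (rows - image_height / 2) / image_height
  coeffs <- stats::coef(stats::lm(centerline ~ stats::poly(u, 8, raw = TRUE)))

  structure(list(
    image_height = image_height, image_width = image_width,
    n_vertebrae = n_vertebrae, vertebra_height = vertebra_height,
    gap_height = gap_height, vertebra_width = vertebra_width,
    top_margin = top_margin, centers = centers,
    centerline = centerline, centerline_coeffs = unname(coeffs),
    tilt_deg = tilt_deg, cobb_deg = cobb_deg, direction = direction,
    intensity_spine = intensity_spine,
    intensity_gradient = intensity_gradient,
    background_level = background_level,
    gap_intensity = 1.5 * background_level,
    noise_sd = noise_sd, include_head_hips = include_head_hips,
    seed = as.integer(seed)), class = "phantom_spec")
}

# evaluate with preserved RNG state, seeded from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# filled ellipse painter (modifies subregion of img, returns img)
paint_ellipse <- function(img, row0, col0, ry, rx, value) {
  h <- nrow(img); w <- ncol(img)
  r <- max(1, floor(row0 - ry)):min(h, ceiling(row0 + ry))
  c <- max(1, floor(col0 - rx)):min(w, ceiling(col0 + rx))
  if (!length(r) || !length(c)) return(img)
  inside <- outer(((r - row0) / ry)^2, ((c - col0) / rx)^2, `+`) <= 1
  sub <- img[r, c]
  sub[inside] <- value
  img[r, c] <- sub
  img
}

#' Render a synthetic spine radiograph with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: the spine column is
#' painted first as a curved band at the intervertebral-gap intensity, then
#' each vertebra is drawn as a filled quadrilateral (an axis-tilted
#' rectangle) centred on the centerline and rotated by its tilt angle, with
#' a linear thoracic-to-lumbar intensity ramp; optional head/hip blobs and
#' additive Gaussian noise (clipped to 0-255) are applied last.  Per-vertebra
#' masks are rendered noise-free.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_sample`: a list with
#' \describe{
#'   \item{image}{numeric matrix (rows x columns), grayscale 0-255.}
#'   \item{masks}{per-vertebra binary masks, each stored as
#'     `list(bbox = c(r0, r1, c0, c1), m = <logical matrix>)`; use
#'     [phantom_mask()] to expand one to full image size.}
#'   \item{boxes}{per-vertebra 4x2 corner matrices (row, col), ordered
#'     top-left, top-right, bottom-right, bottom-left in the vertebra frame.}
#'   \item{upper_slopes, lower_slopes}{endplate slopes (rise/run with the
#'     vertical axis pointing up), equal per vertebra since bodies are
#'     rendered as rectangles.}
#'   \item{true_cobb_deg}{signed ground-truth Cobb angle from [true_cobb()].}
#'   \item{true_end_vertebrae}{indices (a, b) of the maximising pair.}
#' }
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_height; w <- spec$image_width
  nv <- spec$n_vertebrae
  img <- matrix(spec$background_level, h, w)

  if (spec$include_head_hips) {
    # head: bright ellipse truncated by the top border
    img <- paint_ellipse(img, 100, spec$centerline[100], 160, 150, 210)
    hip_row <- spec$centers[nv] + spec$vertebra_height / 2 + 320
    img <- paint_ellipse(img, hip_row, spec$centerline[min(h, round(hip_row))],
                         200, 350, 230)
  }

  # spine column band at gap intensity
  half_w <- spec$vertebra_width / 2
  r0 <- max(1, spec$top_margin - 4)
  r1 <- min(h, spec$centers[nv] + spec$vertebra_height / 2 + 4)
  tang <- c(diff(spec$centerline), 0)
  band_rows <- r0:r1
  hw <- half_w * sqrt(1 + tang[band_rows]^2)
  c_lo <- pmax(1, round(spec$centerline[band_rows] - hw))
  c_hi <- pmin(w, round(spec$centerline[band_rows] + hw))
  lens <- c_hi - c_lo + 1
  img[cbind(rep(band_rows, lens), sequence(lens, from = c_lo))] <-
    spec$gap_intensity

  # vertebrae: tilted rectangles, brighter towards the lumbar end
  ramp <- seq(spec$intensity_gradient, 1, length.out = nv) *
    spec$intensity_spine
  masks <- vector("list", nv)
  boxes <- vector("list", nv)
  vh2 <- spec$vertebra_height / 2
  for (i in seq_len(nv)) {
    rc <- spec$centers[i]
    cc <- spec$centerline[round(rc)]
    a <- pi / 180 * spec$tilt_deg[i]
    # Cartesian tilt a: endplate direction (col, row) = (cos a, -sin a),
    # body axis (top->bottom) = (sin a, cos a)
    ec <- cos(a); er <- -sin(a)
    ac <- sin(a); ar <- cos(a)
    ext_r <- vh2 * abs(ar) + half_w * abs(er) + 2
    ext_c <- vh2 * abs(ac) + half_w * abs(ec) + 2
    rr <- max(1, floor(rc - ext_r)):min(h, ceiling(rc + ext_r))
    cols <- max(1, floor(cc - ext_c)):min(w, ceiling(cc + ext_c))
    dr <- rr - rc
    dc <- cols - cc
    uu <- outer(dr * er, dc * ec, `+`)     # along endplate
    vv <- outer(dr * ar, dc * ac, `+`)     # along body axis
    inside <- abs(uu) <= half_w & abs(vv) <= vh2
    sub <- img[rr, cols]
    sub[inside] <- ramp[i]
    img[rr, cols] <- sub
    masks[[i]] <- list(bbox = c(rr[1], rr[length(rr)], cols[1],
                                cols[length(cols)]),
                       m = inside)
    boxes[[i]] <- rbind(
      c(rc - vh2 * ar - half_w * er, cc - vh2 * ac - half_w * ec),
      c(rc - vh2 * ar + half_w * er, cc - vh2 * ac + half_w * ec),
      c(rc + vh2 * ar + half_w * er, cc + vh2 * ac + half_w * ec),
      c(rc + vh2 * ar - half_w * er, cc + vh2 * ac - half_w * ec))
    colnames(boxes[[i]]) <- c("row", "col")
  }

  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
    img[img < 0] <- 0
    img[img > 255] <- 255
  }

  slopes <- tan(pi / 180 * spec$tilt_deg)
  tc <- true_cobb(slopes, slopes)
  structure(list(image = img, masks = masks, boxes = boxes,
                 upper_slopes = slopes, lower_slopes = slopes,
                 true_cobb_deg = tc$phi,
                 true_end_vertebrae = c(tc$upper_index, tc$lower_index),
                 spec = spec),
            class = "phantom_sample")
}

#' Expand a stored phantom vertebra mask to full image size
#'
#' @param sample a `phantom_sample`.
#' @param i vertebra index (1 = T1, top).
#' @return logical matrix with the dimensions of `sample$image`.
#' @export
phantom_mask <- function(sample, i) {
  mk <- sample$masks[[i]]
  out <- matrix(FALSE, nrow(sample$image), ncol(sample$image))
  out[mk$bbox[1]:mk$bbox[2], mk$bbox[3]:mk$bbox[4]] <- mk$m
  out
}

#' Ground-truth Cobb angle from generative endplate slopes
#'
#' Shares the implementation of [cobb_angle()]: the maximum, over all
#' vertebra pairs at least two indices apart, of the angle between the
#' upper endplate of the upper vertebra and the lower endplate of the lower
#' vertebra.
#'
#' @param upper_slopes,lower_slopes per-vertebra endplate slopes
#'   (dimensionless rise/run, vertical axis up).
#' @return A `cobb_result`, see [cobb_angle()].
#' @export
true_cobb <- function(upper_slopes, lower_slopes) {
  cobb_angle(upper_slopes, lower_slopes)
}

#' Generate a phantom dataset with per-vertebra training chips
#'
#' Draws `n_images` phantoms with randomised curvature and cuts one
#' training chip per vertebra from the quarter-scale image (the scale the
#' detection stage works at), rescaled to `chip_shape` together with its
#' binary mask -- the synthetic stand-in for an annotated vertebra training
#' set.
#'
#' @param n_images number of phantom images.
#' @param spec_ranges list of sampling ranges: `cobb` (length-2 range of the
#'   Cobb magnitude, degrees), `apex_upper` (candidate indices),
#'   `apex_gap` (candidate index gaps between the two tangent bumps), and
#'   any fixed [phantom_spec()] arguments under `fixed`.
#' @param seed integer seed.
#' @param chip_shape chip size `c(rows, cols)`, default 256 x 128.
#' @return list with `samples` (the `phantom_sample`s), `chips` (array
#'   `chip_shape x n_chips`), `masks` (same shape, binary), `image_id`
#'   (chip-to-image map) and `vertebra` (chip-to-vertebra map).
#' @export
make_dataset <- function(n_images, spec_ranges = list(), seed = 1L,
                         chip_shape = c(256L, 128L)) {
  if (n_images < 1) stop("n_images must be at least 1")
  if (!is.list(spec_ranges)) stop("spec_ranges must be a list")
  rng <- utils::modifyList(list(cobb = c(5, 45), apex_upper = 4:6,
                                apex_gap = 5:7, fixed = list()), spec_ranges)
  draws <- with_seed(seed, list(
    cobb = stats::runif(n_images, rng$cobb[1], rng$cobb[2]),
    dir = sample(c("left", "right"), n_images, replace = TRUE),
    au = sample(rep(rng$apex_upper, 2), n_images, replace = TRUE),
    gap = sample(rep(rng$apex_gap, 2), n_images, replace = TRUE),
    seeds = sample.int(.Machine$integer.max, n_images)))

  samples <- vector("list", n_images)
  chips <- list(); cmasks <- list(); image_id <- c(); vertebra <- c()
  for (k in seq_len(n_images)) {
    args <- c(list(cobb_deg = draws$cobb[k], direction = draws$dir[k],
                   apex_upper = draws$au[k],
                   apex_lower = draws$au[k] + draws$gap[k],
                   seed = draws$seeds[k]), rng$fixed)
    spec <- do.call(phantom_spec, args)
    sm <- generate_phantom(spec)
    samples[[k]] <- sm
    q <- downscale_quarter(sm$image)
    period <- (spec$vertebra_height + spec$gap_height) / 4
    for (i in seq_len(spec$n_vertebrae)) {
      rc <- spec$centers[i] / 4
      cc <- spec$centerline[round(spec$centers[i])] / 4
      hw <- spec$vertebra_width / 8 + 4
      rr <- round(max(1, rc - period / 2)):round(min(nrow(q), rc + period / 2))
      cols <- round(max(1, cc - hw)):round(min(ncol(q), cc + hw))
      chip <- resize_matrix(q[rr, cols], chip_shape[1], chip_shape[2])
      mq <- downscale_block(phantom_mask(sm, i) * 1, 4)
      mchip <- resize_matrix(mq[rr, cols], chip_shape[1], chip_shape[2]) >= 0.5
      chips[[length(chips) + 1]] <- chip
      cmasks[[length(cmasks) + 1]] <- mchip
      image_id <- c(image_id, k)
      vertebra <- c(vertebra, i)
    }
  }
  nchips <- length(chips)
  chip_arr <- array(unlist(chips), c(chip_shape, nchips))
  mask_arr <- array(unlist(cmasks), c(chip_shape, nchips)) * 1
  list(samples = samples, chips = chip_arr, masks = mask_arr,
       image_id = image_id, vertebra = vertebra, seed = seed)
}
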