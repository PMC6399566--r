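#' Parameters of the sliding-window vertebra detection stage
#'
#' Defaults follow the published operating point of the method: tracing
#' windows of H = 51 x W = 13 pixels stepped down p = 12 rows with a
#' lateral search range of q = 10 pixels, boundary search range r = 40
#' pixels with 11 x 5 sibling windows, n = 6 reference points per central
#' line segment, 15 progressive thresholds spaced 16 gray levels apart, a
#' 15-bin sub-histogram for cut placement, and 17 expected vertebrae
#' (T1-L5).
#'
#' @param H,W tracing window height/width, pixels (W odd so the top-middle
#'   point is defined).
#' @param p downward step between reference points, pixels.
#' @param q lateral search half-range, pixels.
#' @param r boundary search range along the boundary normal, pixels.
#' @param n reference points per central line segment.
#' @param sibling_h,sibling_w sibling window size for boundary detection.
#' @param theta minimum vote increase marking a vertebra-to-disc
#'   transition ("drastic change") in the accumulated histogram.
#' @param gamma_step,n_thresholds progressive threshold ladder:
#'   `gamma_t = gamma_step * t`, `t = 1..n_thresholds`.
#' @param subhist sub-histogram length scanned from each starting point.
#' @param expected expected vertebra count.
#' @param cls_degree polynomial degree of each central line segment fit.
#' @return object of class `window_params`.
#' @export
window_params <- function(H = 51L, W = 13L, p = 12L, q = 10L, r = 40L,
                          n = 6L, sibling_h = 11L, sibling_w = 5L,
                          theta = 8L, gamma_step = 16L, n_thresholds = 15L,
                          subhist = 15L, expected = 17L, cls_degree = 2L) {
  vals <- c(H = H, W = W, p = p, q = q, r = r, n = n,
            sibling_h = sibling_h, sibling_w = sibling_w, theta = theta,
            gamma_step = gamma_step, n_thresholds = n_thresholds,
            subhist = subhist, expected = expected)
  if (any(vals <= 0)) stop("all window parameters must be positive")
  if (W %% 2 == 0) stop("W must be odd (top-middle point)")
  structure(as.list(c(vals, cls_degree = cls_degree)),
            class = "window_params")
}

#' Reference points of one central line segment
#'
#' Slides H x W windows along a row of the ROI with one-pixel increments;
#' the top-middle point of the maximum-intensity-sum window is the first
#' reference point.  Each subsequent point is found by stepping the window
#' down `p` rows and searching within `q` columns either side of the
#' previous position; ties are broken to the leftmost window.  The `n`
#' points are fitted with a degree-`cls_degree` polynomial (column as a
#' function of row).
#'
#' @param image ROI matrix (quarter scale).
#' @param params a [window_params()].
#' @param start_row row of the first window top (default 1).
#' @param start_col centre column seeding the first search; `NULL` searches
#'   the full width.
#' @return list with `points` (n x 2 matrix, row/col of window top-middle
#'   points), `coeffs` (ascending polynomial coefficients), `window_tops`
#'   (left column of each chosen window), class `cls_segment`.
#' @export
find_reference_points <- function(image, params = window_params(),
                                  start_row = 1L, start_col = NULL) {
  H <- params$H; W <- params$W
  if (ncol(image) < W)
    stop(sprintf("ROI is %d columns wide but the window needs %d",
                 ncol(image), W))
  if (nrow(image) < start_row + H - 1)
    stop("ROI too short for the tracing window")
  sat <- integral_image(image)
  half <- (W - 1L) %/% 2L
  pts <- matrix(NA_real_, params$n, 2)
  lefts <- integer(params$n)
  row <- start_row
  centre <- start_col
  for (k in seq_len(params$n)) {
    if (row + H - 1 > nrow(image)) {
      pts <- pts[seq_len(k - 1), , drop = FALSE]
      lefts <- lefts[seq_len(k - 1)]
      break
    }
    if (is.null(centre)) {
      cand <- seq_len(ncol(image) - W + 1L)
    } else {
      cand <- max(1L, centre - half - params$q):
              min(ncol(image) - W + 1L, centre - half + params$q)
    }
    sums <- window_sum(sat, rep(row, length(cand)), rep(row + H - 1L,
                       length(cand)), cand, cand + W - 1L)
    left <- cand[which.max(sums)]   # which.max: leftmost on ties
    centre <- left + half
    pts[k, ] <- c(row, centre)
    lefts[k] <- left
    row <- row + params$p
  }
  if (nrow(pts) < 3) stop("not enough reference points for a segment fit")
  deg <- min(params$cls_degree, nrow(pts) - 1)
  fit <- stats::lm(pts[, 2] ~ stats::poly(pts[, 1], deg, raw = TRUE))
  structure(list(points = pts, coeffs = unname(stats::coef(fit)),
                 window_tops = lefts),
            class = "cls_segment")
}

polyval_asc <- function(coeffs, x) {
  y <- 0
  for (k in rev(seq_along(coeffs))) y <- y * x + coeffs[k]
  y
}

polyder_asc <- function(coeffs) {
  if (length(coeffs) < 2) return(0)
  coeffs[-1] * seq_len(length(coeffs) - 1)
}

# Chain central line segments down the ROI: each new segment is seeded at
# the final window of the previous one.  Returns per-row column and slope
# of the traced central line (extrapolated to cover all ROI rows).
trace_cls <- function(image, params = window_params()) {
  segs <- list()
  row <- 1L
  centre <- NULL
  repeat {
    seg <- tryCatch(find_reference_points(image, params, start_row = row,
                                          start_col = centre),
                    error = function(e) NULL)
    if (is.null(seg)) break
    segs[[length(segs) + 1]] <- seg
    last <- seg$points[nrow(seg$points), ]
    centre <- as.integer(round(last[2]))
    row <- as.integer(last[1] + params$p)
    if (row + params$H - 1L > nrow(image)) break
  }
  if (!length(segs)) stop("central line tracing failed: ROI too small")
  rows <- seq_len(nrow(image))
  col <- numeric(length(rows))
  slope <- numeric(length(rows))
  starts <- vapply(segs, function(s) s$points[1, 1], numeric(1))
  ends <- vapply(segs, function(s) s$points[nrow(s$points), 1], numeric(1))
  for (y in rows) {
    k <- which(starts <= y & ends >= y)
    if (!length(k))   # between or beyond segments: nearest segment
      k <- which.min(pmax(starts - y, 0) + pmax(y - ends, 0))
    k <- k[1]
    col[y] <- polyval_asc(segs[[k]]$coeffs, y)
    slope[y] <- polyval_asc(polyder_asc(segs[[k]]$coeffs), y)
  }
  list(segments = segs, rows = rows, col = col, slope = slope)
}

#' Trace the left and right spine boundary curves
#'
#' For every point of the chained central line segments, a pair of 11 x 5
#' sibling windows slides outwards (up to `r` pixels) along the local
#' normal on each side; the boundary point is the pair position maximising
#' the intensity difference between the inner and outer window.  Each
#' side's points are then fitted with a degree-3 polynomial (column as a
#' function of row).
#'
#' @param image ROI matrix (quarter scale).
#' @param params a [window_params()].
#' @return object of class `boundary_curves`: `left` and `right` (each a
#'   list with `points` and degree-3 `coeffs`), plus the traced `cls`.
#' @export
trace_boundaries <- function(image, params = window_params()) {
  cls <- trace_cls(image, params)
  sat <- integral_image(image)
  h <- nrow(image); w <- ncol(image)
  hh <- (params$sibling_h - 1) / 2
  hw <- (params$sibling_w - 1) / 2
  # trace only where the central line is anchored by reference points;
  # beyond them the segment extrapolation (and hence the normal
  # direction) is unreliable
  last_anchor <- max(vapply(cls$segments,
                            function(s) s$points[nrow(s$points), 1],
                            numeric(1))) + params$p
  keep <- cls$rows <= last_anchor
  ys <- cls$rows[keep]
  xs <- cls$col[keep]
  sl <- cls$slope[keep]
  if (any(!is.finite(sl))) {
    warning("degenerate central-line slope; using horizontal normals")
    sl[!is.finite(sl)] <- 0
  }
  nrm <- sqrt(1 + sl^2)
  eta_r <- -sl / nrm      # normal (row component), pointing to +col side
  eta_c <- 1 / nrm
  offs <- seq(params$sibling_w %/% 2 + 1L, params$r)
  fit_side <- function(sign) {
    best_d <- rep(NA_real_, length(ys))
    best_s <- rep(-Inf, length(ys))
    for (d in offs) {
      icr <- round(ys + sign * (d - hw - 1) * eta_r)
      icc <- round(xs + sign * (d - hw - 1) * eta_c)
      ocr <- round(ys + sign * (d + hw + 1) * eta_r)
      occ <- round(xs + sign * (d + hw + 1) * eta_c)
      ok <- icr - hh >= 1 & icr + hh <= h & icc - hw >= 1 & icc + hw <= w &
            ocr - hh >= 1 & ocr + hh <= h & occ - hw >= 1 & occ + hw <= w
      if (!any(ok)) next
      sc <- rep(-Inf, length(ys))
      sc[ok] <- window_sum(sat, icr[ok] - hh, icr[ok] + hh,
                           icc[ok] - hw, icc[ok] + hw) -
                window_sum(sat, ocr[ok] - hh, ocr[ok] + hh,
                           occ[ok] - hw, occ[ok] + hw)
      upd <- sc > best_s
      best_s[upd] <- sc[upd]
      best_d[upd] <- d
    }
    keep <- is.finite(best_s) & !is.na(best_d)
    pr <- ys[keep] + sign * best_d[keep] * eta_r[keep]
    pc <- xs[keep] + sign * best_d[keep] * eta_c[keep]
    fit <- stats::lm(pc ~ stats::poly(pr, 3, raw = TRUE))
    list(points = cbind(row = pr, col = pc),
         coeffs = unname(stats::coef(fit)))
  }
  structure(list(left = fit_side(-1), right = fit_side(1), cls = cls,
                 rows = cls$rows),
            class = "boundary_curves")
}

#' Central spinal curve from the boundary curves
#'
#' The central spinal curve (CSC) point at each row is the midpoint of the
#' left and right boundaries at that row; its length `beta` (number of
#' rows) is the bin dimension of the vote histograms.  The traced boundary
#' points (robustly smoothed by a running median and moving average) are
#' preferred over the global degree-3 fit, which cannot follow a full
#' S-shaped curve; the fit remains available in the boundary record.
#'
#' @param boundaries a [trace_boundaries()] result (or a list with `left`
#'   and `right` coefficient sets and `rows`).
#' @return object of class `csc_line`: list with `rows`, `col` (midpoint
#'   columns), `slope` (d col / d row), `left`, `right` (per-row boundary
#'   columns) and `beta`.
#' @export
build_csc <- function(boundaries) {
  ys <- boundaries$rows
  per_row <- function(side) {
    if (is.null(side$points))
      return(polyval_asc(side$coeffs, ys))
    v <- stats::approx(side$points[, "row"], side$points[, "col"],
                       xout = ys, rule = 2, ties = mean)$y
    # robust local smoothing: isolated mistraced points must not bend
    # the midline (a single global cubic cannot follow a full S-curve,
    # so the curve record stays degree 3 but the working midline is
    # built from the traced points themselves)
    smooth_track(v)
  }
  l <- per_row(boundaries$left)
  r <- per_row(boundaries$right)
  bad <- which(l > r)
  if (length(bad))
    stop(sprintf("boundary curves cross at row %d", ys[bad[1]]))
  mid <- (l + r) / 2
  slope <- smooth_track(c(diff(mid), 0))
  structure(list(rows = ys, col = mid, slope = slope,
                 left = l, right = r, beta = length(ys)),
            class = "csc_line")
}

# running median (outlier rejection) followed by a moving average
smooth_track <- function(v, med = 17L, ma = 9L) {
  n <- length(v)
  if (n >= med) v <- stats::runmed(v, med, endrule = "median")
  if (n >= ma) {
    f <- stats::filter(v, rep(1 / ma, ma), sides = 2)
    v <- ifelse(is.na(f), v, as.numeric(f))
  }
  v
}

#' Progressive-thresholding vote histogram
#'
#' The spine foreground between the boundary curves is divided at each row
#' into equal left, middle and right thirds; only the outer thirds are
#' thresholded.  For each threshold `gamma_t = gamma_step * t`
#' (`t = 1..n_thresholds`), pixels at or above the threshold are projected
#' along the local CSC normal (nearest CSC index by perpendicular foot
#' point) into a projection histogram `p_t`.  The binarised complement
#' `f_t(y)` is 0 where `p_t(y) > 0` and 1 otherwise, and the accumulated
#' vote histogram is `P(y) = sum_t f_t(y)`.  Intervertebral discs, dimmer
#' than vertebrae at the spine's lateral margins, collect high vote counts;
#' vertebra rows stay near zero.
#'
#' The `f_t in {0,1}`, `P = sum f_t` and `0 <= P <= n_thresholds`
#' identities are asserted on every call.
#'
#' @param image ROI matrix (quarter scale).
#' @param csc a [build_csc()] result.
#' @param params a [window_params()].
#' @return object of class `vote_histogram`: `p` (n_thresholds x beta
#'   counts), `f` (binarised complements), `P` (accumulated votes),
#'   `gammas`.
#' @export
progressive_threshold <- function(image, csc, params = window_params()) {
  beta <- csc$beta
  px_row <- integer(0); px_col <- integer(0)
  h <- nrow(image); w <- ncol(image)
  rowlist <- vector("list", beta)
  for (k in seq_len(beta)) {
    y <- csc$rows[k]
    l <- max(1, ceiling(csc$left[k]))
    r <- min(w, floor(csc$right[k]))
    if (l >= r) next
    width <- csc$right[k] - csc$left[k]
    m1 <- csc$col[k] - width / 6
    m2 <- csc$col[k] + width / 6
    cols <- l:r
    cols <- cols[cols < m1 | cols > m2]
    if (!length(cols)) next
    rowlist[[k]] <- cbind(y, cols)
  }
  pix <- do.call(rbind, rowlist)
  if (is.null(pix) || !nrow(pix)) stop("empty spine foreground")
  inten <- image[pix]
  # perpendicular foot point onto the CSC, linearised at the pixel's row
  m <- csc$slope[pix[, 1]]
  yidx <- pix[, 1] + (pix[, 2] - csc$col[pix[, 1]]) * m / (1 + m^2)
  yidx <- pmin(pmax(round(yidx), 1L), beta)
  nt <- params$n_thresholds
  p <- matrix(0L, nt, beta)
  for (t in seq_len(nt)) {
    keep <- inten >= params$gamma_step * t
    if (any(keep)) p[t, ] <- tabulate(yidx[keep], nbins = beta)
  }
  f <- (p == 0) * 1L
  P <- colSums(f)
  stopifnot(all(f %in% c(0L, 1L)), all(P >= 0), all(P <= nt),
            identical(as.integer(P), as.integer(colSums(f))))
  structure(list(p = p, f = f, P = P,
                 gammas = params$gamma_step * seq_len(nt)),
            class = "vote_histogram")
}

#' Locate vertebra boxes from the vote histogram
#'
#' Scans the accumulated vote histogram for "drastic" increases (a rise of
#' at least `theta` votes within three bins, starting from a vertebra-level
#' count sustained for at least a few bins, which rejects bright
#' structures bleeding over the ROI border): each such starting point A
#' opens a non-overlapping sub-histogram
#' of `subhist` bins whose first global maximum marks a horizontal cut at
#' the vertebra/disc transition.  Consecutive cuts, together with the
#' boundary curves, enclose the per-vertebra regions of interest; each is
#' cropped (with a small lateral margin) and rescaled to `chip_shape`.
#'
#' @param votes a [progressive_threshold()] result.
#' @param csc a [build_csc()] result.
#' @param image ROI matrix the votes were computed from.
#' @param params a [window_params()].
#' @param chip_shape chip size `c(rows, cols)`.
#' @param margin lateral margin added around the boundary curves, pixels.
#' @return list of vertebra boxes; each box is a list with `index`,
#'   `upper_row`, `lower_row`, `left_col`, `right_col` (ROI coordinates),
#'   `chip` (rescaled crop) and `scale_r`, `scale_c` (chip-per-ROI pixel
#'   scale factors, needed to map slopes measured on the chip back to image
#'   coordinates).  Warns when the count differs from `params$expected`;
#'   fewer than 3 boxes is an error (the Cobb angle is undefined).
#' @export
locate_vertebrae <- function(votes, csc, image, params = window_params(),
                             chip_shape = c(256L, 128L), margin = 4L) {
  P <- votes$P
  beta <- length(P)
  nt <- params$n_thresholds
  low <- nt - params$theta
  # top of the first vertebra: first drop to a vertebra-level count
  c0 <- which(P <= low)[1]
  if (is.na(c0)) stop("no vertebra-level region in the vote histogram")
  cuts <- integer(0)
  y <- c0
  run <- 0L   # consecutive vertebra-level bins ending at y - 1
  min_run <- 4L
  while (y <= beta - 3L) {
    rise <- max(P[y + 1L], P[y + 2L], P[y + 3L]) - P[y]
    if (P[y] <= low && run >= min_run - 1L && rise >= params$theta) {
      sub <- P[y:min(y + params$subhist - 1L, beta)]
      cuts <- c(cuts, y + which.max(sub) - 1L)
      y <- y + params$subhist
      run <- 0L
    } else {
      run <- if (P[y] <= low) run + 1L else 0L
      y <- y + 1L
    }
  }
  if (length(cuts) > params$expected) {
    warning(sprintf("detected %d vertebra boxes, expected %d; keeping the first %d",
                    length(cuts), params$expected, params$expected))
    cuts <- cuts[seq_len(params$expected)]
  }
  nbox <- length(cuts)
  if (nbox < 3)
    stop(sprintf("only %d vertebra boxes detected; Cobb angle undefined",
                 nbox))
  if (nbox != params$expected)
    warning(sprintf("detected %d vertebra boxes, expected %d",
                    nbox, params$expected))
  uppers <- c(max(1L, c0 - 1L), cuts[-nbox])
  boxes <- vector("list", nbox)
  for (i in seq_len(nbox)) {
    yr <- uppers[i]:cuts[i]
    rows <- csc$rows[yr]
    lc <- max(1L, floor(min(csc$left[yr])) - margin)
    rc <- min(ncol(image), ceiling(max(csc$right[yr])) + margin)
    crop <- image[rows, lc:rc, drop = FALSE]
    boxes[[i]] <- list(index = i,
                       upper_row = rows[1], lower_row = rows[length(rows)],
                       left_col = lc, right_col = rc,
                       chip = resize_matrix(crop, chip_shape[1],
                                            chip_shape[2]),
                       scale_r = chip_shape[1] / nrow(crop),
                       scale_c = chip_shape[2] / ncol(crop))
  }
  boxes
}

#' Detect vertebrae in a spine ROI
#'
#' Convenience composition of [trace_boundaries()], [build_csc()],
#' [progressive_threshold()] and [locate_vertebrae()].
#'
#' @param roi a [isolate_spine_roi()] result or a plain ROI matrix.
#' @param params a [window_params()].
#' @param chip_shape chip size passed to [locate_vertebrae()].
#' @return list with `boxes`, `csc`, `boundaries`, `votes`.
#' @export
detect_vertebrae <- function(roi, params = window_params(),
                             chip_shape = c(256L, 128L)) {
  image <- if (inherits(roi, "spine_roi")) roi$image else roi
  boundaries <- trace_boundaries(image, params)
  csc <- build_csc(boundaries)
  votes <- progressive_threshold(image, csc, params)
  boxes <- locate_vertebrae(votes, csc, image, params, chip_shape)
  list(boxes = boxes, csc = csc, boundaries = boundaries, votes = votes)
}
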