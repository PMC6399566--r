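# Shared fixtures, built in code.

# one cached phantom per (cobb, seed) so slow renders are reused
phantom_cache <- new.env()

cached_phantom <- function(cobb_deg = 20, seed = 3, ...) {
  key <- paste0("c", cobb_deg, "s", seed)
  if (is.null(phantom_cache[[key]]))
    phantom_cache[[key]] <- generate_phantom(
      phantom_spec(cobb_deg = cobb_deg, seed = seed, ...))
  phantom_cache[[key]]
}

# independent brute-force maximum-pair Cobb angle (degrees, magnitude)
brute_cobb <- function(upper, lower) {
  n <- length(upper)
  best <- -Inf
  pair <- c(NA, NA)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 2) next
    den <- 1 + upper[i] * lower[j]
    if (abs(den) < 1e-9) next
    ang <- 180 / pi * atan(abs((upper[i] - lower[j]) / den))
    if (ang > best + 1e-12) {
      best <- ang
      pair <- c(i, j)
    }
  }
  list(mag = best, pair = pair)
}

# brute-force minimum rectangle area over rotations in `step`-degree
# increments, for mask pixel centres
brute_mbr_area <- function(mask, step = 0.1) {
  idx <- which(mask != 0, arr.ind = TRUE)
  x <- idx[, 2]; y <- -idx[, 1]
  best <- Inf
  for (a in seq(0, 90 - step, by = step) * pi / 180) {
    rx <- cos(a) * x + sin(a) * y
    ry <- -sin(a) * x + cos(a) * y
    area <- diff(range(rx)) * diff(range(ry))
    if (area < best) best <- area
  }
  best
}

# random compact blob mask (smoothed noise, largest bright component)
random_blob <- function(n = 60, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  k <- stats::dnorm(-5:5, sd = 2.5)
  blur1 <- function(x) {
    f <- stats::filter(x, k, sides = 2)
    f[is.na(f)] <- 0
    f
  }
  sm <- apply(apply(m, 2, blur1), 1, blur1)  # separable Gaussian blur
  mask <- sm >= stats::quantile(sm, 0.8)
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  lv <- EBImage::imageData(lab)
  t(lv == which.max(tabulate(lv[lv > 0]))) * 1
}

# mask of an axis-tilted filled rectangle, tilt in degrees
tilted_rect_mask <- function(n = 120, h = 40, w = 80, tilt = 0) {
  a <- tilt * pi / 180
  ctr <- (n + 1) / 2
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  dc <- g$c - ctr; dr <- g$r - ctr
  u <- dc * cos(a) - dr * sin(a)   # along the long axis (y-up frame)
  v <- -dr * cos(a) - dc * sin(a)
  matrix(abs(u) <= w / 2 & abs(v) <= h / 2, n, n) * 1
}
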