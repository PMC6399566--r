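# Image helpers shared across modules.  Matrices are (row, col) with row 1
# at the top; EBImage stores images x-first, hence the transposes at its
# boundary.

# bilinear resize of a (row, col) matrix to nr x nc
resize_matrix <- function(m, nr, nc) {
  out <- EBImage::resize(EBImage::Image(t(m)), w = nc, h = nr)
  t(EBImage::imageData(out))
}

# Otsu threshold on raw intensities (any range)
otsu_threshold <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(rng[1])
  x <- (m - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(t(x)), range = c(0, 1), levels = 256)
  th * (rng[2] - rng[1]) + rng[1]
}

# rotate by `angle` degrees about the centre, then translate by (dy, dx)
# pixels; bilinear sampling, out-of-frame pixels filled with `fill`
warp_matrix <- function(m, angle = 0, dy = 0, dx = 0, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  a <- angle * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gr <- matrix(seq_len(h), h, w) - cy - dy
  gc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx - dx
  sr <- cos(a) * gr - sin(a) * gc + cy
  sc <- sin(a) * gr + cos(a) * gc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- matrix(fill, h, w)
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v00 <- val(r0, c0); v10 <- val(r0 + 1, c0)
  v01 <- val(r0, c0 + 1); v11 <- val(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

# summed-area table with a zero border; window_sum is O(1) per window
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# inclusive window sums [r0, r1] x [c0, c1]; vectorised over windows
window_sum <- function(sat, r0, r1, c0, c1) {
  n <- nrow(sat)
  idx <- function(r, c) r + 1L + n * c   # sat[(r+1), (c+1)] linearised
  sat[idx(r1, c1)] - sat[idx(r0 - 1L, c1)] -
    sat[idx(r1, c0 - 1L)] + sat[idx(r0 - 1L, c0 - 1L)]
}
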