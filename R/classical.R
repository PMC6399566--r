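#' Training-free classical chip segmenter
#'
#' A fallback segmenter so the full measurement pipeline runs without a
#' fitted network: global Otsu thresholding restricted to the chip's
#' central band (the vertebra body sits mid-chip after detection), hole
#' filling, and retention of the largest connected component.
#'
#' @param chip grayscale matrix (any intensity range).
#' @param central_band fraction of the chip width kept as candidate
#'   foreground (centred), default 0.9.
#' @return binary 0/1 matrix of the chip's shape with attribute
#'   `"threshold"`; an empty mask (with a warning) when no foreground is
#'   found.
#' @export
classical_segment <- function(chip, central_band = 0.9) {
  h <- nrow(chip); w <- ncol(chip)
  rng <- range(chip)
  if (rng[1] == rng[2]) {
    warning("constant chip: empty segmentation")
    out <- matrix(0L, h, w)
    attr(out, "threshold") <- rng[1]
    return(out)
  }
  thr <- otsu_threshold(chip)
  mask <- chip >= thr
  margin <- floor(w * (1 - central_band) / 2)
  if (margin > 0) {
    mask[, seq_len(margin)] <- FALSE
    mask[, (w - margin + 1):w] <- FALSE
  }
  if (!any(mask)) {
    warning("no foreground above the global threshold: empty segmentation")
    out <- matrix(0L, h, w)
    attr(out, "threshold") <- thr
    return(out)
  }
  img <- EBImage::Image(t(mask) * 1)
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  labv <- EBImage::imageData(lab)
  counts <- tabulate(labv[labv > 0])
  keep <- which.max(counts)
  out <- t(labv == keep) * 1L
  attr(out, "threshold") <- thr
  out
}
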