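#' Read a grayscale spine image
#'
#' Reads PNG or TIFF into a (row, col) intensity matrix on the 0-255
#' scale; colour images are averaged across channels.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix.
#' @export
read_spine_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  img * 255
}

#' Write a grayscale spine image
#'
#' @param image numeric matrix, 0-255 scale (clipped).
#' @param path output path; the extension selects PNG or TIFF.
#' @export
write_spine_image <- function(image, path) {
  x <- pmin(pmax(image / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(x, path),
         tif = , tiff = tiff::writeTIFF(x, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Pipeline configuration
#'
#' One serialisable object mirroring every operating parameter of the
#' measurement pipeline; [write_config()] / [read_config()] round-trip it
#' through JSON.
#'
#' @param window a [window_params()].
#' @param segmenter `"classical"`, `"unet"`, `"residual"` or `"dense"`.
#' @param threshold probability cutoff for network masks.
#' @param training a [training_config()].
#' @param roi list of [isolate_spine_roi()] arguments (`c`, `pad`,
#'   `align`).
#' @param chip_shape chip size.
#' @param seed integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = window_params(),
                            segmenter = "classical", threshold = 0.5,
                            training = training_config(),
                            roi = list(c = 1, pad = 60, align = FALSE),
                            chip_shape = c(256L, 128L), seed = 1L) {
  structure(list(window = unclass(window), segmenter = segmenter,
                 threshold = threshold, training = unclass(training),
                 roi = roi, chip_shape = as.integer(chip_shape),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "pipeline_config")
}
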