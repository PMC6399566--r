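#' Cobb-angle recovery experiment on synthetic phantoms
#'
#' Draws phantoms with ground-truth Cobb magnitudes uniform in
#' `cobb_range` and measures how well the angle is recovered, either by
#' feeding the noise-free ground-truth vertebra masks straight into the
#' minimum-bounding-rectangle stage (`mode = "gt"`, isolating the MBR +
#' maximum-pair geometry) or by the full training-free pipeline on the
#' rendered image (`mode = "classical"`: ROI isolation, detection,
#' classical segmentation, MBR).
#'
#' @param n number of phantoms.
#' @param mode `"gt"` or `"classical"`.
#' @param cobb_range range of the true Cobb magnitude, degrees.
#' @param seed integer seed.
#' @param spec_args extra fixed [phantom_spec()] arguments.
#' @return data frame with one row per phantom: `truth`, `estimate`,
#'   `error` (estimate - truth, signed angles), `ok` (the measurement
#'   succeeded), plus attributes `within2` and `within5` (fractions of
#'   successful measurements with absolute error within 2 and 5 degrees;
#'   failed measurements count as misses).
#' @export
cobb_recovery_experiment <- function(n = 50L, mode = c("gt", "classical"),
                                     cobb_range = c(5, 45), seed = 1L,
                                     spec_args = list()) {
  mode <- match.arg(mode)
  draws <- with_seed(seed, list(
    cobb = stats::runif(n, cobb_range[1], cobb_range[2]),
    dir = sample(c("left", "right"), n, replace = TRUE),
    au = sample(4:6, n, replace = TRUE),
    gap = sample(5:7, n, replace = TRUE),
    seeds = sample.int(.Machine$integer.max, n)))
  truth <- numeric(n); est <- rep(NA_real_, n); ok <- logical(n)
  for (k in seq_len(n)) {
    spec <- do.call(phantom_spec,
                    c(list(cobb_deg = draws$cobb[k],
                           direction = draws$dir[k],
                           apex_upper = draws$au[k],
                           apex_lower = draws$au[k] + draws$gap[k],
                           seed = draws$seeds[k]), spec_args))
    sm <- generate_phantom(spec)
    truth[k] <- sm$true_cobb_deg
    res <- tryCatch({
      if (mode == "gt") {
        mbrs <- lapply(seq_len(spec$n_vertebrae), function(i)
          suppressWarnings(min_bounding_rect(sm$masks[[i]]$m)))
        # mask submatrices keep their top-to-bottom order by construction
        sl <- list(upper = vapply(mbrs, `[[`, numeric(1), "upper_slope"),
                   lower = vapply(mbrs, `[[`, numeric(1), "lower_slope"))
        cobb_angle(sl$upper, sl$lower)$phi
      } else {
        suppressWarnings(measure_spine(sm$image)$cobb$phi)
      }
    }, error = function(e) NA_real_)
    est[k] <- res
    ok[k] <- is.finite(res)
  }
  err <- est - truth
  out <- data.frame(truth = truth, estimate = est, error = err, ok = ok)
  attr(out, "within2") <- mean(ok & abs(err) <= 2)
  attr(out, "within5") <- mean(ok & abs(err) <= 5)
  out
}

#' Cross-validated phantom segmentation experiment
#'
#' Generates a phantom chip dataset with [make_dataset()] and runs
#' [crossvalidate()] for each requested network variant under a common
#' training configuration, reporting the held-out Dice similarity
#' coefficient per variant.
#'
#' @param n_images phantom images (17 chips each).
#' @param variants network variants to compare.
#' @param folds cross-validation folds.
#' @param chip_shape chip size for this experiment.
#' @param base_channels first-level channel count.
#' @param epochs,augment_to,batch_size,learning_rate training settings.
#' @param noise_sd phantom noise level.
#' @param seed integer seed covering data generation, folds and training.
#' @param verbose print progress.
#' @return list with `summary` (data frame: variant, dsc_mean, dsc_sd)
#'   and `results` (per-variant [crossvalidate()] outputs).
#' @export
segmentation_cv_experiment <- function(n_images = 40L,
                                       variants = c("unet", "residual",
                                                    "dense"),
                                       folds = 5L,
                                       chip_shape = c(256L, 128L),
                                       base_channels = 8L, epochs = 20L,
                                       augment_to = 200L,
                                       batch_size = 10L,
                                       learning_rate = 0.01,
                                       noise_sd = 5, seed = 1L,
                                       verbose = FALSE) {
  dataset <- make_dataset(n_images, spec_ranges = list(
    fixed = list(noise_sd = noise_sd)), seed = seed,
    chip_shape = chip_shape)
  cfg <- training_config(batch_size = batch_size,
                         learning_rate = learning_rate, epochs = epochs,
                         augment_to = augment_to, seed = seed)
  results <- list()
  for (v in variants) {
    spec <- network_spec(v, input_shape = chip_shape,
                         base_channels = base_channels)
    results[[v]] <- crossvalidate(dataset, spec, folds = folds,
                                  config = cfg, verbose = verbose)
    if (verbose)
      message(sprintf("%s: DSC %.4f +/- %.4f", v,
                      results[[v]]$dsc_mean, results[[v]]$dsc_sd))
  }
  list(summary = data.frame(
         variant = names(results),
         dsc_mean = vapply(results, `[[`, numeric(1), "dsc_mean"),
         dsc_sd = vapply(results, `[[`, numeric(1), "dsc_sd"),
         row.names = NULL),
       results = results)
}
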