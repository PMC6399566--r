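test_that("convolution unit follows the conv/ReLU algebra", {
  x <- array(1, c(8, 8, 1, 1))
  # zero filters and zero bias -> zero output (before normalisation)
  p0 <- list(w = array(0, c(3, 3, 1, 2)), b = c(0, 0))
  expect_true(all(conv_unit(x, p0, batchnorm = FALSE) == 0))
  # all-negative pre-activation -> all zeros after ReLU
  pn <- list(w = array(0, c(3, 3, 1, 2)), b = c(-1, -3))
  expect_true(all(conv_unit(x, pn, batchnorm = FALSE) == 0))
  # identity-like kernel on a constant map -> constant map (interior)
  wi <- array(0, c(3, 3, 1, 1))
  wi[2, 2, 1, 1] <- 1
  y <- conv_unit(array(5, c(8, 8, 1, 1)), list(w = wi, b = 0),
                 batchnorm = FALSE)
  expect_true(all(y[2:7, 2:7, 1, 1] == 5))
})

test_that("compiled convolution matches direct summation", {
  set.seed(3)
  x <- array(stats::rnorm(10 * 7 * 2 * 1), c(10, 7, 2, 1))
  w <- array(stats::rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- stats::rnorm(3)
  y <- spinecobb:::nn_conv_fwd(x, w, b)
  # direct same-padded convolution at a few positions
  ref <- function(h, cc, co) {
    acc <- b[co]
    for (dr in -1:1) for (dc in -1:1) for (ci in 1:2) {
      hh <- h + dr; ww <- cc + dc
      if (hh >= 1 && hh <= 10 && ww >= 1 && ww <= 7)
        acc <- acc + x[hh, ww, ci, 1] * w[dr + 2, dc + 2, ci, co]
    }
    acc
  }
  for (pt in list(c(1, 1, 1), c(5, 4, 2), c(10, 7, 3), c(2, 6, 1)))
    expect_equal(y[pt[1], pt[2], pt[3], 1], ref(pt[1], pt[2], pt[3]),
                 tolerance = 1e-12)
})

test_that("residual block reduces to the identity with a zeroed branch", {
  set.seed(5)
  x <- array(stats::rnorm(16 * 8 * 4), c(16, 8, 4, 1))
  p <- spinecobb:::block_init("residual", 4L, 4L, 0L, 0L)
  expect_null(p$proj)  # equal channels: true identity mapping
  pz <- p
  pz$b1$w[] <- 0; pz$b1$b[] <- 0
  pz$b2$w[] <- 0; pz$b2$b[] <- 0
  expect_equal(residual_block(x, pz), x, tolerance = 1e-12)
  # output - input equals the branch applied alone
  y <- residual_block(x, p)
  br <- spinecobb:::pre_fwd(p$b2, spinecobb:::pre_fwd(p$b1, x)$y)$y
  expect_equal(y - x, br, tolerance = 1e-10)
  # zero input: output equals the branch of zero
  z <- array(0, c(16, 8, 4, 1))
  brz <- spinecobb:::pre_fwd(p$b2, spinecobb:::pre_fwd(p$b1, z)$y)$y
  expect_equal(residual_block(z, p), brz, tolerance = 1e-10)
})

test_that("dense block channel bookkeeping matches l x k", {
  x <- array(stats::rnorm(16 * 8 * 3), c(16, 8, 3, 1))
  expect_equal(dim(dense_block(x, layers = 4, growth = 12))[3], 48)
  expect_equal(dim(dense_block(x, layers = 1, growth = 5))[3], 5)
  # concatenation width before layer j is cin + (j - 1) k
  for (l in c(2, 3)) for (k in c(4, 6)) {
    params <- lapply(seq_len(l), function(j)
      spinecobb:::pre_init(3 + (j - 1) * k, k))
    out <- dense_block(x, layers = l, growth = k, params = params)
    expect_equal(dim(out)[3], l * k)
    widths <- vapply(params, function(p) dim(p$w)[3], numeric(1))
    expect_equal(widths, 3 + (seq_len(l) - 1) * k)
  }
})

test_that("all variants share shape contracts through the network", {
  spec0 <- network_spec("unet", input_shape = c(256, 128), depth = 4,
                        base_channels = 2)
  expect_error(network_spec("unet", input_shape = c(250, 128)),
               "divisible")
  x <- array(stats::runif(256 * 128), c(256, 128, 1, 1))
  for (v in c("unet", "residual", "dense")) {
    net <- build_network(network_spec(v, input_shape = c(256, 128),
                                      base_channels = 2,
                                      dense_layers = 2), seed = 2)
    out <- spinecobb:::forward_net(net, x, training = TRUE)
    expect_equal(dim(out), c(256, 128, 1, 1))
    expect_true(all(out >= 0 & out <= 1))   # probability map range
  }
  # bottleneck spatial size: 256x128 halved depth-4 times is 16x8
  net <- build_network(spec0, seed = 1)
  fw <- spinecobb:::forward_net(net, x, training = TRUE,
                                want_cache = TRUE)
  expect_equal(dim(fw$cache$mid$c1$x)[1:2], c(16, 8))
})

test_that("L2 loss is the mean squared difference", {
  expect_equal(l2_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(l2_loss(rep(0, 10), rep(1, 10)), 1)
  expect_equal(l2_loss(c(0, 1), c(1, 1)), 0.5)
})

test_that("backpropagation matches finite differences in every variant", {
  set.seed(42)
  x <- array(stats::runif(16 * 8 * 2), c(16, 8, 1, 2))
  y <- array(stats::rbinom(16 * 8 * 2, 1, 0.5), c(16, 8, 1, 2))
  getset <- function(obj, path, i, val = NULL) {
    if (length(path) == 1) {
      if (is.null(val)) return(obj[[path]][i])
      obj[[path]][i] <- val
      return(obj)
    }
    if (is.null(val)) return(getset(obj[[path[1]]], path[-1], i))
    obj[[path[1]]] <- getset(obj[[path[1]]], path[-1], i, val)
    obj
  }
  for (v in c("unet", "residual", "dense")) {
    spec <- network_spec(v, input_shape = c(16, 8), depth = 2,
                         base_channels = 4, dense_layers = 2,
                         input_scale = 1)
    net <- build_network(spec, seed = 7)
    fw <- spinecobb:::forward_net(net, x, training = TRUE,
                                  want_cache = TRUE)
    g <- 2 * (fw$prob - y) / length(y)
    grads <- spinecobb:::backward_net(net, fw$cache, g)
    eps <- 1e-5
    for (rep in 1:8) {
      p <- net$params
      path <- c()
      while (is.list(p)) {
        nm <- sample(names(p), 1)
        path <- c(path, nm)
        p <- p[[nm]]
      }
      i <- sample(length(p), 1)
      v0 <- getset(net$params, path, i)
      np <- net; np$params <- getset(net$params, path, i, v0 + eps)
      lp <- l2_loss(spinecobb:::forward_net(np, x, training = TRUE), y)
      nm2 <- net; nm2$params <- getset(net$params, path, i, v0 - eps)
      lm <- l2_loss(spinecobb:::forward_net(nm2, x, training = TRUE), y)
      gnum <- (lp - lm) / (2 * eps)
      gan <- getset(grads, path, i)
      expect_lt(abs(gnum - gan) / max(abs(gnum), abs(gan), 1e-6), 5e-3,
                label = sprintf("%s %s[%d]", v,
                                paste(path, collapse = "."), i))
    }
  }
})

test_that("training configuration defaults follow the published recipe", {
  cfg <- training_config()
  expect_equal(cfg$batch_size, 10L)
  expect_equal(cfg$learning_rate, 0.01)
  expect_equal(cfg$epochs, 100L)
  expect_equal(cfg$augment_to, 1000L)
  expect_equal(cfg$val_fraction, 0.10)
})

test_that("a tiny network can overfit a single chip", {
  set.seed(12)
  chip <- matrix(60, 32, 16)
  chip[8:24, 5:12] <- 220
  mask <- matrix(0, 32, 16)
  mask[8:24, 5:12] <- 1
  ok <- FALSE
  for (sd in 1:3) {
    spec <- network_spec("unet", input_shape = c(32, 16), depth = 2,
                         base_channels = 4)
    net <- build_network(spec, seed = sd)
    net <- train_network(net, array(chip, c(32, 16, 1)),
                         array(mask, c(32, 16, 1)),
                         training_config(epochs = 20, augment_to = NULL,
                                         val_fraction = 0, seed = sd))
    tl <- net$history$train_loss
    # strictly non-increasing over some 5-epoch window
    windows <- sapply(1:16, function(i) all(diff(tl[i:(i + 4)]) <= 0))
    if (any(windows) && tl[20] < tl[1]) ok <- TRUE
  }
  expect_true(ok)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(99)
  chips <- array(stats::runif(32 * 16 * 3, 0, 255), c(32, 16, 3))
  masks <- array(rbinom(32 * 16 * 3, 1, 0.3), c(32, 16, 3))
  run <- function() {
    net <- build_network(network_spec("unet", input_shape = c(32, 16),
                                      depth = 2, base_channels = 2),
                         seed = 5)
    train_network(net, chips, masks,
                  training_config(epochs = 2, augment_to = 6, seed = 5))
  }
  n1 <- run(); n2 <- run()
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("mask prediction thresholds the probability map", {
  spec <- network_spec("unet", input_shape = c(32, 16), depth = 2,
                       base_channels = 2)
  net <- build_network(spec, seed = 1)
  # zero every weight, then drive the head bias: prob = sigmoid(bias)
  net$params <- spinecobb:::tree_zero(net$params)
  net$params$head$b <- 10
  m1 <- predict_mask(net, matrix(100, 32, 16))
  expect_true(all(m1 == 1))
  expect_true(all(attr(m1, "prob") > 0.99))
  net$params$head$b <- -10
  expect_true(all(predict_mask(net, matrix(100, 32, 16)) == 0))
  # documented boundary behaviour: values at the cutoff become 1
  net$params$head$b <- 0   # prob exactly 0.5 everywhere
  expect_true(all(predict_mask(net, matrix(100, 32, 16),
                               threshold = 0.5) == 1))
  expect_error(predict_mask(net, matrix(0, 16, 16)), "chip must be")
})

test_that("classical segmentation separates bimodal chips", {
  chip <- matrix(50, 64, 32)
  chip[20:50, 10:24] <- 200
  set.seed(2)
  chip <- chip + matrix(stats::rnorm(64 * 32, 0, 3), 64, 32)
  seg <- classical_segment(chip)
  truth <- matrix(0, 64, 32)
  truth[20:50, 10:24] <- 1
  expect_gt(evaluate_masks(truth, seg)$dsc, 0.95)
  expect_warning(empty <- classical_segment(matrix(7, 20, 10)),
                 "constant chip")
  expect_true(all(empty == 0))
})

test_that("cross-validation folds are image-level and deterministic", {
  set.seed(31)
  nimg <- 10
  chips <- array(stats::runif(32 * 16 * nimg * 2, 0, 255),
                 c(32, 16, nimg * 2))
  masks <- array(0, c(32, 16, nimg * 2))
  masks[10:20, 5:10, ] <- 1
  ds <- list(chips = chips, masks = masks,
             image_id = rep(seq_len(nimg), each = 2))
  spec <- network_spec("unet", input_shape = c(32, 16), depth = 2,
                       base_channels = 2)
  cfg <- training_config(epochs = 1, augment_to = NULL, seed = 4)
  r1 <- crossvalidate(ds, spec, folds = 5, config = cfg)
  expect_equal(r1$per_fold$n_test, rep(4, 5))  # 2 images x 2 chips each
  r2 <- crossvalidate(ds, spec, folds = 5, config = cfg)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_error(crossvalidate(ds, spec, folds = 11, config = cfg),
               "folds")
})
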