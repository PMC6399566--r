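# Encoder-decoder segmentation networks (plain, residual and dense
# variants) with hand-written backpropagation on top of the compiled
# primitives in src/convnet.cpp.  Tensors are (H, W, C, N) arrays; chips
# enter scaled to [0, 1].

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# ---- conv unit: 3x3 conv -> ReLU -> batch norm -------------------------

cu_init <- function(cin, cout) {
  list(w = he_init(c(3, 3, cin, cout), 9 * cin), b = numeric(cout),
       g = rep(1, cout), be = numeric(cout))
}

bn_update_stats <- function(st, id, mean, invstd) {
  if (is.null(st) || is.null(id)) return(invisible())
  var <- 1 / invstd^2 - BN_EPS
  mkey <- paste0(id, ".mean"); vkey <- paste0(id, ".var")
  if (is.null(st[[mkey]])) {
    st[[mkey]] <- mean; st[[vkey]] <- var
  } else {
    st[[mkey]] <- (1 - BN_MOMENTUM) * st[[mkey]] + BN_MOMENTUM * mean
    st[[vkey]] <- (1 - BN_MOMENTUM) * st[[vkey]] + BN_MOMENTUM * var
  }
  invisible()
}

bn_apply <- function(x, g, be, training, st, id) {
  if (training || is.null(st) || is.null(st[[paste0(id, ".mean")]])) {
    out <- nn_bn_fwd(x, g, be, BN_EPS)
    if (training) bn_update_stats(st, id, out$mean, out$invstd)
    out
  } else {
    list(y = nn_bn_infer(x, g, be, st[[paste0(id, ".mean")]],
                         st[[paste0(id, ".var")]], BN_EPS),
         mean = NULL, invstd = NULL)
  }
}

cu_fwd <- function(p, x, training = TRUE, st = NULL, id = NULL) {
  z <- nn_conv_fwd(x, p$w, p$b)
  a <- nn_relu_fwd(z)
  bn <- bn_apply(a, p$g, p$be, training, st, id)
  list(y = bn$y, cache = list(x = x, z = z, a = a, mean = bn$mean,
                              invstd = bn$invstd))
}

cu_bwd <- function(p, cache, gy) {
  bnb <- nn_bn_bwd(cache$a, p$g, cache$mean, cache$invstd, gy)
  gr <- nn_relu_bwd(cache$z, bnb$gx)
  cb <- nn_conv_bwd(cache$x, p$w, gr)
  list(gx = cb$gx,
       gp = list(w = cb$gw, b = cb$gb, g = bnb$ggamma, be = bnb$gbeta))
}

# ---- pre-activation unit: batch norm -> ReLU -> 3x3 conv ---------------

pre_init <- function(cin, cout) {
  list(g = rep(1, cin), be = numeric(cin),
       w = he_init(c(3, 3, cin, cout), 9 * cin), b = numeric(cout))
}

pre_fwd <- function(p, x, training = TRUE, st = NULL, id = NULL) {
  bn <- bn_apply(x, p$g, p$be, training, st, id)
  a <- nn_relu_fwd(bn$y)
  z <- nn_conv_fwd(a, p$w, p$b)
  list(y = z, cache = list(x = x, bny = bn$y, a = a, mean = bn$mean,
                           invstd = bn$invstd))
}

pre_bwd <- function(p, cache, gy) {
  cb <- nn_conv_bwd(cache$a, p$w, gy)
  gr <- nn_relu_bwd(cache$bny, cb$gx)
  bnb <- nn_bn_bwd(cache$x, p$g, cache$mean, cache$invstd, gr)
  list(gx = bnb$gx,
       gp = list(g = bnb$ggamma, be = bnb$gbeta, w = cb$gw, b = cb$gb))
}

# ---- channel concatenation ---------------------------------------------

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(g, c1) {
  d <- dim(g)
  list(a = g[, , seq_len(c1), , drop = FALSE],
       b = g[, , (c1 + 1):d[3], , drop = FALSE])
}

# ---- blocks ------------------------------------------------------------

block_init <- function(variant, cin, cout, dense_layers, growth) {
  switch(variant,
    unet = list(c1 = cu_init(cin, cout), c2 = cu_init(cout, cout)),
    residual = {
      p <- list(b1 = pre_init(cin, cout), b2 = pre_init(cout, cout))
      if (cin != cout)
        p$proj <- list(w = matrix(stats::rnorm(cin * cout,
                                               0, sqrt(2 / cin)),
                                  cin, cout), b = numeric(cout))
      p
    },
    dense = {
      k <- growth
      layers <- lapply(seq_len(dense_layers), function(j)
        pre_init(cin + (j - 1) * k, k))
      names(layers) <- paste0("d", seq_len(dense_layers))
      c(layers, list(tr = list(
        w = matrix(stats::rnorm(dense_layers * k * cout, 0,
                                sqrt(2 / (dense_layers * k))),
                   dense_layers * k, cout),
        b = numeric(cout))))
    },
    stop("unknown variant: ", variant))
}

block_fwd <- function(variant, p, x, training, st, id) {
  if (variant == "unet") {
    o1 <- cu_fwd(p$c1, x, training, st, paste0(id, ".c1"))
    o2 <- cu_fwd(p$c2, o1$y, training, st, paste0(id, ".c2"))
    list(y = o2$y, cache = list(c1 = o1$cache, c2 = o2$cache))
  } else if (variant == "residual") {
    o1 <- pre_fwd(p$b1, x, training, st, paste0(id, ".b1"))
    o2 <- pre_fwd(p$b2, o1$y, training, st, paste0(id, ".b2"))
    skip <- if (!is.null(p$proj)) nn_conv1x1_fwd(x, p$proj$w, p$proj$b)
            else x
    list(y = skip + o2$y, cache = list(b1 = o1$cache, b2 = o2$cache,
                                       x = x))
  } else { # dense
    nl <- sum(startsWith(names(p), "d"))
    feats <- x
    outs <- vector("list", nl)
    caches <- vector("list", nl)
    for (j in seq_len(nl)) {
      o <- pre_fwd(p[[paste0("d", j)]], feats, training, st,
                   paste0(id, ".d", j))
      outs[[j]] <- o$y
      caches[[j]] <- o$cache
      feats <- cat_channels(feats, o$y)
    }
    stacked <- Reduce(cat_channels, outs)
    tr <- nn_conv1x1_fwd(stacked, p$tr$w, p$tr$b)
    list(y = tr, cache = list(layers = caches, stacked = stacked,
                              cin = dim(x)[3], k = dim(outs[[1]])[3],
                              nl = nl))
  }
}

block_bwd <- function(variant, p, cache, gy) {
  if (variant == "unet") {
    b2 <- cu_bwd(p$c2, cache$c2, gy)
    b1 <- cu_bwd(p$c1, cache$c1, b2$gx)
    list(gx = b1$gx, gp = list(c1 = b1$gp, c2 = b2$gp))
  } else if (variant == "residual") {
    b2 <- pre_bwd(p$b2, cache$b2, gy)
    b1 <- pre_bwd(p$b1, cache$b1, b2$gx)
    gp <- list(b1 = b1$gp, b2 = b2$gp)
    gx <- b1$gx
    if (!is.null(p$proj)) {
      pb <- nn_conv1x1_bwd(cache$x, p$proj$w, gy)
      gp$proj <- list(w = pb$gw, b = pb$gb)
      gx <- gx + pb$gx
    } else {
      gx <- gx + gy
    }
    list(gx = gx, gp = gp)
  } else { # dense
    tb <- nn_conv1x1_bwd(cache$stacked, p$tr$w, gy)
    nl <- cache$nl; k <- cache$k; cin <- cache$cin
    # gradient w.r.t. each layer output from the stacked concatenation
    gouts <- lapply(seq_len(nl), function(j)
      tb$gx[, , (j - 1) * k + seq_len(k), , drop = FALSE])
    gfeats <- NULL  # gradient w.r.t. the running concatenation
    gp <- list()
    gx_in <- 0
    for (j in rev(seq_len(nl))) {
      gj <- gouts[[j]]
      if (!is.null(gfeats)) {
        sp <- split_channels(gfeats, cin + (j - 1) * k)
        gj <- gj + sp$b
        gfeats <- sp$a
      }
      bb <- pre_bwd(p[[paste0("d", j)]], cache$layers[[j]], gj)
      gfeats <- if (is.null(gfeats)) bb$gx else gfeats + bb$gx
      gp[[paste0("d", j)]] <- bb$gp
    }
    list(gx = gfeats, gp = c(gp, list(tr = list(w = tb$gw, b = tb$gb))))
  }
}

# ---- network specification and construction ----------------------------

#' Specification of a vertebra segmentation network
#'
#' All three variants share an encoder-decoder topology with
#' concatenation skip connections: per encoder level a feature block (two
#' 3x3 convolution units for the plain variant; a pre-activation residual
#' block; or a dense block with a 1x1 transition) followed by 2x2
#' max-pooling with stride 2, and per decoder level 2x2 transposed-
#' convolution upsampling, a 3x3 convolution halving the channels,
#' concatenation with the matching encoder map, and a feature block.  The
#' head is a 1x1 convolution squashed logistically to a probability map
#' in [0, 1].
#'
#' @param variant `"unet"`, `"residual"` or `"dense"`.
#' @param input_shape chip size `c(rows, cols)`; must be divisible by
#'   `2^depth`.
#' @param depth encoder levels.
#' @param base_channels channels of the first level (doubling per level).
#' @param dense_layers layers per dense block (dense variant).
#' @param growth dense-block growth rate k; defaults to half the block's
#'   output width so a block emits `dense_layers * k` maps before its
#'   transition.
#' @param input_scale intensity divisor applied to chips on entry.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(variant = c("unet", "residual", "dense"),
                         input_shape = c(256L, 128L), depth = 4L,
                         base_channels = 8L, dense_layers = 4L,
                         growth = NULL, input_scale = 255) {
  variant <- match.arg(variant)
  if (any(input_shape %% 2^depth != 0))
    stop(sprintf("input shape %s not divisible by 2^depth = %d",
                 paste(input_shape, collapse = "x"), 2^depth))
  structure(list(variant = variant, input_shape = as.integer(input_shape),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dense_layers = as.integer(dense_layers),
                 growth = growth, input_scale = input_scale),
            class = "network_spec")
}

#' Build (randomly initialise) a segmentation network
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the He-initialised weights.
#' @return object of class `spine_network`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  D <- spec$depth; C0 <- spec$base_channels
  ch <- C0 * 2^(seq_len(D) - 1)
  gw <- function(cout) {
    if (!is.null(spec$growth)) spec$growth else max(2L, cout %/% 2L)
  }
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(D)) {
      p[[paste0("enc", i)]] <- block_init(spec$variant, cin, ch[i],
                                          spec$dense_layers, gw(ch[i]))
      cin <- ch[i]
    }
    mid <- 2L * ch[D]
    p$mid <- block_init(spec$variant, ch[D], mid, spec$dense_layers,
                        gw(mid))
    cur <- mid
    for (i in rev(seq_len(D))) {
      p[[paste0("up", i)]] <- list(
        w = he_init(c(2, 2, cur, cur), 4 * cur), b = numeric(cur))
      p[[paste0("hc", i)]] <- cu_init(cur, cur %/% 2L)
      p[[paste0("dec", i)]] <- block_init(spec$variant, cur, ch[i],
                                          spec$dense_layers, gw(ch[i]))
      cur <- ch[i]
    }
    p$head <- list(w = matrix(stats::rnorm(C0, 0, sqrt(2 / C0)), C0, 1),
                   b = numeric(1))
    p
  })
  structure(list(spec = spec, params = params, stats = new.env()),
            class = "spine_network")
}

forward_net <- function(net, x, training = FALSE, want_cache = FALSE) {
  v <- net$spec$variant
  p <- net$params
  st <- net$stats
  D <- net$spec$depth
  C <- list()
  skips <- vector("list", D)
  h <- x
  for (i in seq_len(D)) {
    o <- block_fwd(v, p[[paste0("enc", i)]], h, training, st,
                   paste0("enc", i))
    skips[[i]] <- o$y
    C[[paste0("enc", i)]] <- o$cache
    mp <- nn_maxpool_fwd(o$y)
    C[[paste0("pool", i)]] <- list(idx = mp$idx, dim = dim(o$y))
    h <- mp$y
  }
  o <- block_fwd(v, p$mid, h, training, st, "mid")
  C$mid <- o$cache
  h <- o$y
  for (i in rev(seq_len(D))) {
    C[[paste0("upx", i)]] <- h
    h <- nn_upconv_fwd(h, p[[paste0("up", i)]]$w, p[[paste0("up", i)]]$b)
    o <- cu_fwd(p[[paste0("hc", i)]], h, training, st, paste0("hc", i))
    C[[paste0("hc", i)]] <- o$cache
    C[[paste0("cat", i)]] <- dim(o$y)[3]
    h <- cat_channels(o$y, skips[[i]])
    o <- block_fwd(v, p[[paste0("dec", i)]], h, training, st,
                   paste0("dec", i))
    C[[paste0("dec", i)]] <- o$cache
    h <- o$y
  }
  C$headx <- h
  logits <- nn_conv1x1_fwd(h, p$head$w, p$head$b)
  prob <- 1 / (1 + exp(-logits))
  C$prob <- prob
  if (want_cache) list(prob = prob, cache = C) else prob
}

backward_net <- function(net, cache, gprob) {
  v <- net$spec$variant
  p <- net$params
  D <- net$spec$depth
  G <- list()
  glogits <- gprob * cache$prob * (1 - cache$prob)
  hb <- nn_conv1x1_bwd(cache$headx, p$head$w, glogits)
  G$head <- list(w = hb$gw, b = hb$gb)
  g <- hb$gx
  gskips <- vector("list", D)
  for (i in seq_len(D)) {
    bb <- block_bwd(v, p[[paste0("dec", i)]], cache[[paste0("dec", i)]], g)
    G[[paste0("dec", i)]] <- bb$gp
    sp <- split_channels(bb$gx, cache[[paste0("cat", i)]])
    gskips[[i]] <- sp$b
    hcb <- cu_bwd(p[[paste0("hc", i)]], cache[[paste0("hc", i)]], sp$a)
    G[[paste0("hc", i)]] <- hcb$gp
    ub <- nn_upconv_bwd(cache[[paste0("upx", i)]],
                        p[[paste0("up", i)]]$w, hcb$gx)
    G[[paste0("up", i)]] <- list(w = ub$gw, b = ub$gb)
    g <- ub$gx
  }
  bb <- block_bwd(v, p$mid, cache$mid, g)
  G$mid <- bb$gp
  g <- bb$gx
  for (i in rev(seq_len(D))) {
    pl <- cache[[paste0("pool", i)]]
    g <- nn_maxpool_bwd(g, pl$idx, pl$dim[1], pl$dim[2])
    g <- g + gskips[[i]]
    bb <- block_bwd(v, p[[paste0("enc", i)]], cache[[paste0("enc", i)]], g)
    G[[paste0("enc", i)]] <- bb$gp
    g <- bb$gx
  }
  G
}

# ---- parameter-tree utilities ------------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (nm in names(a)) out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  r$p
}

# ---- loss ---------------------------------------------------------------

#' Mean squared (L2) segmentation loss
#'
#' The mean over all elements of the squared difference between the
#' predicted probability map(s) and the binary ground truth.
#'
#' @param pred,truth arrays of identical shape.
#' @return scalar loss.
#' @export
l2_loss <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) &&
      length(pred) != length(truth))
    stop("shape mismatch between prediction and ground truth")
  mean((pred - truth)^2)
}

# ---- exported building blocks (functional form, for inspection/tests) --

#' One convolution unit: 3x3 convolution, ReLU, batch normalisation
#'
#' @param x input array (H, W, Cin, N).
#' @param params parameters as produced by `build_network` for a unit:
#'   list with `w` (3,3,Cin,Cout), `b`, `g`, `be`; defaults to a fresh
#'   He-initialised unit with `filters` output channels.
#' @param filters output channels when `params` is NULL.
#' @param batchnorm apply the batch normalisation stage (TRUE).
#' @return output array (H, W, Cout, N).
#' @export
conv_unit <- function(x, params = NULL, filters = 8L, batchnorm = TRUE) {
  if (is.null(params)) params <- cu_init(dim(x)[3], filters)
  if (!batchnorm)
    return(nn_relu_fwd(nn_conv_fwd(x, params$w, params$b)))
  cu_fwd(params, x, training = TRUE)$y
}

#' One pre-activation residual block
#'
#' `x + F(x)` where the residual branch F stacks two (batch norm, ReLU,
#' 3x3 convolution) units; when input and output channel counts differ
#' the identity path is replaced by a learned 1x1 projection so the
#' addition is well defined.
#'
#' @param x input array (H, W, Cin, N).
#' @param params block parameters (see `block_init`); fresh He-initialised
#'   parameters with `filters` output channels when NULL.
#' @param filters output channels when `params` is NULL.
#' @return output array.
#' @export
residual_block <- function(x, params = NULL, filters = dim(x)[3]) {
  if (is.null(params))
    params <- block_init("residual", dim(x)[3], filters, 0L, 0L)
  block_fwd("residual", params, x, training = TRUE, st = NULL,
            id = "res")$y
}

#' One dense block
#'
#' Each layer consumes the concatenation of the block input and all
#' previous layer outputs and emits `growth` feature maps; the block
#' output is the concatenation of the layer outputs, i.e.
#' `layers x growth` maps (the optional 1x1 transition of the full
#' network is not applied here).
#'
#' @param x input array (H, W, Cin, N).
#' @param layers number of dense layers l.
#' @param growth growth rate k.
#' @param params optional pre-built layer parameters.
#' @return output array with `layers * growth` channels.
#' @export
dense_block <- function(x, layers = 4L, growth = 12L, params = NULL) {
  cin <- dim(x)[3]
  if (is.null(params))
    params <- lapply(seq_len(layers), function(j)
      pre_init(cin + (j - 1) * growth, growth))
  feats <- x
  outs <- vector("list", layers)
  for (j in seq_len(layers)) {
    outs[[j]] <- pre_fwd(params[[j]], feats, training = TRUE)$y
    feats <- cat_channels(feats, outs[[j]])
  }
  Reduce(cat_channels, outs)
}

# ---- training -----------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the published recipe: batch size 10, learning rate
#' 0.01 with an adaptive-moment (Adam) optimizer, 100 epochs, per-fold
#' augmentation to 1000 images of which 10% serve as validation.
#'
#' @param batch_size,learning_rate,epochs optimiser settings.
#' @param augment_to inflate the training set to this many chips by random
#'   small rotation (within 5 degrees), translation (within 5 pixels) and
#'   intensity scaling (0.9-1.1); `NULL` disables augmentation.
#' @param val_fraction fraction held out for validation-loss tracking.
#' @param seed integer seed covering augmentation, splits and batching.
#' @return object of class `training_config`.
#' @export
training_config <- function(batch_size = 10L, learning_rate = 0.01,
                            epochs = 100L, augment_to = 1000L,
                            val_fraction = 0.10, seed = 1L) {
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 augment_to = if (is.null(augment_to)) NULL
                              else as.integer(augment_to),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "training_config")
}

augment_pair <- function(chip, mask) {
  ang <- stats::runif(1, -5, 5)
  dy <- stats::runif(1, -5, 5)
  dx <- stats::runif(1, -5, 5)
  sc <- stats::runif(1, 0.9, 1.1)
  fill <- stats::median(chip)
  list(chip = warp_matrix(chip, ang, dy, dx, fill = fill) * sc,
       mask = (warp_matrix(mask, ang, dy, dx, fill = 0) >= 0.5) * 1)
}

as_chip_array <- function(x) {
  if (is.list(x)) x <- array(unlist(x), c(dim(x[[1]]), length(x)))
  if (length(dim(x)) == 4) x <- x[, , 1, , drop = TRUE]
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  x
}

#' Train a segmentation network
#'
#' Seeded, reproducible (single-threaded) training of a
#' [build_network()] model on vertebra chips with binary masks:
#' optional augmentation up to `config$augment_to` chips, a validation
#' split, mini-batch Adam on the L2 loss, and per-epoch loss history.
#'
#' @param net a `spine_network`.
#' @param chips array (H, W, n) or list of chip matrices.
#' @param masks matching binary masks.
#' @param config a [training_config()].
#' @param verbose print per-epoch losses.
#' @return the trained network, with the history data frame (`epoch`,
#'   `train_loss`, `val_loss`) attached as `net$history`.
#' @export
train_network <- function(net, chips, masks, config = training_config(),
                          verbose = FALSE) {
  stopifnot(inherits(net, "spine_network"))
  chips <- as_chip_array(chips)
  masks <- as_chip_array(masks)
  if (!all(masks %in% c(0, 1))) stop("masks must be binary")
  hw <- net$spec$input_shape
  if (!all(dim(chips)[1:2] == hw))
    stop(sprintf("chips must be %dx%d", hw[1], hw[2]))
  nbase <- dim(chips)[3]
  if (nbase < 1) stop("need at least one training pair")
  with_seed(config$seed, {
    if (!is.null(config$augment_to) && config$augment_to > nbase) {
      extra <- config$augment_to - nbase
      src <- sample.int(nbase, extra, replace = TRUE)
      aug_c <- array(0, c(hw, extra))
      aug_m <- array(0, c(hw, extra))
      for (e in seq_len(extra)) {
        a <- augment_pair(chips[, , src[e]], masks[, , src[e]])
        aug_c[, , e] <- a$chip
        aug_m[, , e] <- a$mask
      }
      chips <- array(c(chips, aug_c), c(hw, nbase + extra))
      masks <- array(c(masks, aug_m), c(hw, nbase + extra))
    }
    ntot <- dim(chips)[3]
    nval <- min(ntot - 1, max(0, round(config$val_fraction * ntot)))
    vidx <- if (nval > 0) sample.int(ntot, nval) else integer(0)
    tidx <- setdiff(seq_len(ntot), vidx)
    state <- new.env()
    state$t <- 0
    state$m <- tree_zero(net$params)
    state$v <- tree_zero(net$params)
    hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    scl <- net$spec$input_scale
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tidx)
      losses <- c()
      for (b0 in seq(1, length(ord), by = config$batch_size)) {
        bi <- ord[b0:min(b0 + config$batch_size - 1, length(ord))]
        x <- chips[, , bi, drop = FALSE] / scl
        dim(x) <- c(hw[1], hw[2], 1, length(bi))
        y <- masks[, , bi, drop = FALSE]
        dim(y) <- dim(x)
        fw <- forward_net(net, x, training = TRUE, want_cache = TRUE)
        loss <- l2_loss(fw$prob, y)
        if (!is.finite(loss))
          stop(sprintf("training diverged (loss %g) at epoch %d",
                       loss, ep))
        losses <- c(losses, loss)
        g <- 2 * (fw$prob - y) / length(y)
        grads <- backward_net(net, fw$cache, g)
        grads <- grads[names(net$params)]
        net$params <- adam_step(net$params, grads, state,
                                config$learning_rate)
      }
      vloss <- NA_real_
      if (length(vidx)) {
        xv <- chips[, , vidx, drop = FALSE] / scl
        dim(xv) <- c(hw[1], hw[2], 1, length(vidx))
        yv <- masks[, , vidx, drop = FALSE]
        dim(yv) <- dim(xv)
        vloss <- l2_loss(forward_net(net, xv, training = FALSE), yv)
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = mean(losses),
                                     val_loss = vloss))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                        mean(losses), vloss))
    }
    net$history <- hist
    net
  })
}

#' Segment a chip with a trained network
#'
#' Runs the forward pass (inference batch-norm statistics) and thresholds
#' the probability map.
#'
#' @param net a trained `spine_network`.
#' @param chip matrix matching the network's input shape.
#' @param threshold probability cutoff (values at or above it become 1).
#' @return binary 0/1 matrix with attributes `"prob"` (the probability
#'   map) and `"threshold"`.
#' @export
predict_mask <- function(net, chip, threshold = 0.5) {
  hw <- net$spec$input_shape
  if (!all(dim(chip) == hw))
    stop(sprintf("chip must be %dx%d, got %dx%d", hw[1], hw[2],
                 nrow(chip), ncol(chip)))
  x <- array(chip / net$spec$input_scale, c(hw[1], hw[2], 1, 1))
  prob <- forward_net(net, x, training = FALSE)[, , 1, 1]
  out <- (prob >= threshold) * 1L
  attr(out, "prob") <- prob
  attr(out, "threshold") <- threshold
  out
}

predict_prob_batch <- function(net, chips, batch = 16L) {
  chips <- as_chip_array(chips)
  hw <- net$spec$input_shape
  n <- dim(chips)[3]
  out <- array(0, c(hw, n))
  for (b0 in seq(1, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1, n)
    x <- chips[, , bi, drop = FALSE] / net$spec$input_scale
    dim(x) <- c(hw[1], hw[2], 1, length(bi))
    out[, , bi] <- forward_net(net, x, training = FALSE)[, , 1, ]
  }
  out
}

#' K-fold cross-validation of a segmentation network
#'
#' Folds are assigned at the image level (all chips of a phantom stay in
#' the same fold) to avoid leakage between training and test chips of the
#' same image.  Each fold trains a freshly initialised network on the
#' remaining folds' chips and reports the Dice similarity coefficient on
#' the held-out chips.
#'
#' @param dataset a [make_dataset()] result (needs `chips`, `masks`,
#'   `image_id`).
#' @param spec a [network_spec()].
#' @param folds number of folds.
#' @param config a [training_config()].
#' @param threshold probability cutoff for the evaluated masks.
#' @param verbose print fold progress.
#' @return list with `per_fold` (data frame: fold, n_test, mean and sd of
#'   DSC), `dsc_mean`, `dsc_sd` (overall, over all held-out chips) and
#'   `per_chip`.
#' @export
crossvalidate <- function(dataset, spec, folds = 5L,
                          config = training_config(), threshold = 0.5,
                          verbose = FALSE) {
  ids <- unique(dataset$image_id)
  if (length(ids) < folds)
    stop(sprintf("%d folds requested but only %d images", folds,
                 length(ids)))
  fold_of <- with_seed(config$seed,
                       sample(rep_len(seq_len(folds), length(ids))))
  names(fold_of) <- ids
  all_dsc <- numeric(0)
  chip_fold <- integer(0)
  rows <- list()
  for (f in seq_len(folds)) {
    test_imgs <- ids[fold_of == f]
    te <- dataset$image_id %in% test_imgs
    cfg <- config
    cfg$seed <- config$seed + f
    net <- build_network(spec, seed = cfg$seed)
    net <- train_network(net,
                         dataset$chips[, , !te, drop = FALSE],
                         dataset$masks[, , !te, drop = FALSE], cfg)
    probs <- predict_prob_batch(net, dataset$chips[, , te, drop = FALSE])
    dsc <- vapply(seq_len(dim(probs)[3]), function(i)
      evaluate_masks(dataset$masks[, , which(te)[i]],
                     (probs[, , i] >= threshold) * 1)$dsc, numeric(1))
    rows[[f]] <- data.frame(fold = f, n_test = length(dsc),
                            dsc_mean = mean(dsc), dsc_sd = stats::sd(dsc))
    all_dsc <- c(all_dsc, dsc)
    chip_fold <- c(chip_fold, rep(f, length(dsc)))
    if (verbose)
      message(sprintf("fold %d/%d: DSC %.4f +/- %.4f", f, folds,
                      mean(dsc), stats::sd(dsc)))
  }
  list(per_fold = do.call(rbind, rows), dsc_mean = mean(all_dsc),
       dsc_sd = stats::sd(all_dsc),
       per_chip = data.frame(fold = chip_fold, dsc = all_dsc))
}
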