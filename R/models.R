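# Segmentation backbones: a modified U-Net (instance normalisation instead
# of batch normalisation, LeakyReLU with slope 1e-2 instead of ReLU) and a
# modified MS-D network (densely connected single-width dilated convolutions
# at fixed resolution, modified the same way), each in 2D and 3D.

#' Specify a segmentation model
#'
#' @param family `"unet"` (encoder-decoder with skip connections) or
#'   `"msd"` (mixed-scale dense network: dilated convolutions, no
#'   down/upsampling).
#' @param dims 2 or 3.
#' @param num_classes Output classes C (>= 2).
#' @param in_channels Input channels (default 1; a 2.5D channel-stacked
#'   input is possible but off by default).
#' @param depth U-Net levels (ignored for msd). Default 4; tests and
#'   desk-scale runs use smaller values.
#' @param base_width U-Net channels at the first level (default 24).
#' @param n_layers MS-D layer count (default 40).
#' @param dilations MS-D dilation cycle (default 1..10, recycled).
#' @param leaky_slope LeakyReLU negative slope (default 1e-2).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("unet", "msd"), dims = 2L, num_classes = 3L,
                       in_channels = 1L, depth = 4L, base_width = 24L,
                       n_layers = 40L, dilations = 1:10, leaky_slope = 1e-2) {
  family <- match.arg(family)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (num_classes < 2L) stop("num_classes must be >= 2")
  if (family == "unet" && depth < 1L) stop("depth must be >= 1")
  if (family == "msd" && (n_layers < 1L || any(dilations < 1L))) {
    stop("msd needs n_layers >= 1 and dilations >= 1")
  }
  structure(list(family = family, dims = as.integer(dims),
                 num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 depth = as.integer(depth), base_width = as.integer(base_width),
                 n_layers = as.integer(n_layers), dilations = as.integer(dilations),
                 leaky_slope = leaky_slope),
            class = "model_spec")
}

#' Build a segmentation model with freshly initialised weights
#'
#' Weight initialisation is He-style and a pure function of the seed: two
#' builds from the same spec and seed have identical parameters.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for initialisation.
#' @return An object of class `ctseg_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  rng <- rng_stream(seed)
  nd <- spec$dims
  off3 <- conv_offsets(3L, nd)
  n3 <- nrow(off3)
  params <- list()
  add_block <- function(prefix, cin, cout) {
    params[[paste0(prefix, "_w1")]] <<- init_conv(n3, cin, cout, rng)
    params[[paste0(prefix, "_b1")]] <<- numeric(cout)
    params[[paste0(prefix, "_g1")]] <<- rep(1, cout)
    params[[paste0(prefix, "_be1")]] <<- numeric(cout)
    params[[paste0(prefix, "_w2")]] <<- init_conv(n3, cout, cout, rng)
    params[[paste0(prefix, "_b2")]] <<- numeric(cout)
    params[[paste0(prefix, "_g2")]] <<- rep(1, cout)
    params[[paste0(prefix, "_be2")]] <<- numeric(cout)
  }
  if (spec$family == "unet") {
    w <- spec$base_width
    cin <- spec$in_channels
    for (l in seq_len(spec$depth)) {
      add_block(paste0("enc", l), cin, w * 2^(l - 1L))
      cin <- w * 2^(l - 1L)
    }
    add_block("bott", cin, w * 2^spec$depth)
    up_in <- w * 2^spec$depth
    for (l in rev(seq_len(spec$depth))) {
      skip_ch <- w * 2^(l - 1L)
      add_block(paste0("dec", l), up_in + skip_ch, skip_ch)
      up_in <- skip_ch
    }
    params$final_w <- init_conv(1L, w, spec$num_classes, rng)
    params$final_b <- numeric(spec$num_classes)
  } else {
    cin <- spec$in_channels
    for (i in seq_len(spec$n_layers)) {
      params[[paste0("msd", i, "_w")]] <- init_conv(n3, cin + i - 1L, 1L, rng)
      params[[paste0("msd", i, "_b")]] <- numeric(1L)
      params[[paste0("msd", i, "_g")]] <- rep(1, 1L)
      params[[paste0("msd", i, "_be")]] <- numeric(1L)
    }
    params$final_w <- init_conv(1L, cin + spec$n_layers, spec$num_classes, rng)
    params$final_b <- numeric(spec$num_classes)
  }
  structure(list(spec = spec, params = params, seed = as.integer(seed)),
            class = "ctseg_model")
}

#' @export
print.ctseg_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<ctseg_model> %s %dD, C=%d, %s parameters\n",
              x$spec$family, x$spec$dims, x$spec$num_classes, format(np, big.mark = ",")))
  invisible(x)
}

# conv3 -> instance norm -> leaky relu, twice
.block_fwd <- function(x, p, prefix, off3, slope) {
  cache <- list(x = x)
  c1 <- conv_fwd_cached(x, p[[paste0(prefix, "_w1")]], p[[paste0(prefix, "_b1")]], off3)
  in1 <- inorm_fwd(c1$y, p[[paste0(prefix, "_g1")]], p[[paste0(prefix, "_be1")]])
  a1 <- lrelu_fwd(in1$y, slope)
  cache$c1 <- c1; cache$in1 <- in1$cache; cache$a1 <- a1$cache; cache$h1in <- a1$y
  c2 <- conv_fwd_cached(a1$y, p[[paste0(prefix, "_w2")]], p[[paste0(prefix, "_b2")]], off3)
  in2 <- inorm_fwd(c2$y, p[[paste0(prefix, "_g2")]], p[[paste0(prefix, "_be2")]])
  a2 <- lrelu_fwd(in2$y, slope)
  cache$c2 <- c2; cache$in2 <- in2$cache; cache$a2 <- a2$cache
  list(y = a2$y, cache = cache)
}

.block_bwd <- function(cache, p, prefix, off3, slope, dy, grads) {
  dy <- lrelu_bwd(cache$a2, dy, slope)
  bi2 <- inorm_bwd(cache$in2, p[[paste0(prefix, "_g2")]], dy)
  grads[[paste0(prefix, "_g2")]] <- bi2$dgamma
  grads[[paste0(prefix, "_be2")]] <- bi2$dbeta
  bc2 <- conv_bwd(cache$h1in, p[[paste0(prefix, "_w2")]], off3, bi2$dx, cache$c2)
  grads[[paste0(prefix, "_w2")]] <- bc2$dW
  grads[[paste0(prefix, "_b2")]] <- bc2$db
  dy <- lrelu_bwd(cache$a1, bc2$dx, slope)
  bi1 <- inorm_bwd(cache$in1, p[[paste0(prefix, "_g1")]], dy)
  grads[[paste0(prefix, "_g1")]] <- bi1$dgamma
  grads[[paste0(prefix, "_be1")]] <- bi1$dbeta
  bc1 <- conv_bwd(cache$x, p[[paste0(prefix, "_w1")]], off3, bi1$dx, cache$c1)
  grads[[paste0(prefix, "_w1")]] <- bc1$dW
  grads[[paste0(prefix, "_b1")]] <- bc1$db
  list(dx = bc1$dx, grads = grads)
}

# Forward pass to pre-softmax logits. x: (spatial..., N, in_channels).
model_forward <- function(model, x) {
  spec <- model$spec; p <- model$params
  nd <- spec$dims
  off3 <- conv_offsets(3L, nd)
  off1 <- conv_offsets(1L, nd)
  slope <- spec$leaky_slope
  if (spec$family == "unet") {
    sp <- dim(x)[seq_len(nd)]
    if (any(sp %% 2^spec$depth != 0)) {
      stop("spatial dims (", paste(sp, collapse = "x"),
           ") must be divisible by 2^depth = ", 2^spec$depth)
    }
    caches <- list(); skips <- list()
    cur <- x
    for (l in seq_len(spec$depth)) {
      bl <- .block_fwd(cur, p, paste0("enc", l), off3, slope)
      caches[[paste0("enc", l)]] <- bl$cache
      skips[[l]] <- bl$y
      pl <- pool_fwd(bl$y)
      caches[[paste0("pool", l)]] <- pl$cache
      cur <- pl$y
    }
    bl <- .block_fwd(cur, p, "bott", off3, slope)
    caches$bott <- bl$cache
    cur <- bl$y
    for (l in rev(seq_len(spec$depth))) {
      up <- upsample_fwd(cur)
      cat_in <- concat_ch(up, skips[[l]])
      caches[[paste0("cat", l)]] <- dim(up)[length(dim(up))]
      bl <- .block_fwd(cat_in, p, paste0("dec", l), off3, slope)
      caches[[paste0("dec", l)]] <- bl$cache
      cur <- bl$y
    }
    logits <- conv_fwd(cur, p$final_w, p$final_b, off1)
    caches$final_in <- cur
    list(logits = logits, cache = caches)
  } else {
    feats <- x
    caches <- list()
    for (i in seq_len(spec$n_layers)) {
      dil <- spec$dilations[((i - 1L) %% length(spec$dilations)) + 1L]
      offd <- conv_offsets(3L, nd, dil)
      cc <- conv_fwd_cached(feats, p[[paste0("msd", i, "_w")]], p[[paste0("msd", i, "_b")]], offd)
      ino <- inorm_fwd(cc$y, p[[paste0("msd", i, "_g")]], p[[paste0("msd", i, "_be")]])
      act <- lrelu_fwd(ino$y, slope)
      caches[[i]] <- list(x = feats, conv = cc, ino = ino$cache, act = act$cache, dil = dil)
      feats <- concat_ch(feats, act$y)
    }
    logits <- conv_fwd(feats, p$final_w, p$final_b, off1)
    list(logits = logits, cache = list(layers = caches, final_in = feats))
  }
}

# Backward pass from dLoss/dlogits to parameter gradients.
model_backward <- function(model, cache, dlogits) {
  spec <- model$spec; p <- model$params
  nd <- spec$dims
  off3 <- conv_offsets(3L, nd)
  off1 <- conv_offsets(1L, nd)
  slope <- spec$leaky_slope
  grads <- list()
  if (spec$family == "unet") {
    bf <- conv_bwd(cache$final_in, p$final_w, off1, dlogits)
    grads$final_w <- bf$dW; grads$final_b <- bf$db
    dy <- bf$dx
    for (l in seq_len(spec$depth)) {
      bb <- .block_bwd(cache[[paste0("dec", l)]], p, paste0("dec", l), off3, slope, dy, grads)
      grads <- bb$grads
      c_up <- cache[[paste0("cat", l)]]
      parts <- split_ch(bb$dx, c_up)
      # skip gradient joins the encoder backward below; the upsampled part
      # flows on to the next (deeper) decoder stage / bottleneck
      cache[[paste0("dskip", l)]] <- parts[[2]]
      dy <- upsample_bwd(parts[[1]])
    }
    # bottleneck
    bb <- .block_bwd(cache$bott, p, "bott", off3, slope, dy, grads)
    grads <- bb$grads
    dy <- bb$dx
    for (l in rev(seq_len(spec$depth))) {
      dpool <- pool_bwd(cache[[paste0("pool", l)]], dy)
      dtot <- dpool + cache[[paste0("dskip", l)]]
      bb <- .block_bwd(cache[[paste0("enc", l)]], p, paste0("enc", l), off3, slope, dtot, grads)
      grads <- bb$grads
      dy <- bb$dx
    }
  } else {
    bf <- conv_bwd(cache$final_in, p$final_w, off1, dlogits)
    grads$final_w <- bf$dW; grads$final_b <- bf$db
    dfeats <- bf$dx
    cin <- spec$in_channels
    for (i in rev(seq_len(spec$n_layers))) {
      lc <- cache$layers[[i]]
      parts <- split_ch(dfeats, cin + i - 1L)
      dprev <- parts[[1]]; dnew <- parts[[2]]
      da <- lrelu_bwd(lc$act, dnew, slope)
      bi <- inorm_bwd(lc$ino, p[[paste0("msd", i, "_g")]], da)
      grads[[paste0("msd", i, "_g")]] <- bi$dgamma
      grads[[paste0("msd", i, "_be")]] <- bi$dbeta
      offd <- conv_offsets(3L, nd, lc$dil)
      bc <- conv_bwd(lc$x, p[[paste0("msd", i, "_w")]], offd, bi$dx, lc$conv)
      grads[[paste0("msd", i, "_w")]] <- bc$dW
      grads[[paste0("msd", i, "_b")]] <- bc$db
      dfeats <- dprev + bc$dx
    }
  }
  grads
}

# Softmax over the trailing class axis.
softmax_probs <- function(logits) {
  d <- dim(logits)
  C <- d[length(d)]
  m <- matrix(logits, ncol = C)
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Run a model forward and return class probabilities
#'
#' @param model A [build_model()] result.
#' @param x Input array `(spatial..., batch, in_channels)`.
#' @return Probability array `(spatial..., batch, num_classes)`; voxel-wise
#'   probabilities sum to 1.
#' @export
model_predict_probs <- function(model, x) {
  softmax_probs(model_forward(model, x)$logits)
}
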