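# The deep U-Net: depth stride-2 downsamplings (8 for the 512x512 clinical
# geometry), encoder blocks of two [3x3 conv -> batch norm -> LeakyReLU]
# units, separate stride-2 3x3 downsampling convs, 5x5 stride-2 transposed
# convs with skip concatenation in the decoder, and a 1x1 softmax head.

#' Network configuration
#'
#' @param input_size pixels per side; must be divisible by \code{2^depth},
#'   with a bottleneck of at least 2 x 2.
#' @param input_channels 1 (intensity only) or 3 (with coordinate channels).
#' @param num_classes number of output classes (3: background, lumen, EEM
#'   ring).
#' @param depth number of stride-2 downsamplings; 8 reproduces the full
#'   architecture at 512 x 512 (2 x 2 bottleneck), tests use 4 at 128 x 128.
#' @param base_channels feature maps of the first encoder block; doubled at
#'   every downsampling.
#' @param max_channels cap on the channel doubling.
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @return An object of class \code{unet_config}.
#' @export
model_config <- function(input_size = 512L, input_channels = 1L,
                         num_classes = 3L, depth = 8L, base_channels = 32L,
                         max_channels = 512L, leaky_slope = 0.01) {
  cfg <- list(input_size = as.integer(input_size),
              input_channels = as.integer(input_channels),
              num_classes = as.integer(num_classes),
              depth = as.integer(depth),
              base_channels = as.integer(base_channels),
              max_channels = as.integer(max_channels),
              leaky_slope = as.numeric(leaky_slope))
  if (cfg$depth < 1) stop_config("depth", "must be >= 1")
  if (cfg$input_size %% 2^cfg$depth != 0)
    stop_config("input_size",
                sprintf("must be divisible by 2^depth = %d", 2^cfg$depth))
  if (cfg$input_size / 2^cfg$depth < 2)
    stop_config("depth", "bottleneck spatial size must be >= 2")
  if (cfg$num_classes < 2) stop_config("num_classes", "must be >= 2")
  if (!cfg$input_channels %in% c(1L, 3L))
    stop_config("input_channels", "must be 1 or 3")
  if (cfg$base_channels < 1 || cfg$max_channels < cfg$base_channels)
    stop_config("base_channels", "must satisfy 1 <= base_channels <= max_channels")
  structure(cfg, class = "unet_config")
}

unet_channels <- function(config) {
  pmin(config$base_channels * 2^(0:config$depth), config$max_channels)
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' Build the U-Net with randomly initialized weights
#'
#' The encoder has \code{depth + 1} blocks (block 1 at full resolution) with
#' a separate stride-2 3x3 convolution between consecutive blocks; the
#' decoder has \code{depth} blocks, each a 5x5 stride-2 transposed
#' convolution (exactly doubling the spatial size) followed by concatenation
#' with the same-resolution encoder output and two conv-BN-LeakyReLU units.
#' All weights use He-style random initialization; no pretrained transfer.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class \code{ivus_unet}.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  depth <- config$depth
  ch <- unet_channels(config)
  params <- list()
  state <- list()
  add_bn <- function(prefix, c) {
    params[[paste0(prefix, ".gamma")]] <<- rep(1, c)
    params[[paste0(prefix, ".beta")]] <<- rep(0, c)
    state[[prefix]] <<- list(mean = rep(0, c), var = rep(1, c))
  }
  add_conv <- function(prefix, k, cin, cout) {
    params[[paste0(prefix, ".w")]] <<- he_init(k, cin, cout)
    params[[paste0(prefix, ".b")]] <<- rep(0, cout)
  }
  with_seed(seed, {
    for (b in seq_len(depth + 1)) {
      cin <- if (b == 1) config$input_channels else ch[b]
      add_conv(sprintf("enc%d.c1", b), 3, cin, ch[b])
      add_bn(sprintf("enc%d.bn1", b), ch[b])
      add_conv(sprintf("enc%d.c2", b), 3, ch[b], ch[b])
      add_bn(sprintf("enc%d.bn2", b), ch[b])
      if (b <= depth) {
        add_conv(sprintf("down%d", b), 3, ch[b], ch[b + 1])
        add_bn(sprintf("down%d.bn", b), ch[b + 1])
      }
    }
    for (d in seq_len(depth)) {
      # transposed conv weight stored as the adjoint conv (k, k, Cout, Cin)
      params[[sprintf("up%d.w", d)]] <- he_init(5, ch[d], ch[d + 1])
      params[[sprintf("up%d.b", d)]] <- rep(0, ch[d])
      add_bn(sprintf("up%d.bn", d), ch[d])
      add_conv(sprintf("dec%d.c1", d), 3, 2 * ch[d], ch[d])
      add_bn(sprintf("dec%d.bn1", d), ch[d])
      add_conv(sprintf("dec%d.c2", d), 3, ch[d], ch[d])
      add_bn(sprintf("dec%d.bn2", d), ch[d])
    }
    add_conv("head", 1, ch[1], config$num_classes)
  })
  structure(list(config = config, params = params, state = state),
            class = "ivus_unet")
}

#' @export
print.ivus_unet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ivus_unet %dx%dx%d depth=%d (%d enc / %d dec blocks), %d classes, %s parameters>\n",
    cfg$input_size, cfg$input_size, cfg$input_channels, cfg$depth,
    cfg$depth + 1, cfg$depth, cfg$num_classes,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an [build_unet()] model.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

#' Spatial/channel trace of the network blocks
#'
#' @param config a [model_config()] (or a built model).
#' @return A data.frame with one row per block: name, spatial size, channels.
#' @export
layer_trace <- function(config) {
  if (inherits(config, "ivus_unet")) config <- config$config
  depth <- config$depth
  ch <- unet_channels(config)
  sizes <- config$input_size / 2^(0:depth)
  enc <- data.frame(block = sprintf("enc%d", seq_len(depth + 1)),
                    spatial = sizes, channels = ch[seq_len(depth + 1)])
  dec <- data.frame(block = sprintf("dec%d", depth:1),
                    spatial = sizes[depth:1], channels = ch[depth:1])
  rbind(enc, dec)
}

# --- forward / backward -----------------------------------------------------

bn_act_fwd <- function(model, st, z, bn_prefix, training, keep_cache) {
  r <- cpp_bn_act_fwd(z, model$params[[paste0(bn_prefix, ".gamma")]],
                      model$params[[paste0(bn_prefix, ".beta")]],
                      st[[bn_prefix]]$mean, st[[bn_prefix]]$var,
                      training, 0.1, 1e-5, model$config$leaky_slope,
                      keep_cache)
  if (training) st[[bn_prefix]] <- list(mean = r$rmean, var = r$rvar)
  list(r = r, st = st)
}

cbr_fwd <- function(model, st, x, prefix, bn_prefix, stride, pad, training,
                    keep_cache = TRUE) {
  w <- model$params[[paste0(prefix, ".w")]]
  b <- model$params[[paste0(prefix, ".b")]]
  cv <- cpp_conv_fwd(x, w, b, stride, pad, FALSE)
  ba <- bn_act_fwd(model, st, cv$y, bn_prefix, training, keep_cache)
  list(y = ba$r$y, st = ba$st,
       cache = if (keep_cache)
         list(x = x, y = ba$r$y, xhat = ba$r$xhat, invstd = ba$r$invstd,
              prefix = prefix, bn_prefix = bn_prefix,
              stride = stride, pad = pad))
}

cbr_bwd <- function(model, dy, cache, grads, want_dx = TRUE) {
  slope <- model$config$leaky_slope
  bnb <- cpp_bn_act_bwd(dy, cache$y, cache$xhat, cache$invstd,
                        model$params[[paste0(cache$bn_prefix, ".gamma")]], slope)
  acc(grads, paste0(cache$bn_prefix, ".gamma"), bnb$dgamma)
  acc(grads, paste0(cache$bn_prefix, ".beta"), bnb$dbeta)
  w <- model$params[[paste0(cache$prefix, ".w")]]
  cb <- cpp_conv_bwd(cache$x, w, bnb$dx, cache$stride, cache$pad,
                     NULL, want_dx)
  acc(grads, paste0(cache$prefix, ".w"), cb$dw)
  acc(grads, paste0(cache$prefix, ".b"), cb$db)
  if (want_dx) cb$dx else NULL
}

tcbr_fwd <- function(model, st, x, d, training, keep_cache = TRUE) {
  prefix <- sprintf("up%d", d)
  w <- model$params[[paste0(prefix, ".w")]]
  b <- model$params[[paste0(prefix, ".b")]]
  hh <- 2L * dim(x)[1]
  z <- cpp_convt_fwd(x, w, b, 2L, 2L, hh, hh)
  bn_prefix <- paste0(prefix, ".bn")
  ba <- bn_act_fwd(model, st, z, bn_prefix, training, keep_cache)
  list(y = ba$r$y, st = ba$st,
       cache = if (keep_cache)
         list(x = x, y = ba$r$y, xhat = ba$r$xhat, invstd = ba$r$invstd,
              prefix = prefix, bn_prefix = bn_prefix))
}

tcbr_bwd <- function(model, dy, cache, grads) {
  slope <- model$config$leaky_slope
  bnb <- cpp_bn_act_bwd(dy, cache$y, cache$xhat, cache$invstd,
                        model$params[[paste0(cache$bn_prefix, ".gamma")]], slope)
  acc(grads, paste0(cache$bn_prefix, ".gamma"), bnb$dgamma)
  acc(grads, paste0(cache$bn_prefix, ".beta"), bnb$dbeta)
  w <- model$params[[paste0(cache$prefix, ".w")]]
  cb <- cpp_convt_bwd(cache$x, w, bnb$dx, 2L, 2L)
  acc(grads, paste0(cache$prefix, ".w"), cb$dw)
  acc(grads, paste0(cache$prefix, ".b"), cb$db)
  cb$dx
}

acc <- function(grads, name, g) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

block_fwd <- function(model, st, x, prefix, training, keep_cache = TRUE) {
  r1 <- cbr_fwd(model, st, x, paste0(prefix, ".c1"), paste0(prefix, ".bn1"),
                1L, 1L, training, keep_cache)
  r2 <- cbr_fwd(model, r1$st, r1$y, paste0(prefix, ".c2"), paste0(prefix, ".bn2"),
                1L, 1L, training, keep_cache)
  list(y = r2$y, st = r2$st,
       cache = if (keep_cache) list(c1 = r1$cache, c2 = r2$cache))
}

block_bwd <- function(model, dy, cache, grads, want_dx = TRUE) {
  d2 <- cbr_bwd(model, dy, cache$c2, grads)
  cbr_bwd(model, d2, cache$c1, grads, want_dx)
}

check_input <- function(model, x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x)
  cfg <- model$config
  if (is.null(d) || length(d) != 4)
    stop("dimension error: expected an (H, W, C, N) array", call. = FALSE)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size)
    stop(sprintf("dimension error: expected %dx%d input, got %dx%d",
                 cfg$input_size, cfg$input_size, d[1], d[2]), call. = FALSE)
  if (d[3] != cfg$input_channels)
    stop(sprintf("dimension error: expected %d channels, got %d",
                 cfg$input_channels, d[3]), call. = FALSE)
  x
}

unet_fwd <- function(model, x, training = FALSE, keep_cache = training) {
  x <- check_input(model, x)
  depth <- model$config$depth
  st <- model$state
  caches <- list()
  skips <- list()
  h <- x
  for (b in seq_len(depth + 1)) {
    r <- block_fwd(model, st, h, sprintf("enc%d", b), training, keep_cache)
    h <- r$y; st <- r$st
    if (keep_cache) caches[[sprintf("enc%d", b)]] <- r$cache
    if (b <= depth) {
      skips[[b]] <- h
      r <- cbr_fwd(model, st, h, sprintf("down%d", b), sprintf("down%d.bn", b),
                   2L, 1L, training, keep_cache)
      h <- r$y; st <- r$st
      if (keep_cache) caches[[sprintf("down%d", b)]] <- r$cache
    }
  }
  for (d in rev(seq_len(depth))) {
    r <- tcbr_fwd(model, st, h, d, training, keep_cache)
    st <- r$st
    if (keep_cache) caches[[sprintf("up%d", d)]] <- r$cache
    h <- cat_channels(r$y, skips[[d]])
    if (!keep_cache) skips[d] <- list(NULL)
    r <- block_fwd(model, st, h, sprintf("dec%d", d), training, keep_cache)
    h <- r$y; st <- r$st
    if (keep_cache) caches[[sprintf("dec%d", d)]] <- r$cache
  }
  cv <- cpp_conv_fwd(h, model$params[["head.w"]], model$params[["head.b"]],
                     1L, 0L, FALSE)
  if (keep_cache) caches$head_x <- h
  list(logits = cv$y, st = st, caches = caches)
}

unet_bwd <- function(model, dlogits, fw) {
  depth <- model$config$depth
  ch <- unet_channels(model$config)
  grads <- new.env(parent = emptyenv())
  cb <- cpp_conv_bwd(fw$caches$head_x, model$params[["head.w"]], dlogits, 1L, 0L,
                     NULL, TRUE)
  acc(grads, "head.w", cb$dw)
  acc(grads, "head.b", cb$db)
  dh <- cb$dx
  dskips <- vector("list", depth)
  for (d in seq_len(depth)) {
    dcat <- block_bwd(model, dh, fw$caches[[sprintf("dec%d", d)]], grads)
    dup <- dcat[, , seq_len(ch[d]), , drop = FALSE]
    dskips[[d]] <- dcat[, , ch[d] + seq_len(ch[d]), , drop = FALSE]
    dh <- tcbr_bwd(model, dup, fw$caches[[sprintf("up%d", d)]], grads)
  }
  for (b in rev(seq_len(depth + 1))) {
    dh <- block_bwd(model, dh, fw$caches[[sprintf("enc%d", b)]], grads,
                    want_dx = (b > 1))
    if (b > 1) {
      dh <- cbr_bwd(model, dh, fw$caches[[sprintf("down%d", b - 1)]], grads)
      dh <- dh + dskips[[b - 1]]
    }
  }
  as.list(grads)
}

#' Forward pass: per-pixel class probabilities
#'
#' @param model a built [build_unet()] model.
#' @param x input array \code{(H, W, C)} or \code{(H, W, C, N)} matching the
#'   model's configured size and channels.
#' @param training if \code{TRUE}, batch-norm uses batch statistics (the
#'   training loop uses this internally); inference uses running statistics
#'   and is deterministic.
#' @return Probability array \code{(H, W, num_classes, N)}; along the class
#'   axis every pixel sums to 1.
#' @export
unet_forward <- function(model, x, training = FALSE) {
  fw <- unet_fwd(model, x, training = training, keep_cache = FALSE)
  softmax_probs(fw$logits)
}

#' Decode a probability map into a label mask
#'
#' Per-pixel argmax over classes; ties break toward the lowest class index
#' (a uniform map decodes to all background).
#'
#' @param probs array \code{(H, W, K)} of per-pixel class probabilities.
#' @return A [new_label_mask()].
#' @export
decode_probs <- function(probs) {
  d <- dim(probs)
  if (length(d) == 4 && d[4] == 1) { dim(probs) <- d[1:3]; d <- d[1:3] }
  stopifnot(length(d) == 3)
  best <- matrix(0L, d[1], d[2])
  bestp <- probs[, , 1]
  for (k in seq_len(d[3])[-1]) {
    pk <- probs[, , k]
    sel <- pk > bestp          # strict: ties keep the lower class
    best[sel] <- k - 1L
    bestp[sel] <- pk[sel]
  }
  new_label_mask(best)
}

#' Predict the segmentation mask of one frame
#'
#' Appends coordinate channels if and only if the model was configured for 3
#' input channels; a mismatching augmentation configuration is an error.
#'
#' @param model a [build_unet()] model.
#' @param frame a [new_frame()] with the model's input size.
#' @param augment_config optional [augment_config()]; only its coordinate
#'   channel setting is consulted (geometric augmentation never applies at
#'   inference).
#' @return A [new_label_mask()].
#' @export
predict_mask <- function(model, frame, augment_config = NULL) {
  stopifnot(inherits(frame, "ivus_frame"))
  want_mg <- model$config$input_channels == 3L
  if (!is.null(augment_config)) {
    have_mg <- strategy_channels(augment_config) == 3L
    if (have_mg != want_mg)
      stop(sprintf(
        "channel mismatch: model expects %d channels but strategy provides %d",
        model$config$input_channels, strategy_channels(augment_config)),
        call. = FALSE)
  }
  s <- as_sample(frame, new_label_mask(matrix(0L, nrow(frame$pixels),
                                              ncol(frame$pixels))))
  if (want_mg) s <- append_meshgrid(s)
  probs <- unet_forward(model, s$image)
  decode_probs(probs)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is the model serialized with \code{saveRDS}, accompanied by
#' a JSON sidecar (\code{<path>.json}) holding the full configuration so
#' checkpoints are self-describing.
#'
#' @param model a [build_unet()] model.
#' @param path checkpoint file path (.rds).
#' @return The path (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "ivus_unet"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ivus_unet"))
    stop("file is not an ivusseg checkpoint", call. = FALSE)
  model
}
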