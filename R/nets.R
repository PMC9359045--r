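# The architecture family: hierarchically dense U-nets (HD), their
# attention-gated version (HDA), and a standard channel-doubling attention
# U-net baseline. Feature maps are (nx, ny, nz, channels) arrays; the encoder
# applies two dense convolutions then a dense downsampling per resolution
# level (four dense convolutions at the bottom), and the decoder mirrors it
# with trilinear upsampling, a 3x3x3 convolution to the gating width, an
# attention gate (HDA) or plain skip concatenation (HD), and two dense
# convolutions. All feature growth is linear in the growth rate.

#' Architecture configuration
#'
#' @param variant `"hda"` (dense + attention gates), `"hd"` (dense, plain
#'   skips) or `"attention"` (standard channel-doubling U-net with attention
#'   gates).
#' @param levels number of resolution levels (`levels - 1` downsamplings);
#'   default 5, which takes 128 x 128 x 96 inputs to 8 x 8 x 6 at the bottom.
#' @param growth_rate feature channels added by each dense operation.
#' @param ag_features width of the post-upsample convolution whose output
#'   both drives the decoder and (in gated variants) enters the attention
#'   gate as the gating signal; also the gate's intermediate projection width.
#' @param in_channels input channels (1 CT + one per structure).
#' @param out_channels output channels; 1 for dose prediction.
#' @param base_features first-level width of the `"attention"` variant
#'   (doubled at each level).
#' @param use_batch_norm add batch normalization after each convolution;
#'   defaults to `TRUE` only for the HDA variant.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(variant = c("hda", "hd", "attention"), levels = 5L,
                        growth_rate = 16L, ag_features = 64L, in_channels,
                        out_channels = 1L, base_features = 32L,
                        use_batch_norm = NULL) {
  variant <- match.arg(variant)
  if (levels < 2) stop("levels must be >= 2")
  if (growth_rate < 1) stop("growth_rate must be >= 1")
  if (is.null(use_batch_norm)) use_batch_norm <- variant == "hda"
  structure(list(variant = variant, levels = as.integer(levels),
                 growth_rate = as.integer(growth_rate),
                 ag_features = as.integer(ag_features),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_features = as.integer(base_features),
                 use_batch_norm = isTRUE(use_batch_norm)),
            class = "arch_config")
}

# --- parameter construction -------------------------------------------

new_model_env <- function(cfg) {
  m <- new.env(parent = emptyenv())
  m$cfg <- cfg
  m$params <- list()
  m$bn <- list()
  m
}

add_conv3 <- function(m, name, cin, cout) {
  sdv <- sqrt(2 / (27 * cin))
  m$params[[paste0(name, ".W")]] <- ag_param(matrix(rnorm(27 * cin * cout, 0, sdv),
                                                   27 * cin, cout))
  m$params[[paste0(name, ".b")]] <- ag_param(numeric(cout))
  if (m$cfg$use_batch_norm) add_bn(m, paste0(name, "_bn"), cout)
  invisible(cout)
}

add_conv1 <- function(m, name, cin, cout) {
  sdv <- sqrt(2 / cin)
  m$params[[paste0(name, ".W")]] <- ag_param(matrix(rnorm(cin * cout, 0, sdv), cin, cout))
  m$params[[paste0(name, ".b")]] <- ag_param(numeric(cout))
  invisible(cout)
}

add_bn <- function(m, name, C) {
  m$params[[paste0(name, ".g")]] <- ag_param(rep(1, C))
  m$params[[paste0(name, ".be")]] <- ag_param(numeric(C))
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(C); st$var <- rep(1, C)
  m$bn[[name]] <- st
}

add_gate <- function(m, name, c_skip, c_gate, ag) {
  add_conv1(m, paste0(name, "_s"), c_skip, ag)
  add_conv1(m, paste0(name, "_g"), c_gate, ag)
  add_conv1(m, paste0(name, "_o"), ag, 1L)
}

#' Build a dose-prediction network
#'
#' Instantiates the configured variant with He-initialized weights. The
#' returned model maps a `(nx, ny, nz, in_channels)` array to a
#' `(nx, ny, nz, 1)` dose array of the same spatial shape.
#'
#' @param cfg an [arch_config()].
#' @param seed optional integer; weight initialization is deterministic given
#'   it (global RNG state is left untouched).
#' @return An object of class `dose_net`.
#' @export
build_model <- function(cfg, seed = NULL) {
  build <- function() {
    m <- new_model_env(cfg)
    if (cfg$variant %in% c("hd", "hda")) build_dense(m) else build_attention_unet(m)
    class(m) <- "dose_net"
    m
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

build_dense <- function(m) {
  cfg <- m$cfg
  g <- cfg$growth_rate
  c <- cfg$in_channels
  skips <- integer(0)
  for (l in seq_len(cfg$levels - 1)) {
    add_conv3(m, sprintf("enc%d_dc1", l), c, g); c <- c + g
    add_conv3(m, sprintf("enc%d_dc2", l), c, g); c <- c + g
    skips[l] <- c
    add_conv3(m, sprintf("enc%d_down", l), c, g); c <- c + g
  }
  for (i in 1:4) { add_conv3(m, sprintf("bot%d", i), c, g); c <- c + g }
  for (l in rev(seq_len(cfg$levels - 1))) {
    add_conv3(m, sprintf("dec%d_up", l), c, cfg$ag_features)
    if (cfg$variant == "hda")
      add_gate(m, sprintf("dec%d_gate", l), skips[l], cfg$ag_features, cfg$ag_features)
    c <- cfg$ag_features + skips[l]
    add_conv3(m, sprintf("dec%d_dc1", l), c, g); c <- c + g
    add_conv3(m, sprintf("dec%d_dc2", l), c, g); c <- c + g
  }
  add_conv1(m, "head", c, cfg$out_channels)
}

build_attention_unet <- function(m) {
  cfg <- m$cfg
  w <- cfg$base_features * 2^(seq_len(cfg$levels) - 1)
  c <- cfg$in_channels
  for (l in seq_len(cfg$levels - 1)) {
    add_conv3(m, sprintf("enc%d_c1", l), c, w[l])
    add_conv3(m, sprintf("enc%d_c2", l), w[l], w[l])
    c <- w[l]
  }
  add_conv3(m, "bot1", c, w[cfg$levels])
  add_conv3(m, "bot2", w[cfg$levels], w[cfg$levels])
  c <- w[cfg$levels]
  for (l in rev(seq_len(cfg$levels - 1))) {
    add_conv3(m, sprintf("dec%d_up", l), c, w[l])
    add_gate(m, sprintf("dec%d_gate", l), w[l], w[l], cfg$ag_features)
    add_conv3(m, sprintf("dec%d_c1", l), 2 * w[l], w[l])
    add_conv3(m, sprintf("dec%d_c2", l), w[l], w[l])
    c <- w[l]
  }
  add_conv1(m, "head", c, cfg$out_channels)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights and biases, batch
#' normalization gains and offsets; running moments are not trainable).
#'
#' @param model a [build_model()] result.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

#' @export
print.dose_net <- function(x, ...) {
  cat(sprintf("<dose_net> %s variant, %d levels, growth %d, %d -> %d channels, %s parameters\n",
              x$cfg$variant, x$cfg$levels, x$cfg$growth_rate, x$cfg$in_channels,
              x$cfg$out_channels, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# --- forward passes ----------------------------------------------------

check_input_shape <- function(cfg, sp) {
  need <- 2^(cfg$levels - 1)
  if (any(sp < need)) {
    pad <- pmax(need - sp, 0)
    stop(sprintf(
      "invalid shape: spatial input %s too small for %d levels; pad axes by at least (%s)",
      paste(sp, collapse = "x"), cfg$levels, paste(pad, collapse = ", ")))
  }
}

conv3_block <- function(m, h, name, training, stride = 1L, relu = TRUE) {
  P <- m$params
  y <- op_conv3(h, P[[paste0(name, ".W")]], P[[paste0(name, ".b")]], stride)
  bn <- paste0(name, "_bn")
  if (!is.null(m$bn[[bn]]))
    y <- op_batchnorm(y, P[[paste0(bn, ".g")]], P[[paste0(bn, ".be")]],
                      m$bn[[bn]], training)
  if (relu) y <- op_relu(y) else y
}

# dense convolution: conv(+bn)+relu producing growth_rate channels,
# concatenated onto the input features
dense_conv_block <- function(m, h, name, training) {
  op_concat(h, conv3_block(m, h, name, training))
}

# dense downsampling: strided conv(+bn)+relu concatenated with max pooling
dense_down_block <- function(m, h, name, training) {
  op_concat(op_maxpool(h), conv3_block(m, h, name, training, stride = 2L))
}

gate_block <- function(m, skip, gat, name, training) {
  P <- m$params
  a1 <- op_conv1(skip, P[[paste0(name, "_s.W")]], P[[paste0(name, "_s.b")]])
  a2 <- op_conv1(gat, P[[paste0(name, "_g.W")]], P[[paste0(name, "_g.b")]])
  r <- op_relu(op_add(a1, a2))
  alpha <- op_sigmoid(op_conv1(r, P[[paste0(name, "_o.W")]], P[[paste0(name, "_o.b")]]))
  list(gated = op_gate_mul(skip, alpha), alpha = alpha)
}

net_forward <- function(m, x, training = FALSE) {
  cfg <- m$cfg
  if (length(dim(x)) != 4 || dim(x)[4] != cfg$in_channels)
    stop("invalid argument: input must be (nx, ny, nz, ", cfg$in_channels, ")")
  check_input_shape(cfg, dim(x)[1:3])
  h <- op_input(x)
  if (cfg$variant %in% c("hd", "hda")) {
    skips <- list()
    for (l in seq_len(cfg$levels - 1)) {
      h <- dense_conv_block(m, h, sprintf("enc%d_dc1", l), training)
      h <- dense_conv_block(m, h, sprintf("enc%d_dc2", l), training)
      skips[[l]] <- h
      h <- dense_down_block(m, h, sprintf("enc%d_down", l), training)
    }
    for (i in 1:4) h <- dense_conv_block(m, h, sprintf("bot%d", i), training)
    for (l in rev(seq_len(cfg$levels - 1))) {
      s <- skips[[l]]
      h <- op_resize(h, dim(s$value)[1:3])
      h <- conv3_block(m, h, sprintf("dec%d_up", l), training)
      if (cfg$variant == "hda")
        s <- gate_block(m, s, h, sprintf("dec%d_gate", l), training)$gated
      h <- op_concat(s, h)
      h <- dense_conv_block(m, h, sprintf("dec%d_dc1", l), training)
      h <- dense_conv_block(m, h, sprintf("dec%d_dc2", l), training)
    }
  } else {
    skips <- list()
    for (l in seq_len(cfg$levels - 1)) {
      h <- conv3_block(m, h, sprintf("enc%d_c1", l), training)
      h <- conv3_block(m, h, sprintf("enc%d_c2", l), training)
      skips[[l]] <- h
      h <- op_maxpool(h)
    }
    h <- conv3_block(m, h, "bot1", training)
    h <- conv3_block(m, h, "bot2", training)
    for (l in rev(seq_len(cfg$levels - 1))) {
      s <- skips[[l]]
      h <- op_resize(h, dim(s$value)[1:3])
      h <- conv3_block(m, h, sprintf("dec%d_up", l), training)
      s <- gate_block(m, s, h, sprintf("dec%d_gate", l), training)$gated
      h <- op_concat(s, h)
      h <- conv3_block(m, h, sprintf("dec%d_c1", l), training)
      h <- conv3_block(m, h, sprintf("dec%d_c2", l), training)
    }
  }
  op_conv1(h, m$params[["head.W"]], m$params[["head.b"]])
}

# Evaluation-mode forward pass on a plain array; returns the 3D output volume.
net_predict <- function(m, x) {
  stopifnot(is.null(.ag$tape))
  out <- net_forward(m, x, training = FALSE)
  v <- out$value
  dim(v) <- dim(v)[1:3]
  v
}

# --- standalone building blocks (for inspection and testing) -----------

#' Dense convolution applied to a plain feature map
#'
#' Functional form of the dense convolution: a 3x3x3 convolution producing
#' `growth_rate` channels (optionally batch-normalized), ReLU, concatenated
#' onto the input. Weights are freshly He-initialized from `seed`, so this is
#' a building-block probe rather than part of a trained model.
#'
#' @param x 4D array `(nx, ny, nz, channels)`.
#' @param growth_rate channels added.
#' @param batch_norm add a batch normalization step after the convolution.
#' @param seed integer seed for the probe weights.
#' @return 4D array with `channels + growth_rate` channels.
#' @export
dense_conv <- function(x, growth_rate = 16L, batch_norm = FALSE, seed = 1L) {
  cfg <- arch_config("hd", levels = 2, growth_rate = growth_rate,
                     in_channels = dim(x)[4], use_batch_norm = batch_norm)
  m <- with_seed(seed, { m <- new_model_env(cfg); add_conv3(m, "dc", dim(x)[4], growth_rate); m })
  dense_conv_block(m, op_input(x), "dc", training = TRUE)$value
}

#' Dense downsampling applied to a plain feature map
#'
#' Functional form of dense downsampling: a strided 3x3x3 convolution (ReLU)
#' concatenated with 2x max pooling of the input; every spatial axis shrinks
#' to its ceiling half and `growth_rate` channels are added.
#'
#' @inheritParams dense_conv
#' @return 4D array with halved (ceiling) spatial dims and
#'   `channels + growth_rate` channels.
#' @export
dense_downsample <- function(x, growth_rate = 16L, seed = 1L) {
  cfg <- arch_config("hd", levels = 2, growth_rate = growth_rate,
                     in_channels = dim(x)[4], use_batch_norm = FALSE)
  m <- with_seed(seed, { m <- new_model_env(cfg); add_conv3(m, "dn", dim(x)[4], growth_rate); m })
  dense_down_block(m, op_input(x), "dn", training = TRUE)$value
}

#' Attention gate applied to plain feature maps
#'
#' Functional form of the soft attention gate: skip and gating features are
#' projected (1x1x1) to `ag_features` channels, summed, passed through ReLU,
#' projected to one channel and squashed by a sigmoid into per-voxel
#' coefficients in `[0, 1]` that reweight the skip features. The gating map is
#' resampled to the skip grid if needed.
#'
#' @param skip 4D skip-feature array.
#' @param gating 4D gating-feature array (typically the decoder features
#'   after upsampling and convolution).
#' @param ag_features intermediate projection width.
#' @param seed integer seed for the probe weights.
#' @param final_bias additive bias on the final projection (useful to probe
#'   the saturation behaviour of the coefficients).
#' @return A list with `output` (gated skip) and `alpha` (coefficients).
#' @export
attention_gate <- function(skip, gating, ag_features = 64L, seed = 1L, final_bias = 0) {
  if (!identical(dim(skip)[1:3], dim(gating)[1:3]))
    gating <- cpp_resize3_fwd(gating, as.integer(dim(skip)[1:3]))
  cfg <- arch_config("hda", levels = 2, in_channels = dim(skip)[4],
                     ag_features = ag_features, use_batch_norm = FALSE)
  m <- with_seed(seed, {
    m <- new_model_env(cfg)
    add_gate(m, "g", dim(skip)[4], dim(gating)[4], ag_features)
    m
  })
  m$params[["g_o.b"]]$value <- m$params[["g_o.b"]]$value + final_bias
  r <- gate_block(m, op_input(skip), op_input(gating), "g", training = TRUE)
  list(output = r$gated$value, alpha = array(r$alpha$value, dim(skip)[1:3]))
}
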