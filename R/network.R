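# Network construction and forward passes.
#
# Three network types share one parameter dictionary layout:
#   backbone  - plain U-shape encoder-decoder (also the cascade's second net)
#   primary   - backbone + bottom SE block + chain of SE-Connection (SEC)
#               fusion modules forming the bottom-up information pyramid
# A parameter set is a named list of arrays; batch-norm running statistics
# live in a separate state list so that a checkpoint is (params, state, config).

he_sd <- function(fan_in) sqrt(2 / fan_in)

init_conv <- function(k, ci, co) {
  array(rnorm(k * k * ci * co, sd = he_sd(k * k * ci)), dim = c(k, k, ci, co))
}

init_dense <- function(out, inn) {
  matrix(rnorm(out * inn, sd = he_sd(inn)), out, inn)
}

se_hidden_width <- function(channels, reduction) max(1L, channels %/% reduction)

#' Initialise squeeze-and-excitation gate parameters
#'
#' @param channels number of feature-map channels the gate acts on
#' @param reduction reduction ratio; hidden width is
#'   `max(1, floor(channels / reduction))`
#' @return list with dense weights `w1`, `b1` (squeeze) and `w2`, `b2`
#'   (excitation)
#' @export
se_params <- function(channels, reduction) {
  h <- se_hidden_width(channels, reduction)
  list(w1 = init_dense(h, channels), b1 = numeric(h),
       w2 = init_dense(channels, h), b2 = numeric(channels))
}

#' Initialise SE-Connection fusion module parameters
#'
#' @param c1 channels of the shallower feature map (level 1)
#' @param c2 channels of the deeper feature map (level 2)
#' @param reduction SE reduction ratio
#' @return list with `conva_*` (3x3, c2 to c1), `convb_*` (3x3, 2*c1 to c1)
#'   and an `se` gate parameter list
#' @export
sec_params <- function(c1, c2, reduction) {
  list(conva_w = init_conv(3L, c2, c1), conva_b = numeric(c1),
       convb_w = init_conv(3L, 2L * c1, c1), convb_b = numeric(c1),
       se = se_params(c1, reduction))
}

# flatten a nested se/sec parameter list into the prefixed flat dictionary
flatten_params <- function(lst, prefix) {
  out <- list()
  for (nm in names(lst)) {
    v <- lst[[nm]]
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(prefix, nm, "_")))
    else out[[paste0(prefix, nm)]] <- v
  }
  out
}

init_params_backbone <- function(cfg) {
  D <- cfg$depth; s <- cfg$stage_channels
  p <- list()
  # with batch normalisation the conv bias is redundant (the normalisation
  # removes any channel offset, so its gradient is identically zero) and is
  # therefore omitted, as is conventional
  add_conv <- function(p, name, ci, co) {
    p[[paste0(name, "_w")]] <- init_conv(3L, ci, co)
    if (cfg$batchnorm) {
      p[[paste0(name, "_bn_g")]] <- rep(1, co)
      p[[paste0(name, "_bn_b")]] <- numeric(co)
    } else {
      p[[paste0(name, "_b")]] <- numeric(co)
    }
    p
  }
  prev <- cfg$in_channels
  for (l in seq_len(D)) {
    p <- add_conv(p, paste0("enc", l, "_conv1"), prev, s[l])
    p <- add_conv(p, paste0("enc", l, "_conv2"), s[l], s[l])
    prev <- s[l]
  }
  p <- add_conv(p, "bot_conv1", s[D], s[D + 1])
  p <- add_conv(p, "bot_conv2", s[D + 1], s[D + 1])
  for (l in seq(D, 1L)) {
    upc <- if (l == D) s[D + 1] else s[l + 1]
    p <- add_conv(p, paste0("dec", l, "_conv1"), upc + s[l], s[l])
    p <- add_conv(p, paste0("dec", l, "_conv2"), s[l], s[l])
  }
  p[["out_w"]] <- init_conv(1L, s[1], cfg$num_classes)
  p[["out_b"]] <- numeric(cfg$num_classes)
  p
}

init_params_primary <- function(cfg) {
  D <- cfg$depth; s <- cfg$stage_channels; r <- cfg$se_reduction
  p <- init_params_backbone(cfg)
  p <- c(p, flatten_params(se_params(s[D + 1], r), "sebot_"))
  # SEC modules pair encoder stage l (shallow, level1) with the pyramid output
  # from stage l+1 (deep, level2), for l = D down to 2; stage 1 keeps a plain
  # skip connection.
  if (D >= 2) {
    for (l in seq(D, 2L)) {
      c2 <- if (l == D) s[D + 1] else s[l + 1]
      p <- c(p, flatten_params(sec_params(s[l], c2, r), paste0("sec", l, "_")))
    }
  }
  p
}

#' Create an untrained segmentation network
#'
#' @param config a [secp_config()]
#' @param type `"backbone"` for the plain U-shape network, `"primary"` for the
#'   SE-Connection pyramid network
#' @param seed optional integer seed for weight initialisation
#' @return an object of class `secp_net` holding `params` (named list of
#'   arrays), `state` (batch-norm running statistics), `config` and `type`
#' @export
secp_net <- function(config, type = c("primary", "backbone"), seed = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(config, "secp_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- switch(type,
                   backbone = init_params_backbone(config),
                   primary = init_params_primary(config))
  structure(list(type = type, config = config, params = params,
                 state = list()),
            class = "secp_net")
}

#' Number of learnable parameters of a network
#' @param net a `secp_net` or a named parameter list
#' @return integer count of scalar parameters
#' @export
n_params <- function(net) {
  p <- if (inherits(net, "secp_net")) net$params else net
  sum(vapply(p, length, integer(1)))
}

#' @export
print.secp_net <- function(x, ...) {
  cat("secp_net (", x$type, "), ", n_params(x), " parameters\n", sep = "")
  print(x$config)
  nsec <- length(unique(sub("_.*", "", grep("^sec[0-9]+_", names(x$params),
                                            value = TRUE))))
  if (x$type == "primary")
    cat("  pyramid: 1 bottom SE block + ", nsec, " SEC modules\n", sep = "")
  invisible(x)
}

# ---- forward-pass machinery -------------------------------------------------

# parameter-binding context: wraps (tape, params, bn state, training flag);
# P() returns a tape leaf node while training, the bare array otherwise
make_ctx <- function(params, state, tape = NULL, training = FALSE,
                     prefix = "") {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- tape
  ctx$params <- params
  ctx$state <- state          # environment for BN running stats
  ctx$training <- training
  ctx$prefix <- prefix        # gradient-name prefix (joint fine-tuning)
  ctx$bound <- list()
  ctx
}

P <- function(ctx, name) {
  v <- ctx$params[[name]]
  if (is.null(v)) stop("missing parameter: ", name)
  if (is.null(ctx$tape)) return(v)
  nd <- ctx$bound[[name]]
  if (is.null(nd)) {
    nd <- tape_param(ctx$tape, v, paste0(ctx$prefix, name))
    ctx$bound[[name]] <- nd
  }
  nd
}

state_env <- function(state) {
  e <- new.env(parent = emptyenv())
  for (nm in names(state)) e[[nm]] <- state[[nm]]
  e
}

state_list <- function(e) {
  out <- list()
  for (nm in ls(e)) out[[nm]] <- e[[nm]]
  out
}

# conv 3x3 -> (batchnorm) -> relu; bias-free when batch-normalised
cbr <- function(ctx, x, name, cfg) {
  b <- if (cfg$batchnorm) numeric(dim(ctx$params[[paste0(name, "_w")]])[4])
       else P(ctx, paste0(name, "_b"))
  y <- op_conv2d(ctx$tape, x, P(ctx, paste0(name, "_w")), b, 3L)
  if (cfg$batchnorm) {
    y <- op_batchnorm(ctx$tape, y, P(ctx, paste0(name, "_bn_g")),
                      P(ctx, paste0(name, "_bn_b")),
                      ctx$state, name, ctx$training,
                      momentum = ctx$bn_momentum %||% 0.1)
  }
  op_relu(ctx$tape, y)
}

se_apply <- function(ctx, x, prefix) {
  g <- op_gap(ctx$tape, x)
  g <- op_dense(ctx$tape, g, P(ctx, paste0(prefix, "_w1")),
                P(ctx, paste0(prefix, "_b1")))
  g <- op_relu(ctx$tape, g)
  g <- op_dense(ctx$tape, g, P(ctx, paste0(prefix, "_w2")),
                P(ctx, paste0(prefix, "_b2")))
  g <- op_sigmoid(ctx$tape, g)
  op_scale_channels(ctx$tape, x, g)
}

# SEC fusion: conv3x3 (C2->C1) on the deep map, bilinear x2 upsample, concat
# with the shallow map, conv3x3 (2C1->C1), SE gate
sec_apply <- function(ctx, level1, level2, prefix) {
  d1 <- dim(.val(level1))
  y <- op_conv2d(ctx$tape, level2, P(ctx, paste0(prefix, "_conva_w")),
                 P(ctx, paste0(prefix, "_conva_b")), 3L)
  y <- op_upsample_bilinear(ctx$tape, y, d1[1], d1[2])
  y <- op_concat_channels(ctx$tape, level1, y)
  y <- op_conv2d(ctx$tape, y, P(ctx, paste0(prefix, "_convb_w")),
                 P(ctx, paste0(prefix, "_convb_b")), 3L)
  se_apply(ctx, y, paste0(prefix, "_se"))
}

check_input_size <- function(x, cfg) {
  d <- dim(x)
  div <- 2^cfg$depth
  if (d[1] %% div != 0)
    stop("image height ", d[1], " is not a multiple of ", div)
  if (d[2] %% div != 0)
    stop("image width ", d[2], " is not a multiple of ", div)
  if (d[3] != cfg$in_channels)
    stop("image has ", d[3], " channels; configuration expects ",
         cfg$in_channels)
  if (any(!is.finite(x))) stop("non-finite values in input image")
}

fwd_encoder <- function(ctx, x, cfg) {
  D <- cfg$depth
  enc <- vector("list", D)
  h <- x
  for (l in seq_len(D)) {
    h <- cbr(ctx, h, paste0("enc", l, "_conv1"), cfg)
    h <- cbr(ctx, h, paste0("enc", l, "_conv2"), cfg)
    enc[[l]] <- h
    h <- op_maxpool2(ctx$tape, h)
  }
  h <- cbr(ctx, h, "bot_conv1", cfg)
  h <- cbr(ctx, h, "bot_conv2", cfg)
  list(enc = enc, bot = h)
}

fwd_decoder <- function(ctx, bot, skips, cfg) {
  D <- cfg$depth
  h <- bot
  for (l in seq(D, 1L)) {
    d <- dim(.val(h))
    h <- op_upsample_bilinear(ctx$tape, h, 2L * d[1], 2L * d[2])
    h <- op_concat_channels(ctx$tape, h, skips[[l]])
    h <- cbr(ctx, h, paste0("dec", l, "_conv1"), cfg)
    h <- cbr(ctx, h, paste0("dec", l, "_conv2"), cfg)
  }
  op_conv2d(ctx$tape, h, P(ctx, "out_w"), P(ctx, "out_b"), 1L)
}

fwd_backbone <- function(ctx, x, cfg) {
  e <- fwd_encoder(ctx, x, cfg)
  fwd_decoder(ctx, e$bot, e$enc, cfg)
}

# the pyramid: bottleneck -> SE -> deepest "level 2"; SEC_l fuses encoder
# stage l with the pyramid output from below; each SEC output is both the
# decoder skip at stage l and the level-2 input of SEC_{l-1}; stage 1 keeps
# the plain encoder skip; the bottleneck itself feeds the first decoder
# upsampling unchanged
fwd_primary <- function(ctx, x, cfg) {
  D <- cfg$depth
  e <- fwd_encoder(ctx, x, cfg)
  skips <- e$enc
  lvl2 <- se_apply(ctx, e$bot, "sebot")
  if (D >= 2) {
    for (l in seq(D, 2L)) {
      lvl2 <- sec_apply(ctx, e$enc[[l]], lvl2, paste0("sec", l))
      skips[[l]] <- lvl2
    }
  }
  fwd_decoder(ctx, e$bot, skips, cfg)
}

# ---- exported forward functions --------------------------------------------

as_feature_map <- function(x, in_channels = 1L) {
  if (is.matrix(x)) dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("expected a (H, W, C, N) array")
  x
}

#' Squeeze-and-excitation channel attention block
#'
#' Squeezes each channel to a global-average-pooled descriptor, passes it
#' through a two-layer gate (linear, ReLU, linear, sigmoid) and rescales the
#' channels by the resulting factors in (0, 1).
#'
#' @param x feature map array `(H, W, C, N)` (a matrix or 3-D array is
#'   promoted)
#' @param weights parameters from [se_params()]; freshly initialised from the
#'   current RNG state when `NULL`
#' @param reduction reduction ratio used when `weights` is `NULL`
#' @return feature map of the same shape; gate factors are attached as
#'   attribute `"gate"` (a channels x batch matrix)
#' @export
se_block <- function(x, weights = NULL, reduction = 16L) {
  x <- as_feature_map(x)
  if (any(!is.finite(x))) stop("non-finite values in input feature map")
  C <- dim(x)[3]
  if (C < 1) stop("feature map must have at least one channel")
  if (is.null(weights)) weights <- se_params(C, reduction)
  g <- op_gap(NULL, x)
  g <- op_dense(NULL, g, weights$w1, weights$b1)
  g <- op_relu(NULL, g)
  g <- op_dense(NULL, g, weights$w2, weights$b2)
  g <- op_sigmoid(NULL, g)
  y <- op_scale_channels(NULL, x, g)
  attr(y, "gate") <- g
  y
}

#' SE-Connection skip-fusion module
#'
#' Fuses a shallow feature map (`level1`, resolution H x W) with the pyramid
#' output from the next deeper stage (`level2`, resolution H/2 x W/2):
#' 3x3 same-padding convolution mapping `level2` to `level1`'s channel width,
#' bilinear x2 upsampling, channel concatenation with `level1`, a second 3x3
#' convolution back to `level1`'s width, and a squeeze-and-excitation gate.
#'
#' @param level1 shallow feature map `(H, W, C1, N)`
#' @param level2 deeper feature map `(H/2, W/2, C2, N)`
#' @param weights parameters from [sec_params()]; freshly initialised when
#'   `NULL`
#' @param reduction SE reduction ratio used when `weights` is `NULL`
#' @return fused feature map `(H, W, C1, N)`
#' @export
sec_fuse <- function(level1, level2, weights = NULL, reduction = 16L) {
  level1 <- as_feature_map(level1)
  level2 <- as_feature_map(level2)
  d1 <- dim(level1); d2 <- dim(level2)
  if (d1[1] != 2L * d2[1] || d1[2] != 2L * d2[2])
    stop("level1 spatial size (", d1[1], "x", d1[2],
         ") must be exactly twice level2 (", d2[1], "x", d2[2], ")")
  if (is.null(weights)) weights <- sec_params(d1[3], d2[3], reduction)
  params <- flatten_params(list(sec = weights), "")
  ctx <- make_ctx(params, new.env(parent = emptyenv()))
  sec_apply(ctx, level1, level2, "sec")
}

#' Plain U-shape backbone forward pass
#'
#' Standard encoder-decoder: per stage two 3x3 convolution blocks and a 2x
#' max-pooling on the way down, bilinear x2 upsampling with skip
#' concatenation and two convolution blocks on the way up, then a final 1x1
#' convolution to class logits.
#'
#' @param image input array `(H, W, in_channels, N)`; H and W must be
#'   multiples of `2^depth`
#' @param net a `secp_net` of type `"backbone"` (or a list with `params`,
#'   `state`, `config`)
#' @return unnormalised class logits `(H, W, num_classes, N)`
#' @export
backbone_unet_forward <- function(image, net) {
  image <- as_feature_map(image)
  cfg <- net$config
  check_input_size(image, cfg)
  ctx <- make_ctx(net$params, state_env(net$state))
  fwd_backbone(ctx, image, cfg)
}

#' SE-Connection pyramid network forward pass
#'
#' Encoder as in the backbone; the bottleneck passes through an SE block and
#' then climbs the pyramid: each SEC module fuses the encoder feature of its
#' stage with the pyramid output from the stage below, and its output serves
#' both as the decoder skip input and as the deep input of the next SEC up.
#'
#' @inheritParams backbone_unet_forward
#' @param net a `secp_net` of type `"primary"`
#' @return list with `logits` and `probs` (channel-softmax probability map)
#' @export
primary_forward <- function(image, net) {
  image <- as_feature_map(image)
  cfg <- net$config
  check_input_size(image, cfg)
  ctx <- make_ctx(net$params, state_env(net$state))
  logits <- fwd_primary(ctx, image, cfg)
  list(logits = logits, probs = softmax_channels(logits))
}

#' Auto-context cascade forward pass
#'
#' Runs the primary pyramid network, concatenates the input image with the
#' primary probability map channel-wise, and feeds the result to the
#' secondary plain U-shape network for refinement.
#'
#' @param image input array `(H, W, in_channels, N)`
#' @param primary a `secp_net` of type `"primary"`
#' @param secondary a `secp_net` of type `"backbone"` whose `in_channels`
#'   equals `image channels + num_classes`
#' @return list with `primary_probs`, `final_logits`, `final_probs`
#' @export
cascade_forward <- function(image, primary, secondary) {
  image <- as_feature_map(image)
  pri <- primary_forward(image, primary)
  expect_in <- dim(image)[3] + primary$config$num_classes
  if (secondary$config$in_channels != expect_in)
    stop("secondary network expects ", secondary$config$in_channels,
         " input channels but image + probability map has ", expect_in)
  xc <- op_concat_channels(NULL, image, pri$probs)
  logits <- backbone_unet_forward(xc, secondary)
  list(primary_probs = pri$probs, final_logits = logits,
       final_probs = softmax_channels(logits))
}

#' Hard label map from a probability map
#'
#' Per-pixel argmax over channels; ties resolve to the lowest class index.
#'
#' @param probs probability map `(H, W, C, N)` (3-D arrays are promoted)
#' @return integer label array `(H, W, N)` with values `0..C-1`
#' @export
predict_labels <- function(probs) {
  probs <- as_feature_map(probs)
  d <- dim(probs)
  m <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  array(as.integer(lab), dim = c(d[1], d[2], d[4]))
}
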