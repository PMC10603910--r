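# Loss, learning-rate schedule, SGD optimizer and the staged training
# orchestration for the cascaded pyramid network.

#' Training plan
#'
#' Hyperparameters of the staged SGD recipe: initial learning rate 0.01 with
#' polynomial decay of power 0.9, momentum 0.9, weight decay 1e-4, batch size
#' up to 16, 100 epochs per stage. Stages run in the fixed order
#' backbone -> secp -> secondary -> finetune; any suffix/subset may be
#' skipped but the order never changes.
#'
#' @param epochs epoch budget per stage
#' @param lr0 initial learning rate
#' @param momentum SGD momentum in `[0, 1)`
#' @param weight_decay L2 weight decay
#' @param batch_size mini-batch size (>= 1)
#' @param stages character vector, ordered subset of
#'   `c("backbone", "secp", "secondary", "finetune")`
#' @param finetune_lr_factor multiplier applied to `lr0` in the fine-tuning
#'   stage
#' @param plateau_patience epochs of loss plateau before early stop (0
#'   disables)
#' @param plateau_tol relative loss-change threshold defining a plateau
#' @param stage_epochs optional named list overriding `epochs` for
#'   individual stages, e.g. `list(secondary = 140)`
#' @param stage_batch optional named list overriding `batch_size` per stage
#'   (smaller stage-3 batches give the freshly initialised secondary network
#'   more update steps per epoch, which helps rare small-organ classes)
#' @param seed integer seed controlling initialisation and batch shuffling
#' @return object of class `secp_train_plan`
#' @export
train_plan <- function(epochs = 100L, lr0 = 0.01, momentum = 0.9,
                       weight_decay = 1e-4, batch_size = 16L,
                       stages = c("backbone", "secp", "secondary", "finetune"),
                       finetune_lr_factor = 0.1,
                       plateau_patience = 10L, plateau_tol = 1e-4,
                       stage_epochs = NULL, stage_batch = NULL,
                       seed = 1L) {
  canonical <- c("backbone", "secp", "secondary", "finetune")
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr0 <= 0) stop("lr0 must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  if (weight_decay < 0) stop("weight_decay must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (!all(stages %in% canonical)) stop("unknown stage name")
  if (is.unsorted(match(stages, canonical), strictly = TRUE))
    stop("stages must follow the order ", paste(canonical, collapse = " -> "))
  structure(list(epochs = as.integer(epochs), lr0 = lr0, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), stages = stages,
                 finetune_lr_factor = finetune_lr_factor,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_tol = plateau_tol,
                 stage_epochs = stage_epochs, stage_batch = stage_batch,
                 seed = as.integer(seed)),
            class = "secp_train_plan")
}

#' Multi-class cross-entropy of a probability map
#'
#' Mean over pixels of `-log(q_true + eps)` in the given log base, where
#' `q_true` is the predicted probability of the true class. The default base
#' is 2 (loss in bits); switching to the natural log rescales the loss (and
#' gradients) by exactly `ln 2`.
#'
#' @param probs probability map `(H, W, C, N)` (3-D arrays are promoted)
#' @param target integer label array `(H, W, N)` with values in `[0, C)`
#' @param eps clamp added to the true-class probability before the logarithm
#' @param base logarithm base
#' @return scalar loss, >= 0
#' @export
cross_entropy_loss <- function(probs, target, eps = 1e-12, base = 2) {
  probs <- as_feature_map(probs)
  d <- dim(probs)
  C <- d[3]
  tv <- as.integer(target)
  if (length(tv) != d[1] * d[2] * d[4])
    stop("target has ", length(tv), " pixels; probability map has ",
         d[1] * d[2] * d[4])
  if (any(tv < 0L | tv >= C)) {
    bad <- tv[tv < 0L | tv >= C][1]
    stop("target label ", bad, " outside [0, ", C, ")")
  }
  hw <- d[1] * d[2]
  idx <- rep(seq_len(hw), times = d[4]) + hw * tv +
    hw * C * rep(0:(d[4] - 1), each = hw)
  -mean(log(probs[idx] + eps)) / log(base)
}

#' Polynomial learning-rate decay
#'
#' `lr = (1 - n / N)^0.9 * lr0`, applied before epoch `n`'s updates, so that
#' the rate starts at `lr0` (n = 0) and decays to 0 at n = N.
#'
#' @param n epoch index, `0 <= n <= N`
#' @param N total epoch budget
#' @param lr0 initial learning rate
#' @param power decay exponent
#' @return learning rate for epoch `n`
#' @export
poly_lr <- function(n, N, lr0 = 0.01, power = 0.9) {
  if (any(n < 0) || any(n > N)) stop("epoch index must satisfy 0 <= n <= N")
  (1 - n / N)^power * lr0
}

#' Create an SGD optimizer state
#'
#' Stochastic gradient descent with momentum and decoupled-from-schedule L2
#' weight decay; the learning rate follows [poly_lr()] at the given epoch.
#'
#' @param params named list of parameter arrays (must be nonempty)
#' @param plan a [train_plan()]
#' @param epoch epoch index used to evaluate the schedule
#' @param lr0 optional override of the plan's initial learning rate
#' @return object of class `secp_sgd` with fields `lr`, `momentum`,
#'   `weight_decay`, `velocity`
#' @export
make_optimizer <- function(params, plan, epoch = 0L, lr0 = plan$lr0) {
  if (length(params) == 0) stop("empty parameter set")
  structure(list(lr = poly_lr(epoch, plan$epochs, lr0),
                 momentum = plan$momentum,
                 weight_decay = plan$weight_decay,
                 velocity = list()),
            class = "secp_sgd")
}

# one SGD step: v <- mu v + (g + wd p); p <- p - lr v
optimizer_step <- function(opt, params, grads) {
  for (nm in names(grads)) {
    p <- params[[nm]]
    if (is.null(p)) next
    g <- grads[[nm]] + opt$weight_decay * p
    v <- opt$velocity[[nm]]
    v <- if (is.null(v)) g else opt$momentum * v + g
    opt$velocity[[nm]] <- v
    params[[nm]] <- p - opt$lr * v
  }
  list(opt = opt, params = params)
}

# ---- per-batch loss + gradient closures ------------------------------------

loss_grads_single <- function(type, params, stenv, cfg, x, y) {
  tape <- tape_new()
  ctx <- make_ctx(params, stenv, tape, training = TRUE)
  logits <- switch(type,
                   backbone = fwd_backbone(ctx, x, cfg),
                   primary = fwd_primary(ctx, x, cfg))
  loss <- op_softmax_xent(tape, logits, y, base = cfg$loss_base)
  grads <- tape_backward(tape, loss)
  list(loss = loss$value, grads = grads)
}

# stage 3: primary frozen (inference mode, no gradients); secondary trained
loss_grads_secondary <- function(pri, sec, x, y) {
  ctxp <- make_ctx(pri$params, pri$stenv, NULL, training = FALSE)
  probs <- softmax_channels(fwd_primary(ctxp, x, pri$cfg))
  xc <- op_concat_channels(NULL, x, probs)
  loss_grads_single("backbone", sec$params, sec$stenv, sec$cfg, xc, y)
}

# stage 4: end-to-end; gradients flow into the primary through the
# probability-map channels of the auto-context input
loss_grads_finetune <- function(pri, sec, x, y) {
  tape <- tape_new()
  ctxp <- make_ctx(pri$params, pri$stenv, tape, TRUE, prefix = "P|")
  ctxs <- make_ctx(sec$params, sec$stenv, tape, TRUE, prefix = "S|")
  logits_p <- fwd_primary(ctxp, x, pri$cfg)
  probs_p <- op_softmax(tape, logits_p)
  xc <- op_concat_channels(tape, x, probs_p)
  logits_s <- fwd_backbone(ctxs, xc, sec$cfg)
  loss <- op_softmax_xent(tape, logits_s, y, base = sec$cfg$loss_base)
  grads <- tape_backward(tape, loss)
  pg <- grads[startsWith(names(grads), "P|")]
  sg <- grads[startsWith(names(grads), "S|")]
  names(pg) <- substring(names(pg), 3)
  names(sg) <- substring(names(sg), 3)
  list(loss = loss$value, grads_primary = pg, grads_secondary = sg)
}

# Recompute batch-norm running statistics over the full training set with the
# final weights (cumulative average over batches). Mini-batch EMA statistics
# can diverge from full-data statistics on channels with very sparse signal
# (e.g. a small organ's probability channel), which would make inference-mode
# behaviour drift from training; this pass removes that mismatch.
recalibrate_bn <- function(type, params, stenv, cfg, images, batch_size = 16L) {
  if (!cfg$batchnorm) return(invisible(NULL))
  n <- dim(images)[4]
  batches <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (i in seq_along(batches)) {
    ctx <- make_ctx(params, stenv, NULL, training = TRUE)
    ctx$bn_momentum <- 1 / i       # running cumulative mean of batch stats
    x <- images[, , , batches[[i]], drop = FALSE]
    switch(type,
           backbone = fwd_backbone(ctx, x, cfg),
           primary = fwd_primary(ctx, x, cfg))
  }
  invisible(NULL)
}

# auto-context inputs (image ++ primary probability map) for a whole set
cascade_inputs <- function(pparams, pstenv, cfg, images, batch_size = 16L) {
  n <- dim(images)[4]
  d <- dim(images)
  out <- array(0, c(d[1], d[2], d[3] + cfg$num_classes, n))
  for (idx in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    ctx <- make_ctx(pparams, pstenv, NULL, training = FALSE)
    xb <- images[, , , idx, drop = FALSE]
    probs <- softmax_channels(fwd_primary(ctx, xb, cfg))
    out[, , seq_len(d[3]), idx] <- xb
    out[, , d[3] + seq_len(cfg$num_classes), idx] <- probs
  }
  out
}

# ---- epoch loop -------------------------------------------------------------

make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

slice_batch <- function(images, masks, idx) {
  list(x = images[, , , idx, drop = FALSE],
       y = masks[, , idx, drop = FALSE])
}

plateaued <- function(losses, patience, tol) {
  if (patience < 1 || length(losses) <= patience) return(FALSE)
  a <- losses[length(losses) - patience]
  b <- losses[length(losses)]
  abs(a - b) / max(abs(a), 1e-12) < tol
}

# generic stage driver: step_fn(x, y) must return list(loss, grads) or
# list(loss, grads_primary, grads_secondary); get/set close over the nets
run_stage <- function(stage, step_fn, get_params, apply_grads,
                      images, masks, plan, lr0, log) {
  n <- dim(images)[4]
  n_epochs <- plan$stage_epochs[[stage]] %||% plan$epochs
  bsz <- plan$stage_batch[[stage]] %||% plan$batch_size
  losses <- numeric(0)
  for (ep in seq_len(n_epochs)) {
    lr <- poly_lr(ep - 1L, n_epochs, lr0)
    batches <- make_batches(n, bsz)
    bl <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- slice_batch(images, masks, batches[[bi]])
      out <- step_fn(b$x, b$y)
      apply_grads(out, lr)
      bl[bi] <- out$loss
    }
    losses <- c(losses, mean(bl))
    log$rows[[length(log$rows) + 1L]] <-
      data.frame(stage = stage, epoch = ep, lr = lr, loss = mean(bl))
    if (plateaued(losses, plan$plateau_patience, plan$plateau_tol)) break
  }
  losses
}

#' Staged training of the cascaded pyramid network
#'
#' Four-stage recipe: (1) train the plain U-shape backbone; (2) build the
#' pyramid network, initialise its shared encoder/decoder weights from stage
#' 1, and train it; (3) freeze the primary network and train the secondary
#' network on auto-context inputs (image plus primary probability map);
#' (4) unfreeze everything and fine-tune end to end at `lr0 *
#' finetune_lr_factor`. Stages listed in `plan$stages` run in order; each
#' stage applies SGD with momentum, weight decay and per-epoch polynomial
#' learning-rate decay, and stops early on a loss plateau.
#'
#' @param images training images `(H, W, in_channels, N)`
#' @param masks integer label masks `(H, W, N)`, values `0..num_classes-1`
#' @param config a [secp_config()]
#' @param plan a [train_plan()]
#' @param init optional list of pre-trained `secp_net` objects (`backbone`,
#'   `primary`, `secondary`) for runs that skip earlier stages
#' @param checkpoint_dir optional directory; when given, each stage writes a
#'   checkpoint via [save_checkpoint()]
#' @return object of class `secp_fit`; see [fit_secpnet()]
#' @export
run_staged_training <- function(images, masks, config, plan,
                                init = list(), checkpoint_dir = NULL) {
  images <- as_feature_map(images)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  set.seed(plan$seed)
  log <- new.env(parent = emptyenv())
  log$rows <- list()

  backbone <- init$backbone
  primary <- init$primary
  secondary <- init$secondary

  for (stage in plan$stages) {
    if (stage == "backbone") {
      backbone <- secp_net(config, "backbone")
      stenv <- state_env(backbone$state)
      opt <- make_optimizer(backbone$params, plan)
      pe <- new.env(parent = emptyenv()); pe$params <- backbone$params
      run_stage("backbone",
                function(x, y) loss_grads_single("backbone", pe$params,
                                                 stenv, config, x, y),
                NULL,
                function(out, lr) {
                  opt$lr <<- lr
                  st <- optimizer_step(opt, pe$params, out$grads)
                  opt <<- st$opt; pe$params <- st$params
                },
                images, masks, plan, plan$lr0, log)
      backbone$params <- pe$params
      recalibrate_bn("backbone", backbone$params, stenv, config, images)
      backbone$state <- state_list(stenv)
      if (!is.null(checkpoint_dir))
        save_checkpoint(backbone, file.path(checkpoint_dir, "backbone"))
    } else if (stage == "secp") {
      if (is.null(backbone))
        stop("stage 'secp' requires a trained backbone ",
             "(run stage 'backbone' first or pass init$backbone)")
      primary <- secp_net(config, "primary")
      shared <- intersect(names(primary$params), names(backbone$params))
      primary$params[shared] <- backbone$params[shared]
      primary$state <- backbone$state
      stenv <- state_env(primary$state)
      opt <- make_optimizer(primary$params, plan)
      pe <- new.env(parent = emptyenv()); pe$params <- primary$params
      run_stage("secp",
                function(x, y) loss_grads_single("primary", pe$params,
                                                 stenv, config, x, y),
                NULL,
                function(out, lr) {
                  opt$lr <<- lr
                  st <- optimizer_step(opt, pe$params, out$grads)
                  opt <<- st$opt; pe$params <- st$params
                },
                images, masks, plan, plan$lr0, log)
      primary$params <- pe$params
      recalibrate_bn("primary", primary$params, stenv, config, images)
      primary$state <- state_list(stenv)
      if (!is.null(checkpoint_dir))
        save_checkpoint(primary, file.path(checkpoint_dir, "primary"))
    } else if (stage == "secondary") {
      if (is.null(primary))
        stop("stage 'secondary' requires a trained primary network ",
             "(run stage 'secp' first or pass init$primary)")
      cfg_s <- secp_config(config$num_classes,
                           in_channels = config$in_channels +
                             config$num_classes,
                           depth = config$depth,
                           stage_channels = config$stage_channels,
                           se_reduction = config$se_reduction,
                           batchnorm = config$batchnorm,
                           loss_base = config$loss_base)
      secondary <- secp_net(cfg_s, "backbone")
      # warm-start from the stage-1 backbone where available: every layer has
      # matching shapes except the first convolution, whose image channel is
      # copied while the probability-map channels stay freshly initialised.
      # A cold-started secondary is slow and erratic on rare small-organ
      # classes; starting from the converged backbone makes stage 3 a
      # refinement that learns to exploit the auto-context channels.
      if (!is.null(backbone)) {
        for (nm in names(secondary$params)) {
          bw <- backbone$params[[nm]]
          if (is.null(bw)) next
          if (identical(dim(bw), dim(secondary$params[[nm]])) &&
              length(bw) == length(secondary$params[[nm]])) {
            secondary$params[[nm]] <- bw
          } else if (nm == "enc1_conv1_w") {
            secondary$params[[nm]][, , seq_len(dim(bw)[3]), ] <- bw
          }
        }
        secondary$state <- backbone$state
      }
      pri <- list(params = primary$params, stenv = state_env(primary$state),
                  cfg = config)
      stenv_s <- state_env(secondary$state)
      opt <- make_optimizer(secondary$params, plan)
      pe <- new.env(parent = emptyenv()); pe$params <- secondary$params
      run_stage("secondary",
                function(x, y) loss_grads_secondary(
                  pri, list(params = pe$params, stenv = stenv_s, cfg = cfg_s),
                  x, y),
                NULL,
                function(out, lr) {
                  opt$lr <<- lr
                  st <- optimizer_step(opt, pe$params, out$grads)
                  opt <<- st$opt; pe$params <- st$params
                },
                images, masks, plan, plan$lr0, log)
      secondary$params <- pe$params
      xc <- cascade_inputs(primary$params, pri$stenv, config, images)
      recalibrate_bn("backbone", secondary$params, stenv_s, cfg_s, xc)
      secondary$state <- state_list(stenv_s)
      if (!is.null(checkpoint_dir))
        save_checkpoint(secondary, file.path(checkpoint_dir, "secondary"))
    } else if (stage == "finetune") {
      if (is.null(primary) || is.null(secondary))
        stop("stage 'finetune' requires trained primary and secondary ",
             "networks")
      stenv_p <- state_env(primary$state)
      stenv_s <- state_env(secondary$state)
      optp <- make_optimizer(primary$params, plan,
                             lr0 = plan$lr0 * plan$finetune_lr_factor)
      opts <- make_optimizer(secondary$params, plan,
                             lr0 = plan$lr0 * plan$finetune_lr_factor)
      pe <- new.env(parent = emptyenv())
      pe$pp <- primary$params; pe$sp <- secondary$params
      run_stage("finetune",
                function(x, y) loss_grads_finetune(
                  list(params = pe$pp, stenv = stenv_p, cfg = config),
                  list(params = pe$sp, stenv = stenv_s,
                       cfg = secondary$config),
                  x, y),
                NULL,
                function(out, lr) {
                  optp$lr <<- lr; opts$lr <<- lr
                  st <- optimizer_step(optp, pe$pp, out$grads_primary)
                  optp <<- st$opt; pe$pp <- st$params
                  st <- optimizer_step(opts, pe$sp, out$grads_secondary)
                  opts <<- st$opt; pe$sp <- st$params
                },
                images, masks, plan,
                plan$lr0 * plan$finetune_lr_factor, log)
      primary$params <- pe$pp
      secondary$params <- pe$sp
      recalibrate_bn("primary", primary$params, stenv_p, config, images)
      xc <- cascade_inputs(primary$params, stenv_p, config, images)
      recalibrate_bn("backbone", secondary$params, stenv_s,
                     secondary$config, xc)
      primary$state <- state_list(stenv_p)
      secondary$state <- state_list(stenv_s)
      if (!is.null(checkpoint_dir)) {
        save_checkpoint(primary, file.path(checkpoint_dir, "primary_ft"))
        save_checkpoint(secondary, file.path(checkpoint_dir, "secondary_ft"))
      }
    }
  }

  structure(list(backbone = backbone, primary = primary,
                 secondary = secondary, config = config, plan = plan,
                 log = do.call(rbind, log$rows)),
            class = "secp_fit")
}

#' Digest of a parameter set
#'
#' Order-independent fingerprint of a named parameter list, used to audit the
#' freeze contract of training stage 3 (the primary network's hash must be
#' identical before and after the secondary network is trained).
#'
#' @param params named list of parameter arrays (or a `secp_net`)
#' @return character digest
#' @export
param_hash <- function(params) {
  if (inherits(params, "secp_net")) params <- params$params
  r <- as.integer(serialize(params[order(names(params))], NULL, xdr = TRUE))
  w <- seq_along(r)
  paste0(length(r), ":",
         sum((r + 1) * ((w %% 97) + 1)) %% 2147483647, ":",
         sum((r + 1) * ((w %% 89) + 1)) %% 2147483647)
}
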