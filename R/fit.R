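# The package's main modelling interface: one fitting function returning a
# classed object with the usual methods.

#' Fit an SE-Connection pyramid segmentation model
#'
#' Trains the cascaded pyramid network on labelled 2D slices with the staged
#' recipe of [run_staged_training()] and returns a fitted-model object. This
#' is the package's front door; `predict()`, `summary()`, `plot()` and
#' `coef()` methods operate on the result.
#'
#' @param images training images `(H, W, in_channels, N)` (a 3-D array of
#'   single-channel slices is promoted)
#' @param masks integer label masks `(H, W, N)`, values `0..num_classes-1`
#' @param config a [secp_config()]; a small preset is derived from the masks
#'   when omitted
#' @param plan a [train_plan()]
#' @param checkpoint_dir optional directory for per-stage checkpoints
#' @return object of class `secp_fit` with components `backbone`, `primary`,
#'   `secondary` (`secp_net` objects or NULL for skipped stages), `config`,
#'   `plan` and `log` (per-epoch data frame: stage, epoch, lr, loss)
#' @seealso [predict.secp_fit()], [run_staged_training()]
#' @export
fit_secpnet <- function(images, masks,
                        config = NULL,
                        plan = train_plan(),
                        checkpoint_dir = NULL) {
  images <- as_feature_map(images)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  if (is.null(config)) {
    config <- secp_config_small(num_classes = max(masks) + 1L,
                                in_channels = dim(images)[3])
  }
  run_staged_training(images, masks, config, plan,
                      checkpoint_dir = checkpoint_dir)
}

#' @export
print.secp_fit <- function(x, ...) {
  cat("Fitted SECP segmentation model\n")
  print(x$config)
  stages <- unique(x$log$stage)
  cat("  stages run:", paste(stages, collapse = " -> "), "\n")
  for (st in stages) {
    l <- x$log[x$log$stage == st, ]
    cat(sprintf("    %-10s %3d epochs, loss %.4f -> %.4f\n", st, nrow(l),
                l$loss[1], l$loss[nrow(l)]))
  }
  invisible(x)
}

#' @export
summary.secp_fit <- function(object, ...) {
  out <- list(config = object$config,
              log = object$log,
              n_params_primary = if (!is.null(object$primary))
                n_params(object$primary) else NA_integer_,
              n_params_secondary = if (!is.null(object$secondary))
                n_params(object$secondary) else NA_integer_)
  class(out) <- "summary.secp_fit"
  out
}

#' @export
print.summary.secp_fit <- function(x, ...) {
  print(x$config)
  cat("primary parameters:  ", x$n_params_primary, "\n")
  cat("secondary parameters:", x$n_params_secondary, "\n")
  agg <- stats::aggregate(loss ~ stage, x$log, function(l) l[length(l)])
  cat("final loss per stage:\n")
  print(agg, row.names = FALSE)
  invisible(x)
}

#' @export
coef.secp_fit <- function(object, which = c("primary", "secondary",
                                            "backbone"), ...) {
  which <- match.arg(which)
  net <- object[[which]]
  if (is.null(net)) stop("model has no trained '", which, "' network")
  net$params
}

#' Predict segmentations from a fitted model
#'
#' @param object a `secp_fit`
#' @param newdata images `(H, W, in_channels, N)` (matrix or 3-D array
#'   promoted)
#' @param stage `"cascade"` (default; falls back to the primary network when
#'   no secondary was trained), `"primary"` or `"backbone"`
#' @param ... unused
#' @return list with `probs` `(H, W, C, N)` and `labels` `(H, W, N)`
#' @export
predict.secp_fit <- function(object, newdata,
                             stage = c("cascade", "primary", "backbone"),
                             ...) {
  stage <- match.arg(stage)
  newdata <- as_feature_map(newdata)
  probs <- if (stage == "cascade" && !is.null(object$secondary)) {
    cascade_forward(newdata, object$primary, object$secondary)$final_probs
  } else if (stage %in% c("cascade", "primary")) {
    if (is.null(object$primary)) stop("model has no trained primary network")
    primary_forward(newdata, object$primary)$probs
  } else {
    if (is.null(object$backbone)) stop("model has no trained backbone")
    softmax_channels(backbone_unet_forward(newdata, object$backbone))
  }
  list(probs = probs, labels = predict_labels(probs))
}

#' Plot training loss curves of a fitted model
#'
#' @param x a `secp_fit`
#' @param ... passed to [graphics::matplot()]-style base plotting
#' @export
plot.secp_fit <- function(x, ...) {
  log <- x$log
  stages <- unique(log$stage)
  cols <- seq_along(stages)
  off <- 0
  graphics::plot(NULL, xlim = c(1, nrow(log)), ylim = range(log$loss),
                 xlab = "epoch (stages concatenated)",
                 ylab = "mean cross-entropy (bits)", ...)
  for (i in seq_along(stages)) {
    l <- log[log$stage == stages[i], ]
    graphics::lines(off + seq_len(nrow(l)), l$loss, col = cols[i], lwd = 2)
    off <- off + nrow(l)
  }
  graphics::legend("topright", legend = stages, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
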