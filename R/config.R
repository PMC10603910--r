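#' Network architecture configuration
#'
#' Describes a U-shape segmentation network: `depth` is the number of 2x
#' down-samplings, `stage_channels` the channel widths from the shallowest
#' encoder stage to the bottleneck (`depth + 1` entries), `se_reduction` the
#' squeeze-and-excitation bottleneck divisor (hidden width is
#' `max(1, floor(channels / se_reduction))`), and `num_classes` the total
#' class count including background. Upsampling is always bilinear, chosen to
#' avoid the checkerboard artifacts of transposed convolution.
#'
#' @param num_classes total number of classes (background + organs), >= 2
#' @param in_channels number of image channels (1 for grayscale CT slices)
#' @param depth number of 2x down-samplings
#' @param stage_channels integer vector of `depth + 1` channel widths,
#'   shallow to deep
#' @param se_reduction positive integer reduction ratio of SE gates
#' @param batchnorm logical; batch-normalise after each 3x3 convolution
#' @param loss_base base of the logarithm in the cross-entropy loss (2 or
#'   `exp(1)`)
#' @return an object of class `secp_config`
#' @examples
#' cfg <- secp_config(num_classes = 5, depth = 3, stage_channels = c(8, 16, 32, 64))
#' @export
secp_config <- function(num_classes,
                        in_channels = 1L,
                        depth = 4L,
                        stage_channels = c(64L, 128L, 256L, 512L, 1024L),
                        se_reduction = 16L,
                        batchnorm = TRUE,
                        loss_base = 2) {
  depth <- as.integer(depth)
  stage_channels <- as.integer(stage_channels)
  if (num_classes < 2) stop("num_classes must be >= 2 (background + organs)")
  if (depth < 1) stop("depth must be >= 1")
  if (length(stage_channels) != depth + 1)
    stop("stage_channels must have depth + 1 = ", depth + 1, " entries, got ",
         length(stage_channels))
  if (any(stage_channels < 1)) stop("all stage channel widths must be >= 1")
  if (se_reduction < 1) stop("se_reduction must be >= 1")
  structure(list(num_classes = as.integer(num_classes),
                 in_channels = as.integer(in_channels),
                 depth = depth,
                 stage_channels = stage_channels,
                 se_reduction = as.integer(se_reduction),
                 batchnorm = isTRUE(batchnorm),
                 loss_base = loss_base,
                 upsample_mode = "bilinear"),
            class = "secp_config")
}

#' Small CPU-friendly preset configuration
#'
#' Depth-3 network with widths 8/16/32/64 and SE reduction 4, suitable for
#' tests and small phantom studies on a single CPU.
#'
#' @inheritParams secp_config
#' @return a `secp_config`
#' @export
secp_config_small <- function(num_classes, in_channels = 1L) {
  secp_config(num_classes, in_channels = in_channels, depth = 3L,
              stage_channels = c(8L, 16L, 32L, 64L), se_reduction = 4L)
}

#' @export
print.secp_config <- function(x, ...) {
  cat("SECP network configuration\n")
  cat("  classes:       ", x$num_classes, " (background + ",
      x$num_classes - 1, " organs)\n", sep = "")
  cat("  input channels:", x$in_channels, "\n")
  cat("  depth:         ", x$depth, " (input sides must be multiples of ",
      2^x$depth, ")\n", sep = "")
  cat("  stage widths:  ", paste(x$stage_channels, collapse = "-"), "\n")
  cat("  SE reduction:  ", x$se_reduction, "\n")
  cat("  batchnorm:     ", x$batchnorm, "\n")
  invisible(x)
}

#' Read a YAML configuration file
#'
#' Reads `model:` (and optionally `train:`) blocks from a YAML file and
#' validates them. Recognised `model:` keys: num_classes, in_channels, depth,
#' stage_channels, se_reduction, batchnorm. Recognised `train:` keys match the
#' arguments of [train_plan()].
#'
#' @param path YAML file path
#' @return list with elements `model` (a `secp_config`) and, when present,
#'   `train` (a `secp_train_plan`)
#' @export
read_secp_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$model)) stop("YAML file has no 'model:' block: ", path)
  m <- y$model
  cfg <- secp_config(num_classes = m$num_classes,
                     in_channels = m$in_channels %||% 1L,
                     depth = m$depth %||% 4L,
                     stage_channels = m$stage_channels %||%
                       c(64L, 128L, 256L, 512L, 1024L),
                     se_reduction = m$se_reduction %||% 16L,
                     batchnorm = m$batchnorm %||% TRUE)
  out <- list(model = cfg)
  if (!is.null(y$train)) {
    tr <- y$train
    out$train <- train_plan(epochs = tr$epochs %||% 100L,
                            lr0 = tr$lr0 %||% 0.01,
                            momentum = tr$momentum %||% 0.9,
                            weight_decay = tr$weight_decay %||% 1e-4,
                            batch_size = tr$batch_size %||% 16L,
                            stages = tr$stages %||%
                              c("backbone", "secp", "secondary", "finetune"),
                            seed = tr$seed %||% 1L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
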