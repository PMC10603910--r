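# Self-describing checkpoints: a serialized parameter archive plus a JSON
# sidecar holding the full network configuration.

#' Save a network checkpoint
#'
#' Writes `<prefix>.rds` (parameters and batch-norm state) and
#' `<prefix>.json` (type, configuration, parameter count), so a checkpoint
#' can be reloaded without external context.
#'
#' @param net a `secp_net`
#' @param prefix file path prefix (directories are created)
#' @return invisibly, the two file paths
#' @export
save_checkpoint <- function(net, prefix) {
  stopifnot(inherits(net, "secp_net"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  rds <- paste0(prefix, ".rds")
  js <- paste0(prefix, ".json")
  saveRDS(list(params = net$params, state = net$state), rds)
  cfg <- unclass(net$config)
  jsonlite::write_json(list(type = net$type, config = cfg,
                            n_params = n_params(net)),
                       js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(rds, js))
}

#' Load a network checkpoint
#'
#' @param prefix path prefix used with [save_checkpoint()]
#' @return a `secp_net`
#' @export
load_checkpoint <- function(prefix) {
  rds <- paste0(prefix, ".rds")
  js <- paste0(prefix, ".json")
  if (!file.exists(rds) || !file.exists(js))
    stop("missing checkpoint file(s) at prefix: ", prefix)
  meta <- jsonlite::read_json(js)
  m <- meta$config
  cfg <- secp_config(num_classes = m$num_classes,
                     in_channels = m$in_channels,
                     depth = m$depth,
                     stage_channels = unlist(m$stage_channels),
                     se_reduction = m$se_reduction,
                     batchnorm = m$batchnorm,
                     loss_base = m$loss_base)
  pl <- readRDS(rds)
  net <- structure(list(type = meta$type, config = cfg, params = pl$params,
                        state = pl$state),
                   class = "secp_net")
  if (n_params(net) != meta$n_params)
    stop("checkpoint parameter count mismatch: expected ", meta$n_params,
         ", found ", n_params(net))
  net
}
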