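# A self-contained scaled-down segmentation study on synthetic phantoms:
# the package's end-to-end worked example and its learning check.

#' Scaled-down phantom segmentation study
#'
#' Generates a seeded population of small multi-organ phantom slices
#' (background + 4 organ classes on a 64 x 64 canvas: a mirrored
#' equal-intensity left/right pair, a medium organ and a small organ, each
#' with per-slice absence), trains the cascaded pyramid network with the
#' staged SGD recipe (lr0 0.01, momentum 0.9, weight decay 1e-4, polynomial
#' learning-rate decay) on the first 8 patients, and evaluates per-case Dice
#' for every foreground class on the held-out patients.
#'
#' @param data_seed seed of the phantom population
#' @param train_seed seed of weight initialisation and batch shuffling
#' @param epochs epoch budget for the backbone, pyramid and secondary stages
#' @param finetune_epochs epoch budget for the fine-tuning stage
#' @param n_patients total patients generated; the last `holdout` form the
#'   held-out fold
#' @param holdout number of held-out patients
#' @param canvas phantom canvas side (must be a multiple of 8)
#' @param batch_size SGD batch size
#' @return list with `fit` (the [fit_secpnet()] object), `dice_primary` and
#'   `dice_cascade` (per-class held-out per-case Dice, foreground classes),
#'   `mean_primary`, `mean_cascade`, and `spec`
#' @export
phantom_study <- function(data_seed = 7L, train_seed = 11L,
                          epochs = 60L, finetune_epochs = 20L,
                          n_patients = 10L, holdout = 2L,
                          canvas = 64L, batch_size = 4L) {
  spec <- phantom_spec(canvas = canvas, organs = phantom_organs_small(canvas),
                       noise_sd = 0.04, ramp = 0.08, bg = 0.12,
                       n_patients = n_patients, slices_per_patient = 2L,
                       seed = data_seed)
  ds <- phantom_dataset(spec)
  train_pat <- seq_len(n_patients - holdout)
  test_pat <- setdiff(seq_len(n_patients), train_pat)
  tr <- ds$patient_id %in% train_pat
  te <- which(!tr)

  cfg <- secp_config_small(num_classes = nrow(spec$organs) + 1L)
  plan <- train_plan(epochs = epochs, lr0 = 0.01, momentum = 0.9,
                     weight_decay = 1e-4, batch_size = batch_size,
                     plateau_patience = 8L, seed = train_seed,
                     stage_epochs = list(finetune = finetune_epochs))
  fit <- fit_secpnet(ds$images[, , , tr, drop = FALSE], ds$masks[, , tr],
                     cfg, plan)

  held_dice <- function(labels) {
    vapply(spec$organs$class, function(cls) {
      vols <- lapply(test_pat, function(p) {
        i <- which(ds$patient_id == p)
        list(pred = labels[, , match(i, te)], truth = ds$masks[, , i])
      })
      dice_per_case_and_global(vols, cls)$per_case
    }, numeric(1))
  }
  x_te <- ds$images[, , , te, drop = FALSE]
  dp <- held_dice(predict(fit, x_te, stage = "primary")$labels)
  dc <- held_dice(predict(fit, x_te, stage = "cascade")$labels)
  list(fit = fit, dice_primary = dp, dice_cascade = dc,
       mean_primary = mean(dp), mean_cascade = mean(dc), spec = spec)
}
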