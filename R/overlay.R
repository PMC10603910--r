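# Qualitative TP/FP/FN overlays for a chosen class.

#' Render a TP/FP/FN colour overlay
#'
#' For the chosen class: pixels predicted and true are green (TP), predicted
#' but not true are red (FP), true but not predicted are blue (FN); all other
#' pixels show the grayscale image. Every coloured pixel belongs to exactly
#' one of the three sets.
#'
#' @param image numeric H x W matrix in `[0, 1]`
#' @param pred,truth integer H x W label masks
#' @param cls class label to visualise
#' @return H x W x 3 RGB array in `[0, 1]`, with attribute `"counts"`
#'   holding the TP/FP/FN pixel counts
#' @export
render_overlay <- function(image, pred, truth, cls) {
  if (!identical(dim(image), dim(pred)) || !identical(dim(pred), dim(truth)))
    stop("image, prediction and truth must have identical shapes")
  g <- pmin(pmax(image, 0), 1)
  rgb <- array(rep(g, 3), dim = c(dim(g), 3L))
  tp <- pred == cls & truth == cls
  fp <- pred == cls & truth != cls
  fn <- pred != cls & truth == cls
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[tp] <- if (ch == 2) 1 else 0
    plane[fp] <- if (ch == 1) 1 else 0
    plane[fn] <- if (ch == 3) 1 else 0
    rgb[, , ch] <- plane
  }
  attr(rgb, "counts") <- c(tp = sum(tp), fp = sum(fp), fn = sum(fn))
  rgb
}

#' Write an overlay to a PNG file
#'
#' @inheritParams render_overlay
#' @param path output PNG path
#' @return invisibly, the overlay counts
#' @export
write_overlay <- function(image, pred, truth, cls, path) {
  ov <- render_overlay(image, pred, truth, cls)
  png::writePNG(ov, path)
  invisible(attr(ov, "counts"))
}
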