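# Seeded synthetic multi-organ phantom slices.
#
# The generator emulates the structural difficulties of head-and-neck
# organ-at-risk CT slices: a wide organ-size spectrum, mirrored left/right
# organ pairs, small organs that occupy a tiny fraction of the foreground,
# and slices from which some organs are absent. It makes no attempt at
# anatomical realism or CT physics; it exists so that every other module is
# testable without any external data.

#' Phantom population specification
#'
#' @param canvas square canvas side in pixels
#' @param organs data frame with one row per organ class and columns
#'   `class` (unique integer >= 1), `name`, `lateral` ("L", "R" or ""),
#'   `cy`, `cx` (canonical centre, pixels), `radius` (mean semi-axis scale,
#'   pixels), `aspect` (semi-axis ratio: x semi-axis = radius * aspect,
#'   y semi-axis = radius / aspect), `jitter` (max centre displacement,
#'   pixels), `rjitter` (relative radius jitter), `intensity` (mean organ
#'   intensity in `[0, 1]`), `presence` (probability the organ appears in a
#'   slice)
#' @param noise_sd Gaussian pixel-noise standard deviation
#' @param ramp vertical background intensity ramp amplitude
#' @param bg background base intensity
#' @param n_patients number of patients in a generated dataset
#' @param slices_per_patient slices per patient
#' @param seed global generator seed; per-slice substreams are derived
#'   deterministically from it
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(canvas = 256L, organs = default_phantom_organs(canvas),
                         noise_sd = 0.02, ramp = 0.08, bg = 0.1,
                         n_patients = 10L, slices_per_patient = 4L,
                         seed = 1L) {
  stopifnot(is.data.frame(organs))
  req <- c("class", "name", "lateral", "cy", "cx", "radius", "aspect",
           "jitter", "rjitter", "intensity", "presence")
  if (!all(req %in% names(organs)))
    stop("organs data frame must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(organs$class)) stop("organ class indices must be unique")
  if (any(organs$class < 1)) stop("organ class indices must be >= 1")
  if (any(organs$radius <= 0)) stop("organ radii must be positive")
  if (any(organs$intensity < 0 | organs$intensity > 1))
    stop("organ intensities must lie in [0, 1]")
  if (any(organs$presence < 0 | organs$presence > 1))
    stop("presence probabilities must lie in [0, 1]")
  # every organ must fit the canvas at its maximal jittered extent
  ax <- organs$radius * (1 + organs$rjitter) * organs$aspect + organs$jitter
  ay <- organs$radius * (1 + organs$rjitter) / organs$aspect + organs$jitter
  bad <- organs$cx - ax < 1 | organs$cx + ax > canvas |
    organs$cy - ay < 1 | organs$cy + ay > canvas
  if (any(bad))
    stop("organ(s) cannot fit the canvas at their radius: ",
         paste(organs$name[bad], collapse = ", "))
  structure(list(canvas = as.integer(canvas), organs = organs,
                 noise_sd = noise_sd, ramp = ramp, bg = bg,
                 n_patients = as.integer(n_patients),
                 slices_per_patient = as.integer(slices_per_patient),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default 13-organ head-and-neck-style phantom population
#'
#' Thirteen organ classes (five mirrored left/right pairs plus brain stem,
#' spinal cord and thyroid) whose pixel areas follow the 2/3-power of a
#' published organ-volume spectrum (the areal analogue of volume), so that
#' eyes, submandibular glands and thyroid are genuinely small targets while
#' the temporal lobes are large.
#'
#' @param canvas canvas side in pixels (radii and positions scale with it)
#' @return organs data frame suitable for [phantom_spec()]
#' @export
default_phantom_organs <- function(canvas = 256L) {
  # average organ volumes (cm^3) of the head-and-neck OAR spectrum
  vols <- c(eye_L = 8.4, eye_R = 8.8,
            temporal_lobe_L = 134.3, temporal_lobe_R = 125.8,
            mandible_L = 35.9, mandible_R = 37.2,
            brain_stem = 30.8,
            parotid_L = 21.8, parotid_R = 22.4,
            spinal_cord = 23.1,
            submandibular_L = 9.3, submandibular_R = 8.9,
            thyroid = 12.8)
  s <- canvas / 256
  # radius ~ volume^(1/3): area ratios follow volume^(2/3)
  rmax <- 34 * s
  radius <- rmax * (vols / max(vols))^(1 / 3)
  lateral <- ifelse(grepl("_L$", names(vols)), "L",
                    ifelse(grepl("_R$", names(vols)), "R", ""))
  # canonical (cy, cx) layout: superior structures high on the canvas,
  # paired organs mirrored about the vertical midline
  cy <- c(60, 60, 95, 95, 150, 150, 105, 140, 140, 175, 195, 195, 222) * s
  off <- c(55, 55, 62, 62, 52, 52, 0, 80, 80, 0, 35, 35, 0) * s
  cx <- ifelse(lateral == "R", canvas / 2 + off,
               ifelse(lateral == "L", canvas / 2 - off, canvas / 2))
  data.frame(class = seq_along(vols),
             name = names(vols),
             lateral = lateral,
             cy = cy, cx = cx,
             radius = radius,
             aspect = c(1, 1, 1.25, 1.25, 1.2, 1.2, 0.9, 0.85, 0.85, 0.8,
                        1, 1, 1.3),
             jitter = 4 * s,
             rjitter = 0.15,
             intensity = seq(0.35, 0.95, length.out = length(vols)),
             presence = c(0.6, 0.6, 0.85, 0.85, 0.8, 0.8, 0.9,
                          0.8, 0.8, 0.95, 0.6, 0.6, 0.5),
             stringsAsFactors = FALSE)
}

#' Small 4-organ phantom population for CPU-scale studies
#'
#' A reduced population (background + 4 organ classes) preserving the
#' structural challenges of the full 13-organ layout on a small canvas: one
#' mirrored left/right pair sharing the same intensity (so the two classes
#' are separable only by spatial context), one medium central organ and one
#' genuinely small organ, with per-slice organ absence.
#'
#' @param canvas canvas side in pixels
#' @return organs data frame suitable for [phantom_spec()]
#' @export
phantom_organs_small <- function(canvas = 64L) {
  s <- canvas / 64
  data.frame(class = 1:4,
             name = c("pair_L", "pair_R", "medium", "small"),
             lateral = c("L", "R", "", ""),
             cy = c(20, 20, 36, 53) * s,
             cx = c(18, 46, 32, 32) * s,
             radius = c(9, 9, 10, 5) * s,
             aspect = c(1, 1, 1.2, 1),
             jitter = 2 * s,
             rjitter = 0.15,
             intensity = c(0.5, 0.5, 0.75, 0.92),
             presence = c(0.9, 0.9, 1.0, 0.9),
             stringsAsFactors = FALSE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec: ", x$canvas, "x", x$canvas, " canvas, ",
      nrow(x$organs), " organ classes, ", x$n_patients, " patients x ",
      x$slices_per_patient, " slices, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# rasterise one ellipse; returns logical matrix
ellipse_mask <- function(H, W, cy, cx, ay, ax) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((x - cx) / ax)^2 + ((y - cy) / ay)^2 <= 1
}

#' Generate one phantom slice
#'
#' Draws each organ with its presence probability as an ellipse at a
#' jittered canonical position. Organs are drawn in order of decreasing
#' size and an earlier (smaller-index in draw order) label is never
#' overwritten, so small organs are not engulfed by large ones. The image is
#' the per-organ mean intensity over a vertical background ramp, plus
#' Gaussian noise, clipped to `[0, 1]`.
#'
#' @param spec a [phantom_spec()]
#' @param seed optional seed for this slice (otherwise the current RNG
#'   state is used)
#' @return list with `image` (H x W matrix in `[0, 1]`) and `mask`
#'   (H x W integer matrix, 0 = background)
#' @export
generate_slice <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$canvas
  mask <- matrix(0L, n, n)
  image <- matrix(spec$bg, n, n) +
    spec$ramp * matrix(seq_len(n) / n, n, n)
  org <- spec$organs[order(-spec$organs$radius), ]
  for (i in seq_len(nrow(org))) {
    o <- org[i, ]
    if (runif(1) > o$presence) next
    jy <- runif(1, -o$jitter, o$jitter)
    jx <- runif(1, -o$jitter, o$jitter)
    r <- o$radius * runif(1, 1 - o$rjitter, 1 + o$rjitter)
    em <- ellipse_mask(n, n, o$cy + jy, o$cx + jx, r / o$aspect, r * o$aspect)
    free <- em & mask == 0L           # first-drawn occupancy wins
    mask[free] <- o$class
    image[free] <- o$intensity
  }
  if (spec$noise_sd > 0)
    image <- image + matrix(rnorm(n * n, sd = spec$noise_sd), n, n)
  list(image = pmin(pmax(image, 0), 1), mask = mask)
}

# deterministic per-slice substream seed derived from the global seed
slice_seed <- function(seed, patient, slice) {
  (seed * 7919 + patient * 104729 + slice * 1299709) %% 2147483647
}

#' Generate an in-memory phantom dataset
#'
#' @param spec a [phantom_spec()]
#' @return list with `images` `(H, W, 1, N)`, `masks` `(H, W, N)`,
#'   `patient_id` and `slice` vectors, and `labels` (class index to organ
#'   name, with 0 = background)
#' @export
phantom_dataset <- function(spec) {
  N <- spec$n_patients * spec$slices_per_patient
  n <- spec$canvas
  images <- array(0, c(n, n, 1L, N))
  masks <- array(0L, c(n, n, N))
  patient <- integer(N); slice <- integer(N)
  k <- 0L
  for (p in seq_len(spec$n_patients)) {
    for (s in seq_len(spec$slices_per_patient)) {
      k <- k + 1L
      sl <- generate_slice(spec, seed = slice_seed(spec$seed, p, s))
      images[, , 1L, k] <- sl$image
      masks[, , k] <- sl$mask
      patient[k] <- p; slice[k] <- s
    }
  }
  labels <- c("background", spec$organs$name)
  names(labels) <- c(0L, spec$organs$class)
  list(images = images, masks = masks, patient_id = patient, slice = slice,
       labels = labels)
}

#' Write a phantom dataset to disk
#'
#' Writes `images/` and `masks/` PNG files, a `manifest.csv` (columns
#' patient_id, slice, image, mask) and a `labels.json` label dictionary.
#' Fully reproducible from the spec seed: two runs produce byte-identical
#' masks.
#'
#' @param spec a [phantom_spec()]
#' @param dir output directory (created if needed)
#' @return invisibly, the manifest data frame
#' @export
generate_dataset <- function(spec, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  rows <- list()
  for (p in seq_len(spec$n_patients)) {
    for (s in seq_len(spec$slices_per_patient)) {
      sl <- generate_slice(spec, seed = slice_seed(spec$seed, p, s))
      img_rel <- file.path("images", sprintf("p%03d_s%03d.png", p, s))
      msk_rel <- file.path("masks", sprintf("p%03d_s%03d.png", p, s))
      png::writePNG(sl$image, file.path(dir, img_rel))
      png::writePNG(sl$mask / 255, file.path(dir, msk_rel))
      rows[[length(rows) + 1L]] <-
        data.frame(patient_id = p, slice = s, image = img_rel, mask = msk_rel)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  labels <- as.list(c("background", spec$organs$name))
  names(labels) <- as.character(c(0L, spec$organs$class))
  jsonlite::write_json(labels, file.path(dir, "labels.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
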