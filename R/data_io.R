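# Reading and writing image slices and label masks, aspect-preserving
# resampling to network-compatible sizes, and dataset manifest management.
#
# Images: PNG (8/16-bit) or NIfTI (via RNifti when installed); masks:
# integer label maps. A manifest is a CSV with header
# (patient_id, slice, image, mask) and a labels.json dictionary mapping
# class index to organ name.

read_image_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI files requires the RNifti package")
    v <- as.array(RNifti::readNifti(path))
    if (length(dim(v)) == 3L && dim(v)[3] == 1L) dim(v) <- dim(v)[1:2]
    return(v)
  }
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]  # first channel of colour PNGs
  v
}

read_mask_file <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    v <- read_image_file(path)
    m <- round(v)
    if (max(abs(v - m)) > 1e-6) stop("mask is not integer-valued: ", path)
    return(matrix(as.integer(m), nrow(m), ncol(m)))
  }
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  # 8-bit PNGs decode as k/255; 16-bit as k/65535
  k <- round(v * 255)
  if (max(abs(v * 255 - k)) > 1e-6) k <- round(v * 65535)
  matrix(as.integer(k), nrow(v), ncol(v))
}

#' Min-max normalise an image to `[0, 1]`
#'
#' Constant (zero-range) images map to all zeros.
#'
#' @param x numeric matrix or array
#' @return normalised array of the same shape
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[2] - r[1] == 0) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Read a dataset manifest
#'
#' @param dir dataset directory containing `manifest.csv` and `labels.json`
#' @return list with `manifest` (data frame: patient_id, slice, image, mask)
#'   and `labels` (named character vector, names are class indices from 0)
#' @export
read_manifest <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  lf <- file.path(dir, "labels.json")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  req <- c("patient_id", "slice", "image", "mask")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  dup <- duplicated(manifest[c("patient_id", "slice")])
  if (any(dup)) stop("duplicate (patient_id, slice) records in manifest")
  labels <- NULL
  if (file.exists(lf)) {
    ll <- jsonlite::read_json(lf)
    labels <- unlist(ll)
    idx <- sort(as.integer(names(labels)))
    if (!identical(idx, seq_along(idx) - 1L))
      stop("label indices must be contiguous from 0")
  }
  missing <- !file.exists(file.path(dir, manifest$image)) |
    !file.exists(file.path(dir, manifest$mask))
  if (any(missing))
    stop("manifest references missing files, e.g. ",
         manifest$image[missing][1])
  list(manifest = manifest, labels = labels, dir = dir)
}

#' Load one (image, mask) sample from a manifest record
#'
#' The image is min-max normalised to `[0, 1]` and returned as an
#' `(H, W, 1, 1)` feature map; the mask keeps its integer labels.
#'
#' @param record one row of a manifest data frame
#' @param dir dataset directory the manifest paths are relative to
#' @param labels optional label dictionary; mask values outside it raise an
#'   error naming the value and file
#' @return list with `image` and `mask`
#' @export
load_sample <- function(record, dir = ".", labels = NULL) {
  img <- minmax_normalize(read_image_file(file.path(dir, record$image)))
  msk <- read_mask_file(file.path(dir, record$mask))
  if (!is.null(labels)) {
    known <- as.integer(names(labels))
    bad <- setdiff(unique(as.vector(msk)), known)
    if (length(bad))
      stop("mask value ", bad[1], " not in label dictionary (file ",
           record$mask, ")")
  }
  dim(img) <- c(dim(img), 1L, 1L)
  list(image = img, mask = msk)
}

#' Load a whole manifest into memory
#'
#' @param ds a dataset as returned by [read_manifest()]
#' @return list with `images` `(H, W, 1, N)`, `masks` `(H, W, N)` and
#'   `patient_id` vector (manifest order)
#' @export
load_dataset <- function(ds) {
  n <- nrow(ds$manifest)
  first <- load_sample(ds$manifest[1, ], ds$dir, ds$labels)
  d <- dim(first$image)
  images <- array(0, c(d[1], d[2], 1L, n))
  masks <- array(0L, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    s <- load_sample(ds$manifest[i, ], ds$dir, ds$labels)
    images[, , 1L, i] <- s$image
    masks[, , i] <- s$mask
  }
  list(images = images, masks = masks, patient_id = ds$manifest$patient_id)
}

nearest_index <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pmin(pmax(round(src), 1L), n_in)
}

#' Resample a slice to a square target size, preserving aspect ratio
#'
#' Scales so the longer side equals `target` (bilinear for the image,
#' nearest-neighbour for the mask — no new labels can appear), then pads
#' symmetrically with background (image 0, mask class 0) to
#' `target x target`. Scale and padding offsets are attached for inverse
#' mapping.
#'
#' @param image numeric H x W matrix
#' @param mask optional integer H x W matrix
#' @param target target side length
#' @return list with `image`, `mask` (or NULL) and `info` (scale, offsets,
#'   original and scaled sizes)
#' @export
resize_keep_aspect <- function(image, mask = NULL, target = 256L) {
  H <- nrow(image); W <- ncol(image)
  if (H < 1 || W < 1 || target < 1) stop("non-positive image or target size")
  if (!is.null(mask) && !identical(dim(mask), dim(image)))
    stop("image and mask have different shapes")
  scale <- target / max(H, W)
  Hn <- if (H >= W) as.integer(target) else max(1L, as.integer(round(H * scale)))
  Wn <- if (W > H) as.integer(target) else max(1L, as.integer(round(W * scale)))
  x <- image; dim(x) <- c(H, W, 1L, 1L)
  img_s <- cpp_resize_bilinear_fw(x, Hn, Wn)[, , 1, 1]
  oy <- (target - Hn) %/% 2L
  ox <- (target - Wn) %/% 2L
  out_img <- matrix(0, target, target)
  out_img[oy + seq_len(Hn), ox + seq_len(Wn)] <- img_s
  out_msk <- NULL
  if (!is.null(mask)) {
    ms <- mask[nearest_index(H, Hn), nearest_index(W, Wn), drop = FALSE]
    out_msk <- matrix(0L, target, target)
    out_msk[oy + seq_len(Hn), ox + seq_len(Wn)] <- ms
  }
  list(image = out_img, mask = out_msk,
       info = list(scale = scale, offset_y = oy, offset_x = ox,
                   scaled = c(Hn, Wn), original = c(H, W)))
}

#' Map a resampled mask back to the original slice geometry
#'
#' Crops the padding recorded by [resize_keep_aspect()] and rescales by
#' nearest neighbour to the original size.
#'
#' @param mask target-sized integer mask
#' @param info the `info` element returned by [resize_keep_aspect()]
#' @return integer mask at the original H x W
#' @export
inverse_resize_mask <- function(mask, info) {
  core <- mask[info$offset_y + seq_len(info$scaled[1]),
               info$offset_x + seq_len(info$scaled[2]), drop = FALSE]
  core[nearest_index(info$scaled[1], info$original[1]),
       nearest_index(info$scaled[2], info$original[2]), drop = FALSE]
}
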