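# Overlap tiling of whole images into fixed-size patches, plus the
# augmentation-based class balancing applied to training folds.

#' Plan a valid-region patch grid
#'
#' Computes the tiling of an image into square patches with fractional
#' overlap, using a valid-region strategy: `stride = round(patch_size *
#' (1 - overlap))` and incomplete boundary patches are discarded. For the
#' native 700 x 460 image with 224-pixel patches at 20% overlap this gives
#' stride 179 and a 3 x 2 grid of 6 patches.
#'
#' @param height,width Image dimensions in pixels.
#' @param patch_size Patch side length (default 224).
#' @param overlap Fractional overlap between adjacent patches (default 0.20).
#' @return An object of class `patch_grid`: list with `patch_size`,
#'   `overlap`, `stride`, `nh`, `nw`, `n_patches`, `height`, `width` and
#'   `offsets` (a data frame of 0-based `(row, col)` top-left anchors in
#'   row-major order, rows outer).
#' @examples
#' plan_grid(700, 460)  # stride 179, 3 x 2 = 6 patches
#' @export
plan_grid <- function(height, width, patch_size = 224L, overlap = 0.20) {
  if (height < patch_size)
    stop("image height ", height, " smaller than patch size ", patch_size,
         call. = FALSE)
  if (width < patch_size)
    stop("image width ", width, " smaller than patch size ", patch_size,
         call. = FALSE)
  height <- as.integer(height); width <- as.integer(width)
  patch_size <- as.integer(patch_size)
  stride <- as.integer(round(patch_size * (1 - overlap)))
  nh <- (height - patch_size) %/% stride + 1L
  nw <- (width - patch_size) %/% stride + 1L
  rows <- rep((seq_len(nh) - 1L) * stride, each = nw)
  cols <- rep((seq_len(nw) - 1L) * stride, times = nh)
  structure(list(patch_size = as.integer(patch_size), overlap = overlap,
                 stride = stride, nh = nh, nw = nw, n_patches = nh * nw,
                 height = as.integer(height), width = as.integer(width),
                 offsets = data.frame(row = rows, col = cols)),
            class = "patch_grid")
}

#' Extract the patches of one image
#'
#' Crops every patch of a [plan_grid()] plan from an image, bit-exactly.
#' Patch indices are 0-based and follow the grid's row-major anchor order.
#'
#' @param image `H x W x 3` array (or `H x W` matrix) of pixel values.
#' @param grid A `patch_grid` planned for this image's dimensions.
#' @param patient_id,image_id,magnification,label Metadata carried on each
#'   record.
#' @return A list of patch records; each is a list with `pixels`
#'   (`patch_size x patch_size x 3`), the metadata fields, `patch_index`
#'   and `augmentation_tag = "none"`.
#' @export
extract_patches <- function(image, grid, patient_id = NA, image_id = NA,
                            magnification = NA, label = NA) {
  stopifnot(inherits(grid, "patch_grid"))
  d <- dim(image)
  if (d[1] != grid$height || d[2] != grid$width)
    stop("image is ", d[1], " x ", d[2], " but grid was planned for ",
         grid$height, " x ", grid$width, call. = FALSE)
  if (length(d) == 2L) image <- array(image, c(d, 1L))
  p <- grid$patch_size
  lapply(seq_len(grid$n_patches), function(k) {
    r0 <- grid$offsets$row[k]
    c0 <- grid$offsets$col[k]
    list(pixels = image[r0 + seq_len(p), c0 + seq_len(p), , drop = FALSE],
         patient_id = patient_id, image_id = image_id,
         magnification = magnification, label = label,
         patch_index = k - 1L, augmentation_tag = "none")
  })
}

#' Geometric patch augmentation
#'
#' Exact pixel permutations used to expand the benign class: horizontal and
#' vertical flips and rotations by 90 and 180 degrees.
#'
#' @param pixels `H x W x C` array (square for rotations).
#' @param tag One of `"none"`, `"hflip"`, `"vflip"`, `"rot90"`, `"rot180"`.
#' @return The transformed array.
#' @export
augment_pixels <- function(pixels, tag) {
  d <- dim(pixels)
  switch(tag,
         none = pixels,
         hflip = pixels[, d[2]:1, , drop = FALSE],
         vflip = pixels[d[1]:1, , , drop = FALSE],
         rot90 = aperm(pixels, c(2L, 1L, 3L))[d[2]:1, , , drop = FALSE],
         rot180 = pixels[d[1]:1, d[2]:1, , drop = FALSE],
         stop("unknown augmentation tag: ", tag, call. = FALSE))
}

.aug_tags <- c("hflip", "vflip", "rot90", "rot180")

#' Balance a training patch set by augmentation and downsampling
#'
#' Expands the benign pool fivefold (original plus the four geometric
#' transforms) and randomly downsamples the malignant pool without
#' replacement to that size; if the expanded benign pool exceeds the
#' malignant count, the augmented benign pool is subsampled to the malignant
#' count instead. The output always has equal class sizes and never
#' duplicates a malignant record.
#'
#' @param records List of patch records (as from [extract_patches()]).
#' @param seed Integer seed for the subsampling draws.
#' @return A list of patch records with equal class counts.
#' @export
balance_training_set <- function(records, seed = 1L) {
  labs <- vapply(records, function(r) as.character(r$label), character(1))
  ben <- records[labs == "benign"]
  mal <- records[labs == "malignant"]
  if (length(ben) == 0L || length(mal) == 0L)
    stop("both classes must be present to balance (benign: ", length(ben),
         ", malignant: ", length(mal), ")", call. = FALSE)
  ben_aug <- ben
  for (tag in .aug_tags) {
    ben_aug <- c(ben_aug, lapply(ben, function(r) {
      r$pixels <- augment_pixels(r$pixels, tag)
      r$augmentation_tag <- tag
      r
    }))
  }
  set.seed(seed)
  if (length(ben_aug) <= length(mal)) {
    mal <- mal[sample.int(length(mal), length(ben_aug))]
  } else {
    ben_aug <- ben_aug[sample.int(length(ben_aug), length(mal))]
  }
  c(ben_aug, mal)
}

#' Stack patch records into a training tensor
#'
#' Converts a list of patch records into the batched patch-set structure the
#' model consumes, optionally resizing every patch to the model input size.
#'
#' @param records List of patch records.
#' @param input_size Output side length; patches are bilinearly resized when
#'   it differs from their native size.
#' @return A patch set: list with `x` (`S x S x N x 3` array) and `meta`
#'   (data frame: `patient_id`, `image_id`, `patch_index`, `label`,
#'   `augmentation_tag`).
#' @export
records_to_patchset <- function(records, input_size = NULL) {
  n <- length(records)
  if (n == 0L) stop("no patch records", call. = FALSE)
  p0 <- dim(records[[1]]$pixels)
  s <- if (is.null(input_size)) p0[1] else as.integer(input_size)
  x <- array(0, c(s, s, n, p0[3]))
  for (i in seq_len(n)) {
    px <- records[[i]]$pixels
    if (dim(px)[1] != s || dim(px)[2] != s) px <- resize_bilinear(px, s, s)
    x[, , i, ] <- px
  }
  meta <- data.frame(
    patient_id = vapply(records, function(r) as.character(r$patient_id), character(1)),
    image_id = vapply(records, function(r) as.character(r$image_id), character(1)),
    patch_index = vapply(records, function(r) as.integer(r$patch_index), integer(1)),
    label = vapply(records, function(r) as.character(r$label), character(1)),
    augmentation_tag = vapply(records, function(r) r$augmentation_tag, character(1)),
    stringsAsFactors = FALSE)
  list(x = x, meta = meta)
}
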