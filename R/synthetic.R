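# Synthetic histology-texture cohort.
#
# Emulates the layout of the public breast-histopathology archives: a
# patient hierarchy with several 700 x 460 RGB images per patient, binary
# benign/malignant labels at the patient level, and a magnification tag.
# The class signal is spectral by construction: both classes share the same
# smooth, pink-tinted low-frequency base field (H&E-like palette), and
# malignant images additionally carry a zero-mean high-frequency texture, so
# the two classes have matched mean color and differ in multi-scale
# frequency content. Per-patient intensity offsets shared across a
# patient's images reproduce the between-patient correlation that makes
# image-level splitting leak.

#' Synthetic cohort specification
#'
#' @param n_benign_patients,n_malignant_patients Patients per class.
#' @param images_per_patient Images per patient.
#' @param image_size `c(height, width)` in pixels (default the native
#'   `c(460, 700)`).
#' @param magnification Magnification tag carried in the index.
#' @param seed Integer seed; the cohort is byte-deterministic per seed.
#' @param benign_smoothness Correlation length (px) of the smooth base
#'   field shared by both classes.
#' @param malignant_period Period (px) of the malignant high-frequency
#'   texture.
#' @param texture_amplitude Peak amplitude of that texture on the 0-255
#'   scale.
#' @param patient_effect_scale SD of the per-patient RGB intensity offset
#'   (0-255 scale), shared across a patient's images.
#' @param noise_sd SD of the per-pixel noise added to every image.
#' @return An object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_benign_patients = 12L,
                                  n_malignant_patients = 12L,
                                  images_per_patient = 4L,
                                  image_size = c(460L, 700L),
                                  magnification = "200X",
                                  seed = 7L,
                                  benign_smoothness = 60,
                                  malignant_period = 8,
                                  texture_amplitude = 30,
                                  patient_effect_scale = 8,
                                  noise_sd = 2) {
  if (n_benign_patients < 1L || n_malignant_patients < 1L ||
      images_per_patient < 1L)
    stop("patient and image counts must be >= 1", call. = FALSE)
  if (texture_amplitude < 0 || texture_amplitude > 100)
    stop("texture_amplitude must lie in [0, 100] to keep pixels in range",
         call. = FALSE)
  structure(list(n_benign_patients = as.integer(n_benign_patients),
                 n_malignant_patients = as.integer(n_malignant_patients),
                 images_per_patient = as.integer(images_per_patient),
                 image_size = as.integer(image_size),
                 magnification = magnification, seed = as.integer(seed),
                 benign_smoothness = benign_smoothness,
                 malignant_period = malignant_period,
                 texture_amplitude = texture_amplitude,
                 patient_effect_scale = patient_effect_scale,
                 noise_sd = noise_sd),
            class = "synthetic_cohort_spec")
}

# Smooth random field: a coarse Gaussian grid bilinearly resized up.
.smooth_field <- function(h, w, corr_len) {
  gh <- max(2L, as.integer(round(h / corr_len)) + 1L)
  gw <- max(2L, as.integer(round(w / corr_len)) + 1L)
  resize_bilinear(matrix(stats::rnorm(gh * gw), gh, gw), h, w)
}

# One synthetic image on the 0-255 scale, quantized to 8 bits.
.synth_image <- function(spec, label, offset) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  base <- c(215, 168, 195)                 # eosin-pink palette
  chan_gain <- c(18, 24, 16)               # blob contrast per channel
  blob <- .smooth_field(h, w, spec$benign_smoothness)
  img <- array(0, c(h, w, 3L))
  tex <- 0
  if (label == "malignant") {
    ph <- stats::runif(2, 0, 2 * pi)
    mask <- .smooth_field(h, w, spec$benign_smoothness * 1.5)
    mask <- 0.5 + 0.5 * (mask - min(mask)) / max(max(mask) - min(mask), 1e-12)
    tex <- spec$texture_amplitude *
      (sin(2 * pi * seq_len(h) / spec$malignant_period + ph[1]) %o%
         sin(2 * pi * seq_len(w) / spec$malignant_period + ph[2])) * mask
  }
  tex_gain <- c(1, 0.85, 0.95)
  for (c in 1:3) {
    img[, , c] <- base[c] + chan_gain[c] * blob + offset[c] +
      tex * tex_gain[c] +
      matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  }
  array(pmin(pmax(round(img), 0), 255), dim(img))
}

.mag_number <- function(mag) sub("[xX]$", "", mag)

#' Generate a synthetic cohort
#'
#' Draws the full cohort deterministically from `spec$seed`. When `out_dir`
#' is given, images are written as 8-bit PNGs in the directory layout of the
#' public dataset
#' (`<class>/SOB/synthetic/<patient>/<mag>/<patient>-<mag>-<seq>.png`) and
#' the index is written next to them as `cohort_index.csv`; otherwise the
#' quantized images are returned in memory.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param out_dir Optional output directory.
#' @return List with `index` (a [cohort_index()]), `spec`, and — when not
#'   writing to disk — `images` (named list of `H x W x 3` arrays in
#'   `[0, 1]`).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(spec$seed)
  magn <- .mag_number(spec$magnification)
  rows <- list()
  images <- list()
  for (cls in c("benign", "malignant")) {
    np <- if (cls == "benign") spec$n_benign_patients else
      spec$n_malignant_patients
    tag <- if (cls == "benign") "B" else "M"
    for (p in seq_len(np)) {
      pid <- sprintf("SOB_%s_SYN_p%02d", tag, p)
      offset <- stats::rnorm(3, sd = spec$patient_effect_scale)
      for (i in seq_len(spec$images_per_patient)) {
        img <- .synth_image(spec, cls, offset)
        fname <- sprintf("%s-%s-%03d.png", pid, magn, i)
        image_id <- sub("\\.png$", "", fname)
        path <- NA_character_
        if (!is.null(out_dir)) {
          dir <- file.path(out_dir, cls, "SOB", "synthetic", pid,
                           spec$magnification)
          dir.create(dir, recursive = TRUE, showWarnings = FALSE)
          path <- file.path(dir, fname)
          png::writePNG(img / 255, path)
        } else {
          images[[image_id]] <- img / 255
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, image_id = image_id,
          magnification = spec$magnification, label = cls, path = path,
          stringsAsFactors = FALSE)
      }
    }
  }
  index <- cohort_index(do.call(rbind, rows))
  if (!is.null(out_dir))
    utils::write.csv(as.data.frame(index),
                     file.path(out_dir, "cohort_index.csv"),
                     row.names = FALSE)
  out <- list(index = index, spec = spec)
  if (is.null(out_dir)) out$images <- images
  out
}

#' Read a cohort from the public dataset's directory layout
#'
#' Indexes a directory tree following the standard naming convention
#' `SOB_<B|M>_<subtype>_<slide>-<mag>-<seq>.png`: one patient per unique
#' patient code, labels from the B/M letter, magnification from the
#' filename. Files whose names cannot be parsed are skipped with a warning.
#'
#' @param root Root directory of the tree.
#' @return A [cohort_index()] with a `path` column.
#' @export
breakhis_reader <- function(root) {
  files <- list.files(root, pattern = "\\.png$", recursive = TRUE,
                      full.names = TRUE)
  pat <- "^(SOB_([BM])_[A-Za-z0-9]+_[A-Za-z0-9.-]+?)-([0-9]+)-([0-9]+)\\.png$"
  rows <- list()
  for (f in files) {
    bn <- basename(f)
    m <- regmatches(bn, regexec(pat, bn))[[1]]
    if (length(m) == 0L) {
      warning("skipping unparsable filename: ", bn, call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = m[2],
      image_id = sub("\\.png$", "", bn),
      magnification = paste0(m[4], "X"),
      label = if (m[3] == "B") "benign" else "malignant",
      path = f, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no parsable images under ", root,
                               call. = FALSE)
  idx <- do.call(rbind, rows)
  idx <- idx[order(idx$patient_id, idx$image_id), ]
  rownames(idx) <- NULL
  cohort_index(idx)
}
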