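# Independent reference implementations and shared fixtures.

# Naive 2-D analysis step: edge-replicate odd dims to even, then decimated
# periodic correlation computed with explicit loops. Deliberately slow and
# independent of the package's operator-matrix implementation.
naive_dwt2 <- function(x, family, boundary = "periodic") {
  f <- wavelet_filters(family)
  if (nrow(x) %% 2 == 1) x <- rbind(x, x[nrow(x), ])
  if (ncol(x) %% 2 == 1) x <- cbind(x, x[, ncol(x)])
  h <- nrow(x); w <- ncol(x)
  dec1 <- function(v, filt) {
    n <- length(v)
    out <- numeric(n %/% 2)
    for (k in seq_len(n %/% 2)) {
      s <- 0
      for (m in seq_along(filt)) {
        pos <- 2 * (k - 1) + m - 1          # 0-based
        if (boundary == "periodic") {
          s <- s + filt[m] * v[pos %% n + 1]
        } else if (pos < n) {
          s <- s + filt[m] * v[pos + 1]
        }
      }
      out[k] <- s
    }
    out
  }
  dec_rows <- function(m, filt) {            # filter along height
    out <- matrix(0, nrow(m) %/% 2, ncol(m))
    for (j in seq_len(ncol(m))) out[, j] <- dec1(m[, j], filt)
    out
  }
  dec_cols <- function(m, filt) {            # filter along width
    out <- matrix(0, nrow(m), ncol(m) %/% 2)
    for (i in seq_len(nrow(m))) out[i, ] <- dec1(m[i, ], filt)
    out
  }
  rows_lo <- dec_rows(x, f$dec_lo)
  rows_hi <- dec_rows(x, f$dec_hi)
  list(ll = dec_cols(rows_lo, f$dec_lo), lh = dec_cols(rows_lo, f$dec_hi),
       hl = dec_cols(rows_hi, f$dec_lo), hh = dec_cols(rows_hi, f$dec_hi))
}

# Patch record stub with distinguishable pixels.
stub_record <- function(i, label, size = 2L) {
  list(pixels = array(i + seq_len(size * size * 3) / 100, c(size, size, 3)),
       patient_id = paste0("p", i %% 7), image_id = paste0("img", i),
       magnification = "200X", label = label, patch_index = 0L,
       augmentation_tag = "none")
}

# Random valid probability table over a patient/image/patch grid.
random_prob_table <- function(n_patients = 3, n_images = 2, n_patches = 4,
                              seed = 1) {
  set.seed(seed)
  g <- expand.grid(patch_index = seq_len(n_patches) - 1L,
                   image_id = paste0("i", seq_len(n_images)),
                   patient_id = paste0("p", seq_len(n_patients)),
                   stringsAsFactors = FALSE)
  p <- runif(nrow(g))
  out <- data.frame(patient_id = g$patient_id,
                    image_id = paste(g$patient_id, g$image_id, sep = "_"),
                    patch_index = g$patch_index,
                    p_benign = p, p_malignant = 1 - p,
                    stringsAsFactors = FALSE)
  class(out) <- c("prob_table", class(out))
  out
}

# Synthetic-patient cohort table (ids and labels only, no pixels).
stub_cohort <- function(n_benign, n_malignant, images_per_patient = 2L) {
  rows <- list()
  for (cls in c("benign", "malignant")) {
    n <- if (cls == "benign") n_benign else n_malignant
    for (p in seq_len(n)) {
      pid <- sprintf("%s_%02d", substr(cls, 1, 3), p)
      for (i in seq_len(images_per_patient)) {
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, image_id = sprintf("%s_im%d", pid, i),
          magnification = "200X", label = cls, stringsAsFactors = FALSE)
      }
    }
  }
  cohort_index(do.call(rbind, rows))
}

# One shared default synthetic cohort, generated once per test session.
.fixture_env <- new.env()
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(synthetic_cohort_spec())
  .fixture_env$cohort
}

# Tiny separable patch set: smooth class vs high-frequency-textured class.
toy_patchset <- function(n_per_class, size = 32L, seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(0, c(size, size, n, 3L))
  lab <- rep(c("benign", "malignant"), each = n_per_class)
  checker <- outer(sin(2 * pi * seq_len(size) / 4),
                   sin(2 * pi * seq_len(size) / 4))
  for (i in seq_len(n)) {
    base <- 0.6 + 0.2 * resize_bilinear(matrix(rnorm(9), 3, 3), size, size)
    img <- array(rep(base, 3), c(size, size, 3))
    if (lab[i] == "malignant") img <- img + 0.15 * array(rep(checker, 3),
                                                         c(size, size, 3))
    x[, , i, ] <- pmin(pmax(img + rnorm(length(img), sd = 0.01), 0), 1)
  }
  meta <- data.frame(patient_id = paste0("p", seq_len(n)),
                     image_id = paste0("im", seq_len(n)),
                     patch_index = 0L, label = lab,
                     augmentation_tag = "none", stringsAsFactors = FALSE)
  list(x = x, meta = meta)
}
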