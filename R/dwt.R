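# Separable 2-D discrete wavelet decomposition.
#
# One analysis step is implemented as a pair of decimated filtering operators
# applied along the two spatial axes. Building the operators as explicit
# (n/2 x n) matrices keeps the transform linear-algebraic: the forward step is
# two GEMMs per sub-band and the adjoint (needed for backpropagation through
# the attention path) is the transpose. Operators are cached per
# (family, length, boundary).

.op_cache <- new.env(parent = emptyenv())

# Decimated correlation operator: row k computes
#   sum_m f[m] * x[(2(k-1) + m) mod n]   (periodic)
# out-of-range taps are dropped under zero extension. n must be even.
.dwt_operator <- function(filter, n, boundary, which, family) {
  key <- paste(family, n, boundary, which, sep = "|")
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  stopifnot(n %% 2L == 0L)
  m <- length(filter)
  op <- matrix(0, n %/% 2L, n)
  for (k in seq_len(n %/% 2L)) {
    pos <- 2L * (k - 1L) + seq_len(m) - 1L  # 0-based tap positions
    if (boundary == "periodic") {
      cols <- pos %% n + 1L
      for (j in seq_len(m)) op[k, cols[j]] <- op[k, cols[j]] + filter[j]
    } else {                                # zero extension
      keep <- pos < n
      cols <- pos[keep] + 1L
      f <- filter[keep]
      for (j in seq_along(cols)) op[k, cols[j]] <- op[k, cols[j]] + f[j]
    }
  }
  .op_cache[[key]] <- op
  op
}

# Coerce an H x W [x C] input to the internal H x W x N x C layout.
.as_hwnc <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 4L)
    stop("input must be an H x W matrix or an H x W x C array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) x <- array(x, c(d[1], d[2], 1L, d[3]))
  x
}

.restore_arity <- function(a, arity) {
  d <- dim(a)
  if (arity == 2L) matrix(a, d[1], d[2])
  else if (arity == 3L) array(a, c(d[1], d[2], d[4]))
  else a
}

# Apply an operator matrix along spatial dim 1 or 2 of an H x W x N x C array.
.apply_op <- function(a, op, along) {
  if (along == 2L) a <- aperm(a, c(2L, 1L, 3L, 4L))
  d <- dim(a)
  a <- array(op %*% matrix(a, nrow = d[1]), c(nrow(op), d[2], d[3], d[4]))
  if (along == 2L) a <- aperm(a, c(2L, 1L, 3L, 4L))
  a
}

# Replicate the last row/column so both spatial dims are even.
.pad_even <- function(a) {
  d <- dim(a)
  ri <- if (d[1] %% 2L == 1L) c(seq_len(d[1]), d[1]) else seq_len(d[1])
  ci <- if (d[2] %% 2L == 1L) c(seq_len(d[2]), d[2]) else seq_len(d[2])
  if (length(ri) != d[1] || length(ci) != d[2]) a <- a[ri, ci, , , drop = FALSE]
  a
}

# Adjoint of .pad_even: fold the padded row/col gradient back onto the edge.
.unpad_adjoint <- function(d4, orig_h, orig_w) {
  d <- dim(d4)
  if (d[1] > orig_h) {
    d4[orig_h, , , ] <- d4[orig_h, , , ] + d4[orig_h + 1L, , , ]
    d4 <- d4[seq_len(orig_h), , , , drop = FALSE]
  }
  if (d[2] > orig_w) {
    d4[, orig_w, , ] <- d4[, orig_w, , ] + d4[, orig_w + 1L, , ]
    d4 <- d4[, seq_len(orig_w), , , drop = FALSE]
  }
  d4
}

.subband_labels <- c("LL", "LH", "HL", "HH")

# One analysis step on an H x W x N x C array. Returns the four sub-bands
# (each ceil(H/2) x ceil(W/2) x N x C) plus what the adjoint needs.
.dwt_step4 <- function(x4, spec) {
  d <- dim(x4)
  if (d[1] < 2L || d[2] < 2L)
    stop("input too small for wavelet decomposition: spatial dims must be >= 2 (got ",
         d[1], " x ", d[2], ")", call. = FALSE)
  xp <- .pad_even(x4)
  dp <- dim(xp)
  f <- spec$filters
  lo_r <- .dwt_operator(f$dec_lo, dp[1], spec$boundary, "lo", spec$family)
  hi_r <- .dwt_operator(f$dec_hi, dp[1], spec$boundary, "hi", spec$family)
  lo_c <- .dwt_operator(f$dec_lo, dp[2], spec$boundary, "lo", spec$family)
  hi_c <- .dwt_operator(f$dec_hi, dp[2], spec$boundary, "hi", spec$family)
  a <- .apply_op(xp, lo_r, 1L)   # low along rows (height axis)
  dtl <- .apply_op(xp, hi_r, 1L) # high along rows
  bands <- list(
    LL = .apply_op(a, lo_c, 2L),
    LH = .apply_op(a, hi_c, 2L),
    HL = .apply_op(dtl, lo_c, 2L),
    HH = .apply_op(dtl, hi_c, 2L)
  )
  list(bands = bands, orig_h = d[1], orig_w = d[2],
       ops = list(lo_r = lo_r, hi_r = hi_r, lo_c = lo_c, hi_c = hi_c))
}

# Adjoint of (one analysis step restricted to one sub-band).
.dwt_band_adjoint <- function(dband, step, label) {
  ops <- step$ops
  row_op <- if (label %in% c("LL", "LH")) ops$lo_r else ops$hi_r
  col_op <- if (label %in% c("LL", "HL")) ops$lo_c else ops$hi_c
  g <- .apply_op(dband, t(col_op), 2L)
  g <- .apply_op(g, t(row_op), 1L)
  .unpad_adjoint(g, step$orig_h, step$orig_w)
}

#' Single-level 2-D wavelet decomposition
#'
#' Decomposes a feature map into its four wavelet sub-bands (approximation
#' `LL` and detail bands `LH`, `HL`, `HH`) by separable filtering and dyadic
#' downsampling, applied independently per channel. The first letter of a
#' band label refers to the filter applied along rows (height), the second
#' along columns (width). Sub-band spatial dimensions are
#' `ceiling(H/2) x ceiling(W/2)`; odd-sized inputs are edge-padded by one
#' row/column at the bottom/right before decomposition.
#'
#' @param x An `H x W` matrix or `H x W x C` array of finite values.
#' @param spec A [wavelet_spec()].
#' @return An object of class `subband_quad`: a list with elements `ll`,
#'   `lh`, `hl`, `hh` (same arity as the input), `parent_shape`, `family`
#'   and `boundary`.
#' @examples
#' q <- dwt2_single(matrix(1, 4, 4), wavelet_spec("haar"))
#' q$ll  # constant 2.0: Haar low-pass doubles a constant per 2-D step
#' @export
dwt2_single <- function(x, spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  if (!all(is.finite(x)))
    stop("input contains non-finite values", call. = FALSE)
  arity <- length(dim(x))
  if (is.null(dim(x))) stop("input must have dim (matrix or array)", call. = FALSE)
  x4 <- .as_hwnc(x)
  step <- .dwt_step4(x4, spec)
  parent <- dim(x)
  structure(list(
    ll = .restore_arity(step$bands$LL, arity),
    lh = .restore_arity(step$bands$LH, arity),
    hl = .restore_arity(step$bands$HL, arity),
    hh = .restore_arity(step$bands$HH, arity),
    parent_shape = parent, family = spec$family, boundary = spec$boundary
  ), class = "subband_quad")
}

.energy_fun <- function(mode) {
  switch(mode,
         "raw-mean" = function(v) mean(v),
         "abs-mean" = function(v) mean(abs(v)),
         "squared-mean" = function(v) mean(v^2),
         stop("unknown energy mode: ", mode, call. = FALSE))
}

#' Sub-band energies
#'
#' Computes the energy score of each sub-band of a decomposition step as the
#' mean of its coefficients (`raw-mean`, the default convention), of their
#' absolute values (`abs-mean`) or of their squares (`squared-mean`). For
#' multi-channel input the score is additionally averaged over channels, so
#' one scalar per sub-band guides the selection.
#'
#' @param quad A `subband_quad` from [dwt2_single()].
#' @param energy_mode `"raw-mean"`, `"abs-mean"` or `"squared-mean"`.
#' @return Named numeric vector with entries `LL`, `LH`, `HL`, `HH`.
#' @export
subband_energy <- function(quad, energy_mode = "raw-mean") {
  stopifnot(inherits(quad, "subband_quad"))
  f <- .energy_fun(energy_mode)
  c(LL = f(quad$ll), LH = f(quad$lh), HL = f(quad$hl), HH = f(quad$hh))
}

#' Dominant sub-band of a decomposition step
#'
#' Selects the sub-band with the highest energy. Ties are broken by the fixed
#' precedence `LL > LH > HL > HH`.
#'
#' @inheritParams subband_energy
#' @return A list with `label` (one of `"LL"`, `"LH"`, `"HL"`, `"HH"`),
#'   `coefficients` (the selected array) and `energies`.
#' @export
dominant_subband <- function(quad, energy_mode = "raw-mean") {
  e <- subband_energy(quad, energy_mode)
  lab <- .subband_labels[which.max(e)]  # which.max keeps first max: LL>LH>HL>HH
  coef <- switch(lab, LL = quad$ll, LH = quad$lh, HL = quad$hl, HH = quad$hh)
  list(label = lab, coefficients = coef, energies = e)
}

#' Write the analysis filter tables as JSON
#'
#' Serializes the filter coefficient tables of all supported families for
#' external inspection.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_tables <- function(path) {
  jsonlite::write_json(.wavelet_filter_table, path, digits = NA, pretty = TRUE)
  invisible(path)
}
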