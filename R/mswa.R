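# Multi-scale wavelet attention (MSWA).
#
# One block: recursively decompose the feature map, keep the sub-band with
# the highest energy at each level, bilinearly upsample the final sub-band
# back to the input resolution, align channels with a 1x1 convolution, and
# add the result to the input (residual fusion). The sub-band selection is a
# discrete argmax: under autodiff it is treated as a constant of the forward
# pass (straight-through), so gradients flow through the selected path only
# and the selection is recomputed at every forward pass.

# Per-sample energies of a band array (h, w, N, C): mean over space and
# channels, per the chosen convention.
.band_energies <- function(band, mode) {
  d <- dim(band)
  m <- matrix(aperm(band, c(1L, 2L, 4L, 3L)), ncol = d[3])
  switch(mode,
         "raw-mean" = colMeans(m),
         "abs-mean" = colMeans(abs(m)),
         "squared-mean" = colMeans(m * m))
}

# Batched MSWA forward on an H x W x N x C array. w is the C x C alignment
# matrix, b the length-C bias.
.mswa_fwd <- function(x4, spec, w, b) {
  d <- dim(x4)
  if (d[1] < 2^spec$levels || d[2] < 2^spec$levels)
    stop("feature map ", d[1], " x ", d[2], " too small for ", spec$levels,
         " decomposition level(s)", call. = FALSE)
  cur <- x4
  lvls <- vector("list", spec$levels)
  for (l in seq_len(spec$levels)) {
    step <- .dwt_step4(cur, spec)
    e <- rbind(LL = .band_energies(step$bands$LL, spec$energy),
               LH = .band_energies(step$bands$LH, spec$energy),
               HL = .band_energies(step$bands$HL, spec$energy),
               HH = .band_energies(step$bands$HH, spec$energy))
    sel <- apply(e, 2L, which.max)           # first max: LL > LH > HL > HH
    bd <- dim(step$bands$LL)
    nxt <- array(0, bd)
    for (n in seq_len(bd[3]))
      nxt[, , n, ] <- step$bands[[sel[n]]][, , n, ]
    step$bands <- NULL                        # backward needs ops/dims only
    lvls[[l]] <- list(step = step, sel = sel, energies = e)
    cur <- nxt
  }
  rs <- resize_fwd(cur, d[1], d[2])
  hwn <- d[1] * d[2] * d[3]
  zm <- matrix(rs$out, hwn, d[4])
  att <- array(sweep(zm %*% w, 2L, b, `+`), d)
  list(out = x4 + att,
       cache = list(lvls = lvls, rs = rs$cache, zm = zm, d = d, w = w))
}

.mswa_bwd <- function(dy, cache) {
  d <- cache$d
  hwn <- d[1] * d[2] * d[3]
  dm <- matrix(dy, hwn, d[4])
  dw <- crossprod(cache$zm, dm)
  db <- colSums(dm)
  dz <- array(tcrossprod(dm, cache$w), d)
  dcur <- resize_bwd(dz, cache$rs)
  for (l in rev(seq_along(cache$lvls))) {
    lv <- cache$lvls[[l]]
    st <- lv$step
    dprev <- array(0, c(st$orig_h, st$orig_w, d[3], d[4]))
    for (lab_i in unique(lv$sel)) {
      idx <- which(lv$sel == lab_i)
      g <- .dwt_band_adjoint(dcur[, , idx, , drop = FALSE], st,
                             .subband_labels[lab_i])
      dprev[, , idx, ] <- g
    }
    dcur <- dprev
  }
  list(dx = dy + dcur, dw = dw, db = db)
}

#' MSWA block configuration
#'
#' @param channels Channel count `C` of the residual stage the block is
#'   attached to.
#' @param spec A [wavelet_spec()] (family, levels, boundary, energy mode).
#' @param interpolation Upsampling mode; only `"bilinear"` is provided.
#' @return An object of class `mswa_config`.
#' @export
mswa_config <- function(channels, spec = wavelet_spec("haar"),
                        interpolation = "bilinear") {
  stopifnot(inherits(spec, "wavelet_spec"))
  interpolation <- match.arg(interpolation, "bilinear")
  channels <- as.integer(channels)
  if (is.na(channels) || channels < 1L)
    stop("channels must be a positive integer", call. = FALSE)
  structure(list(channels = channels, spec = spec,
                 interpolation = interpolation),
            class = "mswa_config")
}

#' Recursive dominant-sub-band selection
#'
#' Applies `spec$levels` analysis steps, each time keeping only the sub-band
#' with the highest energy, so the spatial size is halved per level without
#' any additional downsampling.
#'
#' @param x An `H x W` matrix or `H x W x C` feature map with
#'   `H, W >= 2^levels`.
#' @param spec A [wavelet_spec()].
#' @return A list of class `selection_path` with `labels` (length `levels`)
#'   and `final_subband` (`ceiling(H/2^L) x ceiling(W/2^L)` spatial size).
#' @export
recursive_select <- function(x, spec) {
  stopifnot(inherits(spec, "wavelet_spec"))
  d <- dim(x)
  if (is.null(d)) stop("x must be a matrix or array", call. = FALSE)
  if (d[1] < 2^spec$levels || d[2] < 2^spec$levels)
    stop("input ", d[1], " x ", d[2], " too small for ", spec$levels,
         " decomposition level(s)", call. = FALSE)
  arity <- length(d)
  cur <- x
  labels <- character(spec$levels)
  for (l in seq_len(spec$levels)) {
    dom <- dominant_subband(dwt2_single(cur, spec), spec$energy)
    labels[l] <- dom$label
    cur <- dom$coefficients
  }
  structure(list(labels = labels, final_subband = cur), class = "selection_path")
}

#' Apply one MSWA block to a feature map
#'
#' Computes `y = x + conv1x1(upsample(select(x)))`: recursive dominant
#' sub-band selection, one direct bilinear resize from the final level back
#' to `H x W`, channel alignment by a 1x1 convolution with bias, and residual
#' addition. With a zero alignment convolution the block is exactly the
#' identity.
#'
#' @param x An `H x W x C` array (or `H x W` matrix for `C = 1`).
#' @param block An [mswa_config()].
#' @param align_weights `C x C` matrix of 1x1-convolution weights (input
#'   channels in rows).
#' @param align_bias Length-`C` bias vector (default zeros).
#' @return Array of the same shape as `x`.
#' @export
mswa_forward <- function(x, block, align_weights,
                         align_bias = numeric(block$channels)) {
  stopifnot(inherits(block, "mswa_config"))
  arity <- length(dim(x))
  x4 <- .as_hwnc(x)
  d <- dim(x4)
  if (d[4] != block$channels)
    stop("channel mismatch: input has ", d[4], " channels, block expects ",
         block$channels, call. = FALSE)
  if (!is.matrix(align_weights) || any(dim(align_weights) != block$channels))
    stop("align_weights must be a ", block$channels, " x ", block$channels,
         " matrix", call. = FALSE)
  .restore_arity(.mswa_fwd(x4, block$spec, align_weights, align_bias)$out,
                 arity)
}
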