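# Gradient-weighted class activation mapping over a residual-stage output.

.cam_layers <- paste0("stage", 1:4)

#' Grad-CAM attribution map
#'
#' Computes the class activation map of a patch at a chosen residual-stage
#' output (taken before that stage's MSWA block): the gradient of the class
#' score with respect to the stage activations is globally averaged per
#' channel to give weights `alpha_c`, and the map is
#' `ReLU(sum_c alpha_c * A_c)`. The raw map is bilinearly resized to the
#' patch size and min-max normalized to `[0, 1]`.
#'
#' @param model An `mswa_model`.
#' @param patch `H x W x 3` array of pixel values in `[0, 1]`.
#' @param target_class `"malignant"`, `"benign"`, or a class index.
#' @param layer_selector One of `"stage1"` ... `"stage4"` (default
#'   `"stage4"`, the last residual stage).
#' @param image Optional image to blend the heatmap over (defaults to the
#'   patch itself).
#' @param blend Heatmap opacity for the overlay (default 0.4).
#' @return An object of class `cam_result`: list with `weights` (per-channel
#'   `alpha_c`), `raw_map` (stage-resolution, non-negative),
#'   `normalized_map` (patch-size, in `[0, 1]`, max 1 whenever the raw map
#'   has a positive entry), `overlay` (RGB blend) and `target_class`.
#' @export
gradcam <- function(model, patch, target_class = "malignant",
                    layer_selector = "stage4", image = NULL, blend = 0.4) {
  stopifnot(inherits(model, "mswa_model"))
  if (!layer_selector %in% .cam_layers)
    stop("unknown layer selector '", layer_selector, "'; available: ",
         paste(.cam_layers, collapse = ", "), call. = FALSE)
  s <- match(layer_selector, .cam_layers)
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L)
    stop("patch must be an H x W x 3 array", call. = FALSE)
  cls <- if (is.character(target_class))
    match(target_class, c("benign", "malignant")) else as.integer(target_class)
  if (is.na(cls) || cls < 1L || cls > model$config$num_classes)
    stop("invalid target class", call. = FALSE)
  x4 <- array(patch, c(d[1], d[2], 1L, 3L))
  fw <- model_forward(model, x4, training = FALSE)
  dlogits <- matrix(0, 1L, model$config$num_classes)
  dlogits[1L, cls] <- 1
  bw <- model_backward(model, fw$cache, dlogits)
  a <- fw$stage_feats[[s]]          # (h, w, 1, C)
  g <- bw$dstage[[s]]
  hd <- dim(a)
  alpha <- colMeans(matrix(g, hd[1] * hd[2] * hd[3], hd[4]))
  raw <- matrix(pmax(matrix(a, hd[1] * hd[2], hd[4]) %*% alpha, 0),
                hd[1], hd[2])
  up <- resize_bilinear(raw, d[1], d[2])
  mx <- max(up)
  norm <- if (mx > 0) up / mx else up * 0
  if (is.null(image)) image <- patch
  structure(list(weights = alpha, raw_map = raw, normalized_map = norm,
                 overlay = overlay(norm, image, blend = blend),
                 target_class = cls, layer = layer_selector),
            class = "cam_result")
}

# Piecewise-linear jet-style colormap on [0, 1].
.heat_rgb <- function(v) {
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  list(r = clamp01(1.5 - abs(4 * v - 3)),
       g = clamp01(1.5 - abs(4 * v - 2)),
       b = clamp01(1.5 - abs(4 * v - 1)))
}

#' Blend an attribution heatmap over an image
#'
#' Applies a jet-style colormap to a `[0, 1]` map and alpha-blends it over
#' the image: `out = (1 - blend) * image + blend * heat`.
#'
#' @param normalized_map `H x W` matrix with values in `[0, 1]`.
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @param blend Heatmap opacity (default 0.4).
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
overlay <- function(normalized_map, image, blend = 0.4) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("image must be H x W x 3", call. = FALSE)
  if (!all(dim(normalized_map) == d[1:2]))
    stop("map is ", paste(dim(normalized_map), collapse = " x "),
         " but image is ", d[1], " x ", d[2], call. = FALSE)
  if (min(normalized_map) < 0 || max(normalized_map) > 1)
    stop("normalized map must lie in [0, 1]", call. = FALSE)
  heat <- .heat_rgb(as.vector(normalized_map))
  out <- image * (1 - blend)
  out[, , 1] <- out[, , 1] + blend * matrix(heat$r, d[1], d[2])
  out[, , 2] <- out[, , 2] + blend * matrix(heat$g, d[1], d[2])
  out[, , 3] <- out[, , 3] + blend * matrix(heat$b, d[1], d[2])
  out
}
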