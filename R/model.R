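# 18-layer residual backbone with optional MSWA blocks after each stage.
#
# Architecture: 7x7 stride-2 stem convolution + batch norm + ReLU + 3x3
# stride-2 max pooling, four stages of two basic residual blocks with channel
# widths (64, 128, 256, 512) (times an optional width multiplier), global
# average pooling and a linear head. Convolutions carry no bias (batch norm
# follows each); the head carries one. An MSWA block, when enabled for a
# stage, is applied to the stage output; its 1x1 alignment convolution is
# zero-initialized so an MSWA network starts as the exact plain backbone.

.base_widths <- c(64L, 128L, 256L, 512L)

#' Model configuration
#'
#' @param num_classes Number of output classes (2 for benign/malignant; 1000
#'   for the canonical classification head used in parameter-count
#'   comparisons).
#' @param mswa `NULL` for the plain backbone; a single [wavelet_spec()]
#'   applied after every stage; or a list of four entries (one per stage,
#'   `NULL` to skip a stage).
#' @param width_multiplier Scales the stage widths (64, 128, 256, 512);
#'   reduced widths are intended for CPU-scale experiments and are not part
#'   of the reference architecture.
#' @param input_size Nominal square input size in pixels (the network itself
#'   is fully convolutional down to the pooled head and accepts any input
#'   large enough for its strides); the training pipeline resizes patches to
#'   this size.
#' @param pretrained_init Placeholder flag for transfer-learned weights;
#'   must be `FALSE` here (no weight download), random initialization is
#'   used.
#' @return An object of class `model_config`.
#' @export
model_config <- function(num_classes = 2L, mswa = NULL, width_multiplier = 1,
                         input_size = 224L, pretrained_init = FALSE) {
  if (isTRUE(pretrained_init))
    stop("pretrained initialization is not available in this build", call. = FALSE)
  widths <- pmax(1L, as.integer(round(.base_widths * width_multiplier)))
  if (inherits(mswa, "wavelet_spec")) mswa <- rep(list(mswa), 4L)
  if (!is.null(mswa)) {
    if (!is.list(mswa) || length(mswa) != 4L)
      stop("mswa must be NULL, a wavelet_spec, or a list of 4 per-stage entries",
           call. = FALSE)
    ok <- vapply(mswa, function(m) is.null(m) || inherits(m, "wavelet_spec"),
                 logical(1))
    if (!all(ok)) stop("each mswa entry must be NULL or a wavelet_spec",
                       call. = FALSE)
  }
  structure(list(num_classes = as.integer(num_classes), mswa = mswa,
                 width_multiplier = width_multiplier, widths = widths,
                 input_size = as.integer(input_size)),
            class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW (decoupled weight
#' decay 0.01) at an initial learning rate of 3e-4, batch size 32,
#' cross-entropy loss, 50 epochs. `epochs` is routinely reduced for
#' CPU-scale experiments.
#'
#' @param learning_rate Initial AdamW learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param weight_decay Decoupled weight decay.
#' @param seed Integer seed fixing weight initialization order and data
#'   shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 3e-4, batch_size = 32L,
                         epochs = 50L, weight_decay = 0.01, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

.he_init <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

.bn_params <- function(params, state, name, c) {
  params[[paste0(name, ".gamma")]] <- rep(1, c)
  params[[paste0(name, ".beta")]] <- rep(0, c)
  state[[name]] <- list(running_mean = rep(0, c), running_var = rep(1, c))
  list(params = params, state = state)
}

#' Build an (MSWA-)ResNet-18 model
#'
#' Initializes all learnable parameters. Backbone convolutions use He
#' initialization, batch-norm scales start at 1, and MSWA alignment
#' convolutions start at zero, so a freshly built MSWA model computes
#' exactly the same function as the plain backbone built from the same seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization (optional).
#' @return An object of class `mswa_model`.
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- config$widths
  params <- list()
  state <- list()
  params[["stem.conv"]] <- .he_init(7L, 7L, 3L, w[1])
  r <- .bn_params(params, state, "stem.bn", w[1]); params <- r$params; state <- r$state
  cin <- w[1]
  for (s in 1:4) {
    cout <- w[s]
    for (b in 1:2) {
      pre <- sprintf("stage%d.block%d", s, b)
      stride <- if (s > 1L && b == 1L) 2L else 1L
      bin <- if (b == 1L) cin else cout
      params[[paste0(pre, ".conv1")]] <- .he_init(3L, 3L, bin, cout)
      r <- .bn_params(params, state, paste0(pre, ".bn1"), cout)
      params <- r$params; state <- r$state
      params[[paste0(pre, ".conv2")]] <- .he_init(3L, 3L, cout, cout)
      r <- .bn_params(params, state, paste0(pre, ".bn2"), cout)
      params <- r$params; state <- r$state
      if (b == 1L && (stride == 2L || bin != cout)) {
        params[[paste0(pre, ".down.conv")]] <- .he_init(1L, 1L, bin, cout)
        r <- .bn_params(params, state, paste0(pre, ".down.bn"), cout)
        params <- r$params; state <- r$state
      }
    }
    if (!is.null(config$mswa) && !is.null(config$mswa[[s]])) {
      params[[sprintf("stage%d.mswa.w", s)]] <- matrix(0, cout, cout)
      params[[sprintf("stage%d.mswa.b", s)]] <- rep(0, cout)
    }
    cin <- cout
  }
  params[["fc.w"]] <- matrix(stats::rnorm(w[4] * config$num_classes, sd = 0.01),
                             w[4], config$num_classes)
  params[["fc.b"]] <- rep(0, config$num_classes)
  structure(list(config = config, params = params, bn_state = state),
            class = "mswa_model")
}

#' @export
print.mswa_model <- function(x, ...) {
  cat("mswa_model | widths:", paste(x$config$widths, collapse = "/"),
      "| classes:", x$config$num_classes,
      "| mswa:", if (is.null(x$config$mswa)) "disabled" else "enabled",
      "| parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' Count learnable parameters
#'
#' Exact sum of the lengths of all learnable arrays (convolution kernels,
#' batch-norm scales and shifts, MSWA alignment weights and biases, head
#' weights and bias). Batch-norm running statistics are buffers, not
#' parameters, and are not counted.
#'
#' @param model An `mswa_model`.
#' @return Integer parameter count.
#' @examples
#' \donttest{
#' m <- build_model(model_config(num_classes = 1000), seed = 1)
#' count_parameters(m)  # 11689512 for the plain backbone
#' }
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mswa_model"))
  sum(vapply(model$params, length, integer(1)))
}

.block_fwd <- function(x, params, pre, stride, state, training) {
  has_down <- !is.null(params[[paste0(pre, ".down.conv")]])
  if (has_down) {
    dcv <- conv_fwd(x, params[[paste0(pre, ".down.conv")]], stride, 0L)
    dbn <- bn_fwd(dcv$out, params[[paste0(pre, ".down.bn.gamma")]],
                  params[[paste0(pre, ".down.bn.beta")]],
                  state[[paste0(pre, ".down.bn")]], training)
    state[[paste0(pre, ".down.bn")]] <- dbn$state
    sc <- dbn$out
  } else {
    dcv <- NULL; dbn <- NULL; sc <- x
  }
  c1 <- conv_fwd(x, params[[paste0(pre, ".conv1")]], stride, 1L)
  b1 <- bn_fwd(c1$out, params[[paste0(pre, ".bn1.gamma")]],
               params[[paste0(pre, ".bn1.beta")]],
               state[[paste0(pre, ".bn1")]], training)
  state[[paste0(pre, ".bn1")]] <- b1$state
  r1 <- relu_fwd(b1$out)
  c2 <- conv_fwd(r1$out, params[[paste0(pre, ".conv2")]], 1L, 1L)
  b2 <- bn_fwd(c2$out, params[[paste0(pre, ".bn2.gamma")]],
               params[[paste0(pre, ".bn2.beta")]],
               state[[paste0(pre, ".bn2")]], training)
  state[[paste0(pre, ".bn2")]] <- b2$state
  rout <- relu_fwd(b2$out + sc)
  list(out = rout$out, state = state,
       cache = list(c1 = c1$cache, b1 = b1$cache, m1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, mout = rout$cache,
                    down_c = if (has_down) dcv$cache,
                    down_b = if (has_down) dbn$cache,
                    has_down = has_down, pre = pre))
}

.block_bwd <- function(dy, cache, grads) {
  pre <- cache$pre
  dsum <- relu_bwd(dy, cache$mout)
  b2 <- bn_bwd(dsum, cache$b2)
  grads[[paste0(pre, ".bn2.gamma")]] <- b2$dgamma
  grads[[paste0(pre, ".bn2.beta")]] <- b2$dbeta
  c2 <- conv_bwd(b2$dx, cache$c2)
  grads[[paste0(pre, ".conv2")]] <- c2$dw
  dr1 <- relu_bwd(c2$dx, cache$m1)
  b1 <- bn_bwd(dr1, cache$b1)
  grads[[paste0(pre, ".bn1.gamma")]] <- b1$dgamma
  grads[[paste0(pre, ".bn1.beta")]] <- b1$dbeta
  c1 <- conv_bwd(b1$dx, cache$c1)
  grads[[paste0(pre, ".conv1")]] <- c1$dw
  dx <- c1$dx
  if (cache$has_down) {
    db <- bn_bwd(dsum, cache$down_b)
    grads[[paste0(pre, ".down.bn.gamma")]] <- db$dgamma
    grads[[paste0(pre, ".down.bn.beta")]] <- db$dbeta
    dc <- conv_bwd(db$dx, cache$down_c)
    grads[[paste0(pre, ".down.conv")]] <- dc$dw
    dx <- dx + dc$dx
  } else {
    dx <- dx + dsum
  }
  list(dx = dx, grads = grads)
}

# Full forward pass. x4 is H x W x N x 3 in [0, 1]. Returns logits, the
# cache needed for backward, and the per-stage outputs taken before the MSWA
# block (the Grad-CAM attachment points).
model_forward <- function(model, x4, training = FALSE) {
  p <- model$params
  state <- model$bn_state
  cfg <- model$config
  cache <- list()
  cv <- conv_fwd(x4, p[["stem.conv"]], 2L, 3L)
  bn <- bn_fwd(cv$out, p[["stem.bn.gamma"]], p[["stem.bn.beta"]],
               state[["stem.bn"]], training)
  state[["stem.bn"]] <- bn$state
  rl <- relu_fwd(bn$out)
  mp <- maxpool_fwd(rl$out)
  cache$stem <- list(cv = cv$cache, bn = bn$cache, m = rl$cache, mp = mp$cache)
  h <- mp$out
  stage_feats <- vector("list", 4L)
  for (s in 1:4) {
    stride1 <- if (s > 1L) 2L else 1L
    b1 <- .block_fwd(h, p, sprintf("stage%d.block1", s), stride1, state, training)
    state <- b1$state
    b2 <- .block_fwd(b1$out, p, sprintf("stage%d.block2", s), 1L, state, training)
    state <- b2$state
    h <- b2$out
    stage_feats[[s]] <- h
    mcache <- NULL
    if (!is.null(cfg$mswa) && !is.null(cfg$mswa[[s]])) {
      mw <- .mswa_fwd(h, cfg$mswa[[s]], p[[sprintf("stage%d.mswa.w", s)]],
                      p[[sprintf("stage%d.mswa.b", s)]])
      h <- mw$out
      mcache <- mw$cache
    }
    cache[[sprintf("stage%d", s)]] <- list(b1 = b1$cache, b2 = b2$cache,
                                           mswa = mcache)
  }
  gp <- gap_fwd(h)
  fc <- linear_fwd(gp$out, p[["fc.w"]], p[["fc.b"]])
  cache$gap <- gp$cache
  cache$fc <- fc$cache
  list(logits = fc$out, cache = cache, stage_feats = stage_feats,
       bn_state = state)
}

# Full backward pass from d(logits). Returns parameter gradients and the
# gradient at each stage output (pre-MSWA), used by Grad-CAM.
model_backward <- function(model, cache, dlogits) {
  grads <- list()
  fc <- linear_bwd(dlogits, cache$fc)
  grads[["fc.w"]] <- fc$dw
  grads[["fc.b"]] <- fc$db
  d <- gap_bwd(fc$dx, cache$gap)
  dstage <- vector("list", 4L)
  for (s in 4:1) {
    sc <- cache[[sprintf("stage%d", s)]]
    if (!is.null(sc$mswa)) {
      mb <- .mswa_bwd(d, sc$mswa)
      grads[[sprintf("stage%d.mswa.w", s)]] <- mb$dw
      grads[[sprintf("stage%d.mswa.b", s)]] <- mb$db
      d <- mb$dx
    }
    dstage[[s]] <- d
    r2 <- .block_bwd(d, sc$b2, grads)
    grads <- r2$grads
    r1 <- .block_bwd(r2$dx, sc$b1, grads)
    grads <- r1$grads
    d <- r1$dx
  }
  d <- maxpool_bwd(d, cache$stem$mp)
  d <- relu_bwd(d, cache$stem$m)
  bs <- bn_bwd(d, cache$stem$bn)
  grads[["stem.bn.gamma"]] <- bs$dgamma
  grads[["stem.bn.beta"]] <- bs$dbeta
  cs <- conv_bwd(bs$dx, cache$stem$cv)
  grads[["stem.conv"]] <- cs$dw
  list(grads = grads, dstage = dstage, dx = cs$dx)
}

# Stack a list/array of patches into the batched tensor for given indices.
.batch_tensor <- function(patch_x, idx) {
  patch_x[, , idx, , drop = FALSE]
}

#' Train one model on a patch set
#'
#' Supervised training with cross-entropy loss and AdamW. When a validation
#' patch set is supplied, the parameters of the epoch with the highest
#' patient-level validation accuracy are kept (model selection); otherwise
#' the final epoch's parameters are returned.
#'
#' @param model An `mswa_model` from [build_model()].
#' @param patches A patch set: list with `x` (`H x W x N x 3` array of
#'   pixel values in `[0, 1]`) and `meta` (data frame with `patient_id`,
#'   `image_id`, `patch_index`, `label`).
#' @param cfg A [train_config()].
#' @param val_patches Optional validation patch set for model selection.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained model, with a `history` data frame attached
#'   (`$history`: epoch, loss, train_acc, val_acc).
#' @export
train_fold <- function(model, patches, cfg, val_patches = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "mswa_model"), inherits(cfg, "train_config"))
  meta <- patches$meta
  n <- nrow(meta)
  if (n == 0L) stop("empty training set", call. = FALSE)
  labs <- .label_index(meta$label)
  set.seed(cfg$seed)
  opt <- adamw_init(model$params)
  best_val <- -Inf
  best_params <- NULL
  best_state <- NULL
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     train_acc = numeric(), val_acc = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- .batch_tensor(patches$x, idx)
      yb <- labs[idx]
      fw <- model_forward(model, xb, training = TRUE)
      model$bn_state <- fw$bn_state
      ce <- softmax_ce(fw$logits, yb)
      losses <- c(losses, ce$loss)
      correct <- correct + sum(max.col(ce$probs) == yb)
      bw <- model_backward(model, fw$cache, ce$dlogits)
      stp <- adamw_step(model$params, bw$grads, opt, cfg$learning_rate,
                        weight_decay = cfg$weight_decay)
      model$params <- stp$params
      opt <- stp$state
    }
    val_acc <- NA_real_
    if (!is.null(val_patches)) {
      pt <- predict_probs(model, val_patches)
      val_acc <- .patient_accuracy(pt, val_patches$meta)
      if (val_acc > best_val) {
        best_val <- val_acc
        best_params <- model$params
        best_state <- model$bn_state
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   train_acc = correct / n, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f train_acc %.3f val_acc %s",
                      ep, mean(losses), correct / n,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
  }
  if (!is.null(best_params)) {
    model$params <- best_params
    model$bn_state <- best_state
  }
  model$history <- hist
  model
}

.label_index <- function(label) {
  i <- match(as.character(label), c("benign", "malignant"))
  if (anyNA(i)) stop("labels must be 'benign' or 'malignant'", call. = FALSE)
  i
}

# Patient-level accuracy of a probability table against patch metadata.
.patient_accuracy <- function(prob_table, meta) {
  pp <- aggregate_patient(aggregate_image(prob_table))
  truth <- unique(meta[, c("patient_id", "label")])
  m <- merge(pp, truth, by = "patient_id")
  mean(m$label_pred == m$label)
}

#' Patch-level class probabilities
#'
#' Runs the model in evaluation mode over a patch set and returns the
#' softmax class-probability table keyed by (patient, image, patch).
#'
#' @inheritParams train_fold
#' @param batch_size Inference batch size.
#' @return A `prob_table` data frame with columns `patient_id`, `image_id`,
#'   `patch_index`, `p_benign`, `p_malignant`.
#' @export
predict_probs <- function(model, patches, batch_size = 64L) {
  stopifnot(inherits(model, "mswa_model"))
  meta <- patches$meta
  n <- nrow(meta)
  probs <- matrix(NA_real_, n, 2L)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward(model, .batch_tensor(patches$x, idx), training = FALSE)
    probs[idx, ] <- softmax_probs(fw$logits)
  }
  out <- data.frame(patient_id = meta$patient_id, image_id = meta$image_id,
                    patch_index = meta$patch_index,
                    p_benign = probs[, 1L], p_malignant = probs[, 2L],
                    stringsAsFactors = FALSE)
  class(out) <- c("prob_table", class(out))
  out
}
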