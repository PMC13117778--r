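# Minimal CPU neural-network engine.
#
# Feature maps are numeric arrays in H x W x N x C layout (spatial, batch,
# channel). Convolutions are lowered to GEMM via im2col with cached index
# vectors; all other layers are expressed with vectorized base-R linear
# algebra so the whole network runs on BLAS. Every forward op returns the
# cache its backward pass needs.

.idx_cache <- new.env(parent = emptyenv())

.cache_get <- function(key, builder) {
  hit <- .idx_cache[[key]]
  if (is.null(hit)) {
    hit <- builder()
    .idx_cache[[key]] <- hit
  }
  hit
}

.pad_spatial <- function(x4, p, fill = 0) {
  if (p == 0L) return(x4)
  d <- dim(x4)
  out <- array(fill, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x4
  out
}

conv_fwd <- function(x4, w, stride = 1L, pad = 0L) {
  d <- dim(x4); kd <- dim(w)
  stopifnot(d[4] == kd[3])
  xp <- .pad_spatial(x4, pad)
  dp <- dim(xp)
  oh <- (dp[1] - kd[1]) %/% stride + 1L
  ow <- (dp[2] - kd[2]) %/% stride + 1L
  k <- kd[1] * kd[2] * kd[3]
  # rows (oi, oj, n), cols (u, v, c) with u fastest — matches kernel layout
  xcol <- im2col_taps(as.vector(xp), dim(xp), kd[1], kd[2], stride, oh, ow)
  wmat <- matrix(w, k, kd[4])
  out <- array(xcol %*% wmat, c(oh, ow, d[3], kd[4]))
  list(out = out,
       cache = list(xcol = xcol, wmat = wmat, kd = kd, stride = stride,
                    in_dim = d, pad_dim = dp, pad = pad, k = k,
                    out_dim = c(oh, ow, d[3], kd[4])))
}

conv_bwd <- function(dy, cache) {
  od <- cache$out_dim
  dymat <- matrix(dy, od[1] * od[2] * od[3], od[4])     # (P*N, Cout)
  dw <- array(crossprod(cache$xcol, dymat), cache$kd)
  dxcol <- tcrossprod(dymat, cache$wmat)                # (P*N, K)
  dxp <- array(col2im_taps(dxcol, cache$pad_dim, cache$kd[1], cache$kd[2],
                           cache$stride, od[1], od[2]),
               cache$pad_dim)
  p <- cache$pad; d <- cache$in_dim
  if (p > 0L) dxp <- dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
  list(dx = dxp, dw = dw)
}

bn_fwd <- function(x4, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x4)
  m <- d[1] * d[2] * d[3]
  xm <- matrix(x4, m, d[4])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va
  } else {
    mu <- state$running_mean
    xc <- sweep(xm, 2L, mu)
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = array(y, d), state = state,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    m = m, training = training))
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  dym <- matrix(dy, cache$m, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  if (cache$training) {
    t1 <- sweep(dym, 2L, dbeta / cache$m) -
      sweep(cache$xhat, 2L, dgamma / cache$m, `*`)
    dx <- sweep(t1, 2L, cache$gamma * cache$invstd, `*`)
  } else {
    dx <- sweep(dym, 2L, cache$gamma * cache$invstd, `*`)
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dy, mask) dy * mask

# 3x3 stride-2 max pooling with one-pixel zero... -Inf padding, as in the
# backbone stem.
maxpool_fwd <- function(x4, kh = 3L, kw = 3L, stride = 2L, pad = 1L) {
  d <- dim(x4)
  xp <- .pad_spatial(x4, pad, fill = -Inf)
  dp <- dim(xp)
  oh <- (dp[1] - kh) %/% stride + 1L
  ow <- (dp[2] - kw) %/% stride + 1L
  key <- paste("pool", dp[1], dp[2], d[3], d[4], kh, kw, stride, sep = "|")
  idx <- .cache_get(key, function() {
    kk <- kh * kw
    u <- rep.int(seq_len(kh), kw * oh * ow * d[3] * d[4])
    v <- rep.int(rep(seq_len(kw), each = kh), oh * ow * d[3] * d[4])
    oi <- rep.int(rep(seq_len(oh), each = kk), ow * d[3] * d[4])
    oj <- rep.int(rep(seq_len(ow), each = kk * oh), d[3] * d[4])
    nn <- rep.int(rep(seq_len(d[3]), each = kk * oh * ow), d[4])
    cc <- rep(seq_len(d[4]), each = kk * oh * ow * d[3])
    h <- u + (oi - 1L) * stride
    w <- v + (oj - 1L) * stride
    h + (w - 1L) * dp[1] + (nn - 1L) * (dp[1] * dp[2]) +
      (cc - 1L) * (dp[1] * dp[2] * d[3])
  })
  kk <- kh * kw
  xcol <- matrix(xp[idx], kk)
  y <- xcol[1L, ]
  amax <- rep.int(1L, ncol(xcol))
  for (r in 2:kk) {
    sel <- xcol[r, ] > y
    amax[sel] <- r
    y[sel] <- xcol[r, sel]
  }
  list(out = array(y, c(oh, ow, d[3], d[4])),
       cache = list(idx = idx, amax = amax, kk = kk, pad_dim = dp,
                    in_dim = d, pad = pad))
}

maxpool_bwd <- function(dy, cache) {
  dxp <- numeric(prod(cache$pad_dim))
  idxm <- matrix(cache$idx, cache$kk)
  dyv <- as.vector(dy)
  for (r in seq_len(cache$kk)) {
    sel <- cache$amax == r
    pos <- idxm[r, sel]
    dxp[pos] <- dxp[pos] + dyv[sel]
  }
  dxp <- array(dxp, cache$pad_dim)
  p <- cache$pad; d <- cache$in_dim
  dxp[p + seq_len(d[1]), p + seq_len(d[2]), , , drop = FALSE]
}

gap_fwd <- function(x4) {
  d <- dim(x4)
  y <- matrix(colMeans(matrix(x4, d[1] * d[2])), d[3], d[4])
  list(out = y, cache = d)
}

gap_bwd <- function(dy, d) {
  array(rep(as.vector(dy) / (d[1] * d[2]), each = d[1] * d[2]), d)
}

linear_fwd <- function(x, w, b) {
  list(out = sweep(x %*% w, 2L, b, `+`), cache = list(x = x, w = w))
}

linear_bwd <- function(dy, cache) {
  list(dx = tcrossprod(dy, cache$w), dw = crossprod(cache$x, dy),
       db = colSums(dy))
}

# 1-D bilinear interpolation operator (half-pixel centers, edges clamped),
# valid for both up- and downscaling.
.interp_mat <- function(nin, nout) {
  key <- paste("interp", nin, nout, sep = "|")
  .cache_get(key, function() {
    m <- matrix(0, nout, nin)
    scale <- nin / nout
    for (i in seq_len(nout)) {
      src <- (i - 0.5) * scale - 0.5          # 0-based source coordinate
      i0 <- floor(src)
      fr <- src - i0
      i0c <- min(max(i0, 0), nin - 1)
      i1c <- min(max(i0 + 1, 0), nin - 1)
      m[i, i0c + 1] <- m[i, i0c + 1] + (1 - fr)
      m[i, i1c + 1] <- m[i, i1c + 1] + fr
    }
    m
  })
}

resize_fwd <- function(x4, oh, ow) {
  d <- dim(x4)
  rh <- .interp_mat(d[1], oh)
  rw <- .interp_mat(d[2], ow)
  out <- .apply_op(.apply_op(x4, rh, 1L), rw, 2L)
  list(out = out, cache = list(rh = rh, rw = rw))
}

resize_bwd <- function(dy, cache) {
  .apply_op(.apply_op(dy, t(cache$rw), 2L), t(cache$rh), 1L)
}

#' Bilinear resize of an image or feature map
#'
#' Resizes the two leading spatial dimensions by separable bilinear
#' interpolation (half-pixel sample centers, clamped edges).
#'
#' @param x An `H x W` matrix or `H x W x C` array.
#' @param height,width Output spatial size.
#' @return The resized matrix/array.
#' @export
resize_bilinear <- function(x, height, width) {
  arity <- length(dim(x))
  x4 <- .as_hwnc(x)
  .restore_arity(resize_fwd(x4, height, width)$out, arity)
}

softmax_probs <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

softmax_ce <- function(logits, labels) {
  p <- softmax_probs(logits)
  n <- nrow(logits)
  picked <- p[cbind(seq_len(n), labels)]
  dlogits <- p
  dlogits[cbind(seq_len(n), labels)] <- picked - 1
  list(loss = -mean(log(pmax(picked, 1e-12))), dlogits = dlogits / n,
       probs = p)
}

adamw_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One decoupled-weight-decay Adam step over a named flat parameter list.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (upd + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
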