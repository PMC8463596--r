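
# Convolutional backbone with explicit im2col forward and backward passes.
# The package trains its networks with hand-written backpropagation on plain
# R arrays; matrix products carry all heavy arithmetic.

# Convolution padding. "zero" is the conventional choice; "replicate"
# (edge) padding removes the absolute-position signature that zero borders
# give edge cells, at some cost in learning speed.
pad_array_ <- function(x, p, mode = "zero") {
  if (p == 0) return(x)
  d <- dim(x)
  if (mode == "zero") {
    out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
    out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
    return(out)
  }
  ri <- c(rep(1L, p), seq_len(d[1]), rep(d[1], p))
  ci <- c(rep(1L, p), seq_len(d[2]), rep(d[2], p))
  x[ri, ci, , drop = FALSE]
}

# Fold the gradient of a padded array back onto the source pixels.
unpad_grad_ <- function(dxp, p, hi, wi, mode = "zero") {
  if (p == 0) return(dxp)
  if (mode == "zero")
    return(dxp[(p + 1):(p + hi), (p + 1):(p + wi), , drop = FALSE])
  core <- dxp[(p + 1):(p + hi), (p + 1):(p + wi), , drop = FALSE]
  for (r in seq_len(p)) {
    core[1, , ] <- core[1, , ] + dxp[r, (p + 1):(p + wi), ]
    core[hi, , ] <- core[hi, , ] + dxp[hi + p + r, (p + 1):(p + wi), ]
  }
  for (cc in seq_len(p)) {
    core[, 1, ] <- core[, 1, ] + dxp[(p + 1):(p + hi), cc, ]
    core[, wi, ] <- core[, wi, ] + dxp[(p + 1):(p + hi), wi + p + cc, ]
  }
  for (r in seq_len(p)) {
    for (cc in seq_len(p)) {
      core[1, 1, ] <- core[1, 1, ] + dxp[r, cc, ]
      core[1, wi, ] <- core[1, wi, ] + dxp[r, wi + p + cc, ]
      core[hi, 1, ] <- core[hi, 1, ] + dxp[hi + p + r, cc, ]
      core[hi, wi, ] <- core[hi, wi, ] + dxp[hi + p + r, wi + p + cc, ]
    }
  }
  core
}

# im2col: (ho*wo) x (ci*k*k) patch matrix; column order is channel fastest,
# then kernel row, then kernel column (matches aperm(W, c(3,1,2,4)) below).
im2col_ <- function(xp, k, stride, ho, wo) {
  ci <- dim(xp)[3]
  base_i <- (seq_len(ho) - 1L) * stride
  base_j <- (seq_len(wo) - 1L) * stride
  blocks <- vector("list", k * k)
  n <- 1L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      blocks[[n]] <- matrix(xp[base_i + ki, base_j + kj, , drop = FALSE],
                            ho * wo, ci)
      n <- n + 1L
    }
  }
  do.call(cbind, blocks)
}

conv_forward_ <- function(x, W, b, stride = 2L, pad = 1L,
                          pad_mode = "zero") {
  k <- dim(W)[1]
  ci <- dim(W)[3]; co <- dim(W)[4]
  stopifnot(dim(x)[3] == ci)
  hi <- dim(x)[1]; wi <- dim(x)[2]
  ho <- (hi + 2L * pad - k) %/% stride + 1L
  wo <- (wi + 2L * pad - k) %/% stride + 1L
  xp <- pad_array_(x, pad, pad_mode)
  cols <- im2col_(xp, k, stride, ho, wo)
  Wmat <- matrix(aperm(W, c(3, 1, 2, 4)), ci * k * k, co)
  out_mat <- sweep(cols %*% Wmat, 2L, b, "+")
  list(out = array(out_mat, c(ho, wo, co)),
       cache = list(cols = cols, Wmat = Wmat, dims = dim(x),
                    k = k, stride = stride, pad = pad,
                    pad_mode = pad_mode, ho = ho, wo = wo))
}

conv_backward_ <- function(dout, cache) {
  k <- cache$k; stride <- cache$stride; pad <- cache$pad
  ho <- cache$ho; wo <- cache$wo
  hi <- cache$dims[1]; wi <- cache$dims[2]; ci <- cache$dims[3]
  co <- ncol(cache$Wmat)
  dmat <- matrix(dout, ho * wo, co)
  dW_flat <- crossprod(cache$cols, dmat)              # (ci*k*k) x co
  dW <- aperm(array(dW_flat, c(ci, k, k, co)), c(2, 3, 1, 4))
  db <- colSums(dmat)
  dcols <- dmat %*% t(cache$Wmat)                     # (ho*wo) x (ci*k*k)
  dxp <- array(0, c(hi + 2L * pad, wi + 2L * pad, ci))
  base_i <- (seq_len(ho) - 1L) * stride
  base_j <- (seq_len(wo) - 1L) * stride
  n <- 1L
  for (kj in seq_len(k)) {
    for (ki in seq_len(k)) {
      block <- array(dcols[, ((n - 1L) * ci + 1L):(n * ci)], c(ho, wo, ci))
      dxp[base_i + ki, base_j + kj, ] <-
        dxp[base_i + ki, base_j + kj, , drop = FALSE] + block
      n <- n + 1L
    }
  }
  list(dx = unpad_grad_(dxp, pad, hi, wi, cache$pad_mode), dW = dW, db = db)
}

# Backbone registry. Each entry maps a model_config to a plan of 3x3 conv
# layers (ReLU after every layer) turning H x W x 3 into h x w x C: "tiny"
# uses one stride-2 conv per halving; "tiny2" adds a stride-1 conv at every
# resolution level for sharper shape features; "deep" is the wide full-scale
# variant of "tiny2".
backbone_plan_ <- function(name, n_blocks, C) {
  widths <- switch(name,
    tiny = c(16, 32, 64, 128, 256),
    tiny2 = c(16, 32, 64, 128, 256),
    deep = c(32, 64, 128, 256, 512),
    stop_field("backbone", sprintf("unknown backbone '%s'", name)))
  ch <- widths[seq_len(n_blocks)]
  ch[n_blocks] <- C
  if (name %in% c("tiny2", "deep")) {
    # a stride-1 refinement conv at every level; the deep-level ones carry
    # the margin/shape capacity that separates spiculated from smooth
    # lesions, and the saliency L1 penalty (not a restricted receptive
    # field) is what keeps the maps spatially aligned
    list(channels = rep(ch, each = 2), strides = rep(c(2L, 1L), n_blocks))
  } else {
    list(channels = ch, strides = rep(2L, n_blocks))
  }
}

backbone_forward_ <- function(x, conv_layers, strides, pad_mode = "zero") {
  caches <- vector("list", length(conv_layers))
  for (l in seq_along(conv_layers)) {
    cv <- conv_forward_(x, conv_layers[[l]]$W, conv_layers[[l]]$b,
                        stride = strides[l], pad_mode = pad_mode)
    pre <- cv$out
    x <- pre * (pre > 0)                               # ReLU
    caches[[l]] <- list(conv = cv$cache, mask = pre > 0)
  }
  list(out = x, caches = caches)
}

backbone_backward_ <- function(dout, caches) {
  grads <- vector("list", length(caches))
  for (l in rev(seq_along(caches))) {
    dout <- dout * caches[[l]]$mask
    bk <- conv_backward_(dout, caches[[l]]$conv)
    grads[[l]] <- list(W = bk$dW, b = bk$db)
    dout <- bk$dx
  }
  list(dx = dout, grads = grads)
}
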