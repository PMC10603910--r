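# Differentiable layer operations. Each op computes its value from node-or-array
# inputs; when `tape` is non-NULL it records a node with the matching
# vector-Jacobian product. Feature maps are (H, W, C, N) arrays.

op_conv2d <- function(tape, x, w, b, k = 3L) {
  xv <- .val(x); wv <- .val(w); bv <- .val(b)
  y <- cpp_conv2d_fw(xv, wv, bv, k)
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(x, w, b), function(g) {
    bw <- cpp_conv2d_bw(xv, wv, g, k)
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_relu <- function(tape, x) {
  xv <- .val(x)
  y <- xv * (xv > 0)
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(x), function(g) list(g * (xv > 0)))
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-.val(x)))
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

op_maxpool2 <- function(tape, x) {
  xv <- .val(x)
  fw <- cpp_maxpool2_fw(xv)
  if (is.null(tape)) return(fw$y)
  d <- dim(xv)
  tape_node(tape, fw$y, list(x), function(g) {
    list(cpp_maxpool2_bw(fw$idx, g, d[1], d[2]))
  })
}

op_upsample_bilinear <- function(tape, x, Ho, Wo) {
  xv <- .val(x)
  y <- cpp_resize_bilinear_fw(xv, as.integer(Ho), as.integer(Wo))
  if (is.null(tape)) return(y)
  d <- dim(xv)
  tape_node(tape, y, list(x), function(g) {
    list(cpp_resize_bilinear_bw(g, d[1], d[2]))
  })
}

op_concat_channels <- function(tape, a, b) {
  av <- .val(a); bv <- .val(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  ia <- seq_len(da[3]); ib <- da[3] + seq_len(db[3])
  y[, , ia, ] <- av
  y[, , ib, ] <- bv
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(a, b), function(g) {
    list(g[, , ia, , drop = FALSE], g[, , ib, , drop = FALSE])
  })
}

# global average pooling: (H,W,C,N) -> (C,N) matrix of spatial means
op_gap <- function(tape, x) {
  xv <- .val(x)
  d <- dim(xv)
  hw <- d[1] * d[2]
  m <- matrix(colMeans(matrix(xv, nrow = hw)), d[3], d[4])
  if (is.null(tape)) return(m)
  tape_node(tape, m, list(x), function(g) {
    gx <- array(rep(as.vector(g) / hw, each = hw), dim = d)
    list(gx)
  })
}

# fully-connected on (Cin, N) channel descriptors: y = W x + b
op_dense <- function(tape, x, w, b) {
  xv <- .val(x); wv <- .val(w); bv <- .val(b)
  y <- wv %*% xv + bv
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(x, w, b), function(g) {
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

# per-(channel, sample) rescaling: y[h,w,c,n] = x[h,w,c,n] * s[c,n]
op_scale_channels <- function(tape, x, s) {
  xv <- .val(x); sv <- .val(s)
  d <- dim(xv)
  hw <- d[1] * d[2]
  y <- xv * array(rep(as.vector(sv), each = hw), dim = d)
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(x, s), function(g) {
    gx <- g * array(rep(as.vector(sv), each = hw), dim = d)
    gs <- matrix(colSums(matrix(g * xv, nrow = hw)), d[3], d[4])
    list(gx, gs)
  })
}

# batch normalisation over (H, W, N) per channel; running stats live in `state`
# (an environment) under `name`. Training mode uses batch statistics and
# updates the running estimates; inference uses the running estimates.
op_batchnorm <- function(tape, x, gamma, beta, state, name, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- .val(x); gv <- .val(gamma); bv <- .val(beta)
  d <- dim(xv)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m_elem <- hw * N
  xr <- array(xv, c(hw, C, N))
  if (training) {
    mu <- numeric(C); va <- numeric(C)
    for (ch in seq_len(C)) {
      v <- xr[, ch, ]
      mu[ch] <- mean(v)
      va[ch] <- mean((v - mu[ch])^2)
    }
    rs <- state[[name]]
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    state[[name]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                          var  = (1 - momentum) * rs$var + momentum * va)
  } else {
    rs <- state[[name]]
    if (is.null(rs)) rs <- list(mean = numeric(C), var = rep(1, C))
    mu <- rs$mean; va <- rs$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- array(0, c(hw, C, N))
  yr <- array(0, c(hw, C, N))
  for (ch in seq_len(C)) {
    xhat[, ch, ] <- (xr[, ch, ] - mu[ch]) * invstd[ch]
    yr[, ch, ] <- gv[ch] * xhat[, ch, ] + bv[ch]
  }
  y <- array(yr, d)
  if (is.null(tape)) return(y)
  tape_node(tape, y, list(x, gamma, beta), function(g) {
    gr <- array(g, c(hw, C, N))
    ggamma <- numeric(C); gbeta <- numeric(C)
    gxr <- array(0, c(hw, C, N))
    for (ch in seq_len(C)) {
      gch <- gr[, ch, ]; xh <- xhat[, ch, ]
      ggamma[ch] <- sum(gch * xh)
      gbeta[ch] <- sum(gch)
      if (training) {
        gh <- gch * gv[ch]
        gxr[, ch, ] <- invstd[ch] / m_elem *
          (m_elem * gh - sum(gh) - xh * sum(gh * xh))
      } else {
        gxr[, ch, ] <- gch * gv[ch] * invstd[ch]
      }
    }
    list(array(gxr, d), ggamma, gbeta)
  })
}

# channel-wise softmax, differentiable (used where probability maps feed the
# auto-context cascade during end-to-end fine-tuning)
op_softmax <- function(tape, x) {
  q <- softmax_channels(.val(x))
  if (is.null(tape)) return(q)
  d <- dim(q)
  hw <- d[1] * d[2]
  tape_node(tape, q, list(x), function(g) {
    qr <- array(q, c(hw, d[3], d[4]))
    gr <- array(g, c(hw, d[3], d[4]))
    dot <- array(0, c(hw, d[4]))
    for (ch in seq_len(d[3])) dot <- dot + qr[, ch, ] * gr[, ch, ]
    gx <- array(0, c(hw, d[3], d[4]))
    for (ch in seq_len(d[3])) {
      gx[, ch, ] <- qr[, ch, ] * (gr[, ch, ] - dot)
    }
    list(array(gx, d))
  })
}

# numerically stable channel softmax on a plain (H,W,C,N) array
softmax_channels <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xr <- array(x, c(hw, C, N))
  m <- xr[, 1, ]
  if (C > 1) for (ch in 2:C) m <- pmax(m, xr[, ch, ])
  s <- 0
  for (ch in seq_len(C)) {
    xr[, ch, ] <- exp(xr[, ch, ] - m)
    s <- s + xr[, ch, ]
  }
  for (ch in seq_len(C)) xr[, ch, ] <- xr[, ch, ] / s
  array(xr, d)
}

# fused softmax + multi-class cross-entropy on logits.
# Loss = mean over pixels of -log_base(q_true + eps); gradient uses the exact
# softmax/cross-entropy form (q - onehot), scaled for the log base.
op_softmax_xent <- function(tape, logits, target, base = 2, eps = 1e-12) {
  lv <- .val(logits)
  d <- dim(lv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  tv <- as.integer(target)
  if (any(tv < 0L | tv >= C)) {
    bad <- tv[tv < 0L | tv >= C][1]
    stop("target label ", bad, " outside [0, ", C, ")")
  }
  q <- softmax_channels(lv)
  npix <- H * W * N
  hw <- H * W
  # flat indices of the true-class probability for every pixel
  idx <- rep(seq_len(hw), times = N) + hw * tv +
    hw * C * rep(0:(N - 1), each = hw)
  logc <- if (base == 2) log(2) else 1
  loss <- -sum(log(q[idx] + eps)) / (npix * logc)
  if (is.null(tape)) return(loss)
  tape_node(tape, loss, list(logits), function(g) {
    gl <- q
    gl[idx] <- gl[idx] - 1
    list(gl * (g / (npix * logc)))
  })
}
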