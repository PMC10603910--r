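# Brute-force oracles, written independently of the package internals:
# explicit per-pixel loops, no shared code with the compute engine.

rand_fmap <- function(h, w, c, n, sd = 1) {
  array(rnorm(h * w * c * n, sd = sd), dim = c(h, w, c, n))
}

rand_mask <- function(h, w, classes, n = 1) {
  array(sample(0:(classes - 1), h * w * n, replace = TRUE), dim = c(h, w, n))
}

# 3x3 (or 1x1) same-padding stride-1 convolution by explicit loops,
# one sample: x (H,W,Ci), w (k,k,Ci,Co), b (Co)
oracle_conv <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Ci <- dim(x)[3]
  k <- dim(w)[1]; Co <- dim(w)[4]
  pad <- (k - 1) / 2
  y <- array(0, c(H, W, Co))
  for (co in 1:Co) for (i in 1:H) for (j in 1:W) {
    acc <- b[co]
    for (ci in 1:Ci) for (kh in 1:k) for (kw in 1:k) {
      ii <- i + kh - 1 - pad; jj <- j + kw - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, ci] * w[kh, kw, ci, co]
    }
    y[i, j, co] <- acc
  }
  y
}

# bilinear x2 upsampling with half-pixel centres, one sample: x (H,W,C)
oracle_upsample2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  y <- array(0, c(2 * H, 2 * W, C))
  coord <- function(i, n_in) {           # 1-based source coordinate
    s <- (i - 0.5) / 2 + 0.5
    min(max(s, 1), n_in)
  }
  for (c in 1:C) for (i in 1:(2 * H)) for (j in 1:(2 * W)) {
    si <- coord(i, H); sj <- coord(j, W)
    i0 <- floor(si); i1 <- min(i0 + 1, H); wi <- si - i0
    j0 <- floor(sj); j1 <- min(j0 + 1, W); wj <- sj - j0
    y[i, j, c] <- (1 - wi) * (1 - wj) * x[i0, j0, c] +
      wi * (1 - wj) * x[i1, j0, c] +
      (1 - wi) * wj * x[i0, j1, c] +
      wi * wj * x[i1, j1, c]
  }
  y
}

# GAP -> affine -> ReLU -> affine -> sigmoid -> channel scaling, one sample
oracle_se <- function(x, wts) {
  C <- dim(x)[3]
  g <- numeric(C)
  for (c in 1:C) g[c] <- mean(x[, , c])
  h <- as.vector(wts$w1 %*% g + wts$b1)
  h[h < 0] <- 0
  s <- 1 / (1 + exp(-(as.vector(wts$w2 %*% h + wts$b2))))
  y <- x
  for (c in 1:C) y[, , c] <- x[, , c] * s[c]
  list(y = y, gate = s)
}

# the five SEC steps: conv C2->C1, upsample x2, concat, conv 2C1->C1, SE
oracle_sec <- function(l1, l2, wts) {
  a <- oracle_conv(l2, wts$conva_w, wts$conva_b)
  u <- oracle_upsample2(a)
  cc <- array(0, c(dim(l1)[1], dim(l1)[2], dim(l1)[3] + dim(u)[3]))
  cc[, , seq_len(dim(l1)[3])] <- l1
  cc[, , dim(l1)[3] + seq_len(dim(u)[3])] <- u
  f <- oracle_conv(cc, wts$convb_w, wts$convb_b)
  oracle_se(f, wts$se)$y
}

# per-class pixel-set metrics by explicit set construction
oracle_dice <- function(pred, truth, cls) {
  A <- which(as.vector(pred) == cls)
  B <- which(as.vector(truth) == cls)
  if (length(A) + length(B) == 0) return(1)
  2 * length(intersect(A, B)) / (length(A) + length(B))
}

oracle_counts <- function(pred, truth, cls) {
  A <- which(as.vector(pred) == cls)
  B <- which(as.vector(truth) == cls)
  c(tp = length(intersect(A, B)),
    fp = length(setdiff(A, B)),
    fn = length(setdiff(B, A)))
}

# textbook paired t statistic from scratch
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, p = p)
}

tiny_config <- function(classes = 3L, batchnorm = TRUE) {
  secp_config(num_classes = classes, depth = 2L, stage_channels = c(4L, 6L, 8L),
              se_reduction = 2L, batchnorm = batchnorm)
}

tiny_data <- function(classes = 3L, n = 4L, size = 16L, seed = 99L) {
  set.seed(seed)
  list(images = array(runif(size * size * n), c(size, size, 1L, n)),
       masks = rand_mask(size, size, classes, n))
}
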