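# Numeric layer primitives for the executable network. Feature maps are base
# arrays (height x width x channels); convolutions go through im2col so the
# heavy lifting is a single BLAS matrix multiply. Every primitive has a
# hand-written backward pass; caches carry exactly what the backward needs.

# -- convolution --------------------------------------------------------------

# Unfold a same-padded H x W x C volume into an (H*W) x (kh*kw*C) matrix.
# Column blocks are ordered by kernel offset (row-major over the kernel),
# channels fastest within a block; conv weight matrices use the same order.
im2col <- function(x, kh, kw) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  if (kh == 1L && kw == 1L) return(matrix(x, H * W, C))
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2L * ph, W + 2L * pw, C))
  xp[ph + seq_len(H), pw + seq_len(W), ] <- x
  cols <- matrix(0, H * W, kh * kw * C)
  o <- 0L
  for (dr in seq_len(kh)) {
    for (dc in seq_len(kw)) {
      cols[, (o * C + 1L):((o + 1L) * C)] <-
        matrix(xp[dr:(dr + H - 1L), dc:(dc + W - 1L), , drop = FALSE], H * W, C)
      o <- o + 1L
    }
  }
  cols
}

conv_forward <- function(x, W, b, kh, kw) {
  d <- dim(x)
  cols <- im2col(x, kh, kw)
  out <- cols %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(d[1], d[2], length(b))),
       cache = list(cols = cols, dim_in = d, kh = kh, kw = kw))
}

conv_backward <- function(dout, W, cache) {
  d <- cache$dim_in; H <- d[1]; Wd <- d[2]; C <- d[3]
  kh <- cache$kh; kw <- cache$kw
  dmat <- matrix(dout, H * Wd, ncol(W))
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- dmat %*% t(W)
  if (kh == 1L && kw == 1L) {
    dx <- array(dcols, c(H, Wd, C))
  } else {
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
    dxp <- array(0, c(H + 2L * ph, Wd + 2L * pw, C))
    o <- 0L
    for (dr in seq_len(kh)) {
      for (dc in seq_len(kw)) {
        dxp[dr:(dr + H - 1L), dc:(dc + Wd - 1L), ] <-
          dxp[dr:(dr + H - 1L), dc:(dc + Wd - 1L), , drop = FALSE] +
          array(dcols[, (o * C + 1L):((o + 1L) * C)], c(H, Wd, C))
        o <- o + 1L
      }
    }
    dx <- dxp[ph + seq_len(H), pw + seq_len(Wd), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# -- batch normalization ------------------------------------------------------

bn_forward <- function(x, p, eps, training) {
  d <- dim(x); N <- d[1] * d[2]; C <- d[3]
  xm <- matrix(x, N, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, "-")
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv, "*")
  } else {
    inv <- 1 / sqrt(p$run_var + eps)
    xhat <- sweep(sweep(xm, 2L, p$run_mean, "-"), 2L, inv, "*")
    mu <- p$run_mean; v <- p$run_var
  }
  y <- sweep(sweep(xhat, 2L, p$gamma, "*"), 2L, p$beta, "+")
  list(out = array(y, d),
       cache = list(xhat = xhat, inv = inv, dim = d, training = training,
                    batch_mean = mu, batch_var = v),
       batch_mean = mu, batch_var = v)
}

bn_backward <- function(dout, p, cache) {
  if (!cache$training) {
    abort("batch-norm backward requires a training-mode forward cache")
  }
  d <- cache$dim; N <- d[1] * d[2]; C <- d[3]
  dy <- matrix(dout, N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, p$gamma, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*")
  dx <- sweep(dx, 2L, cache$inv, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# -- relu ---------------------------------------------------------------------

relu_forward <- function(x) {
  out <- x; out[out < 0] <- 0
  list(out = out, cache = x > 0)
}

relu_backward <- function(dout, mask) {
  dout * mask
}

# -- 2x2 max pooling with retained indices ------------------------------------

# Quadrant order is row-major within each window: (0,0), (0,1), (1,0), (1,1);
# strict comparison keeps the first maximum, giving deterministic indices.
maxpool_forward <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  if (H %% 2L || W %% 2L) abort("max_pool input spatial dims must be even")
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  cands <- list(
    x[i1, j1, , drop = FALSE], x[i1, j2, , drop = FALSE],
    x[i2, j1, , drop = FALSE], x[i2, j2, , drop = FALSE]
  )
  m <- cands[[1L]]
  idx <- array(1L, dim(m))
  for (q in 2:4) {
    upd <- cands[[q]] > m
    m[upd] <- cands[[q]][upd]
    idx[upd] <- q
  }
  list(out = m, idx = idx, dim_in = d)
}

# Flat positions (into the unpooled H x W x C volume) of quadrant q for every
# pooled cell.
pool_flat_index <- function(q, H, W, C) {
  oh <- H %/% 2L; ow <- W %/% 2L
  dr <- c(0L, 0L, 1L, 1L)[q]; dc <- c(0L, 1L, 0L, 1L)[q]
  rows <- 2L * seq_len(oh) - 1L + dr
  cols <- 2L * seq_len(ow) - 1L + dc
  rep(rows, times = ow * C) +
    (rep(rep(cols, each = oh), times = C) - 1L) * H +
    (rep(seq_len(C), each = oh * ow) - 1L) * H * W
}

# Place pooled values back at their recorded argmax positions, zero elsewhere.
maxunpool_forward <- function(v, idx, dim_out) {
  H <- dim_out[1]; W <- dim_out[2]; C <- dim_out[3]
  y <- array(0, c(H, W, C))
  for (q in 1:4) {
    sel <- idx == q
    if (any(sel)) {
      flat <- pool_flat_index(q, H, W, C)
      y[flat[sel]] <- v[sel]
    }
  }
  y
}

maxpool_backward <- function(dout, idx, dim_in) {
  # gradient routes to the argmax position of each window
  maxunpool_forward(dout, idx, dim_in)
}

maxunpool_backward <- function(dout, idx, dim_out) {
  H <- dim_out[1]; W <- dim_out[2]; C <- dim_out[3]
  dv <- array(0, dim(idx))
  for (q in 1:4) {
    sel <- idx == q
    if (any(sel)) {
      flat <- pool_flat_index(q, H, W, C)
      dv[sel] <- dout[flat[sel]]
    }
  }
  dv
}

# -- softmax ------------------------------------------------------------------

softmax_forward <- function(x) {
  d <- dim(x); N <- d[1] * d[2]; C <- d[3]
  zm <- matrix(x, N, C)
  mx <- do.call(pmax, lapply(seq_len(C), function(k) zm[, k]))
  e <- exp(zm - mx)
  array(e / rowSums(e), d)
}
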