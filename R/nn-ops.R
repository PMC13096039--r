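# Differentiable primitives for the segmentation network.
#
# Feature maps live in "pixel-row" form: a (H*W*B) x C matrix whose row index
# is y + (x-1)*H + (b-1)*H*W (y fastest, then x, then sample). Token
# sequences use the same layout at the token-grid resolution, so reshaping
# tokens into a spatial grid is a no-op. Every op returns `list(out, cache)`
# and has a matching `*_bw(dout, cache)` returning input and parameter
# gradients; correctness is pinned by finite-difference tests.

.idx_cache <- new.env(parent = emptyenv())

idx_memo <- function(key, maker) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- maker()
  .idx_cache[[key]]
}

pix_coords <- function(h, w, B) {
  list(y = rep.int(seq_len(h), w * B),
       x = rep.int(rep(seq_len(w), each = h), B),
       b = rep(seq_len(B), each = h * w))
}

# ---- dense / normalisation / activations -------------------------------

nn_linear <- function(X, W, b) {
  out <- add_bias(X %*% W, b)
  list(out = out, cache = list(X = X, W = W))
}

nn_linear_bw <- function(dout, cache) {
  list(dx = dout %*% t(cache$W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

nn_layernorm <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(xhat * g[col(xhat)], 2, b, "+")
  # g[col(xhat)] broadcasts g across rows
  list(out = out, cache = list(xhat = xhat, istd = istd, g = g))
}

nn_layernorm_bw <- function(dout, cache) {
  g <- cache$g; xhat <- cache$xhat; istd <- cache$istd
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * g[col(dout)]
  m <- ncol(dout)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
  list(dx = dx, dg = dgamma, db = dbeta)
}

nn_gelu <- function(X) {
  phi <- pnorm(X)
  list(out = X * phi, cache = list(X = X, phi = phi))
}

nn_gelu_bw <- function(dout, cache) {
  dout * (cache$phi + cache$X * dnorm(cache$X))
}

nn_relu <- function(X) {
  m <- X > 0
  list(out = X * m, cache = m)
}

nn_relu_bw <- function(dout, cache) dout * cache

nn_sigmoid <- function(X) {
  s <- 1 / (1 + exp(-X))
  list(out = s, cache = s)
}

nn_sigmoid_bw <- function(dout, cache) dout * cache * (1 - cache)

nn_dropout <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  keep <- matrix(runif(length(X)) >= rate, nrow(X), ncol(X)) / (1 - rate)
  list(out = X * keep, cache = keep)
}

nn_dropout_bw <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# Batch normalisation over rows (per-channel). `bufs` carries running stats;
# training mode uses batch statistics and updates the running buffers.
nn_batchnorm <- function(X, g, b, bufs, training, momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    v <- colMeans(xc^2)
    bufs$mean <- (1 - momentum) * bufs$mean + momentum * mu
    bufs$var <- (1 - momentum) * bufs$var + momentum * v
  } else {
    mu <- bufs$mean
    v <- bufs$var
    xc <- X - rep(mu, each = n)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = n)
  out <- xhat * rep(g, each = n) + rep(b, each = n)
  list(out = out, cache = list(xhat = xhat, istd = istd, g = g,
                               training = training),
       bufs = bufs)
}

nn_batchnorm_bw <- function(dout, cache) {
  xhat <- cache$xhat; istd <- cache$istd; g <- cache$g
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  n <- nrow(dout)
  dxhat <- dout * rep(g, each = n)
  if (cache$training) {
    dx <- (dxhat - rep(colMeans(dxhat), each = n) -
             xhat * rep(colMeans(dxhat * xhat), each = n)) * rep(istd, each = n)
  } else {
    dx <- dxhat * rep(istd, each = n)
  }
  list(dx = dx, dg = dg, db = db)
}

# ---- convolutional ops --------------------------------------------------

# Fast row-broadcast bias add (avoids sweep's aperm overhead).
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Same-padded stride-1 k x k convolution via im2col. W: (C_in*k*k) x C_out.
# The column matrix is cached for the backward pass (memory for speed).
nn_conv <- function(X, W, b, h, w, B, k = 3L) {
  cols <- cpp_im2col(X, h, w, B, k)
  out <- add_bias(cols %*% W, b)
  list(out = out, cache = list(cols = cols, W = W, c_in = ncol(X),
                               h = h, w = w, B = B, k = k))
}

nn_conv_bw <- function(dout, cache) {
  dW <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- dout %*% t(cache$W)
  dx <- cpp_col2im(dcols, cache$h, cache$w, cache$B, cache$c_in, cache$k)
  list(dx = dx, dW = dW, db = db)
}

# 2x2 stride-2 transposed convolution (exact resolution doubling, no
# overlap). W: C_in x (4*C_out); position blocks ordered (dy,dx) =
# (0,0),(1,0),(0,1),(1,1).
tconv_idx <- function(h, w, B) {
  idx_memo(sprintf("tconv_%d_%d_%d", h, w, B), function() {
    p <- pix_coords(h, w, B)
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    lapply(offs, function(o) {
      (2L * (p$y - 1L) + o[1] + 1L) +
        (2L * (p$x - 1L) + o[2]) * (2L * h) +
        (p$b - 1L) * (4L * h * w)
    })
  })
}

nn_tconv2 <- function(X, W, b, h, w, B) {
  c_out <- length(b)
  Y4 <- X %*% W
  out <- matrix(0, 4L * h * w * B, c_out)
  idx <- tconv_idx(h, w, B)
  for (q in 1:4) {
    out[idx[[q]], ] <- Y4[, ((q - 1L) * c_out + 1L):(q * c_out), drop = FALSE]
  }
  out <- add_bias(out, b)
  list(out = out, cache = list(X = X, W = W, h = h, w = w, B = B,
                               c_out = c_out))
}

nn_tconv2_bw <- function(dout, cache) {
  idx <- tconv_idx(cache$h, cache$w, cache$B)
  c_out <- cache$c_out
  dY4 <- matrix(0, nrow(cache$X), 4L * c_out)
  for (q in 1:4) {
    dY4[, ((q - 1L) * c_out + 1L):(q * c_out)] <- dout[idx[[q]], , drop = FALSE]
  }
  list(dx = dY4 %*% t(cache$W),
       dW = crossprod(cache$X, dY4),
       db = colSums(dout))
}

# Nearest-neighbour upsampling by integer factor f.
upsample_idx <- function(h, w, B, f) {
  idx_memo(sprintf("up_%d_%d_%d_%d", h, w, B, f), function() {
    p <- pix_coords(h * f, w * f, B)
    iy <- (p$y - 1L) %/% f + 1L
    ix <- (p$x - 1L) %/% f + 1L
    iy + (ix - 1L) * h + (p$b - 1L) * h * w
  })
}

nn_upnearest <- function(X, f, h, w, B) {
  if (f == 1L) return(list(out = X, cache = list(f = 1L)))
  idx <- upsample_idx(h, w, B, f)
  list(out = X[idx, , drop = FALSE],
       cache = list(f = f, h = h, w = w, B = B, idx = idx))
}

nn_upnearest_bw <- function(dout, cache) {
  if (cache$f == 1L) return(dout)
  out <- rowsum(dout, group = cache$idx, reorder = TRUE)
  # every source row receives f^2 outputs, so groups 1..h*w*B are all present
  out
}

# ---- attention ----------------------------------------------------------

softmax_rows <- function(Z) {
  m <- as.numeric(do.call(pmax.int, asplit(Z, 2)))
  e <- exp(Z - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`; each softmax row
#' sums to one.
#'
#' @param Q,K,V Query, key, value matrices; `Q` and `K` share `d_k` columns,
#'   `K` and `V` share their row count.
#' @param d_k Key dimension (defaults to `ncol(K)`).
#' @return The attended value matrix (`nrow(Q)` x `ncol(V)`).
#' @export
attention <- function(Q, K, V, d_k = ncol(K)) {
  abort_if(ncol(Q) != ncol(K), "Q and K must share the key dimension")
  abort_if(nrow(K) != nrow(V), "K and V must share their row count")
  A <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  A %*% V
}

# Single-sample multi-head self-attention with cache for backprop.
mhsa_fwd <- function(Xs, Wq, bq, Wk, bk, Wv, bv, Wo, bo, heads) {
  D <- ncol(Xs)
  dh <- D %/% heads
  Q <- sweep(Xs %*% Wq, 2, bq, "+")
  K <- sweep(Xs %*% Wk, 2, bk, "+")
  V <- sweep(Xs %*% Wv, 2, bv, "+")
  O <- matrix(0, nrow(Xs), D)
  A_list <- vector("list", heads)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1L) * dh + 1L):(hd * dh)
    A <- softmax_rows(Q[, cols, drop = FALSE] %*%
                        t(K[, cols, drop = FALSE]) / sqrt(dh))
    A_list[[hd]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- sweep(O %*% Wo, 2, bo, "+")
  list(out = out,
       cache = list(Xs = Xs, Q = Q, K = K, V = V, O = O, A = A_list,
                    heads = heads, dh = dh, Wq = Wq, Wk = Wk, Wv = Wv,
                    Wo = Wo))
}

mhsa_bw <- function(dout, cache) {
  ch <- cache
  dWo <- crossprod(ch$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(ch$Wo)
  dQ <- matrix(0, nrow(ch$Q), ncol(ch$Q))
  dK <- dQ; dV <- dQ
  for (hd in seq_len(ch$heads)) {
    cols <- ((hd - 1L) * ch$dh + 1L):(hd * ch$dh)
    A <- ch$A[[hd]]
    Vh <- ch$V[, cols, drop = FALSE]
    dOh <- dO[, cols, drop = FALSE]
    dV[, cols] <- crossprod(A, dOh)
    dA <- dOh %*% t(Vh)
    # softmax backward per row
    dZ <- A * (dA - rowSums(dA * A))
    scale <- 1 / sqrt(ch$dh)
    dQ[, cols] <- (dZ %*% ch$K[, cols, drop = FALSE]) * scale
    dK[, cols] <- (crossprod(dZ, ch$Q[, cols, drop = FALSE])) * scale
  }
  dx <- dQ %*% t(ch$Wq) + dK %*% t(ch$Wk) + dV %*% t(ch$Wv)
  list(dx = dx,
       dWq = crossprod(ch$Xs, dQ), dbq = colSums(dQ),
       dWk = crossprod(ch$Xs, dK), dbk = colSums(dK),
       dWv = crossprod(ch$Xs, dV), dbv = colSums(dV),
       dWo = dWo, dbo = dbo)
}
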