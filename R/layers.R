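# Numerical layer primitives with hand-written reverse-mode gradients.
# Feature maps are H x W x C arrays (or HW x C matrices where noted); all
# heavy lifting happens in BLAS matrix products via im2col-style reshapes.
# Every *_fw returns list(y, cache); every *_bw consumes (dy, params, cache)
# and returns list(dx, grads...). Gradients are validated against central
# finite differences in the test suite.

im2col_idx <- function(H, W, k, pad, stride) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  r0 <- rep(seq(0L, by = stride, length.out = Ho), times = Wo)
  c0 <- rep(seq(0L, by = stride, length.out = Wo), each = Ho)
  list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, base = r0 + c0 * Hp)
}

pad_xy <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

# Dense convolution, kernel k x k, weights (k,k,Cin,Cout). The im2col
# matrix keeps the native weight-array order along its columns (kernel
# offset fastest, then channel), so weights need no permutation at all.
.conv_idx_memo <- new.env(parent = emptyenv())

conv_gather_idx <- function(H, W, k, pad, stride) {
  key <- paste(H, W, k, pad, stride, sep = "_")
  hit <- .conv_idx_memo[[key]]
  if (!is.null(hit)) return(hit)
  ii <- im2col_idx(H, W, k, pad, stride)
  n <- length(ii$base)
  koff <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * ii$Hp, `+`))
  ii$ridx <- rep(ii$base + 1L, times = k * k) + rep(koff, each = n)
  .conv_idx_memo[[key]] <- ii
  ii
}

conv2d_fw <- function(x, w, b, pad = 1L, stride = 1L) {
  d <- dim(x); k <- dim(w)[1]; C <- d[3]; Cout <- dim(w)[4]
  ii <- conv_gather_idx(d[1], d[2], k, pad, stride)
  xpm <- matrix(pad_xy(x, pad), ii$Hp * ii$Wp, C)
  n <- length(ii$base)
  # rows: pixel fastest, then offset; columns: channel -> reinterpreted as
  # (pixel) x (offset, channel), matching w's native flattening
  cols <- matrix(xpm[ii$ridx, ], n, k * k * C)
  wm <- matrix(w, k * k * C, Cout)
  y <- cols %*% wm
  y <- y + rep(b, each = n)
  list(y = array(y, c(ii$Ho, ii$Wo, Cout)),
       cache = list(cols = cols, ii = ii, dimx = d, k = k, pad = pad,
                    wm = wm))
}

conv2d_bw <- function(dy, w, cache) {
  ii <- cache$ii; k <- cache$k; C <- cache$dimx[3]; Cout <- dim(w)[4]
  dym <- matrix(dy, ii$Ho * ii$Wo, Cout)
  dw <- array(crossprod(cache$cols, dym), dim(w))
  db <- colSums(dym)
  dcols <- tcrossprod(dym, cache$wm)
  dxp <- matrix(0, ii$Hp * ii$Wp, C)
  kk <- k * k
  for (o in seq_len(kk)) {
    rows <- ii$ridx[((o - 1L) * length(ii$base) + 1L):(o * length(ii$base))]
    dxp[rows, ] <- dxp[rows, , drop = FALSE] +
      dcols[, seq(o, by = kk, length.out = C), drop = FALSE]
  }
  dxp <- array(dxp, c(ii$Hp, ii$Wp, C))
  pad <- cache$pad
  dx <- dxp[pad + seq_len(cache$dimx[1]), pad + seq_len(cache$dimx[2]), ,
            drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# Depthwise convolution: per-channel k x k kernel, same padding, stride 1.
# Channels never mix.
dwconv_fw <- function(x, w, b) {
  d <- dim(x); k <- dim(w)[1]; C <- d[3]
  pad <- (k - 1L) %/% 2L
  ii <- im2col_idx(d[1], d[2], k, pad, 1L)
  xpm <- matrix(pad_xy(x, pad), ii$Hp * ii$Wp, C)
  y <- matrix(0, length(ii$base), C)
  n <- length(ii$base)
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    rows <- ii$base + (ki - 1L) + (kj - 1L) * ii$Hp + 1L
    y <- y + xpm[rows, , drop = FALSE] *
      matrix(w[ki, kj, ], n, C, byrow = TRUE)
  }
  y <- y + rep(b, each = n)
  list(y = array(y, c(ii$Ho, ii$Wo, C)),
       cache = list(xpm = xpm, ii = ii, dimx = d, k = k, pad = pad))
}

dwconv_bw <- function(dy, w, cache) {
  ii <- cache$ii; k <- cache$k; C <- cache$dimx[3]
  n <- length(ii$base)
  dym <- matrix(dy, n, C)
  dw <- array(0, dim(w))
  dxp <- matrix(0, ii$Hp * ii$Wp, C)
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    rows <- ii$base + (ki - 1L) + (kj - 1L) * ii$Hp + 1L
    dw[ki, kj, ] <- colSums(cache$xpm[rows, , drop = FALSE] * dym)
    dxp[rows, ] <- dxp[rows, , drop = FALSE] +
      dym * matrix(w[ki, kj, ], n, C, byrow = TRUE)
  }
  db <- colSums(dym)
  dxp <- array(dxp, c(ii$Hp, ii$Wp, C))
  pad <- cache$pad
  dx <- dxp[pad + seq_len(cache$dimx[1]), pad + seq_len(cache$dimx[2]), ,
            drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

# Transposed convolution 2x2, stride 2 (exact 2x upsampling); w is
# (2, 2, Cin, Cout).
tconv_fw <- function(x, w, b) {
  d <- dim(x); Cin <- d[3]; Cout <- dim(w)[4]
  xm <- matrix(x, d[1] * d[2], Cin)
  y <- array(0, c(2L * d[1], 2L * d[2], Cout))
  for (dj in 1:2) for (di in 1:2) {
    yb <- xm %*% matrix(w[di, dj, , ], Cin, Cout)
    y[seq(di, 2L * d[1], 2L), seq(dj, 2L * d[2], 2L), ] <-
      array(yb, c(d[1], d[2], Cout))
  }
  y <- y + rep(b, each = 4L * d[1] * d[2])
  list(y = y, cache = list(xm = xm, dimx = d))
}

tconv_bw <- function(dy, w, cache) {
  d <- cache$dimx; Cin <- d[3]; Cout <- dim(w)[4]
  dw <- array(0, dim(w))
  dxm <- matrix(0, d[1] * d[2], Cin)
  for (dj in 1:2) for (di in 1:2) {
    dyb <- matrix(dy[seq(di, 2L * d[1], 2L), seq(dj, 2L * d[2], 2L), ],
                  d[1] * d[2], Cout)
    dw[di, dj, , ] <- crossprod(cache$xm, dyb)
    dxm <- dxm + tcrossprod(dyb, matrix(w[di, dj, , ], Cin, Cout))
  }
  db <- colSums(matrix(dy, ncol = Cout))
  list(dx = array(dxm, d), dw = dw, db = db)
}

# Layer normalization over the channel axis (x: n x C matrix).
ln_fw <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

ln_bw <- function(dy, gamma, cache) {
  n <- nrow(dy)
  dxhat <- dy * rep(gamma, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx,
       dgamma = colSums(dy * cache$xhat),
       dbeta = colSums(dy))
}

gelu_fw <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, cache = list(x = x, ph = ph))
}

gelu_bw <- function(dy, cache) {
  dy * (cache$ph + cache$x * stats::dnorm(cache$x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Row-wise softmax of a matrix of logits. Row maxima are computed via pmax
# over columns (apply() is too slow on the hot path).
softmax_rows <- function(z) {
  mx <- z[, 1L]
  for (j in seq_len(ncol(z))[-1L]) mx <- pmax(mx, z[, j])
  e <- exp(z - mx)
  e / rowSums(e)
}

# ---- parameter-tree utilities ------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zero <- function(a) tree_map(function(x) x * 0, a)

tree_count <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_count, numeric(1))) else length(a)
}

# Flatten / unflatten for finite-difference checks and serialization.
tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

tree_unflatten <- function(template, v) {
  pos <- 0L
  rec <- function(a) {
    if (is.list(a)) {
      lapply(a, rec)
    } else {
      n <- length(a)
      out <- array(v[pos + seq_len(n)], dim = if (is.null(dim(a))) n else dim(a))
      pos <<- pos + n
      if (is.null(dim(a))) out <- as.numeric(out)
      out
    }
  }
  rec(template)
}
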