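# Local-window multi-head self-attention (W-MSA): attention is computed
# independently within non-overlapping ws x ws spatial windows; no
# information crosses window boundaries. Maps are zero-padded to window
# multiples and un-padded exactly.

#' Partition a feature map into non-overlapping windows
#'
#' Zero-pads both spatial dims up to multiples of `window`, then tiles.
#' Returned tiles are disjoint and cover the padded map;
#' [window_reverse()] inverts the operation exactly.
#'
#' @param x `H x W x C` array.
#' @param window Window size in pixels.
#' @return List: `tiles` (`window^2 x n_windows x C` array, tokens in
#'   column-major order within a window), `pad` (rows/cols of zero padding
#'   added), `dims` (original dims), `grid` (windows per axis).
#' @export
window_partition <- function(x, window = 4L) {
  d <- dim(x)
  ph <- (window - d[1] %% window) %% window
  pw <- (window - d[2] %% window) %% window
  if (ph || pw) {
    xp <- array(0, c(d[1] + ph, d[2] + pw, d[3]))
    xp[seq_len(d[1]), seq_len(d[2]), ] <- x
    x <- xp
  }
  dp <- dim(x)
  nh <- dp[1] %/% window; nw <- dp[2] %/% window
  # (i, a, j, b, C) -> (i, j, a, b, C): token index (i,j) fastest
  xt <- array(x, c(window, nh, window, nw, d[3]))
  xt <- aperm(xt, c(1, 3, 2, 4, 5))
  tiles <- array(xt, c(window * window, nh * nw, d[3]))
  list(tiles = tiles, pad = c(ph, pw), dims = d, grid = c(nh, nw),
       window = window)
}

#' @rdname window_partition
#' @param part A [window_partition()] result (tiles possibly replaced by a
#'   same-shaped array).
#' @param tiles Tile array to reassemble (defaults to `part$tiles`).
#' @return The original `H x W x C` array (padding removed).
#' @export
window_reverse <- function(part, tiles = part$tiles) {
  w <- part$window; nh <- part$grid[1]; nw <- part$grid[2]; d <- part$dims
  xt <- array(tiles, c(w, w, nh, nw, d[3]))
  xt <- aperm(xt, c(1, 3, 2, 4, 5))
  xp <- array(xt, c(w * nh, w * nw, d[3]))
  xp[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
}

# W-MSA forward. p: list(wq, wk, wv, wo [C x C], bq, bk, bv, bo [C]).
# Standard scaled dot-product attention per window per head.
wmsa_fw <- function(x, p, window, heads) {
  C <- dim(x)[3]
  if (C %% heads != 0L) stop("channels not divisible by heads", call. = FALSE)
  dh <- C %/% heads
  part <- window_partition(x, window)
  Tn <- window * window
  nwin <- prod(part$grid)
  X2 <- matrix(part$tiles, Tn * nwin, C)  # token fastest within window
  Q <- X2 %*% p$wq + rep(p$bq, each = nrow(X2))
  K <- X2 %*% p$wk + rep(p$bk, each = nrow(X2))
  V <- X2 %*% p$wv + rep(p$bv, each = nrow(X2))
  O <- matrix(0, Tn * nwin, C)
  P <- array(0, c(Tn, Tn, nwin * heads))
  sc <- 1 / sqrt(dh)
  for (b in seq_len(nwin)) {
    rows <- (b - 1L) * Tn + seq_len(Tn)
    for (h in seq_len(heads)) {
      cl <- (h - 1L) * dh + seq_len(dh)
      S <- tcrossprod(Q[rows, cl, drop = FALSE], K[rows, cl, drop = FALSE]) * sc
      Pb <- softmax_rows(S)
      P[, , (b - 1L) * heads + h] <- Pb
      O[rows, cl] <- Pb %*% V[rows, cl, drop = FALSE]
    }
  }
  Y2 <- O %*% p$wo + rep(p$bo, each = nrow(O))
  y <- window_reverse(part, array(Y2, c(Tn, nwin, C)))
  list(y = y,
       cache = list(part = part, X2 = X2, Q = Q, K = K, V = V, O = O, P = P,
                    heads = heads, dh = dh))
}

wmsa_bw <- function(dy, p, cache) {
  part <- cache$part
  w <- part$window; Tn <- w * w
  nwin <- prod(part$grid)
  C <- part$dims[3]
  heads <- cache$heads; dh <- cache$dh
  # pad dy like the forward padded x, partition identically
  dpart <- window_partition(dy, w)
  dY2 <- matrix(dpart$tiles, Tn * nwin, C)
  dO <- tcrossprod(dY2, p$wo)
  dwo <- crossprod(cache$O, dY2)
  dbo <- colSums(dY2)
  dQ <- matrix(0, Tn * nwin, C)
  dK <- matrix(0, Tn * nwin, C)
  dV <- matrix(0, Tn * nwin, C)
  sc <- 1 / sqrt(dh)
  for (b in seq_len(nwin)) {
    rows <- (b - 1L) * Tn + seq_len(Tn)
    for (h in seq_len(heads)) {
      cl <- (h - 1L) * dh + seq_len(dh)
      Pb <- cache$P[, , (b - 1L) * heads + h]
      dOb <- dO[rows, cl, drop = FALSE]
      Vb <- cache$V[rows, cl, drop = FALSE]
      dP <- tcrossprod(dOb, Vb)
      dV[rows, cl] <- crossprod(Pb, dOb)
      dS <- Pb * (dP - rowSums(dP * Pb))
      dQ[rows, cl] <- dS %*% cache$K[rows, cl, drop = FALSE] * sc
      dK[rows, cl] <- crossprod(dS, cache$Q[rows, cl, drop = FALSE]) * sc
    }
  }
  dX2 <- tcrossprod(dQ, p$wq) + tcrossprod(dK, p$wk) + tcrossprod(dV, p$wv)
  grads <- list(
    wq = crossprod(cache$X2, dQ), bq = colSums(dQ),
    wk = crossprod(cache$X2, dK), bk = colSums(dK),
    wv = crossprod(cache$X2, dV), bv = colSums(dV),
    wo = dwo, bo = dbo)
  dx <- window_reverse(part, array(dX2, c(Tn, nwin, C)))
  list(dx = dx, grads = grads)
}

#' Dense single-window attention (reference oracle)
#'
#' Direct `softmax(Q K^T / sqrt(d)) V` on one token matrix; used as the
#' independent check for the windowed implementation.
#'
#' @param x `T x C` token matrix.
#' @param p Projection list as in the W-MSA parameters.
#' @param heads Number of heads.
#' @return `T x C` matrix.
#' @export
dense_attention <- function(x, p, heads = 1L) {
  C <- ncol(x); dh <- C %/% heads
  Q <- x %*% p$wq + rep(p$bq, each = nrow(x))
  K <- x %*% p$wk + rep(p$bk, each = nrow(x))
  V <- x %*% p$wv + rep(p$bv, each = nrow(x))
  O <- matrix(0, nrow(x), C)
  for (h in seq_len(heads)) {
    cl <- (h - 1L) * dh + seq_len(dh)
    S <- tcrossprod(Q[, cl, drop = FALSE], K[, cl, drop = FALSE]) / sqrt(dh)
    O[, cl] <- softmax_rows(S) %*% V[, cl, drop = FALSE]
  }
  O %*% p$wo + rep(p$bo, each = nrow(x))
}
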