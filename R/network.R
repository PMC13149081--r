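# Hybrid conv/self-attention encoder-decoder for multi-offset CEST stacks.
# Encoder stages are stacks of "mixing blocks": a depthwise-convolution
# branch and a windowed multi-head self-attention branch run in parallel on
# the same (layer-normalized) input, exchange bi-directional channel/spatial
# gates, and are fused by a two-layer GELU feed-forward network inside a
# residual connection. The decoder is a plain transposed-conv + double-conv
# U-Net path with skip connections; a 1x1 softmax head emits per-pixel class
# probabilities. Forward and reverse passes are hand-written (see layers.R).

#' Network configuration
#'
#' Describes every architectural variant: the full dual-branch network, the
#' single-branch ablations, the no-interaction ablation, and the
#' spectral-only per-pixel baseline.
#'
#' Stage widths default to `base_width * (2, 4, 8, 16)`; with
#' `literal_widths = TRUE` they are `in_channels * (2, 4, 8, 16)` (the
#' channel-expansion rule applied literally to the input channel count).
#'
#' @param in_channels Input channels `C` (41 saturation offsets by default).
#' @param n_classes Output classes `N` (default 2).
#' @param base_width Base width `W0`; stage widths are `W0 * (2,4,8,16)`.
#'   Must be a multiple of 2 so that head counts divide widths.
#' @param literal_widths Use `in_channels` in place of `W0`.
#' @param depths Mixing blocks per encoder stage, default `c(2, 2, 4, 2)`.
#' @param window W-MSA window size (default 4).
#' @param dw_kernel Depthwise-convolution kernel (default 3).
#' @param heads Attention heads per stage; default `max(1, width/16)`.
#' @param ffn_ratio FFN expansion ratio (default 4).
#' @param conv_branch,attn_branch Enable the depthwise-conv / W-MSA branch.
#' @param interactions Enable the bi-directional channel/spatial gates
#'   (requires both branches).
#' @param swap_interactions Reverse the gate direction (sensitivity switch).
#' @param decoder_mixing Also place mixing blocks in the decoder.
#' @param type `"mixing"` (the encoder-decoder network) or
#'   `"spectral_mlp"` (per-pixel fully connected baseline over the
#'   Z-spectrum, no spatial context).
#' @param hidden Hidden layer sizes for the spectral MLP baseline.
#' @param normalize_input Standardize each input stack to zero mean and unit
#'   variance (one scalar mean/sd per sample) before the stem; Z-values sit
#'   close to 1 with small informative contrast, and centering them is
#'   essential for optimization at desk scale.
#' @return Object of class `network_config`.
#' @export
network_config <- function(in_channels = 41L, n_classes = 2L,
                           base_width = 32L, literal_widths = FALSE,
                           depths = c(2L, 2L, 4L, 2L), window = 4L,
                           dw_kernel = 3L, heads = NULL, ffn_ratio = 4,
                           conv_branch = TRUE, attn_branch = TRUE,
                           interactions = TRUE, swap_interactions = FALSE,
                           decoder_mixing = FALSE,
                           type = c("mixing", "spectral_mlp"),
                           hidden = c(64L, 32L), normalize_input = TRUE) {
  type <- match.arg(type)
  stopifnot(length(depths) == 4L, n_classes >= 2L)
  if (!conv_branch && !attn_branch) {
    stop("at least one branch must be enabled", call. = FALSE)
  }
  if (interactions && !(conv_branch && attn_branch)) interactions <- FALSE
  w0 <- if (literal_widths) as.integer(in_channels) else as.integer(base_width)
  widths <- w0 * c(2L, 4L, 8L, 16L)
  if (is.null(heads)) heads <- pmax(1L, widths %/% 16L)
  if (any(widths %% heads != 0L)) {
    stop("stage widths must be divisible by head counts", call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), widths = widths,
                 depths = as.integer(depths), window = as.integer(window),
                 dw_kernel = as.integer(dw_kernel), heads = as.integer(heads),
                 ffn_ratio = ffn_ratio, conv_branch = conv_branch,
                 attn_branch = attn_branch, interactions = interactions,
                 swap_interactions = swap_interactions,
                 decoder_mixing = decoder_mixing, type = type,
                 hidden = as.integer(hidden),
                 normalize_input = isTRUE(normalize_input)),
            class = "network_config")
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_conv <- function(k, cin, cout) {
  list(w = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

init_block <- function(C, cfg) {
  p <- list(ln1 = list(g = rep(1, C), b = numeric(C)))
  if (cfg$conv_branch) {
    k <- cfg$dw_kernel
    p$dw <- list(w = array(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))),
                           c(k, k, C)),
                 b = numeric(C))
  }
  if (cfg$attn_branch) {
    sd <- sqrt(1 / C)
    p$attn <- list(wq = rnorm_mat(C, C, sd), bq = numeric(C),
                   wk = rnorm_mat(C, C, sd), bk = numeric(C),
                   wv = rnorm_mat(C, C, sd), bv = numeric(C),
                   wo = rnorm_mat(C, C, sd), bo = numeric(C))
  }
  if (cfg$interactions) {
    Cr <- max(1L, C %/% 4L)  # bottleneck ratio 4 in the channel gate
    p$ci <- list(w1 = rnorm_mat(C, Cr, sqrt(2 / C)), b1 = numeric(Cr),
                 w2 = rnorm_mat(Cr, C, sqrt(2 / Cr)), b2 = numeric(C))
    p$si <- list(w = rnorm_mat(C, 1L, sqrt(1 / C)), b = 0)
  }
  Cc <- C * (cfg$conv_branch + cfg$attn_branch)
  hid <- as.integer(round(cfg$ffn_ratio * C))
  p$ln2 <- list(g = rep(1, Cc), b = numeric(Cc))
  p$f1 <- list(w = rnorm_mat(Cc, hid, sqrt(2 / Cc)), b = numeric(hid))
  p$f2 <- list(w = rnorm_mat(hid, C, sqrt(2 / hid)), b = numeric(C))
  p
}

#' Build a network from a configuration
#'
#' Initializes all parameters (seeded) and returns the model object used by
#' [cest_train()] and [predict.cest_network()].
#'
#' @param config A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return Object of class `cest_network`: list(config, params).
#' @export
build_network <- function(config, seed = 42L) {
  stopifnot(inherits(config, "network_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  if (config$type == "spectral_mlp") {
    sizes <- c(config$in_channels, config$hidden, config$n_classes)
    layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
      list(w = rnorm_mat(sizes[i], sizes[i + 1], sqrt(2 / sizes[i])),
           b = numeric(sizes[i + 1]))
    })
    return(structure(list(config = config, params = list(layers = layers)),
                     class = "cest_network"))
  }
  wd <- config$widths
  params <- list(stem = init_conv(3L, config$in_channels, wd[1]))
  params$enc <- lapply(1:4, function(s) {
    st <- list(blocks = lapply(seq_len(config$depths[s]),
                               function(i) init_block(wd[s], config)))
    if (s < 4L) st$down <- init_conv(2L, wd[s], wd[s + 1])
    st
  })
  params$dec <- lapply(3:1, function(s) {
    d <- list(up = init_conv(2L, wd[s + 1], wd[s]),
              c1 = init_conv(3L, 2L * wd[s], wd[s]),
              c2 = init_conv(3L, wd[s], wd[s]))
    if (config$decoder_mixing) {
      d$blocks <- lapply(seq_len(config$depths[s]),
                         function(i) init_block(wd[s], config))
    }
    d
  })
  # near-zero head: the initial posterior is ~0.5 everywhere, which keeps
  # the first large-schedule updates from saturating the softmax
  params$head <- list(w = rnorm_mat(wd[1], config$n_classes, 0.01),
                      b = numeric(config$n_classes))
  structure(list(config = config, params = params), class = "cest_network")
}

#' Number of trainable parameters
#' @param model A `cest_network` or `cest_fit`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  if (inherits(model, "cest_fit")) model <- model$model
  tree_count(model$params)
}

#' @export
print.cest_network <- function(x, ...) {
  cfg <- x$config
  if (cfg$type == "spectral_mlp") {
    cat(sprintf("<cest_network> spectral MLP %s, %d parameters\n",
                paste(c(cfg$in_channels, cfg$hidden, cfg$n_classes),
                      collapse = "-"),
                n_params(x)))
    return(invisible(x))
  }
  branches <- c(if (cfg$conv_branch) "DwConv", if (cfg$attn_branch) "W-MSA")
  cat(sprintf(
    "<cest_network> mixing encoder-decoder\n  widths %s, depths %s, window %d, heads %s\n  branches: %s%s; %d parameters\n",
    paste(cfg$widths, collapse = "/"), paste(cfg$depths, collapse = "/"),
    cfg$window, paste(cfg$heads, collapse = "/"),
    paste(branches, collapse = " + "),
    if (cfg$interactions) " with bi-directional gates" else "",
    n_params(x)))
  invisible(x)
}

# ---- mixing block -------------------------------------------------------

mixing_block_fw <- function(x, p, cfg, stage) {
  d <- dim(x)
  hw <- d[1] * d[2]
  C <- d[3]
  xm <- matrix(x, hw, C)
  ln1 <- ln_fw(xm, p$ln1$g, p$ln1$b)
  xn <- array(ln1$y, d)
  cache <- list(dimx = d, ln1 = ln1)
  convf <- attnf <- NULL
  if (cfg$conv_branch) {
    dwr <- dwconv_fw(xn, p$dw$w, p$dw$b)
    cache$dw <- dwr$cache
    convf <- matrix(dwr$y, hw, C)
  }
  if (cfg$attn_branch) {
    at <- wmsa_fw(xn, p$attn, cfg$window, cfg$heads[stage])
    cache$attn <- at$cache
    attnf <- matrix(at$y, hw, C)
  }
  conv_out <- convf
  attn_out <- attnf
  if (cfg$interactions) {
    # channel gate computed from one branch, applied to the other; the
    # default direction is conv -> channel gate -> attention output and
    # attention -> spatial gate -> conv output
    csrc <- if (cfg$swap_interactions) attnf else convf
    ssrc <- if (cfg$swap_interactions) convf else attnf
    g <- matrix(colMeans(csrc), 1L, C)
    u <- g %*% p$ci$w1 + rep(p$ci$b1, each = 1L)
    gl <- gelu_fw(u)
    z <- gl$y %*% p$ci$w2 + rep(p$ci$b2, each = 1L)
    gate_c <- sigmoid(as.vector(z))
    svec <- as.vector(ssrc %*% p$si$w) + p$si$b
    gate_s <- sigmoid(svec)
    if (cfg$swap_interactions) {
      conv_out <- convf * rep(gate_c, each = hw)
      attn_out <- attnf * gate_s
    } else {
      attn_out <- attnf * rep(gate_c, each = hw)
      conv_out <- convf * gate_s
    }
    cache$ci <- list(g = g, u = u, gl = gl, gate_c = gate_c)
    cache$si <- list(gate_s = gate_s)
    cache$convf <- convf
    cache$attnf <- attnf
  }
  cat_m <- cbind(conv_out, attn_out)  # NULLs drop automatically
  ln2 <- ln_fw(cat_m, p$ln2$g, p$ln2$b)
  u1 <- ln2$y %*% p$f1$w + rep(p$f1$b, each = hw)
  g1 <- gelu_fw(u1)
  delta <- g1$y %*% p$f2$w + rep(p$f2$b, each = hw)
  y <- x + array(delta, d)
  cache$ln2 <- ln2
  cache$g1 <- g1
  cache$catn <- ln2$y
  list(y = y, cache = cache,
       conv_out = conv_out, attn_out = attn_out)  # exposed for tests
}

mixing_block_bw <- function(dy, p, cfg, stage, cache) {
  d <- cache$dimx
  hw <- d[1] * d[2]
  C <- d[3]
  dym <- matrix(dy, hw, C)
  grads <- list(ln1 = NULL)
  # FFN backward (residual: dx accumulates dy directly)
  ddelta <- dym
  grads$f2 <- list(w = crossprod(cache$g1$y, ddelta), b = colSums(ddelta))
  da <- tcrossprod(ddelta, p$f2$w)
  du1 <- gelu_bw(da, cache$g1$cache)
  grads$f1 <- list(w = crossprod(cache$catn, du1), b = colSums(du1))
  dcatn <- tcrossprod(du1, p$f1$w)
  ln2b <- ln_bw(dcatn, p$ln2$g, cache$ln2$cache)
  grads$ln2 <- list(g = ln2b$dgamma, b = ln2b$dbeta)
  dcat <- ln2b$dx
  nb <- cfg$conv_branch + cfg$attn_branch
  if (cfg$conv_branch && cfg$attn_branch) {
    dconv_out <- dcat[, seq_len(C), drop = FALSE]
    dattn_out <- dcat[, C + seq_len(C), drop = FALSE]
  } else if (cfg$conv_branch) {
    dconv_out <- dcat
    dattn_out <- NULL
  } else {
    dconv_out <- NULL
    dattn_out <- dcat
  }
  dconvf <- dconv_out
  dattnf <- dattn_out
  if (cfg$interactions) {
    gate_c <- cache$ci$gate_c
    gate_s <- cache$si$gate_s
    convf <- cache$convf
    attnf <- cache$attnf
    if (cfg$swap_interactions) {
      gated_c_target <- convf; dgated_c <- dconv_out
      gated_s_target <- attnf; dgated_s <- dattn_out
      dconvf <- dconv_out * rep(gate_c, each = hw)
      dattnf <- dattn_out * gate_s
    } else {
      gated_c_target <- attnf; dgated_c <- dattn_out
      gated_s_target <- convf; dgated_s <- dconv_out
      dattnf <- dattn_out * rep(gate_c, each = hw)
      dconvf <- dconv_out * gate_s
    }
    # channel-gate path
    dgate_c <- colSums(dgated_c * gated_c_target)
    dz <- matrix(dgate_c * gate_c * (1 - gate_c), 1L, C)
    grads$ci <- list(w1 = NULL, b1 = NULL, w2 = crossprod(cache$ci$gl$y, dz),
                     b2 = as.vector(dz))
    dh <- tcrossprod(dz, p$ci$w2)
    du <- gelu_bw(dh, cache$ci$gl$cache)
    grads$ci$w1 <- crossprod(cache$ci$g, du)
    grads$ci$b1 <- as.vector(du)
    dg <- tcrossprod(du, p$ci$w1)  # 1 x C
    dcsrc_gate <- matrix(rep(as.vector(dg) / hw, each = hw), hw, C)
    # spatial-gate path
    dgate_s <- rowSums(dgated_s * gated_s_target)
    dsv <- dgate_s * gate_s * (1 - gate_s)
    ssrc <- if (cfg$swap_interactions) convf else attnf
    grads$si <- list(w = crossprod(ssrc, matrix(dsv, hw, 1L)), b = sum(dsv))
    dssrc_gate <- matrix(dsv, hw, 1L) %*% t(p$si$w)
    if (cfg$swap_interactions) {
      dattnf <- dattnf + dcsrc_gate
      dconvf <- dconvf + dssrc_gate
    } else {
      dconvf <- dconvf + dcsrc_gate
      dattnf <- dattnf + dssrc_gate
    }
  }
  dxn <- matrix(0, hw, C)
  if (cfg$conv_branch) {
    dwb <- dwconv_bw(array(dconvf, d), p$dw$w, cache$dw)
    grads$dw <- list(w = dwb$dw, b = dwb$db)
    dxn <- dxn + matrix(dwb$dx, hw, C)
  }
  if (cfg$attn_branch) {
    ab <- wmsa_bw(array(dattnf, d), p$attn, cache$attn)
    grads$attn <- ab$grads
    dxn <- dxn + matrix(ab$dx, hw, C)
  }
  ln1b <- ln_bw(dxn, p$ln1$g, cache$ln1$cache)
  grads$ln1 <- list(g = ln1b$dgamma, b = ln1b$dbeta)
  dx <- dy + array(ln1b$dx, d)
  # order grads to mirror the parameter list exactly
  list(dx = dx, grads = grads[names(p)])
}

# ---- full network forward / backward -----------------------------------

# Pads input spatially to a multiple of 8 (three 2x downsamplings) and
# crops the logits back; returns list(logits H x W x N, cache).
net_forward <- function(model, x) {
  cfg <- model$config
  p <- model$params
  if (isTRUE(cfg$normalize_input) && cfg$type == "mixing") {
    # fixed per-sample affine; a constant w.r.t. the parameters, so it needs
    # no backward path. The spectral MLP sees raw per-pixel spectra (its
    # signal lives in absolute Z-amplitudes).
    x <- (x - mean(x)) / (stats::sd(x) + 1e-6)
  }
  if (cfg$type == "spectral_mlp") return(mlp_forward(model, x))
  d0 <- dim(x)
  ph <- (8L - d0[1] %% 8L) %% 8L
  pw <- (8L - d0[2] %% 8L) %% 8L
  if (ph || pw) {
    xp <- array(0, c(d0[1] + ph, d0[2] + pw, d0[3]))
    xp[seq_len(d0[1]), seq_len(d0[2]), ] <- x
    x <- xp
  }
  cache <- list(dim0 = d0, pad = c(ph, pw))
  st <- conv2d_fw(x, p$stem$w, p$stem$b, pad = 1L)
  cache$stem <- st$cache
  h <- st$y
  cache$enc <- vector("list", 4L)
  skips <- vector("list", 3L)
  for (s in 1:4) {
    bl <- vector("list", cfg$depths[s])
    for (i in seq_len(cfg$depths[s])) {
      r <- mixing_block_fw(h, p$enc[[s]]$blocks[[i]], cfg, s)
      bl[[i]] <- r$cache
      h <- r$y
    }
    cache$enc[[s]] <- list(blocks = bl)
    if (s < 4L) {
      skips[[s]] <- h
      dn <- conv2d_fw(h, p$enc[[s]]$down$w, p$enc[[s]]$down$b,
                      pad = 0L, stride = 2L)
      cache$enc[[s]]$down <- dn$cache
      h <- dn$y
    }
  }
  cache$dec <- vector("list", 3L)
  for (j in 1:3) {            # decodes to stage 3, 2, 1 resolutions
    s <- 4L - j
    dp <- p$dec[[j]]
    up <- tconv_fw(h, dp$up$w, dp$up$b)
    skip <- skips[[s]]
    dd <- dim(up$y)
    xin <- array(0, c(dd[1], dd[2], dd[3] + dim(skip)[3]))
    xin[, , seq_len(dd[3])] <- up$y
    xin[, , dd[3] + seq_len(dim(skip)[3])] <- skip
    c1 <- conv2d_fw(xin, dp$c1$w, dp$c1$b, pad = 1L)
    a1 <- gelu_fw(c1$y)
    c2 <- conv2d_fw(a1$y, dp$c2$w, dp$c2$b, pad = 1L)
    a2 <- gelu_fw(c2$y)
    h <- a2$y
    dc <- list(up = up$cache, c1 = c1$cache, a1 = a1$cache,
               c2 = c2$cache, a2 = a2$cache, n_up = dd[3],
               n_skip = dim(skip)[3])
    if (cfg$decoder_mixing) {
      bl <- vector("list", cfg$depths[s])
      for (i in seq_len(cfg$depths[s])) {
        r <- mixing_block_fw(h, dp$blocks[[i]], cfg, s)
        bl[[i]] <- r$cache
        h <- r$y
      }
      dc$blocks <- bl
    }
    cache$dec[[j]] <- dc
  }
  dh <- dim(h)
  hm <- matrix(h, dh[1] * dh[2], dh[3])
  logits <- hm %*% p$head$w + rep(p$head$b, each = nrow(hm))
  cache$head_in <- hm
  cache$dimh <- dh
  logits <- array(logits, c(dh[1], dh[2], cfg$n_classes))
  logits <- logits[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
  list(logits = logits, cache = cache)
}

# dlogits: H x W x N on the *unpadded* extent.
net_backward <- function(model, dlogits, cache) {
  cfg <- model$config
  p <- model$params
  if (cfg$type == "spectral_mlp") return(mlp_backward(model, dlogits, cache))
  grads <- tree_zero(p)
  dh0 <- cache$dimh
  dlp <- array(0, c(dh0[1], dh0[2], cfg$n_classes))
  d0 <- cache$dim0
  dlp[seq_len(d0[1]), seq_len(d0[2]), ] <- dlogits
  dlm <- matrix(dlp, dh0[1] * dh0[2], cfg$n_classes)
  grads$head$w <- crossprod(cache$head_in, dlm)
  grads$head$b <- colSums(dlm)
  dh <- array(tcrossprod(dlm, p$head$w), dh0)
  for (j in 3:1) {
    s <- 4L - j
    dp <- p$dec[[j]]
    dc <- cache$dec[[j]]
    if (cfg$decoder_mixing) {
      for (i in rev(seq_len(cfg$depths[s]))) {
        r <- mixing_block_bw(dh, dp$blocks[[i]], cfg, s, dc$blocks[[i]])
        grads$dec[[j]]$blocks[[i]] <- r$grads
        dh <- r$dx
      }
    }
    da2 <- gelu_bw(dh, dc$a2)
    b2 <- conv2d_bw(da2, dp$c2$w, dc$c2)
    grads$dec[[j]]$c2 <- list(w = b2$dw, b = b2$db)
    da1 <- gelu_bw(b2$dx, dc$a1)
    b1 <- conv2d_bw(da1, dp$c1$w, dc$c1)
    grads$dec[[j]]$c1 <- list(w = b1$dw, b = b1$db)
    dup <- b1$dx[, , seq_len(dc$n_up), drop = FALSE]
    dskip <- b1$dx[, , dc$n_up + seq_len(dc$n_skip), drop = FALSE]
    bu <- tconv_bw(dup, dp$up$w, dc$up)
    grads$dec[[j]]$up <- list(w = bu$dw, b = bu$db)
    dh <- bu$dx
    # stash the skip gradient to merge when the encoder pass reaches stage s
    cache$dec[[j]]$dskip <- dskip
  }
  for (s in 4:1) {
    if (s < 4L) {
      bd <- conv2d_bw(dh, p$enc[[s]]$down$w, cache$enc[[s]]$down)
      grads$enc[[s]]$down <- list(w = bd$dw, b = bd$db)
      dh <- bd$dx + cache$dec[[4L - s]]$dskip
    }
    for (i in rev(seq_len(cfg$depths[s]))) {
      r <- mixing_block_bw(dh, p$enc[[s]]$blocks[[i]], cfg, s,
                           cache$enc[[s]]$blocks[[i]])
      grads$enc[[s]]$blocks[[i]] <- r$grads
      dh <- r$dx
    }
  }
  bs <- conv2d_bw(dh, p$stem$w, cache$stem)
  grads$stem <- list(w = bs$dw, b = bs$db)
  list(grads = grads, dx = bs$dx)
}

# ---- spectral MLP baseline ---------------------------------------------

mlp_forward <- function(model, x) {
  d <- dim(x)
  h <- matrix(x, d[1] * d[2], d[3])
  layers <- model$params$layers
  nl <- length(layers)
  acts <- vector("list", nl)
  for (i in seq_len(nl)) {
    z <- h %*% layers[[i]]$w + rep(layers[[i]]$b, each = nrow(h))
    if (i < nl) {
      g <- gelu_fw(z)
      acts[[i]] <- list(input = h, gcache = g$cache)
      h <- g$y
    } else {
      acts[[i]] <- list(input = h)
      h <- z
    }
  }
  list(logits = array(h, c(d[1], d[2], ncol(h))),
       cache = list(acts = acts, dim0 = d))
}

mlp_backward <- function(model, dlogits, cache) {
  layers <- model$params$layers
  nl <- length(layers)
  d <- cache$dim0
  dz <- matrix(dlogits, d[1] * d[2], dim(dlogits)[3])
  grads <- list(layers = vector("list", nl))
  for (i in rev(seq_len(nl))) {
    a <- cache$acts[[i]]
    grads$layers[[i]] <- list(w = crossprod(a$input, dz), b = colSums(dz))
    dz <- tcrossprod(dz, layers[[i]]$w)
    if (i > 1L) dz <- gelu_bw(dz, cache$acts[[i - 1L]]$gcache)
  }
  list(grads = grads, dx = array(dz, d))
}

#' Forward pass producing per-pixel class probabilities
#'
#' Runs the network on one `H x W x C` stack (or a [cest_volume()]) and
#' applies the per-pixel softmax head. Probabilities sum to one per pixel.
#'
#' @param object A `cest_network`.
#' @param newdata A `cest_volume` or `H x W x C` array.
#' @param ... Unused.
#' @return `H x W x N` array of class probabilities.
#' @export
predict.cest_network <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "cest_volume")) newdata$data else newdata
  if (dim(x)[3] != object$config$in_channels) {
    stop(sprintf("input has %d channels, model expects %d", dim(x)[3],
                 object$config$in_channels), call. = FALSE)
  }
  fw <- net_forward(object, x)
  d <- dim(fw$logits)
  pm <- softmax_rows(matrix(fw$logits, d[1] * d[2], d[3]))
  array(pm, d)
}

#' Per-pixel spectral classifier baseline
#'
#' Applies the spectral-MLP network to each pixel's Z-spectrum
#' independently (no spatial context by construction).
#'
#' @param model A `cest_network` with `type = "spectral_mlp"`.
#' @param zspec Either a length-`C` vector or an `n x C` matrix of spectra.
#' @return Matrix of class probabilities (rows sum to 1).
#' @export
spectral_mlp_baseline <- function(model, zspec) {
  stopifnot(model$config$type == "spectral_mlp")
  if (is.null(dim(zspec))) zspec <- matrix(zspec, 1L)
  if (ncol(zspec) != model$config$in_channels) {
    stop("input length must equal the offset count", call. = FALSE)
  }
  x <- array(zspec, c(nrow(zspec), 1L, ncol(zspec)))
  fw <- mlp_forward(model, x)
  softmax_rows(matrix(fw$logits, nrow(zspec), model$config$n_classes))
}
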