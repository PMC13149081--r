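# Architecture contracts: window partition, attention, branches, gates,
# shapes, parameter census, and exactness of the hand-written gradients.

test_that("window partition tiles, pads, and inverts exactly", {
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- window_partition(x, 4L)
  expect_equal(dim(p$tiles), c(16, 4, 3))
  expect_equal(window_reverse(p), x)

  x6 <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  p6 <- window_partition(x6, 4L)
  expect_equal(p6$pad, c(2, 2))
  expect_equal(dim(p6$tiles), c(16, 4, 2))
  expect_equal(window_reverse(p6), x6)

  x4 <- array(rnorm(16 * 1), c(4, 4, 1))
  p4 <- window_partition(x4, 4L)
  expect_equal(dim(p4$tiles)[2], 1L)
  expect_equal(as.vector(p4$tiles), as.vector(x4))
})

test_that("W-MSA matches dense attention per window and leaks nothing across windows", {
  set.seed(3)
  C <- 8L
  p <- list(wq = matrix(rnorm(C * C, sd = 0.3), C), bq = rnorm(C, sd = 0.1),
            wk = matrix(rnorm(C * C, sd = 0.3), C), bk = rnorm(C, sd = 0.1),
            wv = matrix(rnorm(C * C, sd = 0.3), C), bv = rnorm(C, sd = 0.1),
            wo = matrix(rnorm(C * C, sd = 0.3), C), bo = rnorm(C, sd = 0.1))
  x <- array(rnorm(8 * 8 * C), c(8, 8, C))
  for (heads in c(1L, 2L)) {
    out <- cestmix:::wmsa_fw(x, p, 4L, heads)$y
    # oracle: dense attention on each 4x4 window separately
    for (wr in 0:1) for (wc in 0:1) {
      rows <- wr * 4 + 1:4; cols <- wc * 4 + 1:4
      tok <- matrix(x[rows, cols, ], 16, C)
      ref <- dense_attention(tok, p, heads)
      expect_equal(matrix(out[rows, cols, ], 16, C), ref, tolerance = 1e-5)
    }
  }
  # locality: perturbing one window leaves the others untouched
  x2 <- x
  x2[1:4, 1:4, ] <- x2[1:4, 1:4, ] + 5
  o1 <- cestmix:::wmsa_fw(x, p, 4L, 2L)$y
  o2 <- cestmix:::wmsa_fw(x2, p, 4L, 2L)$y
  expect_equal(o1[5:8, , ], o2[5:8, , ])
  expect_equal(o1[1:4, 5:8, ], o2[1:4, 5:8, ])
  # constancy: identical tokens give identical outputs
  xc <- array(rep(rnorm(C), each = 16), c(4, 4, C))
  oc <- cestmix:::wmsa_fw(xc, p, 4L, 1L)$y
  expect_lt(max(abs(sweep(matrix(oc, 16, C), 2, matrix(oc, 16, C)[1, ]))), 1e-10)
})

test_that("depthwise convolution is channel-separable with same padding", {
  set.seed(4)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  # identity kernel reproduces the input
  wid <- array(0, c(3, 3, 2)); wid[2, 2, ] <- 1
  y <- cestmix:::dwconv_fw(x, wid, c(0, 0))$y
  expect_equal(y, x)
  # impulse reveals the kernel footprint (direct convolution oracle)
  w <- array(rnorm(9 * 2), c(3, 3, 2))
  imp <- array(0, c(5, 5, 2)); imp[3, 3, 1] <- 1
  yi <- cestmix:::dwconv_fw(imp, w, c(0, 0))$y
  expect_equal(yi[2:4, 2:4, 1], w[3:1, 3:1, 1])  # flipped kernel footprint
  expect_equal(max(abs(yi[, , 2])), 0)  # channels never mix
  # channel c output depends only on channel c input
  x2 <- x; x2[, , 2] <- rnorm(36)
  y1 <- cestmix:::dwconv_fw(x, w, c(0, 0))$y
  y2 <- cestmix:::dwconv_fw(x2, w, c(0, 0))$y
  expect_equal(y1[, , 1], y2[, , 1])
})

test_that("channel and spatial gates behave as documented", {
  set.seed(5)
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 2)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  bp <- net$params$enc[[1]]$blocks[[1]]
  # zero-initialized gate projections give gates exactly 1/2, so the gated
  # branches are exactly half the ungated ones
  bp0 <- bp
  bp0$ci$w2[] <- 0; bp0$ci$b2[] <- 0
  bp0$si$w[] <- 0; bp0$si$b <- 0
  on_r <- cestmix:::mixing_block_fw(x, bp0, cfg, 1L)
  cfg_off <- cfg; cfg_off$interactions <- FALSE
  off_r <- cestmix:::mixing_block_fw(x, bp0, cfg_off, 1L)
  expect_equal(on_r$conv_out, 0.5 * off_r$conv_out, tolerance = 1e-12)
  expect_equal(on_r$attn_out, 0.5 * off_r$attn_out, tolerance = 1e-12)
  # gates always in (0,1) for any finite input
  r <- cestmix:::mixing_block_fw(x, bp, cfg, 1L)
  expect_true(all(r$cache$ci$gate_c > 0 & r$cache$ci$gate_c < 1))
  expect_true(all(r$cache$si$gate_s > 0 & r$cache$si$gate_s < 1))
  # spatial gate has one value per pixel
  expect_length(r$cache$si$gate_s, 64L)
  # mean-pool invariance: a constant input at doubled extent yields the
  # same channel gate (gate source = attention branch, which is exactly
  # extent-invariant on constant inputs)
  cfg_swap <- cfg; cfg_swap$swap_interactions <- TRUE
  vals <- rnorm(4)
  xc <- array(rep(vals, each = 16), c(4, 4, 4))
  xc2 <- array(rep(vals, each = 64), c(8, 8, 4))
  g1 <- cestmix:::mixing_block_fw(xc, bp, cfg_swap, 1L)$cache$ci$gate_c
  g2 <- cestmix:::mixing_block_fw(xc2, bp, cfg_swap, 1L)$cache$ci$gate_c
  expect_equal(g1, g2, tolerance = 1e-10)
  # spatially permuting the gate-source input permutes the spatial gate map
  # identically (the 1x1 reduction is pixel-local); conv-source default
  # direction uses the attention features, so probe the op directly
  feats <- matrix(rnorm(64 * 4), 64, 4)
  s1 <- cestmix:::sigmoid(as.vector(feats %*% bp$si$w) + bp$si$b)
  perm <- sample(64)
  s2 <- cestmix:::sigmoid(as.vector(feats[perm, ] %*% bp$si$w) + bp$si$b)
  expect_equal(s2, s1[perm])
})

test_that("network preserves shapes, softmax head sums to one, ablations order parameters", {
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 1)
  for (hw in list(c(8, 8), c(12, 16), c(10, 10))) {  # incl. non-divisible
    x <- array(rnorm(prod(hw) * 3), c(hw, 3))
    pr <- predict(net, x)
    expect_equal(dim(pr), c(hw, 2))
    expect_true(all(abs(apply(pr, c(1, 2), sum) - 1) < 1e-6))
  }
  n_full <- n_params(net)
  n_noint <- n_params(build_network(tiny_net_config(interactions = FALSE),
                                    seed = 1))
  n_conv <- n_params(build_network(tiny_net_config(attn_branch = FALSE),
                                   seed = 1))
  n_attn <- n_params(build_network(tiny_net_config(conv_branch = FALSE),
                                   seed = 1))
  expect_lt(n_conv, n_noint)
  expect_lte(n_noint, n_full)
  expect_lt(n_attn, n_noint)
  expect_error(network_config(conv_branch = FALSE, attn_branch = FALSE),
               "branch")
})

test_that("hand-written gradients match finite differences", {
  set.seed(11)
  configs <- list(full = tiny_net_config(),
                  conv_only = tiny_net_config(attn_branch = FALSE),
                  mlp = network_config(in_channels = 3L, type = "spectral_mlp",
                                       hidden = c(6L, 4L)))
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    net <- build_network(cfg, seed = 7)
    x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
    t0 <- matrix(rbinom(64, 1, 0.4), 8, 8)
    lossfun <- function(params) {
      net$params <- params
      fw <- cestmix:::net_forward(net, x)
      cestmix:::loss_and_grad(fw$logits, t0, c(1, 2), 1, 1)$loss
    }
    fw <- cestmix:::net_forward(net, x)
    lg <- cestmix:::loss_and_grad(fw$logits, t0, c(1, 2), 1, 1)
    bw <- cestmix:::net_backward(net, lg$dlogits, fw$cache)
    gflat <- cestmix:::tree_flatten(bw$grads)
    pflat <- cestmix:::tree_flatten(net$params)
    idx <- sort(sample(length(pflat), min(40L, length(pflat))))
    eps <- 1e-4  # central differences; smaller eps hits roundoff when a
                 # pixel's posterior saturates
    num <- vapply(idx, function(i) {
      pp <- pflat; pp[i] <- pp[i] + eps
      lp <- lossfun(cestmix:::tree_unflatten(net$params, pp))
      pp[i] <- pflat[i] - eps
      lm <- lossfun(cestmix:::tree_unflatten(net$params, pp))
      (lp - lm) / (2 * eps)
    }, numeric(1))
    rel <- abs(num - gflat[idx]) / pmax(1e-5, abs(num) + abs(gflat[idx]))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("one SGD step on a single batch reduces its loss", {
  set.seed(12)
  cfg <- tiny_net_config()
  net <- build_network(cfg, seed = 3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  t0 <- matrix(rbinom(64, 1, 0.3), 8, 8)
  fw <- cestmix:::net_forward(net, x)
  lg <- cestmix:::loss_and_grad(fw$logits, t0, c(1, 2), 1, 1)
  bw <- cestmix:::net_backward(net, lg$dlogits, fw$cache)
  net$params <- cestmix:::tree_map2(function(p, g) p - 0.05 * g,
                                    net$params, bw$grads)
  fw2 <- cestmix:::net_forward(net, x)
  lg2 <- cestmix:::loss_and_grad(fw2$logits, t0, c(1, 2), 1, 1)
  expect_lt(lg2$loss, lg$loss)
})

test_that("spectral MLP is pixel-independent and learns a separable toy", {
  set.seed(13)
  cfg <- network_config(in_channels = 5L, type = "spectral_mlp",
                        hidden = c(16L, 8L))
  net <- build_network(cfg, seed = 5)
  # pixel independence: permuting pixels permutes outputs identically
  x <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  pr <- predict(net, x)
  xm <- matrix(x, 16, 5)
  perm <- sample(16)
  pr_perm <- predict(net, array(xm[perm, ], c(4, 4, 5)))
  expect_equal(matrix(pr_perm, 16, 2), matrix(pr, 16, 2)[perm, ],
               tolerance = 1e-12)
  expect_true(all(abs(rowSums(matrix(pr, 16, 2)) - 1) < 1e-9))
  expect_error(spectral_mlp_baseline(net, rnorm(4)), "offset")

  # two Gaussian-amplitude classes, linearly separable spectra
  n <- 400L
  amp <- c(rnorm(n / 2, 1, 0.1), rnorm(n / 2, 2, 0.1))
  lab <- rep(c(0, 1), each = n / 2)
  spec <- t(sapply(amp, function(a) a * exp(-(seq(-2, 2, 1))^2) +
                     rnorm(5, sd = 0.05)))
  params <- net$params
  for (step in 1:150) {
    i <- sample(n, 16)
    gsum <- NULL
    for (j in i) {
      xx <- array(spec[j, ], c(1, 1, 5))
      net$params <- params
      fw <- cestmix:::net_forward(net, xx)
      lg <- cestmix:::loss_and_grad(fw$logits, matrix(lab[j], 1, 1),
                                    c(1, 1), 1, 0)
      bw <- cestmix:::net_backward(net, lg$dlogits, fw$cache)
      gsum <- if (is.null(gsum)) bw$grads else
        cestmix:::tree_map2(`+`, gsum, bw$grads)
    }
    params <- cestmix:::tree_map2(function(p, g) p - 0.5 * g / 16,
                                  params, gsum)
  }
  net$params <- params
  pr <- spectral_mlp_baseline(net, spec)
  acc <- mean((pr[, 2] > 0.5) == lab)
  expect_gte(acc, 0.95)
})
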