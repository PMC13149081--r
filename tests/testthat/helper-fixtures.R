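# Shared fixtures: everything is generated in code at test time.

# Tiny deterministic volume: linear ramp data, unit M0.
tiny_volume <- function(h = 12L, w = 12L, offsets = seq(-2, 2, by = 0.5)) {
  nc <- length(offsets)
  data <- array(seq_len(h * w * nc) / (h * w * nc), c(h, w, nc))
  cest_volume(data, matrix(1, h, w), offsets)
}

# Small easy phantom cohort used across training tests: 48 x 48 images so a
# tumor fits one 48/12 patch grid; strong APT contrast, low noise.
easy_phantom_config <- function(n = 12L, seed = 101L, noise = 0.01,
                                apt_effect = 0.03, image = 48L) {
  phantom_config(n_patients = n, image_size = image,
                 tumor_radius = c(6, 11), apt_effect = apt_effect,
                 noise_sigma = noise, seed = seed)
}

# Tiny network configuration for fast exact checks (8 x 8 inputs).
tiny_net_config <- function(in_channels = 3L, ...) {
  network_config(in_channels = in_channels, base_width = 2L,
                 depths = c(1L, 1L, 1L, 1L), ...)
}

# Constant-probability oracle predictions for a patch grid.
constant_predictions <- function(grid, p1) {
  lapply(seq_len(nrow(grid$origins)), function(i) {
    out <- array(0, c(grid$size, grid$size, 2L))
    out[, , 1] <- 1 - p1
    out[, , 2] <- p1
    out
  })
}

# Brute-force two-sided paired Wilcoxon by full 2^n sign-flip enumeration
# (midranks on |d|, zeros dropped) -- the independence oracle for the DP
# implementation.
wilcoxon_enumeration <- function(a, b) {
  d <- a - b
  dn <- d[d != 0]
  n <- length(dn)
  if (n == 0) return(1)
  r <- rank(abs(dn))
  W <- sum(r[dn > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  p_le <- mean(Wall <= W + 1e-9)
  p_ge <- mean(Wall >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Dense accumulator oracle for crop-and-stitch aggregation.
aggregate_bruteforce <- function(predictions, grid, crop) {
  s <- grid$size
  H <- grid$image_extent[1]; W <- grid$image_extent[2]
  nc <- dim(predictions[[1]])[3]
  acc <- array(0, c(H, W, nc)); cnt <- matrix(0, H, W)
  rmin <- min(grid$origins[, 1]); rmax <- max(grid$origins[, 1])
  cmin <- min(grid$origins[, 2]); cmax <- max(grid$origins[, 2])
  for (i in seq_along(predictions)) {
    o <- grid$origins[i, ]
    for (pr in 1:s) for (pc in 1:s) {
      keep_r <- (pr > crop || o[1] == rmin) && (pr <= s - crop || o[1] == rmax)
      keep_c <- (pc > crop || o[2] == cmin) && (pc <= s - crop || o[2] == cmax)
      if (keep_r && keep_c) {
        r <- o[1] + pr; c <- o[2] + pc
        acc[r, c, ] <- acc[r, c, ] + predictions[[i]][pr, pc, ]
        cnt[r, c] <- cnt[r, c] + 1
      }
    }
  }
  for (k in seq_len(nc)) {
    plane <- acc[, , k]
    plane[cnt > 0] <- plane[cnt > 0] / cnt[cnt > 0]
    plane[cnt == 0] <- NA_real_
    acc[, , k] <- plane
  }
  acc
}
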