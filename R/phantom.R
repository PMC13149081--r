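# Multi-pool Lorentzian phantom: synthetic multi-offset CEST volumes with
# known tumor masks, genotype-dependent Z-spectral structure, and the two
# acquisition-degradation operators (Rician noise, B0 shift).

#' Lorentzian pool parameters
#'
#' A single saturable proton pool of the multi-pool Z-spectrum model,
#' parameterized by its peak amplitude (fraction of M0), center offset and
#' full width at half maximum.
#'
#' @param name Text label (e.g. `"water"`, `"apt"`, `"noe"`).
#' @param amplitude Peak absorption amplitude `A` in `[0, 1)` (unitless
#'   fraction of M0).
#' @param center Resonance offset `delta` in ppm relative to water.
#' @param width Full width at half maximum `Gamma` in ppm; must be positive.
#' @return An object of class `pool_params`.
#' @export
pool_params <- function(name, amplitude, center, width) {
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("pool amplitude must be >= 0", call. = FALSE)
  }
  if (!is.numeric(width) || width <= 0) {
    stop("pool width (FWHM) must be > 0", call. = FALSE)
  }
  structure(list(name = as.character(name), amplitude = amplitude,
                 center = center, width = width),
            class = "pool_params")
}

#' Lorentzian absorption line
#'
#' Evaluates the standard Lorentzian line shape
#' `A * (Gamma/2)^2 / ((Gamma/2)^2 + (offset - delta)^2)` at each saturation
#' offset. The peak value `A` is attained at the pool center and the value
#' drops to `A/2` at `delta +/- Gamma/2`.
#'
#' @param offsets Numeric vector of saturation offsets in ppm.
#' @param pool A [pool_params()] object.
#' @return Numeric vector of per-offset absorption values.
#' @export
lorentzian <- function(offsets, pool) {
  stopifnot(inherits(pool, "pool_params"))
  if (pool$width <= 0) stop("pool width (FWHM) must be > 0", call. = FALSE)
  hw2 <- (pool$width / 2)^2
  pool$amplitude * hw2 / (hw2 + (offsets - pool$center)^2)
}

#' Tissue spectral parameters
#'
#' Bundles the Lorentzian pools of one tissue class. The default presets
#' (gray matter, white matter, tumor) carry water, a broad semi-solid MT
#' component, APT at +3.5 ppm, NOE at -3.5 ppm, creatine at +2.0 ppm and a
#' glucose-related pool at +1.2 ppm. Amplitudes are package configuration
#' chosen to give plausible Z-spectra, not quantitative claims.
#'
#' @param pools List of [pool_params()] objects.
#' @param label One of `"gray_matter"`, `"white_matter"`, `"tumor"`.
#' @return Object of class `tissue_params`.
#' @export
tissue_params <- function(pools, label) {
  stopifnot(is.list(pools), all(vapply(pools, inherits, TRUE, "pool_params")))
  structure(list(pools = pools, label = label), class = "tissue_params")
}

#' @rdname tissue_params
#' @param apt_amplitude,noe_amplitude Override the APT / NOE pool amplitudes
#'   of the preset (used for genotype-conditioned tumor spectra).
#' @export
tissue_preset <- function(label = c("gray_matter", "white_matter", "tumor"),
                          apt_amplitude = NULL, noe_amplitude = NULL) {
  label <- match.arg(label)
  base <- switch(label,
    gray_matter = list(apt = 0.035, noe = 0.040, mt = 0.10, water = 0.78,
                       cr = 0.015, glc = 0.010),
    # white matter: strong NOE from abundant myelin, larger MT background
    # (MT kept moderate so tumors stay darker at +3.5 ppm than any
    # background tissue, the expected APT-weighted contrast direction)
    white_matter = list(apt = 0.030, noe = 0.070, mt = 0.11, water = 0.74,
                        cr = 0.012, glc = 0.008),
    tumor = list(apt = 0.060, noe = 0.030, mt = 0.08, water = 0.80,
                 cr = 0.020, glc = 0.015))
  if (!is.null(apt_amplitude)) base$apt <- apt_amplitude
  if (!is.null(noe_amplitude)) base$noe <- noe_amplitude
  tissue_params(list(
    pool_params("water", base$water, 0.0, 2.2),
    pool_params("mt", base$mt, -1.0, 25.0),
    pool_params("apt", base$apt, 3.5, 1.2),
    pool_params("noe", base$noe, -3.5, 2.0),
    pool_params("cr", base$cr, 2.0, 0.8),
    pool_params("glc", base$glc, 1.2, 1.0)
  ), label)
}

#' Forward Z-spectrum model
#'
#' Evaluates `Z(offset) = 1 - sum_pools lorentzian(offset)` for a tissue.
#' Errors if the summed absorption reaches 1 anywhere on the grid (Z must
#' stay in `(0, 1]`).
#'
#' @param params A [tissue_params()] object.
#' @param offsets Numeric vector of offsets in ppm.
#' @return Numeric vector of Z-values (S/M0) per offset.
#' @export
simulate_zspectrum <- function(params, offsets) {
  stopifnot(inherits(params, "tissue_params"))
  absorption <- Reduce(`+`, lapply(params$pools, lorentzian, offsets = offsets))
  if (any(absorption >= 1)) {
    stop("pool amplitudes sum to >= 1 on the offset grid; Z would leave (0,1]",
         call. = FALSE)
  }
  1 - absorption
}

#' Default 41-point acquisition offset grid
#'
#' 41 evenly spaced saturation offsets from -5.0 to +5.0 ppm (0.25 ppm
#' spacing); the saturation-free M0 reference (nominally 100 ppm) is stored
#' separately, not on this grid.
#'
#' @return Numeric vector of length 41.
#' @export
default_offsets <- function() seq(-5, 5, length.out = 41L)

#' CEST volume container
#'
#' One patient-slice stack of normalized Z-value images (`S/M0`) plus the M0
#' reference image and the offset list.
#'
#' @param data Array `H x W x C` of Z-values.
#' @param m0 Matrix `H x W` of (strictly positive) M0 intensities.
#' @param offsets Numeric vector of length `C`, ppm.
#' @return Object of class `cest_volume`.
#' @export
cest_volume <- function(data, m0, offsets) {
  stopifnot(length(dim(data)) == 3L, length(offsets) == dim(data)[3L])
  if (!all(dim(m0) == dim(data)[1:2])) {
    stop("M0 image and CEST stack have different spatial extents", call. = FALSE)
  }
  if (!all(is.finite(data))) stop("non-finite Z-values", call. = FALSE)
  structure(list(data = data, m0 = m0, offsets = as.numeric(offsets)),
            class = "cest_volume")
}

#' @export
print.cest_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cest_volume> %d x %d pixels, %d offsets (%.2f .. %.2f ppm)\n",
              d[1], d[2], d[3], min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Phantom configuration
#'
#' The stated acquisition world: image geometry, offset grid, tumor geometry,
#' genotype effect sizes, and degradation levels. The per-class genotype
#' effect follows the direction reported for gliomas in this cohort: class-1
#' tumors (IDH-mutant / MGMT-methylated analogue) get a higher APT and a
#' lower NOE amplitude than class-0 tumors; `flip_effect = TRUE` reverses it.
#'
#' @param n_patients Number of synthetic patients.
#' @param image_size Pixels per axis (square image); clinical geometry is 240.
#' @param offsets Offset grid in ppm (default [default_offsets()]).
#' @param tumor_radius Range (min, max) of tumor blob radii in pixels.
#' @param class_balance Fraction of class-1 patients.
#' @param tumor_apt Base tumor APT amplitude (class 0); raise it for
#'   high-contrast ("easy") phantoms.
#' @param tumor_noe Base tumor NOE amplitude (class 0).
#' @param apt_effect Additive APT amplitude shift applied to class-1 tumors
#'   (class-0 tumors use the base amplitude).
#' @param noe_effect Additive NOE amplitude shift applied (negatively) to
#'   class-1 tumors.
#' @param noise_sigma Rician noise level as a fraction of M0.
#' @param b0_amplitude Peak amplitude of the smooth B0 field map, ppm.
#' @param b0_smoothness Spatial correlation length of the B0 field, pixels.
#' @param flip_effect Reverse the genotype effect direction.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 20L, image_size = 240L,
                           offsets = default_offsets(),
                           tumor_radius = c(10, 25), class_balance = 0.5,
                           tumor_apt = 0.06, tumor_noe = 0.03,
                           apt_effect = 0.02, noe_effect = 0.01,
                           noise_sigma = 0.01, b0_amplitude = 0,
                           b0_smoothness = 24, flip_effect = FALSE,
                           seed = 42L) {
  stopifnot(n_patients >= 1, image_size >= 16, length(offsets) >= 2,
            class_balance >= 0, class_balance <= 1, noise_sigma >= 0)
  if (max(tumor_radius) > image_size / 2) {
    stop("tumor radius incompatible with image size", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 image_size = as.integer(image_size),
                 offsets = as.numeric(offsets),
                 tumor_radius = tumor_radius, class_balance = class_balance,
                 tumor_apt = tumor_apt, tumor_noe = tumor_noe,
                 apt_effect = apt_effect, noe_effect = noe_effect,
                 noise_sigma = noise_sigma, b0_amplitude = b0_amplitude,
                 b0_smoothness = b0_smoothness, flip_effect = flip_effect,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Smooth pseudo-random field in [-1,1]: white noise blurred by a separable
# Gaussian kernel, rescaled to unit maximum absolute value.
smooth_field <- function(h, w, smoothness) {
  z <- matrix(stats::rnorm(h * w), h, w)
  r <- max(3L, as.integer(round(smoothness)))
  k <- stats::dnorm(seq(-2, 2, length.out = 2L * r + 1L))
  k <- k / sum(k)
  blur1 <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    pad <- length(k) %/% 2L
    idx <- pmin(pmax(outer(seq_len(n), seq(-pad, pad), `+`), 1L), n)
    if (along == 1) {
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
      out
    } else {
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_along(k)) out <- out + k[j] * m[, idx[, j], drop = FALSE]
      out
    }
  }
  z <- blur1(blur1(z, 1), 2)
  z / max(abs(z))
}

# Tumor mask: thresholded smooth blob around a random center inside the
# brain ellipse; largest connected component kept (guarantees connectedness).
make_tumor_mask <- function(h, w, radius, brain) {
  repeat {
    cr <- sample(seq(ceiling(h * 0.25), floor(h * 0.75)), 1L)
    cc <- sample(seq(ceiling(w * 0.25), floor(w * 0.75)), 1L)
    if (brain[cr, cc]) break
  }
  rr <- matrix(seq_len(h), h, w)
  cc2 <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (rr - cr)^2 + (cc2 - cc)^2
  bump <- exp(-d2 / (2 * (radius / 1.5)^2))
  irregular <- 0.25 * smooth_field(h, w, radius / 2)
  mask <- (bump + irregular * bump > 0.45) & brain
  mask <- largest_component(mask)
  list(mask = mask, center = c(cr, cc))
}

# 4-connected largest component via flood fill (base R, no imaging deps).
largest_component <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    n <- 0L
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      n <- n + 1L
      r <- (p - 1L) %% h + 1L
      cl <- (p - 1L) %/% h + 1L
      if (r > 1L) stack <- c(stack, p - 1L)
      if (r < h) stack <- c(stack, p + 1L)
      if (cl > 1L) stack <- c(stack, p - h)
      if (cl < w) stack <- c(stack, p + h)
    }
    sizes[cur] <- n
  }
  if (cur == 0L) return(mask)
  lab == which.max(sizes)
}

#' Generate a synthetic CEST cohort
#'
#' Builds `n_patients` patient records: a brain-ellipse background split into
#' gray/white matter, one connected tumor blob per patient whose APT/NOE
#' amplitudes depend on the (binary) genotype class, Z-spectra from the
#' multi-pool Lorentzian forward model, optional smooth B0 displacement and
#' Rician noise. Identical configuration (including seed) gives bit-identical
#' output.
#'
#' @param config A [phantom_config()].
#' @return List of `patient_record` objects (see [patient_record()]).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  n <- config$n_patients
  n1 <- round(n * config$class_balance)
  pool <- c(rep(1L, n1), rep(0L, n - n1))
  labels <- pool[sample.int(n)]
  h <- w <- config$image_size
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  brain <- ((rr - (h + 1) / 2) / (0.46 * h))^2 +
    ((cc - (w + 1) / 2) / (0.42 * w))^2 <= 1
  offs <- config$offsets
  lapply(seq_len(n), function(i) {
    g <- labels[i]
    eff <- if (config$flip_effect) -1 else 1
    apt <- config$tumor_apt + eff * if (g == 1L) config$apt_effect else 0
    noe <- config$tumor_noe - eff * if (g == 1L) config$noe_effect else 0
    spec_tumor <- simulate_zspectrum(
      tissue_preset("tumor", apt_amplitude = apt, noe_amplitude = max(noe, 0)),
      offs)
    spec_gm <- simulate_zspectrum(tissue_preset("gray_matter"), offs)
    spec_wm <- simulate_zspectrum(tissue_preset("white_matter"), offs)
    radius <- stats::runif(1, config$tumor_radius[1], config$tumor_radius[2])
    tum <- make_tumor_mask(h, w, radius, brain)
    # gray/white partition: smooth field sign inside the brain
    gw <- smooth_field(h, w, config$b0_smoothness) > 0
    data <- array(0, c(h, w, length(offs)))
    for (k in seq_along(offs)) {
      plane <- matrix(0, h, w)
      plane[brain & gw] <- spec_gm[k]
      plane[brain & !gw] <- spec_wm[k]
      plane[tum$mask] <- spec_tumor[k]
      plane[!brain] <- 1  # air/background: no saturation transfer
      data[, , k] <- plane
    }
    m0 <- matrix(0.05, h, w)
    m0[brain] <- 1
    vol <- cest_volume(data, m0, offs)
    if (config$b0_amplitude > 0) {
      field <- config$b0_amplitude * smooth_field(h, w, config$b0_smoothness)
      vol <- apply_b0_shift(vol, field)
    }
    if (config$noise_sigma > 0) {
      vol <- add_rician_noise(vol, config$noise_sigma,
                              seed = config$seed + 1000L + i)
    }
    patient_record(vol, tum$mask, genotype = g,
                   patient_id = sprintf("P%03d", i))
  })
}

#' Patient record
#'
#' Ties a [cest_volume()] to its ground-truth tumor mask, binary genotype
#' label and (optional) split assignment.
#'
#' @param volume A `cest_volume`.
#' @param mask Logical/binary `H x W` tumor mask.
#' @param genotype Binary label: 0 = wildtype/unmethylated analogue,
#'   1 = mutant/methylated analogue.
#' @param patient_id Character identifier.
#' @param split Either `"holdout"` or an integer fold index (set by
#'   [make_splits()]).
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(volume, mask, genotype, patient_id, split = NA) {
  stopifnot(inherits(volume, "cest_volume"))
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (!all(dim(mask) == dim(volume$data)[1:2])) {
    stop("mask extent differs from volume extent", call. = FALSE)
  }
  stopifnot(genotype %in% c(0L, 1L))
  structure(list(volume = volume, mask = mask, genotype = as.integer(genotype),
                 patient_id = patient_id, split = split),
            class = "patient_record")
}

#' Rician noise injection
#'
#' Replaces every channel value `v` by `sqrt((v + n1)^2 + n2^2)` with
#' `n1, n2 ~ N(0, sigma^2)`, the magnitude-image noise model. `sigma` is a
#' fraction of M0 (i.e. on the Z-value scale); `sigma = 0` returns the input
#' unchanged. Channels are corrupted independently.
#'
#' @param volume A [cest_volume()].
#' @param sigma Noise standard deviation, fraction of M0; must be `>= 0`.
#' @param seed Integer seed for reproducibility.
#' @return A new `cest_volume`.
#' @export
add_rician_noise <- function(volume, sigma, seed = 1L) {
  stopifnot(inherits(volume, "cest_volume"))
  if (sigma < 0) stop("noise sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(volume)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  d <- volume$data
  n1 <- array(stats::rnorm(length(d), sd = sigma), dim(d))
  n2 <- array(stats::rnorm(length(d), sd = sigma), dim(d))
  cest_volume(sqrt((d + n1)^2 + n2^2), volume$m0, volume$offsets)
}

#' Apply a B0 frequency-offset displacement field
#'
#' A field value `f` (ppm) at a pixel means the true resonance is displaced
#' by `f`; the stored Z-spectrum is therefore resampled by linear
#' interpolation at `offset - f`. Shifts beyond the grid ends are clamped to
#' the edge values and flagged.
#'
#' @param volume A [cest_volume()].
#' @param field Numeric `H x W` matrix of ppm shifts (or a scalar).
#' @return A `cest_volume` with attribute `"clamped"`: logical `H x W` map of
#'   pixels whose resampling hit a grid end.
#' @export
apply_b0_shift <- function(volume, field) {
  stopifnot(inherits(volume, "cest_volume"))
  d <- dim(volume$data)
  if (length(field) == 1L) field <- matrix(field, d[1], d[2])
  stopifnot(all(dim(field) == d[1:2]), all(is.finite(field)))
  offs <- volume$offsets
  span <- max(offs) - min(offs)
  if (max(abs(field)) >= span / 2) {
    stop("|B0 field| must be smaller than half the offset span", call. = FALSE)
  }
  hw <- d[1] * d[2]
  zmat <- matrix(volume$data, hw, d[3])  # pixels x offsets
  fvec <- as.vector(field)
  out <- matrix(0, hw, d[3])
  clamped <- rep(FALSE, hw)
  # group pixels by identical shift for speed (phantom fields are smooth but
  # generic); interpolation is linear along the offset axis per pixel
  step <- offs[2] - offs[1]
  for (k in seq_len(d[3])) {
    target <- offs[k] - fvec
    clamped <- clamped | target < offs[1] | target > offs[d[3]]
    tc <- pmin(pmax(target, offs[1]), offs[d[3]])
    pos <- (tc - offs[1]) / step
    i0 <- pmin(floor(pos), d[3] - 2)
    frac <- pos - i0
    idx0 <- cbind(seq_len(hw), i0 + 1)
    idx1 <- cbind(seq_len(hw), i0 + 2)
    out[, k] <- (1 - frac) * zmat[idx0] + frac * zmat[idx1]
  }
  res <- cest_volume(array(out, d), volume$m0, offs)
  attr(res, "clamped") <- matrix(clamped, d[1], d[2])
  res
}

# RNG bookkeeping: phantom/noise operators are pure functions of their seed
# and must not disturb the caller's RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
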