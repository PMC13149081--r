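# Shift-window patch extraction over tumor regions, the overlap formula, and
# crop-and-stitch aggregation of patch-wise predictions.
#
# Coordinate convention (used everywhere): 0-based, row-major origins; a
# patch with origin (r, c) covers the half-open window
# [r, r + size) x [c, c + size).

#' Patch overlap percentage
#'
#' `Overlap = (1 - stride / size) * 100`. Zero when `stride == size`,
#' strictly decreasing in the stride.
#'
#' @param size Patch size, pixels.
#' @param stride Shift distance, pixels; `1 <= stride <= size`.
#' @return Overlap in percent.
#' @export
overlap_fraction <- function(size, stride) {
  if (any(size < 1) || any(stride < 1) || any(stride > size)) {
    stop("need 1 <= stride <= size", call. = FALSE)
  }
  (1 - stride / size) * 100
}

#' Build a sliding-window patch grid over a region
#'
#' Origins tile the region's bounding box at the given stride, anchored at
#' the box's top-left; one final origin per axis is clamped so the far edge
#' of the box is covered. Regions smaller than one patch are inflated to
#' `size x size` centered on the region centroid (clipped to the image), so
#' every non-empty region yields at least one patch. All patches lie fully
#' inside the image.
#'
#' @param region Logical `H x W` mask, or a bounding box
#'   `c(r0, c0, r1, c1)` (0-based, inclusive of `r0/c0`, exclusive of
#'   `r1/c1`).
#' @param image_extent `c(H, W)` in pixels.
#' @param size Patch size, pixels.
#' @param stride Stride, pixels.
#' @return Object of class `patch_grid`: `origins` (n x 2 matrix, 0-based
#'   row/col), `size`, `stride`, `bbox`, `image_extent`, `overlap`.
#' @export
build_grid <- function(region, image_extent = NULL, size = 48L, stride = 12L) {
  if (any(stride < 1) || any(stride > size)) {
    stop("need 1 <= stride <= size", call. = FALSE)
  }
  if (is.matrix(region) && (is.logical(region) || all(region %in% c(0, 1)))) {
    if (is.null(image_extent)) image_extent <- dim(region)
    if (!any(region > 0)) stop("empty region", call. = FALSE)
    rows <- which(rowSums(region > 0) > 0)
    cols <- which(colSums(region > 0) > 0)
    bbox <- c(min(rows) - 1L, min(cols) - 1L, max(rows), max(cols))
  } else {
    bbox <- as.integer(region)
    stopifnot(length(bbox) == 4L)
    if (is.null(image_extent)) stop("image_extent required with a bbox",
                                    call. = FALSE)
    if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
      stop("empty region", call. = FALSE)
    }
  }
  H <- image_extent[1]; W <- image_extent[2]
  if (size > H || size > W) stop("patch size exceeds image extent", call. = FALSE)
  if (bbox[1] < 0 || bbox[2] < 0 || bbox[3] > H || bbox[4] > W) {
    stop("region larger than image", call. = FALSE)
  }
  # inflate boxes smaller than one patch to size x size about the centroid
  infl <- function(lo, hi, n) {
    if (hi - lo >= size) return(c(lo, hi))
    ctr <- (lo + hi) / 2
    lo2 <- round(ctr - size / 2)
    lo2 <- min(max(lo2, 0), n - size)
    c(lo2, lo2 + size)
  }
  rb <- infl(bbox[1], bbox[3], H)
  cb <- infl(bbox[2], bbox[4], W)
  bbox <- c(rb[1], cb[1], rb[2], cb[2])
  axis_origins <- function(lo, hi, n) {
    span <- hi - lo
    o <- seq(lo, by = stride, length.out = (span - size) %/% stride + 1L)
    last <- hi - size
    if (max(o) < last) o <- c(o, last)     # clamped final origin
    pmin(pmax(o, 0L), n - size)
  }
  ro <- axis_origins(bbox[1], bbox[3], H)
  co <- axis_origins(bbox[2], bbox[4], W)
  origins <- cbind(rep(ro, times = length(co)), rep(co, each = length(ro)))
  colnames(origins) <- c("row", "col")
  structure(list(origins = origins, size = as.integer(size),
                 stride = as.integer(stride), bbox = as.integer(bbox),
                 image_extent = as.integer(image_extent),
                 overlap = overlap_fraction(size, stride)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf(
    "<patch_grid> %d patches of %dx%d, stride %d (overlap %.2f%%), bbox [%d,%d)x[%d,%d)\n",
    nrow(x$origins), x$size, x$size, x$stride, x$overlap,
    x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Extract patches from a CEST volume
#'
#' Cuts one channel-complete `size x size x C` patch per grid origin;
#' optional pixel-wise label images are cut identically.
#'
#' @param volume A [cest_volume()] or a plain `H x W x C` array.
#' @param grid A [build_grid()] result.
#' @param labels Optional `H x W` matrix of pixel-wise labels (NA allowed).
#' @return Object of class `patch_set`: `patches` (list of arrays),
#'   `label_patches` (list of matrices or NULL), `origins`, `grid`.
#' @export
extract_patches <- function(volume, grid, labels = NULL) {
  x <- if (inherits(volume, "cest_volume")) volume$data else volume
  stopifnot(length(dim(x)) == 3L)
  if (!all(dim(x)[1:2] == grid$image_extent)) {
    stop("grid inconsistent with volume extent", call. = FALSE)
  }
  if (!is.null(labels) && !all(dim(labels) == dim(x)[1:2])) {
    stop("label image extent differs from volume extent", call. = FALSE)
  }
  s <- grid$size
  cut1 <- function(o) x[o[1] + seq_len(s), o[2] + seq_len(s), , drop = FALSE]
  patches <- apply(grid$origins, 1L, cut1, simplify = FALSE)
  label_patches <- if (!is.null(labels)) {
    apply(grid$origins, 1L,
          function(o) labels[o[1] + seq_len(s), o[2] + seq_len(s), drop = FALSE],
          simplify = FALSE)
  }
  structure(list(patches = patches, label_patches = label_patches,
                 origins = grid$origins, grid = grid),
            class = "patch_set")
}

#' Stitch patch-wise predictions into a full-image probability map
#'
#' Each patch contributes its central `(size - 2*crop)^2` window; patches on
#' the border of the grid (no neighbour beyond them) keep their uncropped
#' edge there so every covered pixel receives at least one contribution.
#' Overlapping contributions are averaged. Pixels with zero contributions are
#' flagged invalid (probability `NA`).
#'
#' @param predictions List of `size x size x N` class-probability arrays, one
#'   per grid origin (in grid order).
#' @param grid The [build_grid()] result the patches came from.
#' @param crop Pixels cropped from each patch edge; must satisfy
#'   `crop < size / 2`. Default: the grid stride (the recommended setting).
#' @return Object of class `prob_map`: `data` (`H x W x N` array, NA outside
#'   coverage), `valid` (logical `H x W`), `roi` (NULL until restricted).
#' @export
aggregate_patches <- function(predictions, grid, crop = grid$stride) {
  s <- grid$size
  if (crop >= s / 2) stop("crop must be < size/2", call. = FALSE)
  if (length(predictions) != nrow(grid$origins)) {
    stop("one prediction per grid origin required", call. = FALSE)
  }
  nc <- dim(predictions[[1]])[3]
  H <- grid$image_extent[1]; W <- grid$image_extent[2]
  acc <- array(0, c(H, W, nc))
  cnt <- matrix(0, H, W)
  rmin <- min(grid$origins[, 1]); rmax <- max(grid$origins[, 1])
  cmin <- min(grid$origins[, 2]); cmax <- max(grid$origins[, 2])
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]
    if (!all(dim(p)[1:2] == c(s, s))) {
      stop("prediction shape inconsistent with grid", call. = FALSE)
    }
    o <- grid$origins[i, ]
    r1 <- if (o[1] == rmin) 1L else crop + 1L
    r2 <- if (o[1] == rmax) s else s - crop
    c1 <- if (o[2] == cmin) 1L else crop + 1L
    c2 <- if (o[2] == cmax) s else s - crop
    rows <- o[1] + (r1:r2)
    cols <- o[2] + (c1:c2)
    acc[rows, cols, ] <- acc[rows, cols, , drop = FALSE] +
      p[r1:r2, c1:c2, , drop = FALSE]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  valid <- cnt > 0
  for (k in seq_len(nc)) {
    plane <- acc[, , k]
    plane[valid] <- plane[valid] / cnt[valid]
    plane[!valid] <- NA_real_
    acc[, , k] <- plane
  }
  structure(list(data = acc, valid = valid, roi = NULL), class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prob_map> %d x %d x %d classes, %d valid pixels%s\n",
              d[1], d[2], d[3], sum(x$valid),
              if (is.null(x$roi)) "" else sprintf(", ROI %d px", sum(x$roi))))
  invisible(x)
}
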