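# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No R NIfTI package ships in this environment, so the 348-byte header is
# written by hand. Supported on read: uint8, int16, int32, float32,
# float64, with scl_slope/scl_inter applied. Axis order on disk follows the
# NIfTI convention (fastest axis first); in R the array is (row, col,
# offset) with row as the first (fastest) axis.

nifti_datatypes <- c("uint8" = 2L, "int16" = 4L, "int32" = 8L,
                     "float32" = 16L, "float64" = 64L)
nifti_bitpix <- c("uint8" = 8L, "int16" = 16L, "int32" = 32L,
                  "float32" = 32L, "float64" = 64L)

open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 file
#'
#' @param x Numeric array (2-D, 3-D or 4-D).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param pixdim Voxel sizes per axis (recycled/padded).
#' @param datatype Storage type: `"float32"` (default), `"float64"`,
#'   `"uint8"`, `"int16"`, `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, pixdim = c(1, 1, 1), datatype = "float32") {
  dt <- match.arg(datatype, names(nifti_datatypes))
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  nd <- length(d)
  stopifnot(nd <= 7)
  dim8 <- c(nd, d, rep(1L, 7 - nd))
  pd8 <- c(1, pixdim, rep(1, 7))[1:8]
  con <- open_conn(path, "wb")
  on.exit(close(con))
  wB <- function(v, size, what = "integer") {
    writeBin(v, con, size = size, endian = "little")
  }
  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(36), con)                                    # unused + dim_info
  writeBin(as.integer(dim8), con, size = 2, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")    # intent_p1..p3
  writeBin(0L, con, size = 2, endian = "little")            # intent_code
  writeBin(nifti_datatypes[[dt]], con, size = 2, endian = "little")
  writeBin(nifti_bitpix[[dt]], con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(as.numeric(pd8), con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope/inter
  writeBin(0L, con, size = 2, endian = "little")            # slice_end
  writeBin(raw(2), con)                                     # slice_code, units
  writeBin(numeric(4), con, size = 4, endian = "little")    # cal/slice_dur/toff
  writeBin(integer(2), con, size = 4, endian = "little")    # glmax, glmin
  writeBin(raw(80 + 24), con)                               # descrip, aux_file
  writeBin(integer(2), con, size = 2, endian = "little")    # qform, sform
  writeBin(numeric(6), con, size = 4, endian = "little")    # quatern, qoffset
  srow <- rbind(c(pd8[2], 0, 0, 0), c(0, pd8[3], 0, 0), c(0, 0, pd8[4], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)             # magic
  writeBin(raw(4), con)                                     # extension flag
  v <- as.vector(x)
  if (dt %in% c("uint8", "int16", "int32")) {
    writeBin(as.integer(round(v)), con, size = nifti_bitpix[[dt]] / 8,
             endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = nifti_bitpix[[dt]] / 8,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Numeric array with the on-disk dimensions; attribute `"pixdim"`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  rint <- function(off, size, n = 1L, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  }
  rflt <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4,
            endian = "little")
  }
  if (rint(0, 4) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)",
                               call. = FALSE)
  dim8 <- rint(40, 2, 8)
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  datatype <- rint(70, 2)
  code <- names(nifti_datatypes)[match(datatype, nifti_datatypes)]
  if (is.na(code)) stop("unsupported NIfTI datatype code ", datatype,
                        call. = FALSE)
  pixdim <- rflt(76, 8)[2:(1 + nd)]
  vox_offset <- rflt(108)
  slope <- rflt(112); inter <- rflt(116)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  sz <- nifti_bitpix[[code]] / 8
  v <- if (code %in% c("float32", "float64")) {
    readBin(con, "numeric", n = n, size = sz, endian = "little")
  } else if (code == "uint8") {
    readBin(con, "integer", n = n, size = 1, signed = FALSE,
            endian = "little")
  } else {
    readBin(con, "integer", n = n, size = sz, endian = "little")
  }
  if (slope != 0 && !(slope == 1 && inter == 0)) v <- v * slope + inter
  out <- array(v, d)
  attr(out, "pixdim") <- pixdim
  out
}

#' Write a CEST volume to NIfTI + sidecar files
#'
#' Writes `<prefix>.nii.gz` (4-D stack, offset as 4th axis),
#' `<prefix>_M0.nii.gz`, and a sidecar `<prefix>_offsets.csv` with the
#' offset list in ppm. An optional mask goes to `<prefix>_mask.nii.gz`.
#'
#' @param volume A [cest_volume()].
#' @param prefix Path prefix (no extension).
#' @param mask Optional binary mask.
#' @return `prefix`, invisibly.
#' @export
write_cest_nifti <- function(volume, prefix, mask = NULL) {
  stopifnot(inherits(volume, "cest_volume"))
  d <- dim(volume$data)
  write_nifti(array(volume$data, c(d[1], d[2], 1L, d[3])),
              paste0(prefix, ".nii.gz"), datatype = "float64")
  write_nifti(volume$m0, paste0(prefix, "_M0.nii.gz"), datatype = "float64")
  utils::write.csv(data.frame(offset_ppm = volume$offsets),
                   paste0(prefix, "_offsets.csv"), row.names = FALSE)
  if (!is.null(mask)) {
    write_nifti(mask * 1, paste0(prefix, "_mask.nii.gz"), datatype = "uint8")
  }
  invisible(prefix)
}

#' Read a CEST volume written by [write_cest_nifti()]
#'
#' @param prefix Path prefix used at write time.
#' @return A [cest_volume()] (attribute `"mask"` if a mask file exists).
#' @export
read_cest_nifti <- function(prefix) {
  x <- read_nifti(paste0(prefix, ".nii.gz"))
  offs <- utils::read.csv(paste0(prefix, "_offsets.csv"))$offset_ppm
  d <- dim(x)
  nc <- if (length(d) == 4L) d[4] else d[3]
  if (nc != length(offs)) {
    stop(sprintf("offset-count mismatch: image has %d volumes, sidecar lists %d",
                 nc, length(offs)), call. = FALSE)
  }
  data <- array(x, c(d[1], d[2], nc))
  m0 <- read_nifti(paste0(prefix, "_M0.nii.gz"))
  vol <- cest_volume(data, matrix(m0, d[1], d[2]), offs)
  mp <- paste0(prefix, "_mask.nii.gz")
  if (file.exists(mp)) {
    attr(vol, "mask") <- matrix(read_nifti(mp), d[1], d[2]) > 0
  }
  vol
}

#' Write a synthetic cohort to a directory
#'
#' Per-patient NIfTI stacks plus a `cohort.csv` sidecar (patient id, split,
#' genotype label).
#'
#' @param records List of [patient_record()]s.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in records) {
    write_cest_nifti(r$volume, file.path(dir, r$patient_id), mask = r$mask)
  }
  meta <- do.call(rbind, lapply(records, function(r) {
    data.frame(patient_id = r$patient_id, split = as.character(r$split),
               genotype = r$genotype, stringsAsFactors = FALSE)
  }))
  utils::write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List of [patient_record()]s.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    vol <- read_cest_nifti(file.path(dir, meta$patient_id[i]))
    mask <- attr(vol, "mask")
    attr(vol, "mask") <- NULL
    split <- meta$split[i]
    split <- if (split %in% c("NA", "")) NA
             else if (split == "holdout") "holdout" else as.integer(split)
    patient_record(vol, mask, meta$genotype[i], meta$patient_id[i],
                   split = split)
  })
}
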