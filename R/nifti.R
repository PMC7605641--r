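# Minimal NIfTI-1 reader/writer.
#
# Only what the pipeline needs: single-file .nii / .nii.gz, the common
# datatypes (uint8, int16, int32, float32, float64), scl_slope/scl_inter
# scaling, sform (preferred) or qform affine, TR from pixdim[4]. The writer
# always emits float64 with an sform, so round-trips are lossless.

DT_UINT8 <- 2L; DT_INT16 <- 4L; DT_INT32 <- 8L
DT_FLOAT32 <- 16L; DT_FLOAT64 <- 64L

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 image (.nii or .nii.gz). 3D images are promoted to a
#' single-frame 4D volume. The repetition time is taken from the header
#' (pixdim, time units honoured) unless overridden.
#'
#' @param path path to a NIfTI-1 file.
#' @param tr_s optional explicit repetition time in seconds; overrides the
#'   header value with a warning on conflict.
#' @return a [volume4d].
#' @export
read_volume <- function(path, tr_s = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L)
    stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  rd_i16 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 2 * n)],
                                     "integer", n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(raw_hdr[(off + 1):(off + 4 * n)],
                                     "numeric", n, 4L, endian = endian)
  dim_raw <- rd_i16(40, 8)
  ndim <- dim_raw[1]
  if (ndim < 3L || ndim > 4L)
    stop("unsupported NIfTI dimensionality: ", ndim)
  d <- dim_raw[2:(1 + ndim)]
  if (ndim == 3L) d <- c(d, 1L)
  datatype <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  xyzt_units <- as.integer(raw_hdr[124])
  qform_code <- rd_i16(252, 1)
  sform_code <- rd_i16(254, 1)

  n_vox <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n_vox, 1L, signed = FALSE,
                             endian = endian)),
    "4" = as.numeric(readBin(con, "integer", n_vox, 2L, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n_vox, 4L, endian = endian)),
    "16" = readBin(con, "numeric", n_vox, 4L, endian = endian),
    "64" = readBin(con, "numeric", n_vox, 8L, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (length(data) < n_vox)
    stop("truncated NIfTI data section: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  if (!all(is.finite(data)))
    stop("NIfTI image contains non-finite voxels: ", path)

  voxel_size <- abs(pixdim[2:4])
  voxel_size[voxel_size == 0] <- 1
  spat_unit <- bitwAnd(xyzt_units, 7L)
  if (spat_unit == 1L) voxel_size <- voxel_size * 1000    # meters -> mm
  if (spat_unit == 3L) voxel_size <- voxel_size / 1000    # microns -> mm

  if (sform_code > 0L) {
    affine <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    affine <- qform_to_affine(rd_f32(256, 6), pixdim, voxel_size)
  } else {
    affine <- default_affine(voxel_size, d[1:3])
  }

  hdr_tr <- pixdim[5]
  time_unit <- bitwAnd(xyzt_units, 56L)
  if (time_unit == 16L) hdr_tr <- hdr_tr / 1000           # ms -> s
  if (time_unit == 24L) hdr_tr <- hdr_tr / 1e6            # us -> s
  if (!is.finite(hdr_tr) || hdr_tr <= 0) hdr_tr <- 1
  if (!is.null(tr_s)) {
    if (is.finite(hdr_tr) && abs(hdr_tr - tr_s) > 1e-6 && hdr_tr != 1)
      warning(sprintf("TR override: header says %.4g s, using %.4g s",
                      hdr_tr, tr_s))
    hdr_tr <- tr_s
  }
  volume4d(array(data, dim = d), voxel_size, hdr_tr, affine)
}

qform_to_affine <- function(q, pixdim, voxel_size) {
  b <- q[1]; c <- q[2]; dq <- q[3]
  a2 <- 1 - b^2 - c^2 - dq^2
  a <- if (a2 < 1e-7) 0 else sqrt(a2)
  R <- matrix(c(
    a^2 + b^2 - c^2 - dq^2, 2 * (b * c - a * dq),   2 * (b * dq + a * c),
    2 * (b * c + a * dq),   a^2 + c^2 - b^2 - dq^2, 2 * (c * dq - a * b),
    2 * (b * dq - a * c),   2 * (c * dq + a * b),   a^2 + dq^2 - b^2 - c^2),
    3, 3, byrow = TRUE)
  qfac <- if (is.finite(pixdim[1]) && pixdim[1] < 0) -1 else 1
  S <- diag(c(voxel_size[1], voxel_size[2], qfac * voxel_size[3]))
  affine <- diag(4)
  affine[1:3, 1:3] <- R %*% S
  affine[1:3, 4] <- q[4:6]
  affine
}

#' Write a NIfTI volume
#'
#' Writes a [volume4d] as a single-file NIfTI-1 image (float64, sform affine,
#' TR in pixdim, mm/sec units). `.gz` suffixes are honoured.
#'
#' @param vol a [volume4d].
#' @param path destination path (.nii or .nii.gz).
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume4d"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  d <- dim(vol$data)
  hdr <- raw(348)
  put <- function(off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put_i16 <- function(off, x) put(off, as.integer(x), "integer", 2L)
  put_i32 <- function(off, x) put(off, as.integer(x), "integer", 4L)
  put_f32 <- function(off, x) put(off, as.numeric(x), "numeric", 4L)

  put_i32(0, 348L)
  ndim <- if (d[4] > 1L) 4L else 3L
  put_i16(40, c(ndim, d[1:4], 1L, 1L, 1L))          # dim[8]
  put_i16(70, DT_FLOAT64)                           # datatype
  put_i16(72, 64L)                                  # bitpix
  put_f32(76, c(1, vol$voxel_size_mm, vol$tr_s, 0, 0, 0))  # pixdim[8]
  put_f32(108, 352)                                 # vox_offset
  put_f32(112, 1); put_f32(116, 0)                  # scl_slope/inter
  hdr[124] <- as.raw(bitwOr(2L, 8L))                # xyzt_units: mm | sec
  put_i16(252, 0L)                                  # qform_code
  put_i16(254, 1L)                                  # sform_code
  put_f32(280, vol$affine[1, ])                     # srow_x
  put_f32(296, vol$affine[2, ])                     # srow_y
  put_f32(312, vol$affine[3, ])                     # srow_z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- tryCatch(nifti_open(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           " (", conditionMessage(e), ")"))
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4), con)                             # no extensions
  writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
  invisible(path)
}
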