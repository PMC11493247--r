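# Minimal NIfTI-1 I/O for label volumes.  Only what label-map export needs:
# 3D int32 data, voxel spacing, and an axis-aligned world affine (sform).
# Little-endian throughout; ".nii.gz" paths are gzip-compressed.

#' Write a 3D label volume as NIfTI-1
#'
#' @param volume 3D integer or numeric array (stored as int32).
#' @param path output path; `.nii` or `.nii.gz`.
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world position of voxel (1,1,1)'s center, mm (sform offset;
#'   0-based voxel indices, voxel-center convention).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  stopifnot(length(dim(volume)) == 3L, all(spacing > 0))
  dims <- dim(volume)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                                   # sizeof_hdr
  wc(36L)                                        # data_type..dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)            # dim[8]
  wf(c(0, 0, 0))                                 # intent_p1..p3
  wi(0L, 2L)                                     # intent_code
  wi(8L, 2L)                                     # datatype DT_INT32
  wi(32L, 2L)                                    # bitpix
  wi(0L, 2L)                                     # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))                  # pixdim[8] (qfac = 1)
  wf(352)                                        # vox_offset
  wf(1); wf(0)                                   # scl_slope, scl_inter
  wi(0L, 2L); wc(1L)                             # slice_end, slice_code
  writeBin(as.raw(2L), con)                      # xyzt_units: mm
  wf(c(0, 0, 0, 0))                              # cal_max..toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  wc(104L)                                       # descrip + aux_file
  wi(0L, 2L); wi(1L, 2L)                         # qform_code, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                        # quatern/qoffset
  wf(c(spacing[1], 0, 0, origin[1]))             # srow_x
  wf(c(0, spacing[2], 0, origin[2]))             # srow_y
  wf(c(0, 0, spacing[3], origin[3]))             # srow_z
  wc(16L)                                        # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  wc(1L)                                         # magic terminator
  wc(4L)                                         # extension flag
  wi(as.vector(volume), 4L)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports the subset this package writes: single-file little-endian NIfTI-1
#' with int32, int16, uint8, float32 or float64 data.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array), `spacing`, `origin`.
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352L)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L) stop("not a little-endian NIfTI-1 file")
  dim8 <- ri(40L, 2L, 8L)
  dims <- dim8[2:4]
  datatype <- ri(70L, 2L)
  pixdim <- rf(76L, 8L)
  srow <- matrix(rf(280L, 12L), 3L, 4L, byrow = TRUE)
  nvox <- prod(dims)
  data <- switch(as.character(datatype),
                 "2" = readBin(con, "integer", nvox, size = 1L, signed = FALSE),
                 "4" = readBin(con, "integer", nvox, size = 2L,
                               endian = "little"),
                 "8" = readBin(con, "integer", nvox, size = 4L,
                               endian = "little"),
                 "16" = readBin(con, "numeric", nvox, size = 4L,
                                endian = "little"),
                 "64" = readBin(con, "numeric", nvox, size = 8L,
                                endian = "little"),
                 stop("unsupported NIfTI datatype ", datatype))
  list(data = array(data, dims), spacing = pixdim[2:4], origin = srow[, 4L])
}
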