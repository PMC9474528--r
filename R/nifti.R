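# Minimal self-contained NIfTI-1 reader/writer (little-endian).
#
# Only what the pipeline needs: 3-D volumes, voxel spacing from pixdim,
# origin from the sform translation column (sform_code 1 written, sform then
# qform then zero honoured on read), datatypes uint8 / int16 / int32 /
# float32 / float64, plain .nii or gzipped .nii.gz. No NIfTI package exists
# in the supported dependency set, hence this in-package implementation.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L)
)

nifti_write <- function(data, spacing, origin, path, datatype = 64L) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype: ", datatype)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size,
                                        endian = "little")
  wc <- function(txt, n) {
    raw_txt <- charToRaw(txt)
    writeBin(c(raw_txt, raw(n - length(raw_txt))), con)
  }
  d <- dim(data)
  wi(348L, 4L)                               # sizeof_hdr
  writeBin(raw(36L), con)                    # data_type,db_name,extents,ses,reg,dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2L)          # dim[8]
  wf(c(0, 0, 0))                             # intent_p1..3
  wi(0L, 2L)                                 # intent_code
  wi(as.integer(datatype), 2L)               # datatype
  wi(dt$bitpix, 2L)                          # bitpix
  wi(0L, 2L)                                 # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))              # pixdim[8] (qfac = 1)
  wf(352)                                    # vox_offset
  wf(1); wf(0)                               # scl_slope, scl_inter
  wi(0L, 2L); writeBin(as.raw(c(0L, 2L)), con) # slice_end, slice_code, xyzt=mm
  wf(c(0, 0, 0, 0))                          # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4L)                          # glmax, glmin
  wc("petclust", 80L)                        # descrip
  wc("", 24L)                                # aux_file
  wi(c(0L, 1L), 2L)                          # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0))                             # quatern b,c,d
  wf(origin)                                 # qoffset x,y,z
  wf(c(spacing[1], 0, 0, origin[1]))         # srow_x
  wf(c(0, spacing[2], 0, origin[2]))         # srow_y
  wf(c(0, 0, spacing[3], origin[3]))         # srow_z
  wc("", 16L)                                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con) # magic
  writeBin(raw(4L), con)                     # no extensions
  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

nifti_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")   # gzfile transparently reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0L, 4L) != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  dims <- ri(40L, 2L, n = 8L)
  ndim <- dims[1]
  d <- dims[2:(1 + max(ndim, 1L))]
  if (ndim > 3L) {
    if (prod(d[4:ndim]) != 1L)
      stop("volume is not 3-D (dims: ", paste(d, collapse = "x"), ")")
    d <- d[1:3]
  }
  if (length(d) != 3L || any(d < 1L))
    stop("volume is not 3-D (dims: ", paste(d, collapse = "x"), ")")
  datatype <- ri(70L, 2L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype on read: ", datatype)
  pixdim <- rf(76L, n = 8L)
  spacing <- abs(pixdim[2:4])
  vox_offset <- rf(108L)
  scl_slope <- rf(112L); scl_inter <- rf(116L)
  qform_code <- ri(252L, 2L); sform_code <- ri(254L, 2L)
  origin <- c(0, 0, 0)
  if (sform_code > 0L) {
    origin <- c(rf(280L, 4L)[4], rf(296L, 4L)[4], rf(312L, 4L)[4])
  } else if (qform_code > 0L) {
    origin <- rf(268L, 3L)
  }
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n_vox <- prod(d)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(vals) < n_vox) stop("truncated NIfTI data section: ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(as.double(vals), dim = d), spacing = spacing,
       origin = origin)
}
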