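# Minimal NIfTI-1 I/O.
#
# The package writes masks, doses, coefficient maps and deformation fields as
# .nii / .nii.gz. Only the subset of NIfTI-1 this package produces is
# supported on read: float64 or float32 data, 3D or 4D (vector field)
# volumes, sform with a diagonal direction matrix (the axis convention is
# fixed package-wide, so no reorientation is performed).

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume as NIfTI-1
#'
#' @param v a `volume_grid`, or a 4D array attribute-carrying deformation
#'   field as produced by [deformation_field()] (written as a 4D volume with
#'   three components).
#' @param path output path; `.nii` or `.nii.gz`.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(v, path) {
  if (is_volume_grid(v)) {
    vals <- v$values; spacing <- v$spacing; origin <- v$origin
  } else if (inherits(v, "deformation_field")) {
    vals <- v$displacement; spacing <- v$spacing; origin <- v$origin
  } else stop("unsupported object for write_nifti")
  d <- dim(vals)
  ndim <- length(d)
  stopifnot(ndim %in% c(3L, 4L))
  dim8 <- c(ndim, d, rep(1L, 7L - ndim))
  pixdim8 <- c(1, spacing, rep(1, 7 - 3))

  con <- nii_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size)
  wf <- function(x) writeBin(as.numeric(x), con, size = 4)
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wi(348L, 4)                        # sizeof_hdr
  wc("", 10); wc("", 18)             # data_type, db_name
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)                        # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)          # intent_p1..3, intent_code
  wi(64L, 2); wi(64L, 2)             # datatype float64, bitpix
  wi(0L, 2)                          # slice_start
  wf(pixdim8)                        # pixdim[8]
  wf(352); wf(1); wf(0)              # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1)    # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                   # glmax, glmin
  wc("voxdose", 80); wc("", 24)      # descrip, aux_file
  wi(0L, 2); wi(1L, 2)               # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))            # quatern_b..d, qoffset_x..z
  wf(c(spacing[1], 0, 0, origin[1])) # srow_x
  wf(c(0, spacing[2], 0, origin[2])) # srow_y
  wf(c(0, 0, spacing[3], origin[3])) # srow_z
  wc("", 16)                         # intent_name
  wc("n+1", 4)                       # magic
  writeBin(raw(4), con)              # no extensions
  writeBin(as.numeric(vals), con, size = 8)
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return a `volume_grid` (3D) or `deformation_field` (4D, 3 components).
#' @export
read_nifti <- function(path) {
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size)
  rf <- function(n) readBin(con, "numeric", n = n, size = 4)
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a NIfTI-1 file (or wrong endianness)")
  readBin(con, "raw", n = 10 + 18 + 4 + 2 + 1 + 1)
  dim8 <- ri(8, 2)
  rf(3); ri(1, 2)
  datatype <- ri(1, 2); ri(1, 2); ri(1, 2)
  pixdim8 <- rf(8)
  vox_offset <- rf(1); rf(2); ri(1, 2)
  readBin(con, "raw", n = 2)
  rf(4); ri(2, 4)
  readBin(con, "raw", n = 80 + 24)
  ri(1, 2); ri(1, 2); rf(6)
  srx <- rf(4); sry <- rf(4); srz <- rf(4)
  readBin(con, "raw", n = 16 + 4)
  readBin(con, "raw", n = vox_offset - 348)
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  n <- prod(d)
  vals <- switch(as.character(datatype),
                 "64" = readBin(con, "numeric", n = n, size = 8),
                 "16" = readBin(con, "numeric", n = n, size = 4),
                 stop("unsupported NIfTI datatype: ", datatype))
  spacing <- pixdim8[2:4]
  origin <- c(srx[4], sry[4], srz[4])
  if (nd == 3L) {
    volume_grid(array(vals, d), spacing, origin)
  } else {
    deformation_field(array(vals, d), spacing, origin)
  }
}
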