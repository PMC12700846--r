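# Minimal NIfTI-1 reader/writer (.nii and .nii.gz).
#
# Only the header fields the pipeline needs are interpreted: dim, datatype,
# pixdim, vox_offset and scl_slope/scl_inter.  Data are returned in on-disk
# (x, y, z) order; the volume-level wrappers in data_io.R convert to the
# package's (d, h, w) convention.  Little-endian files only (the writer always
# produces them); big-endian input raises a format error.

NIFTI_TYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

#' Read a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array in x,y,z order) and `pixdim`
#'   (voxel spacing `(dx, dy, dz)` in mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("not a NIfTI file (truncated header): ", path)
  rint <- function(off, n = 1L, size = 4L) {
    readBin(hdr[(off + 1L):(off + n * size)], "integer", n, size = size,
            endian = "little")
  }
  rshort <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + n * 2L)], "integer", n, size = 2L,
            endian = "little")
  }
  rfloat <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + n * 4L)], "double", n, size = 4L,
            endian = "little")
  }
  sizeof_hdr <- rint(0L)
  if (sizeof_hdr != 348L) {
    stop("not a little-endian NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ",
         path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic in ", path)
  dim_field <- rshort(40L, 8L)
  ndim <- dim_field[1L]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim field in ", path)
  shape <- dim_field[2L:(1L + ndim)]
  datatype <- rshort(70L)
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype ", datatype, " in ", path)
  pixdim <- rfloat(76L, 8L)[2L:4L]
  vox_offset <- rfloat(108L)
  scl_slope <- rfloat(112L)
  scl_inter <- rfloat(116L)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(shape)
  data <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = "little")
  if (length(data) < n) stop("truncated NIfTI data in ", path)
  data <- as.double(data)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  list(data = array(data, shape), pixdim = pixdim)
}

#' Write a NIfTI-1 file
#'
#' @param data numeric array (up to 7-d) in x,y,z order.
#' @param path output path; compressed when it ends in `.gz`.
#' @param pixdim voxel spacing `(dx, dy, dz)`.
#' @param datatype NIfTI datatype code: 16 (float32, default), 64 (float64),
#'   4 (int16) or 2 (uint8).
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1), datatype = 16L) {
  spec <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype ", datatype)
  shape <- dims_of(data)
  ndim <- length(shape)
  dim_field <- rep(1L, 8L)
  dim_field[1L] <- ndim
  dim_field[2L:(1L + ndim)] <- as.integer(shape)
  hdr <- raw(348L)
  put <- function(bytes, off) {
    hdr[(off + 1L):(off + length(bytes))] <<- bytes
    invisible(NULL)
  }
  put(writeBin(348L, raw(), size = 4L, endian = "little"), 0L)
  put(writeBin(dim_field, raw(), size = 2L, endian = "little"), 40L)
  put(writeBin(as.integer(datatype), raw(), size = 2L, endian = "little"), 70L)
  put(writeBin(as.integer(spec$size * 8L), raw(), size = 2L, endian = "little"), 72L)
  pd <- c(1, pixdim[1L], pixdim[2L], pixdim[3L], rep(1, 4))
  put(writeBin(pd, raw(), size = 4L, endian = "little"), 76L)
  put(writeBin(352, raw(), size = 4L, endian = "little"), 108L) # vox_offset
  put(writeBin(c(1, 0), raw(), size = 4L, endian = "little"), 112L) # slope/inter
  put(c(charToRaw("n+1"), as.raw(0L)), 344L)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con) # pad to vox_offset 352
  vals <- as.vector(data)
  if (spec$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = spec$size, endian = "little")
  }
  invisible(path)
}
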