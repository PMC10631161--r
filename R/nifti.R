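#' @useDynLib adrenalseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O. Only what the pipeline
# needs: 3D volumes, the common scalar datatypes, pixdim spacing, scl_slope /
# scl_inter rescaling. Connections handle gzip transparently on read.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' Reads a 3D single-file NIfTI-1 image (optionally gzip-compressed) and
#' returns its voxel data and per-axis spacing in mm. Higher trailing
#' dimensions of size 1 are squeezed; a genuinely 4D (or higher) image is
#' rejected because the pipeline operates on single-channel 3D CT volumes.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D numeric array) and `spacing` (numeric
#'   length-3, mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)

  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(off, what, size, n = 1L) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim_field <- rd(40L, "integer", 2L, 8L)
  ndim <- dim_field[1]
  if (ndim < 3L) stop("expected 3D volume, got ", ndim, "D: ", path)
  dims <- dim_field[2:(1 + ndim)]
  if (ndim > 3L && any(dims[4:ndim] != 1L)) {
    stop("expected 3D volume, got ", ndim, "D image with dim ",
         paste(dims, collapse = "x"), ": ", path)
  }
  dims <- dims[1:3]
  datatype <- rd(70L, "integer", 2L)
  spec <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  pixdim <- rd(76L, "numeric", 4L, 8L)
  vox_offset <- rd(108L, "numeric", 4L)
  scl_slope <- rd(112L, "numeric", 4L)
  scl_inter <- rd(116L, "numeric", 4L)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(dims)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data: ", path)
  vals <- as.numeric(vals)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = dims), spacing = abs(pixdim[2:4]))
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array with per-axis mm spacing as a single-file NIfTI-1
#' image, little-endian, with an identity-orientation sform. Paths ending
#' in `.gz` are gzip-compressed.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype `"float32"`, `"float64"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, spacing, path, datatype = "float32") {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  code <- switch(datatype,
    float32 = c(16L, 32L), float64 = c(64L, 64L), uint8 = c(2L, 8L),
    stop("unsupported datatype: ", datatype))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")

  w(348L, 4L)                                   # sizeof_hdr
  w(raw(36L), 1L)                               # unused + dim_info
  w(as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  w(raw(14L), 1L)                               # intent_p1..p3, intent_code
  w(code[1], 2L)                                # datatype
  w(code[2], 2L)                                # bitpix
  w(0L, 2L)                                     # slice_start
  w(c(1, as.numeric(spacing), 1, 1, 1, 1), 4L)  # pixdim[8]
  w(352, 4L)                                    # vox_offset
  w(c(1, 0), 4L)                                # scl_slope, scl_inter
  w(raw(28L), 1L)       # slice_end..glmin (2+1+1+4+4+4+4+4+4 = 28 bytes)
  w(raw(104L), 1L)                              # descrip[80] + aux_file[24]
  w(c(0L, 1L), 2L)                              # qform_code, sform_code
  w(rep(0, 6), 4L)                              # quatern_b/c/d, qoffset x/y/z
  w(c(spacing[1], 0, 0, 0), 4L)                 # srow_x
  w(c(0, spacing[2], 0, 0), 4L)                 # srow_y
  w(c(0, 0, spacing[3], 0), 4L)                 # srow_z
  w(raw(16L), 1L)                               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w(raw(4L), 1L)                                # extension indicator

  vals <- as.vector(data)
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(round(vals))), con)
  } else {
    w(as.numeric(vals), code[2] %/% 8L)
  }
  invisible(path)
}
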