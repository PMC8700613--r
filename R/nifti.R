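# Minimal NIfTI-1 I/O.
#
# Covers exactly what the pipeline needs: single-file .nii / .nii.gz,
# 3D or 4D, datatypes uint8 / int16 / int32 / float32 / float64, both
# endiannesses, scl_slope / scl_inter scaling. No orientation handling:
# images and atlases are required to share the voxel grid, and all
# aggregation happens in voxel space.

NIFTI_DT <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  what   = c("integer", "integer", "integer", "double", "double"),
  size   = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 image
#'
#' Minimal single-file NIfTI-1 reader (`.nii` or `.nii.gz`) supporting the
#' datatypes produced by common fMRI tooling (uint8, int16, int32, float32,
#' float64). `scl_slope`/`scl_inter` scaling is applied when set. Returns
#' voxel data as a plain numeric array; no orientation or world-space
#' interpretation is attempted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return object of class `nifti_image`: a list with `data` (3D/4D array),
#'   `pixdim` (per-dimension grid spacing, seconds for the 4th), and
#'   `datatype` (NIfTI datatype code as stored).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    # 348 with swapped bytes
    if (sizeof_hdr == 1543569408L) endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  }
  readBin(con, "raw", 36L)                      # unused header fields
  dim0 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                      # intent_p*, intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 348L - 120L)              # rest of header
  row <- NIFTI_DT[NIFTI_DT$code == datatype, ]
  if (nrow(row) == 0L)
    stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  ndim <- dim0[1L]
  if (ndim < 3L || ndim > 4L)
    stop("only 3D/4D images supported, got ", ndim, "D: ", path)
  dims <- dim0[2L:(1L + ndim)]
  nvox <- prod(dims)
  skip <- max(vox_offset, 352) - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  vals <- readBin(con, row$what, nvox, size = row$size,
                  signed = row$signed, endian = endian)
  if (length(vals) != nvox)
    stop("truncated NIfTI data in ", path, ": expected ", nvox,
         " voxels, read ", length(vals))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  structure(list(data = array(vals, dim = dims),
                 pixdim = pixdim[2L:(1L + ndim)],
                 datatype = datatype),
            class = "nifti_image")
}

#' Write a NIfTI-1 image
#'
#' Writes a 3D or 4D numeric array as a single-file little-endian NIfTI-1
#' image (`.nii`, gzipped if the path ends in `.gz`). Integer-valued label
#' images should be written with `datatype = "int16"` (or `"int32"`);
#' continuous data default to float32.
#'
#' @param data 3D or 4D numeric array, or a `nifti_image`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim grid spacing per dimension (4th entry: TR in seconds).
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = NULL, datatype = "float32") {
  if (inherits(data, "nifti_image")) {
    if (is.null(pixdim)) pixdim <- data$pixdim
    data <- data$data
  }
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("data must be a 3D or 4D array")
  dt_code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                    float32 = 16L, float64 = 64L,
                    stop("unsupported datatype: ", datatype))
  row <- NIFTI_DT[NIFTI_DT$code == dt_code, ]
  ndim <- length(dim(data))
  if (is.null(pixdim)) pixdim <- rep(1, ndim)
  dim0 <- integer(8L); dim0[1L] <- ndim; dim0[2L:(1L + ndim)] <- dim(data)
  dim0[dim0 == 0L] <- 1L
  pd <- numeric(8L); pd[2L:(1L + ndim)] <- pixdim[seq_len(ndim)]
  con <- nii_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4L, endian = "little")
  writeBin(raw(36L), con)
  writeBin(as.integer(dim0), con, size = 2L, endian = "little")
  writeBin(raw(14L), con)
  writeBin(dt_code, con, size = 2L, endian = "little")
  writeBin(8L * row$size, con, size = 2L, endian = "little")   # bitpix
  writeBin(0L, con, size = 2L, endian = "little")              # slice_start
  writeBin(pd, con, size = 4L, endian = "little")
  writeBin(352, con, size = 4L, endian = "little")             # vox_offset
  writeBin(1, con, size = 4L, endian = "little")               # scl_slope
  writeBin(0, con, size = 4L, endian = "little")               # scl_inter
  writeBin(raw(224L), con)                                     # bytes 120..343
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)      # magic @344
  writeBin(raw(4L), con)                                       # extension flag
  vals <- as.vector(data)
  if (row$what == "integer") {
    vals <- as.integer(round(vals))
    writeBin(vals, con, size = row$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = row$size, endian = "little")
  }
  invisible(path)
}

#' @export
print.nifti_image <- function(x, ...) {
  cat(sprintf("NIfTI-1 image: %s, pixdim [%s], datatype %d\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$pixdim, 4), collapse = ", "), x$datatype))
  invisible(x)
}
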