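# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
# Only what a parametric-map pipeline needs: 2-D/3-D volumes, the common
# datatypes, scl_slope/scl_inter scaling, pixdim spacing and the sform
# matrix. No R NIfTI package is assumed.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE))  # uint16

.open_bin <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 volume (optionally gzipped). 2-D images are
#' returned as single-slice 3-D arrays. Data scaling (scl_slope/scl_inter)
#' is applied. Voxel spacing and the sform affine are attached as the
#' \code{"geometry"} attribute so that \code{\link{write_volume}} can
#' preserve them.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return A 3-D numeric array with attribute \code{geometry}: a list with
#'   \code{spacing_mm} (length 3) and \code{srow} (3x4 affine, NA if the
#'   file carried none).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .open_bin(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  rd <- function(what, n, off, size, endian, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  endian <- "little"
  if (rd("integer", 1, 0, 4, "little") != 348L) {
    endian <- "big"
    if (rd("integer", 1, 0, 4, "big") != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1")
    stop("two-file (.hdr/.img) NIfTI not supported: ", path)
  dim8 <- rd("integer", 8, 40, 2, endian)
  ndim <- dim8[1]
  if (ndim < 2) stop("unsupported dimensionality: ", ndim)
  dims <- dim8[2:(1 + ndim)]
  if (ndim > 3) {
    if (any(dims[4:ndim] > 1))
      stop("volume has ", ndim, " non-trivial dimensions; only 2-D/3-D ",
           "volumes are supported")
    dims <- dims[1:3]
  }
  if (length(dims) == 2) dims <- c(dims, 1L)
  datatype <- rd("integer", 1, 70, 2, endian)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd("double", 8, 76, 4, endian)
  vox_offset <- rd("double", 1, 108, 4, endian)
  scl_slope <- rd("double", 1, 112, 4, endian)
  scl_inter <- rd("double", 1, 116, 4, endian)
  sform_code <- rd("integer", 1, 254, 2, endian)
  srow <- matrix(rd("double", 12, 280, 4, endian), 3, 4, byrow = TRUE)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < n) stop("truncated voxel data in ", path)
  data <- as.numeric(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  vol <- array(data, dims)
  attr(vol, "geometry") <- list(
    spacing_mm = pixdim[2:4],
    srow = if (sform_code > 0) srow else matrix(NA_real_, 3, 4))
  vol
}

#' Write a NIfTI-1 volume
#'
#' Writes a 2-D or 3-D numeric array as a float64 single-file NIfTI-1 volume
#' (gzipped when the path ends in \code{.gz}), preserving the voxel spacing
#' and sform affine from the array's \code{geometry} attribute (as attached
#' by \code{\link{read_volume}}); a default identity geometry is used
#' otherwise. float64 keeps the roundtrip lossless.
#'
#' @param volume Numeric array (2-D or 3-D).
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing_mm Voxel spacing override (length 3).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, spacing_mm = NULL) {
  dm <- dim(volume)
  if (is.null(dm) || !length(dm) %in% 2:3)
    stop("volume must be a 2-D or 3-D array")
  if (length(dm) == 2) dm <- c(dm, 1L)
  geom <- attr(volume, "geometry")
  if (is.null(spacing_mm))
    spacing_mm <- if (!is.null(geom)) geom$spacing_mm else c(1, 1, 1)
  srow <- if (!is.null(geom) && all(is.finite(geom$srow))) geom$srow
          else cbind(diag(spacing_mm), c(0, 0, 0))
  con <- .open_bin(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wb(348L, 4)                                  # sizeof_hdr
  wraw(36)                                     # unused through byte 39
  wb(as.integer(c(3, dm, 1, 1, 1, 1)), 2)      # dim[8]
  wraw(14)                                     # intent params/codes
  wb(64L, 2)                                   # datatype float64
  wb(64L, 2)                                   # bitpix
  wb(0L, 2)                                    # slice_start
  wb(c(1, spacing_mm, 1, 1, 1, 1), 4)          # pixdim[8]
  wb(352, 4)                                   # vox_offset
  wb(1, 4); wb(0, 4)                           # scl_slope, scl_inter
  wraw(3)                                      # slice_end, slice_code, xyzt
  wb(2L, 1)                                    # xyzt_units: mm
  wb(c(0, 0, 0), 4)                            # cal_max, cal_min, slice_dur
  wb(0, 4)                                     # toffset
  wraw(8)                                      # glmax, glmin (unused)
  wraw(80 + 24)                                # descrip, aux_file
  wb(0L, 2); wb(1L, 2)                         # qform_code 0, sform_code 1
  wb(rep(0, 6), 4)                             # quatern b,c,d + offsets x,y,z
  wb(as.numeric(t(srow)), 4)                   # srow_x, srow_y, srow_z
  wraw(16)                                     # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  wraw(4)                                      # extension flag
  wb(as.numeric(volume), 8)
  invisible(path)
}

# Error if two volumes cannot be fitted jointly.
.check_same_geometry <- function(a, b, name_a = "volume_b",
                                 name_b = "volume_d") {
  if (!identical(dim(a), dim(b)))
    stop(name_a, " and ", name_b, " have mismatched dimensions (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")")
  ga <- attr(a, "geometry"); gb <- attr(b, "geometry")
  if (!is.null(ga) && !is.null(gb) &&
      any(abs(ga$spacing_mm - gb$spacing_mm) > 1e-5))
    stop(name_a, " and ", name_b, " have mismatched voxel spacing")
  invisible(TRUE)
}
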