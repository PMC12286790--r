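#' Create a 3D volume
#'
#' A `volume` is the imaging substrate used throughout the package: a 3D
#' numeric array with a physical voxel spacing in millimetres. Masks are
#' volumes with values in \{0, 1\}; habitat maps are volumes with small
#' non-negative integer labels.
#'
#' @param data A 3D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm per axis.
#' @return An object of class `volume` (a 3D array with a `spacing`
#'   attribute).
#' @export
volume <- function(data, spacing = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array, got ", length(dim(data)), " dims")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values (mm)")
  }
  structure(data, spacing = spacing, class = c("volume", "array"))
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<volume %d x %d x %d, spacing %s mm, range [%g, %g]>\n",
              d[1], d[2], d[3],
              paste(signif(attr(x, "spacing"), 4), collapse = " x "),
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE))))
  invisible(x)
}

#' Voxel spacing of a volume
#' @param x A `volume`.
#' @return Numeric length-3 spacing in mm.
#' @export
vox_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) c(1, 1, 1) else sp
}

#' Voxel volume in cubic millimetres
#' @param x A `volume`.
#' @return Scalar mm^3 per voxel.
#' @export
vox_volume_mm3 <- function(x) prod(vox_spacing(x))

# Internal: coerce to plain array, keeping dims.
vol_data <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b))) {
    stop(what, " have mismatched dimensions: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O (uncompressed .nii, single file).
#
# No NIfTI package is available in the target library, so the package carries
# a small reader/writer for the subset it produces: 3D/4D volumes, float32 or
# uint8 data, diagonal affine from the voxel spacing, little-endian. This is
# deliberately not a general NIfTI implementation.
# ---------------------------------------------------------------------------

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)

#' Write a volume as NIfTI-1
#'
#' Writes an uncompressed single-file `.nii` with a diagonal affine built
#' from the voxel spacing. `uint8` is used for masks and label maps,
#' `float32` for everything else.
#'
#' @param x A `volume`, or a 4D array with a `spacing` attribute (e.g. a
#'   z-spectrum stack; the 4th axis gets pixdim 1).
#' @param path Output path ending in `.nii`.
#' @param datatype `"float32"` (default) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  d <- dim(x)
  if (!(length(d) %in% c(3L, 4L))) stop("only 3D/4D volumes are supported")
  sp <- vox_spacing(x)
  ndim <- length(d)
  dim16 <- rep(1L, 8L); dim16[1] <- ndim; dim16[2:(1 + ndim)] <- d
  pixdim <- rep(1, 8); pixdim[1] <- 1; pixdim[2:4] <- sp

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")           # sizeof_hdr
  writeBin(raw(36), con)                                     # unused
  writeBin(as.integer(dim16), con, size = 2, endian = "little")
  writeBin(raw(14), con)                                     # intent etc.
  writeBin(NIFTI_DT[[datatype]], con, size = 2, endian = "little")
  bitpix <- if (datatype == "uint8") 8L else 32L
  writeBin(bitpix, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")             # slice_start
  writeBin(pixdim, con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")            # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")        # scl_slope/inter
  writeBin(raw(123 - 120), con)                              # slice_end..xyzt
  # pad up to offset 253 (descrip 80 + aux_file 24 start at 148)
  writeBin(raw(148 - 123), con)
  writeBin(raw(104), con)                                    # descrip+aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")      # qform, sform
  writeBin(rep(0, 6), con, size = 4, endian = "little")      # quatern b..z
  srow <- rbind(c(sp[1], 0, 0, 0), c(0, sp[2], 0, 0), c(0, 0, sp[3], 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                     # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                      # extension flag
  vals <- as.numeric(x)
  if (datatype == "uint8") {
    writeBin(as.integer(round(vals)), con, size = 1, endian = "little")
  } else {
    writeBin(vals, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package
#'
#' @param path Path to an uncompressed `.nii` file.
#' @return A `volume` (3D) or a spacing-tagged array (4D).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(hdr_size, 348L)) stop("not a NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36))
  dim16 <- readBin(con, "integer", 8, size = 2, endian = "little")
  invisible(readBin(con, "raw", 14))
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "integer", 1, size = 2, endian = "little")) # bitpix
  invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  slope <- readBin(con, "numeric", 1, size = 4, endian = "little")
  inter <- readBin(con, "numeric", 1, size = 4, endian = "little")
  ndim <- dim16[1]
  if (!(ndim %in% c(3L, 4L))) stop("unsupported NIfTI dimensionality: ", ndim)
  d <- dim16[2:(1 + ndim)]
  n <- prod(d)
  seek(con, where = vox_offset, origin = "start")
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE,
                              endian = "little")),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype))
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    vals <- vals * slope + inter
  }
  arr <- array(vals, dim = d)
  sp <- pixdim[2:4]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  if (ndim == 3L) volume(arr, spacing = sp)
  else structure(arr, spacing = sp)
}
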