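# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O for 3D float volumes.
# Only what the synthetic-cohort interface needs: no orientation matrices
# beyond an identity affine, float32 storage, little-endian.

#' Write a 3D volume to a NIfTI-1 file
#'
#' Stores a single-channel 3D array as a little-endian float32 `.nii` or
#' `.nii.gz` file with an identity affine and unit voxel size.  This is a
#' purposely minimal writer for exchanging synthetic phantom volumes with
#' standard neuroimaging tools; it does not attempt to cover the full
#' NIfTI specification.
#'
#' @param volume numeric 3D array (H x W x D).
#' @param path output file path; compressed with gzip when it ends in `.gz`.
#' @return `path`, invisibly.
#' @seealso [read_nifti_volume()]
#' @export
write_nifti_volume <- function(volume, path) {
  stop_if_not(is.array(volume) && length(dim(volume)) == 3L,
              "`volume` must be a 3D array")
  dims <- dim(volume)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)

  writeBin(348L, con, size = 4, endian = "little")        # sizeof_hdr
  writeBin(raw(36), con)                                   # unused junk
  writeBin(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), con,   # dim[0..7]
           size = 2, endian = "little")
  writeBin(raw(14), con)                                   # intent params
  writeBin(c(16L, 32L), con, size = 2, endian = "little")  # datatype float32, bitpix
  writeBin(0L, con, size = 2, endian = "little")           # slice_start
  writeBin(c(0, 1, 1, 1, 0, 0, 0, 0), con, size = 4, endian = "little") # pixdim
  writeBin(352, con, size = 4, endian = "little")          # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")      # scl_slope, scl_inter
  writeBin(raw(3), con)                                    # slice_end, slice_code, xyzt_units
  writeBin(raw(1), con)
  writeBin(c(0, 0, 0, 0), con, size = 4, endian = "little") # cal_max/min, slice_duration, toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")    # glmax, glmin
  writeBin(raw(104), con)                                  # descrip + aux_file
  writeBin(c(0L, 1L), con, size = 2, endian = "little")    # qform_code 0, sform_code 1
  writeBin(rep(0, 6), con, size = 4, endian = "little")    # quaternion
  srow <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  writeBin(as.numeric(t(srow)), con, size = 4, endian = "little")
  writeBin(charToRaw(sprintf("%-16s", "")), con)           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)            # magic
  writeBin(raw(4), con)                                    # extension flag
  writeBin(as.numeric(volume), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' Companion reader for [write_nifti_volume()]; supports little-endian
#' float32/float64/int16 single-frame 3D images.
#'
#' @param path `.nii` or `.nii.gz` file path.
#' @return numeric 3D array.
#' @export
read_nifti_volume <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  stop_if_not(hdr_size == 348L, "not a NIfTI-1 file (sizeof_hdr=%d)", hdr_size)
  readBin(con, "raw", 36)
  dims <- readBin(con, "integer", 8, size = 2, endian = "little")
  readBin(con, "raw", 14)
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "integer", 1, size = 2, endian = "little")  # bitpix
  readBin(con, "integer", 1, size = 2, endian = "little")  # slice_start
  readBin(con, "numeric", 8, size = 4, endian = "little")  # pixdim
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = "little")
  readBin(con, "raw", 348 - 112)                           # rest of header
  readBin(con, "raw", max(0, round(vox_offset) - 348))     # skip to data
  shp <- dims[2:4]
  n <- prod(shp)
  vals <- switch(as.character(datatype),
    "16" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    stop("unsupported NIfTI datatype: ", datatype))
  array(vals, dim = shp)
}
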