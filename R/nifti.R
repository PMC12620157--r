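# Minimal NIfTI-1 (.nii, uncompressed, single-file) reader/writer.
# No NIfTI package ships with the supported environment, so the package
# carries its own codec for the subset it needs: 3D/4D volumes, float32/
# float64 writing, and the common integer/float dtypes on read.

#' Write a 3D/4D array as an uncompressed NIfTI-1 file
#'
#' A JSON sidecar (`<path>.json`) records units and a free-form description.
#'
#' @param vol numeric array, 3 or 4 dimensions
#' @param path output filename (conventionally `.nii`)
#' @param pixdim voxel sizes in mm (recycled to the array rank)
#' @param datatype "float32" or "float64"
#' @param units value units recorded in the sidecar
#' @param description free-form sidecar text
#' @export
write_nifti <- function(vol, path, pixdim = c(1, 1, 1), datatype = "float32",
                        units = "", description = "") {
  d <- dim(vol)
  if (is.null(d) || length(d) < 3 || length(d) > 4)
    stop("vol must be a 3D or 4D array")
  code <- switch(datatype, float32 = 16L, float64 = 64L,
                 stop("unsupported datatype"))
  bits <- switch(datatype, float32 = 32L, float64 = 64L)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4) writeBin(as.double(x), con, size = size,
                                       endian = "little")
  dims <- c(length(d), d, rep(1L, 7 - length(d)))
  pix <- c(0, rep_len(pixdim, length(d)), rep(0, 7 - length(d)))
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(dims, 2)                                   # dim[8]
  wf(rep(0, 3))                                 # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(code, 2)                                   # datatype
  wi(bits, 2)                                   # bitpix
  wi(0L, 2)                                     # slice_start
  wf(pix)                                       # pixdim[8]
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  wf(rep(0, 6))                                 # quatern b c d, qoffset x y z
  wf(c(pix[2], 0, 0, 0))                        # srow_x
  wf(c(0, pix[3], 0, 0))                        # srow_y
  wf(c(0, 0, pix[4], 0))                        # srow_z
  writeBin(raw(16), con)                          # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)      # magic
  writeBin(raw(4), con)                           # extension flag
  wf(as.double(vol), size = bits / 8)
  jsonlite::write_json(list(units = units, description = description,
                            dim = d, pixdim = rep_len(pixdim, length(d))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_nifti
#' @return `read_nifti`: the array, with attributes `pixdim`
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 348) stop("not a little-endian NIfTI-1 file")
  invisible(readBin(con, "raw", 36))
  dims <- readBin(con, "integer", 8, size = 2, endian = "little")
  invisible(readBin(con, "double", 3, size = 4, endian = "little"))
  invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
  datatype <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "integer", 2, size = 2, endian = "little"))
  pixdim <- readBin(con, "double", 8, size = 4, endian = "little")
  vox_offset <- readBin(con, "double", 1, size = 4, endian = "little")
  scl_slope <- readBin(con, "double", 1, size = 4, endian = "little")
  scl_inter <- readBin(con, "double", 1, size = 4, endian = "little")
  seek(con, vox_offset)
  nd <- dims[1]
  d <- dims[2:(1 + nd)]
  n <- prod(d)
  vals <- switch(as.character(datatype),
    "2" = as.double(readBin(con, "integer", n, size = 1, signed = FALSE)),
    "4" = as.double(readBin(con, "integer", n, size = 2, endian = "little")),
    "8" = as.double(readBin(con, "integer", n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  out <- array(vals, d)
  attr(out, "pixdim") <- pixdim[2:(1 + nd)]
  out
}

#' Write a set of parameter maps as NIfTI volumes with unit sidecars
#'
#' @param maps named list of 3D arrays
#' @param dir output directory (created if needed)
#' @param pixdim voxel size, mm
#' @export
write_parameter_maps <- function(maps, dir, pixdim = c(1, 1, 1)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  units <- c(fa = "fraction", fw = "fraction", p2 = "dimensionless",
             Da = "um^2/ms", De_par = "um^2/ms", De_perp = "um^2/ms",
             FA = "dimensionless", MD = "um^2/ms", MK = "dimensionless")
  for (nm in names(maps)) {
    u <- if (nm %in% names(units)) units[[nm]] else ""
    write_nifti(maps[[nm]], file.path(dir, paste0(nm, ".nii")),
                pixdim = pixdim, units = u)
  }
  invisible(dir)
}
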