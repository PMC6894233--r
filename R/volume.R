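#' 3-D intensity volume
#'
#' The image currency of the pipeline: a 3-D scalar array with isotropic (or
#' per-axis) voxel spacing, an annotated axial (scan) axis and a frame label.
#' The axial axis is the first array dimension; the physical coordinate of
#' voxel `(i, j, k)` (1-based) is `(i - 1, j - 1, k - 1) * spacing` millimetres,
#' with no origin offset.
#'
#' @param data numeric 3-D array of intensities (finite values).
#' @param spacing_mm voxel spacing in mm; a scalar (isotropic, default 0.082,
#'   the nominal XtremeCT voxel size) or a length-3 vector.
#' @param axial_axis which array axis is the scan (slice) axis; fixed to 1 in
#'   this implementation and kept as metadata.
#' @param frame one of `"baseline"`, `"followup"`, `"baseline-registered"`.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_mm = 0.082, axial_axis = 1L,
                     frame = c("baseline", "followup", "baseline-registered")) {
  frame <- match.arg(frame)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (!all(is.finite(data))) stop("intensities must be finite")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be positive (scalar or length 3)")
  if (!identical(as.integer(axial_axis), 1L))
    stop("the axial axis must be array axis 1")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 axial_axis = 1L, frame = frame),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, frame '%s'\n",
              d[1], d[2], d[3],
              paste(format(x$spacing_mm, digits = 4), collapse = " x "),
              x$frame))
  cat(sprintf("  axial axis 1: %d slices, physical extent %.3f mm\n",
              d[1], axial_extent_mm(x)))
  invisible(x)
}

#' Axial physical extent of a volume
#'
#' Number of axial slices times the axial voxel spacing, e.g. 110 slices at
#' 0.082 mm span 9.02 mm.
#'
#' @param vol a [volume3d].
#' @return extent in mm.
#' @export
axial_extent_mm <- function(vol) {
  stopifnot(inherits(vol, "volume3d"))
  dim(vol$data)[1L] * vol$spacing_mm[1L]
}

#' Voxel volume in cubic millimetres
#' @param vol a [volume3d] (or a spacing vector).
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(vol) {
  sp <- if (inherits(vol, "volume3d")) vol$spacing_mm else rep(vol, length.out = 3)
  prod(sp)
}

#' Read and write volumes
#'
#' Volumes are exchanged as NIfTI (`.nii` / `.nii.gz`, via \pkg{RNifti}) or
#' uncompressed MetaImage (`.mha`, minimal `MET_FLOAT`/`MET_DOUBLE` support
#' written directly: no installed reader covers the format). Spacing metadata
#' is preserved; the frame label is not (NIfTI has no such field) and must be
#' supplied on read.
#'
#' @param vol a [volume3d].
#' @param path output file; format chosen by extension.
#' @return `write_volume` returns `path` invisibly; `read_volume` a [volume3d].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(vol$data, reference = NULL)
    RNifti::pixdim(img) <- vol$spacing_mm
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.mha$", path)) {
    write_mha(vol$data, vol$spacing_mm, path)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

#' @rdname write_volume
#' @param frame frame label to attach on read.
#' @export
read_volume <- function(path, frame = "baseline") {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    volume3d(array(as.numeric(img), dim = dim(img)[1:3]), spacing_mm = sp,
             frame = frame)
  } else if (grepl("\\.mha$", path)) {
    r <- read_mha(path)
    volume3d(r$data, spacing_mm = r$spacing, frame = frame)
  } else {
    stop("unsupported volume format: ", path)
  }
}

write_mha <- function(data, spacing, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           "Offset = 0 0 0",
           paste("ElementSpacing =", paste(format(spacing, digits = 10), collapse = " ")),
           paste("DimSize =", paste(dim(data), collapse = " ")),
           "ElementType = MET_DOUBLE",
           "ElementDataFile = LOCAL")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(data), con, size = 8, endian = "little")
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  gethdr <- function(key) {
    ln <- grep(paste0("^", key, " ?="), hdr, value = TRUE)
    trimws(sub("^[^=]*=", "", ln[1]))
  }
  if (!identical(gethdr("ElementDataFile"), "LOCAL"))
    stop("only LOCAL MetaImage payloads are supported")
  dims <- as.integer(strsplit(gethdr("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(gethdr("ElementSpacing"), "\\s+")[[1]])
  type <- gethdr("ElementType")
  size <- switch(type, MET_DOUBLE = 8L, MET_FLOAT = 4L,
                 stop("unsupported ElementType: ", type))
  n <- prod(dims)
  raw <- readBin(con, "numeric", n = n, size = size, endian = "little")
  list(data = array(raw, dim = dims), spacing = spacing)
}
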