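#' 3D image volume with voxel geometry
#'
#' Light container for a 3D scalar grid plus its voxel spacing in mm and a
#' modality tag. All geometric computations in the package work in physical
#' (mm) coordinates derived from `spacing`, with voxel centers at
#' `(i - 0.5) * spacing` along each axis (1-based indices), so anisotropic
#' grids (e.g. 0.4688 x 0.4688 x 5.0 mm FLAIR) are handled uniformly.
#'
#' @param data numeric (or logical) 3D array.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param modality character tag, e.g. `"flair"`, `"magnitude"`, `"phase"`.
#' @param origin numeric length-3, mm position of the grid's corner
#'   (voxel center i sits at `origin + (i - 0.5) * spacing`); default 0.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, modality = "unknown",
                         origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing,
                 modality = as.character(modality)[1],
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels  spacing %.4f x %.4f x %.4f mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  rng <- range(x$data[is.finite(x$data)])
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

is_image_volume <- function(x) inherits(x, "image_volume")

#' Voxel volume in mm^3 for a spacing triple
#' @param spacing numeric length-3 spacing in mm.
#' @return scalar mm^3.
#' @export
voxel_volume_mm3 <- function(spacing) prod(as.numeric(spacing))

# stop unless two grids (arrays, masks, or image_volumes) agree in shape
check_same_grid <- function(a, b, what = "volumes") {
  da <- if (is_image_volume(a)) dim(a$data) else dim(a)
  db <- if (is_image_volume(b)) dim(b$data) else dim(b)
  if (is.null(da) || is.null(db) || length(da) != length(db) || any(da != db))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(da, collapse = "x"), paste(db, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

as_mask <- function(m) {
  if (is_image_volume(m)) m <- m$data
  if (!is.logical(m)) {
    storage.mode(m) <- "double"
    m <- m != 0
  }
  m
}

#' Wrap angles into the principal interval (-pi, pi]
#'
#' @param x numeric array of angles in radians.
#' @return array of the same shape with every value in (-pi, pi].
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

#' Voxel-center coordinates (mm) along one axis
#' @param n number of voxels, @param sp spacing mm.
#' @keywords internal
axis_coords_mm <- function(n, sp) (seq_len(n) - 0.5) * sp

# ---------------------------------------------------------------------------
# Minimal NIfTI-1 I/O. Only what the pipeline needs: single-file .nii or
# .nii.gz, 3D, float32 (images) or uint8 (masks), little-endian, no
# extensions, qform/sform left at pixdim scaling. There is no NIfTI package
# in the supported dependency set, so this is implemented directly against
# the NIfTI-1 header layout (348-byte header, vox_offset 352).
# ---------------------------------------------------------------------------

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' Masks (logical data) are stored as uint8, everything else as float32.
#'
#' @param vol an [image_volume()] or a 3D array (then `spacing` is required).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param spacing spacing in mm when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, spacing = NULL) {
  if (is_image_volume(vol)) {
    arr <- vol$data; spacing <- vol$spacing
  } else {
    arr <- vol
    if (is.null(spacing)) stop("`spacing` required when writing a bare array", call. = FALSE)
  }
  if (length(dim(arr)) != 3L) stop("only 3D volumes are supported", call. = FALSE)
  is_mask <- is.logical(arr)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(c(3L, dim(arr), 1L, 1L, 1L, 1L), 2)      # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(if (is_mask) 2L else 16L, 2)  # datatype: 2 uint8, 16 float32
  wi(if (is_mask) 8L else 32L, 2)  # bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, spacing, 0, 0, 0, 0))    # pixdim[8] (qfac 1)
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc("", 1)  # slice_end, slice_code, xyzt_units
  wf(0); wf(0); wf(0)              # cal_max, cal_min, slice_duration
  wf(0); wi(0L, 4); wi(0L, 4)      # toffset, glmax, glmin
  wc("dmvq", 80); wc("", 24)       # descrip, aux_file
  wi(0L, 2); wi(0L, 2)             # qform_code, sform_code
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d, qoffset x,y,z
  wf(c(spacing[1], 0, 0, 0)); wf(c(0, spacing[2], 0, 0)); wf(c(0, 0, spacing[3], 0))
  wc("", 16); wc("n+1", 4)         # intent_name, magic
  writeBin(raw(4), con)            # extension flag -> vox_offset 352
  if (is_mask) {
    writeBin(as.integer(arr), con, size = 1, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package (or any plain 3D float/int file)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param modality modality tag to attach.
#' @return an [image_volume()]; uint8 data are returned as logical masks.
#' @export
read_nifti <- function(path, modality = "unknown") {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  readBin(con, "raw", n = 36)      # skip to dim
  dims <- ri(8, 2)
  if (dims[1] < 3) stop("expected a 3D volume", call. = FALSE)
  d <- dims[2:4]
  rf(3); ri(1, 2)                  # intent_p, intent_code
  datatype <- ri(1, 2); ri(1, 2); ri(1, 2)  # datatype, bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  # skip the rest of the header + extension bytes
  readBin(con, "raw", n = as.integer(vox_offset) - 120L)
  n <- prod(d)
  arr <- switch(as.character(datatype),
    "2"  = readBin(con, "integer", n = n, size = 1, signed = FALSE, endian = "little"),
    "4"  = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8"  = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype, call. = FALSE))
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    arr <- arr * scl_slope + scl_inter
  dim(arr) <- d
  if (datatype == 2 && all(arr %in% c(0, 1))) arr <- arr == 1
  image_volume(arr, pixdim[2:4], modality)
}
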