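# Minimal NIfTI-1 I/O. No NIfTI reader ships with the R stack this package
# targets, so a small single-file (.nii / .nii.gz) reader/writer is provided
# for the optional volume-based entry point. Supports the scalar datatypes a
# preprocessed gray-matter map realistically uses; no extensions, no .hdr/.img
# pairs.

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)    # float64
)

#' Read a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 reader: returns the voxel array (with
#' `scl_slope`/`scl_inter` applied when set) plus grid metadata. Handles both
#' endiannesses and gzip compression by extension.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (numeric array), `dim`, `pixdim`, and `srow`
#'   (3x4 affine rows).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop(path, " is not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic in ", path)
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n, 4L, endian = endian)
  dims <- rd_i16(40L, 8L)
  ndim <- dims[1L]
  shape <- dims[2:(1L + max(ndim, 1L))]
  if (any(shape <= 0L)) stop("invalid dimensions in ", path)
  datatype <- rd_i16(70L, 1L)
  spec <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd_f32(76L, 8L)[2:4]
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n_vox <- prod(shape)
  data <- readBin(con, spec$what, n_vox, spec$size, signed = spec$signed,
                  endian = endian)
  if (length(data) < n_vox) stop("truncated voxel data in ", path)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = shape), dim = shape, pixdim = pixdim,
       srow = srow)
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file float32 or float64 NIfTI-1 volume with an axial
#' affine built from `pixdim`. Intended for fixtures and simulated volumes.
#'
#' @param data numeric array (up to 3-D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim voxel sizes (length 3).
#' @param datatype `"float32"` or `"float64"`.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1),
                        datatype = c("float32", "float64")) {
  datatype <- match.arg(datatype)
  dt_code <- if (datatype == "float32") 16L else 64L
  dt_size <- if (datatype == "float32") 4L else 8L
  shape <- dim(data)
  if (is.null(shape)) shape <- length(data)
  if (length(shape) > 3L) stop("write_nifti supports up to 3-D arrays")
  dims <- integer(8L)
  dims[1L] <- length(shape)
  dims[2:(1L + length(shape))] <- shape
  dims[dims == 0L] <- 1L
  hdr <- raw(348L)
  put <- function(x, off, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(x) else as.double(x),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
    invisible(NULL)
  }
  put(348L, 0L, 4L)
  put(dims, 40L, 2L)
  put(dt_code, 70L, 2L)
  put(8L * dt_size, 72L, 2L)                     # bitpix
  put(c(1, pixdim, rep(0, 4)), 76L, 4L, "double")
  put(352, 108L, 4L, "double")                   # vox_offset
  put(1, 112L, 4L, "double")                     # scl_slope
  put(0, 116L, 4L, "double")                     # scl_inter
  put(1L, 252L, 2L)                              # sform_code
  srow <- rbind(c(pixdim[1L], 0, 0, 0), c(0, pixdim[2L], 0, 0),
                c(0, 0, pixdim[3L], 0))
  put(srow[1L, ], 280L, 4L, "double")
  put(srow[2L, ], 296L, 4L, "double")
  put(srow[3L, ], 312L, 4L, "double")
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                         # pad to vox_offset 352
  writeBin(as.double(data), con, size = dt_size, endian = "little")
  invisible(path)
}

#' Describe a gray-matter volume / atlas volume pair
#'
#' @param gm_volume path to the scalar gray-matter NIfTI volume.
#' @param atlas_volume path to the integer-labeled parcellation volume on the
#'   same grid.
#' @param label_map data.frame with columns `parcel` (integer) and `name`;
#'   defaults to AAL-90 (parcel i = canonical region i).
#' @return An object of class `atlas_volume_pair`.
#' @export
atlas_volume_pair <- function(gm_volume, atlas_volume, label_map = NULL) {
  if (is.null(label_map))
    label_map <- data.frame(parcel = 1:90, name = aal90_names(),
                            stringsAsFactors = FALSE)
  stopifnot(all(c("parcel", "name") %in% names(label_map)))
  structure(list(gm_volume = gm_volume, atlas_volume = atlas_volume,
                 label_map = label_map), class = "atlas_volume_pair")
}

#' Extract per-ROI gray-matter samples from a volume pair
#'
#' For each parcel integer in the label map, collects the gray-matter values
#' at voxels whose atlas label equals that integer. By default gray-matter
#' values `<= 0` are dropped (background exclusion); set `mask_nonpositive =
#' FALSE` to retain them.
#'
#' @param pair an [atlas_volume_pair()].
#' @param subject_id subject identifier for the resulting sample set.
#' @param mask_nonpositive drop GM values `<= 0` (default TRUE).
#' @param min_samples minimum samples per region.
#' @return An `roi_sample_set`.
#' @export
extract_roi_samples <- function(pair, subject_id, mask_nonpositive = TRUE,
                                min_samples = 30L) {
  stopifnot(inherits(pair, "atlas_volume_pair"))
  gm <- read_nifti(pair$gm_volume)
  at <- read_nifti(pair$atlas_volume)
  if (!identical(gm$dim, at$dim))
    stop("gray-matter and atlas volumes have different shapes (",
         paste(gm$dim, collapse = "x"), " vs ",
         paste(at$dim, collapse = "x"), ")")
  if (max(abs(gm$srow - at$srow)) > 1e-4)
    stop("gray-matter and atlas volumes have different affines")
  lab <- as.integer(round(at$data))
  vals <- as.double(gm$data)
  samples <- list()
  for (k in seq_len(nrow(pair$label_map))) {
    parcel <- pair$label_map$parcel[k]
    name <- pair$label_map$name[k]
    v <- vals[lab == parcel]
    if (length(v) == 0L)
      stop("parcel ", parcel, " (", name, ") has no voxels in the atlas")
    if (mask_nonpositive) v <- v[v > 0]
    if (length(v) == 0L)
      stop("parcel ", parcel, " (", name,
           ") is empty after masking non-positive gray-matter values")
    samples[[name]] <- v
  }
  roi_sample_set(subject_id, samples, min_samples = min_samples)
}
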