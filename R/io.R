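# Readers and writers. Slices are plain numeric matrices throughout; NIfTI
# access goes through RNifti, 2-D fixtures through png/tiff. Row-major,
# 0-based pixel coordinates are used in all reports.

#' Read slices from a NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param axis Slicing axis for 3-D volumes (default 3, axial for standard
#'   orientation).
#' @param indices Optional integer vector of slice indices to keep.
#' @return List of numeric slice matrices; voxel spacing (mm) in attribute
#'   `pixdim`.
#' @export
read_nifti_slices <- function(path, axis = 3, indices = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pixdim <- RNifti::pixdim(img)
  if (length(dim(arr)) == 2L) {
    slices <- list(matrix(arr, nrow(arr), ncol(arr)))
  } else if (length(dim(arr)) == 3L) {
    slices <- lapply(asplit(arr, axis), function(s) matrix(s, dim(s)[1], dim(s)[2]))
  } else {
    abort("Only 2-D and 3-D NIfTI images are supported.")
  }
  if (!is.null(indices)) slices <- slices[indices]
  attr(slices, "pixdim") <- pixdim
  slices
}

#' Write a volume of slices to NIfTI
#'
#' @param slices List of equally sized slice matrices.
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_slices <- function(slices, path) {
  arr <- simplify2array(slices)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Read a 2-D grayscale image fixture (PNG or TIFF)
#'
#' Multi-channel images are averaged to one grayscale channel.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix of intensities on \[0, 1\].
#' @export
read_slice_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("Unsupported image format: '%s'.", ext))
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  matrix(arr, nrow(arr), ncol(arr))
}

#' Write a 2-D slice as a grayscale image (PNG or TIFF)
#'
#' Intensities are min-max rescaled to \[0, 1\] for storage.
#'
#' @param x Slice matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_slice_image <- function(x, path) {
  rng <- range(x)
  xn <- if (rng[1] == rng[2]) x * 0 else (x - rng[1]) / (rng[2] - rng[1])
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(xn, path),
    tif = ,
    tiff = tiff::writeTIFF(xn, path),
    abort(sprintf("Unsupported image format: '%s'.", ext))
  )
  invisible(path)
}

#' Write a volume report to CSV and JSON
#'
#' The per-slice table goes to CSV (one row per slice: index, n_t, window,
#' mu_d, mu_c, q1-q4, Q); the volume summary (mean scores, cut-off, pass
#' flag) goes to JSON.
#'
#' @param report A `briq_volume`.
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!inherits(report, "briq_volume")) abort("`report` must be a briq_volume.")
  if (!is.null(csv_path)) readr::write_csv(tidy(report), csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(glance(report)), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
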