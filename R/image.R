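#' Construct a dense scalar image
#'
#' An image is a dense 2-D or 3-D grid of finite real intensities. This is the
#' common currency of the whole package: every metric compares two images of
#' identical shape voxel by voxel or through their intensity distributions.
#'
#' @param voxels numeric vector or array of intensities; if a vector, `shape`
#'   must be given.
#' @param shape integer vector of per-axis voxel counts (length 2 or 3).
#'   Defaults to `dim(voxels)`.
#' @return An object of class `mm_image` with fields `voxels` (array),
#'   `shape`, `n` (total voxel count) and `intensity_range`.
#' @export
mm_image <- function(voxels, shape = NULL) {
  if (is.null(shape)) {
    shape <- dim(voxels)
    if (is.null(shape)) stop("`shape` must be given when `voxels` is a plain vector")
  }
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L)
    stop("images must be 2-D or 3-D; got shape of length ", length(shape))
  if (any(shape < 1L)) stop("all axis lengths must be positive")
  v <- as.numeric(voxels)
  if (length(v) != prod(shape))
    stop("voxel count ", length(v), " does not match shape ",
         paste(shape, collapse = "x"))
  if (!all(is.finite(v)))
    stop("image contains non-finite intensities (NaN/Inf)")
  arr <- array(v, dim = shape)
  structure(
    list(voxels = arr, shape = shape, n = length(v),
         intensity_range = range(v)),
    class = "mm_image")
}

#' @export
print.mm_image <- function(x, ...) {
  cat("<mm_image> ", paste(x$shape, collapse = " x "),
      " (", x$n, " voxels), intensities in [",
      format(x$intensity_range[1]), ", ", format(x$intensity_range[2]), "]\n",
      sep = "")
  invisible(x)
}

is_mm_image <- function(x) inherits(x, "mm_image")

#' Coerce to an image
#' @param x an `mm_image`, array or numeric vector.
#' @param shape shape for plain vectors.
#' @return an `mm_image`.
#' @export
as_mm_image <- function(x, shape = NULL) {
  if (is_mm_image(x)) return(x)
  mm_image(x, shape = shape)
}

check_same_shape <- function(r, s, what = "images") {
  if (!identical(r$shape, s$shape))
    stop("shape mismatch between ", what, ": ",
         paste(r$shape, collapse = "x"), " vs ",
         paste(s$shape, collapse = "x"))
  invisible(TRUE)
}

#' Extract intensity values, optionally under a mask
#'
#' @param img an `mm_image`.
#' @param mask optional logical array (same shape) or an `mm_image` whose
#'   nonzero voxels are kept.
#' @return numeric vector of in-mask intensities.
#' @export
image_values <- function(img, mask = NULL) {
  v <- as.numeric(img$voxels)
  if (is.null(mask)) return(v)
  m <- if (is_mm_image(mask)) mask$voxels != 0 else as.logical(mask)
  if (length(m) != length(v)) stop("mask shape does not match image shape")
  v[m]
}

#' Background-exclusion mask
#'
#' Voxel-level measures can be dominated by large uniform background; this
#' builds a mask excluding voxels equal to a given background value. Masking
#' is off by default everywhere in the package.
#'
#' @param img an `mm_image`.
#' @param background intensity value to exclude.
#' @return logical array, `TRUE` where the voxel is kept.
#' @export
background_mask <- function(img, background = 0) {
  array(as.numeric(img$voxels) != background, dim = img$shape)
}

# ---- file I/O ---------------------------------------------------------------

#' Read an image from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and a plain grid-text format: the
#' first line holds the shape, following whitespace-separated numbers are the
#' intensities in row-major (C) order, i.e. the last axis varies fastest.
#'
#' @param path file path.
#' @param format `"nifti"`, `"grid-text"`, or `"auto"` (by extension).
#' @return an `mm_image`. For NIfTI input the affine is kept as attribute
#'   `"affine"` (opaque metadata; metrics never use it).
#' @export
read_image <- function(path, format = c("auto", "nifti", "grid-text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "grid-text"
  if (format == "nifti") {
    nii <- RNifti::readNifti(path)
    arr <- as.array(nii)
    img <- mm_image(arr)
    attr(img, "affine") <- RNifti::xform(nii)
    img
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (length(lines) < 2L) stop("grid-text file too short: ", path)
    shape <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
    vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
    vals <- vals[!is.na(vals) | TRUE]  # keep positions; validated below
    if (anyNA(vals)) stop("non-numeric or NaN intensity in ", path)
    # row-major on disk -> fill reversed dims then transpose axes
    arr <- aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
    mm_image(arr)
  }
}

#' Write an image to disk
#'
#' @param img an `mm_image`.
#' @param path destination; `.nii`/`.nii.gz` selects NIfTI unless `format`
#'   says otherwise.
#' @param format `"auto"`, `"nifti"` or `"grid-text"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "nifti", "grid-text")) {
  format <- match.arg(format)
  img <- as_mm_image(img)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "grid-text"
  if (format == "nifti") {
    RNifti::writeNifti(RNifti::asNifti(img$voxels), path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(img$shape, collapse = " "), con)
    flat <- as.numeric(aperm(img$voxels, rev(seq_along(img$shape))))
    writeLines(paste(format(flat, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = " "), con)
  }
  invisible(path)
}
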