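#' lumident: retinex decomposition and enhancement of low-light dental images
#'
#' Enhancement of under-exposed RGB photographs of teeth and oral mucosa.
#' The central model is the retinex decomposition `S = r * l` of an image into
#' a 3-channel reflectance map `r` and a single-channel illumination field
#' `l`.  The package offers two routes to that decomposition: a training-free
#' chain built on the dark channel prior ([classic_enhance()]) and a pair of
#' small convolutional networks fitted self-supervised with [luminet()].
#' Either way, exponential weighting maps ([weight_config()]) let the user
#' steer output brightness without refitting.
#'
#' @keywords internal
#' @aliases lumident-package
#' @useDynLib lumident, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# ---- internal numeric helpers shared across modules ----

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

# broadcast an H x W matrix across the 3 channels of an H x W x 3 array by
# recycling in column-major order (channel is the slowest-varying index)
bcast3 <- function(m) as.vector(m)

#' RGB image container
#'
#' Construct an `rgb_image`: an `H x W x 3` numeric array of intensities in
#' `[0, 1]` with the source bit depth kept as metadata.  All enhancement
#' operations in the package take and return this representation; the
#' coordinate convention is (row, column) with row 1 at the top.
#'
#' @param pixels numeric `H x W x 3` array with finite values in `[0, 1]`.
#' @param bit_depth 8 or 16; metadata recording the source quantization.
#' @return an `rgb_image` object (the array, classed, with a `bit_depth`
#'   attribute).
#' @examples
#' img <- rgb_image(array(0.5, c(16, 16, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels, bit_depth = 8L) {
  if (!is_rgb_array(pixels))
    stop("`pixels` must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 8L || d[2] < 8L)
    stop("image must be at least 8 x 8")
  if (!all(is.finite(pixels)))
    stop("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image values must lie in [0, 1]")
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  structure(pixels, class = "rgb_image", bit_depth = as.integer(bit_depth))
}

#' Coerce to an rgb_image
#'
#' Matrices (grayscale) are replicated across the three channels; 4-channel
#' arrays have their alpha plane dropped.
#'
#' @param x matrix or 3-d array.
#' @param bit_depth source bit depth metadata, 8 or 16.
#' @return an [rgb_image()].
#' @export
as_rgb_image <- function(x, bit_depth = 8L) {
  if (inherits(x, "rgb_image")) return(x)
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("cannot interpret input as an RGB image")
  nc <- dim(x)[3]
  if (nc == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  else if (nc == 4L) x <- x[, , 1:3, drop = FALSE]
  else if (nc != 3L) stop("unsupported channel count: ", nc)
  rgb_image(x, bit_depth)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, %d-bit source, range [%.3f, %.3f]>\n",
              d[1], d[2], attr(x, "bit_depth"), min(x), max(x)))
  invisible(x)
}

#' Read a PNG or TIFF image
#'
#' Loads an 8- or 16-bit PNG or TIFF file and scales it to unit-interval
#' intensities (division by 255 or 65535 according to the stored bit depth).
#' Grayscale images are replicated to three channels and an alpha channel, if
#' present, is discarded.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return an [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else {
    stop("unsupported image format: .", ext, " (PNG or TIFF expected)")
  }
  # readPNG/readTIFF already return [0,1] doubles scaled by the file's maxval
  as_rgb_image(unclass(raw), bit_depth = as.integer(depth))
}

#' Write an image as PNG or TIFF
#'
#' Quantizes a unit-interval image to the requested bit depth and writes it.
#' PNG output is 8-bit; TIFF supports 8 or 16 bits per sample.  A read-back
#' of the written file agrees with the input to within half a quantization
#' step.
#'
#' @param img an [rgb_image()] (or coercible array).
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 8L) {
  img <- as_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(img)
  attr(x, "bit_depth") <- NULL
  if (ext == "png") {
    if (bit_depth != 8L)
      stop("PNG output is written at 8 bits; use TIFF for 16-bit output")
    ok <- try(png::writePNG(x, path), silent = TRUE)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
    ok <- try(tiff::writeTIFF(x, path, bits.per.sample = as.integer(bit_depth)),
              silent = TRUE)
  } else {
    stop("unsupported image format: .", ext)
  }
  if (inherits(ok, "try-error"))
    stop("could not write image to ", path)
  invisible(path)
}

#' Invert an image
#'
#' Replaces every value `v` by `1 - v`.  The inversion maps a low-light image
#' into a haze-like residue image (and back): applying it twice is the exact
#' identity, which is what makes the dehazing machinery of
#' [classic_enhance()] applicable to under-exposed photographs.
#'
#' @param img an [rgb_image()] (or coercible array).
#' @return the inverted [rgb_image()].
#' @examples
#' img <- rgb_image(array(0.3, c(8, 8, 3)))
#' range(invert_image(img))  # 0.7
#' @export
invert_image <- function(img) {
  img <- as_rgb_image(img)
  rgb_image(1 - unclass(img), attr(img, "bit_depth"))
}
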