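#' Construct a 16-bit-container grayscale image
#'
#' The internal image type for SHG micrographs: a rectangular grid of
#' non-negative integer intensities held in a 16-bit container, with a
#' nominal bit depth (12-bit acquisitions are common and are stored in the
#' 16-bit container unchanged) and optional pixel-size metadata.
#'
#' @param pixels Integer (or whole-number numeric) matrix, values in
#'   `[0, 2^bit_depth - 1]`. Rows are image rows (y), columns are x.
#' @param bit_depth Nominal bit depth, one of 8, 12, 16.
#' @param pixel_size_um Micrometers per pixel (default 1).
#' @return An object of class `image16`.
#' @export
image16 <- function(pixels, bit_depth = 12L, pixel_size_um = 1.0) {
  if (!is.matrix(pixels) || nrow(pixels) == 0L || ncol(pixels) == 0L) {
    stop("pixels must be a non-empty matrix")
  }
  if (!bit_depth %in% c(8L, 12L, 16L)) stop("bit_depth must be 8, 12 or 16")
  if (is.double(pixels)) {
    if (any(pixels != round(pixels))) stop("pixel values must be integers")
    storage.mode(pixels) <- "integer"
  }
  if (anyNA(pixels)) stop("pixel values must not be NA")
  if (min(pixels) < 0L) stop("pixel values must be >= 0")
  maxv <- bitwShiftL(1L, as.integer(bit_depth)) - 1L
  if (max(pixels) > maxv) {
    stop("pixel values exceed 2^bit_depth - 1 = ", maxv)
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um),
    class = "image16"
  )
}

#' @exportS3Method base::print
print.image16 <- function(x, ...) {
  cat(sprintf(
    "image16: %d x %d px, %d-bit, mean %.2f counts, pixel size %g um\n",
    nrow(x$pixels), ncol(x$pixels), x$bit_depth,
    mean(x$pixels), x$pixel_size_um
  ))
  invisible(x)
}

stopifnot_image16 <- function(img) {
  if (!inherits(img, "image16")) stop("expected an image16 object")
}

#' Read a grayscale TIFF micrograph
#'
#' Reads a single-plane grayscale TIFF (8/12/16-bit) losslessly into an
#' [image16]. The nominal bit depth is inferred from the container and the
#' maximum value: a 16-bit container whose values all fit in 12 bits is
#' recorded as 12-bit (the usual situation for scientific CMOS/PMT
#' acquisitions).
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_um Micrometers per pixel to record (default 1; TIFF
#'   resolution tags are not relied upon).
#' @return An [image16].
#' @export
read_image <- function(path, pixel_size_um = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- tryCatch(
    tiff::readTIFF(path, as.is = FALSE, info = TRUE),
    error = function(e) stop("failed to read TIFF: ", conditionMessage(e))
  )
  if (length(dim(raw)) == 3L) {
    stop("unsupported format: multi-channel TIFF (grayscale required)")
  }
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8L, 16L)) {
    stop("unsupported format: ", bits, "-bit samples")
  }
  scale <- 2^bits - 1
  vals <- matrix(as.integer(round(raw * scale)), nrow(raw), ncol(raw))
  depth <- if (bits == 8L) 8L else if (max(vals) <= 4095L) 12L else 16L
  image16(vals, bit_depth = depth, pixel_size_um = pixel_size_um)
}

#' Write an image as a 16-bit grayscale TIFF
#'
#' The write is lossless: reading the file back with [read_image()] yields
#' pixel-identical data. 8- and 12-bit images are stored in the 16-bit
#' container without rescaling.
#'
#' @param img An [image16].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  stopifnot_image16(img)
  m <- img$pixels / 65535
  ok <- tryCatch(
    tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none"),
    error = function(e) stop("failed to write TIFF: ", conditionMessage(e))
  )
  invisible(path)
}

#' Full-bit-range intensity histogram of an image
#'
#' One bin per integer intensity level over the image's full nominal bit
#' range (e.g. 0..4095 for 12-bit). The histogram mean is by construction
#' identical to the direct pixel mean.
#'
#' @param img An [image16].
#' @return A list of class `histogram_summary` with `levels` (0..max),
#'   `counts`, `mean` and `n_pixels`.
#' @export
image_histogram <- function(img) {
  stopifnot_image16(img)
  maxv <- bitwShiftL(1L, img$bit_depth) - 1L
  counts <- tabulate(as.vector(img$pixels) + 1L, nbins = maxv + 1L)
  n <- length(img$pixels)
  levels <- 0:maxv
  structure(
    list(levels = levels, counts = counts,
         mean = sum(as.numeric(levels) * counts) / n, n_pixels = n),
    class = "histogram_summary"
  )
}

#' Mean pixel density of an image
#'
#' The arithmetic mean of all pixel intensities, the "brightness" readout
#' used for SHG signal quantification. Identical to the mean of the
#' full-bit-range histogram.
#'
#' @param img An [image16].
#' @return Mean intensity in counts.
#' @export
mean_pixel_density <- function(img) {
  stopifnot_image16(img)
  mean(img$pixels)
}
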