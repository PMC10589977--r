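#' Gel image raster
#'
#' A raster is a numeric matrix of non-negative intensities in arbitrary
#' units, with rows running in the migration direction (down = farther
#' migrated). All engine computation assumes *signal-high* polarity: larger
#' values mean more signal. Images where bands are dark on a light
#' background (e.g. Ponceau-stained membranes photographed in transmission)
#' are converted once at read time with `invert = TRUE`.
#'
#' All pixel coordinates in this package are 0-based and row-major, and all
#' ranges are half-open, so a crop of height `h` starting at `top` covers
#' rows `top, ..., top + h - 1`.
#'
#' @param pixels numeric matrix, all values finite and >= 0.
#' @param bit_depth_origin one of `"8"`, `"16"`, `"float"`; records the bit
#'   depth of the source file, for provenance only.
#' @return A `gel_raster`: the matrix with class and provenance attributes.
#' @examples
#' r <- gel_raster(matrix(0:5, 2, 3))
#' dim(r)
#' @export
gel_raster <- function(pixels, bit_depth_origin = "float") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("raster must have at least one row and one column", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("raster intensities must all be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("raster intensities must all be >= 0", call. = FALSE)
  }
  bit_depth_origin <- match.arg(as.character(bit_depth_origin),
                                c("float", "8", "16"))
  structure(pixels,
            bit_depth_origin = bit_depth_origin,
            polarity = "signal-high",
            class = c("gel_raster", "matrix", "array"))
}

#' @export
print.gel_raster <- function(x, ...) {
  cat(sprintf("<gel_raster> %d x %d px, range [%g, %g], origin %s-bit\n",
              nrow(x), ncol(x), min(x), max(x),
              attr(x, "bit_depth_origin")))
  invisible(x)
}

as_pixel_matrix <- function(r) {
  m <- unclass(r)
  attr(m, "bit_depth_origin") <- NULL
  attr(m, "polarity") <- NULL
  m
}

# keep the raster class when an operation produced a plain matrix
reraster <- function(pixels, template) {
  gel_raster(pixels, bit_depth_origin = attr(template, "bit_depth_origin") %||% "float")
}

#' Read a gel or membrane image
#'
#' Reads single-page TIFF (8/16-bit), PNG or JPEG. RGB images are reduced
#' to luminance with Rec.709 weights (0.2126 R + 0.7152 G + 0.0722 B). Set
#' `invert = TRUE` for images whose bands are dark on a light background;
#' the result is always signal-high.
#'
#' @param path path to a TIFF/PNG/JPEG file.
#' @param invert logical; if `TRUE`, pixels become `max(pixels) - pixels`.
#' @param page 1-based page of a multi-page TIFF; reading a multi-page file
#'   without naming a page is an error.
#' @return A [gel_raster()] in source-file intensity units (0..255 for
#'   8-bit, 0..65535 for 16-bit).
#' @export
read_gel_image <- function(path, invert = FALSE, page = NULL) {
  if (!file.exists(path)) {
    stop("image file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                      error = function(e) stop("unreadable TIFF: ", path,
                                               " (", conditionMessage(e), ")",
                                               call. = FALSE))
    if (length(pages) > 1L && is.null(page)) {
      stop("multi-page TIFF (", length(pages),
           " pages): select one with the `page` argument", call. = FALSE)
    }
    page <- page %||% 1L
    if (page < 1L || page > length(pages)) {
      stop("`page` out of range: file has ", length(pages), " page(s)",
           call. = FALSE)
    }
    img <- pages[[page]]
    depth <- if (is.integer(img) && max(img) > 255) "16" else
      if (is.integer(img)) "8" else "float"
    img <- img * 1.0
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path, info = TRUE),
                    error = function(e) stop("unreadable PNG: ", path,
                                             call. = FALSE))
    info <- attr(img, "info")
    bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    depth <- if (bits > 8) "16" else "8"
    img <- round(img * (2^bits - 1))
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- tryCatch(jpeg::readJPEG(path),
                    error = function(e) stop("unreadable JPEG: ", path,
                                             call. = FALSE))
    depth <- "8"
    img <- round(img * 255)
  } else {
    stop("unsupported image format: .", ext,
         " (TIFF, PNG and JPEG are supported)", call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    # RGB(A): Rec.709 luminance; alpha, if present, is ignored
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  if (isTRUE(invert)) {
    img <- max(img) - img
  }
  gel_raster(img, bit_depth_origin = depth)
}

#' Write a raster as a 16-bit grayscale TIFF
#'
#' Intensities must lie in `[0, 65535]`; they are rounded to integers, so a
#' write-then-read round trip is bit-identical for integer-valued rasters.
#'
#' @param r a [gel_raster()] or numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gel_tiff <- function(r, path) {
  m <- as_pixel_matrix(r)
  if (max(m) > 65535) {
    stop("intensities exceed the 16-bit range; rescale before writing",
         call. = FALSE)
  }
  tiff::writeTIFF(round(m) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Crop rectangle
#'
#' 0-based, half-open: the crop covers rows `top .. top+height-1` and
#' columns `left .. left+width-1`.
#'
#' @param top,left 0-based row/column of the upper-left corner.
#' @param height,width extent in pixels, both >= 1.
#' @export
crop_rect <- function(top, left, height, width) {
  v <- c(top = top, left = left, height = height, width = width)
  if (any(v != round(v))) stop("crop coordinates must be integers", call. = FALSE)
  storage.mode(v) <- "integer"
  if (v[["height"]] < 1L || v[["width"]] < 1L) {
    stop("crop height and width must be >= 1", call. = FALSE)
  }
  if (v[["top"]] < 0L || v[["left"]] < 0L) {
    stop("crop top/left must be >= 0", call. = FALSE)
  }
  structure(as.list(v), class = "crop_rect")
}

#' Crop a raster
#'
#' @param r a [gel_raster()] or numeric matrix.
#' @param rect a [crop_rect()].
#' @return The cropped [gel_raster()]; the input is unchanged.
#' @export
crop <- function(r, rect) {
  stopifnot(inherits(rect, "crop_rect"))
  m <- as_pixel_matrix(r)
  if (rect$top + rect$height > nrow(m) || rect$left + rect$width > ncol(m)) {
    stop(sprintf(
      "crop rect [%d,%d)x[%d,%d) exceeds raster %dx%d",
      rect$top, rect$top + rect$height, rect$left, rect$left + rect$width,
      nrow(m), ncol(m)), call. = FALSE)
  }
  out <- m[(rect$top + 1L):(rect$top + rect$height),
           (rect$left + 1L):(rect$left + rect$width), drop = FALSE]
  reraster(out, r)
}
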