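#' Raster image and bounding-box primitives
#'
#' Every stage of the pipeline operates on three light-weight S3 types:
#' a `raster_image` (an H x W x 3 integer array of 8-bit intensities with a
#' color-space tag), a binary mask (a plain logical H x W matrix aligned to
#' its image), and a `bbox` (an axis-aligned box in 0-based, half-open pixel
#' coordinates: the box `[x0, x1) x [y0, y1)` with x running along columns
#' and y along rows, origin at the top-left corner). This coordinate
#' convention is fixed package-wide; label exporters convert to each
#' dialect's own convention at the boundary.
#'
#' @name raster-primitives
NULL

#' Construct a raster image
#'
#' @param pixels numeric H x W x 3 array; values must lie in `[0, 255]`.
#'   Stored internally as integers (rounded half-even).
#' @param color_space `"RGB"` or `"CIELAB8"` (the 8-bit CIELAB encoding:
#'   L scaled to `[0,255]`, a and b offset by +128).
#' @return object of class `raster_image`
#' @export
raster_image <- function(pixels, color_space = c("RGB", "CIELAB8")) {
  color_space <- match.arg(color_space)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must have H >= 1 and W >= 1", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  px <- array(as.integer(round(pixels)), dim = dim(pixels))
  structure(list(pixels = px, color_space = color_space),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image %dx%d %s>\n", d[1], d[2], x$color_space))
  invisible(x)
}

#' @rdname raster-primitives
#' @param x a `raster_image`
#' @export
img_height <- function(x) dim(x$pixels)[1]

#' @rdname raster-primitives
#' @export
img_width <- function(x) dim(x$pixels)[2]

is_raster_image <- function(x) inherits(x, "raster_image")

stopifnot_rgb <- function(image, what = "image") {
  if (!is_raster_image(image)) {
    stop(what, " must be a raster_image", call. = FALSE)
  }
  if (image$color_space != "RGB") {
    stop(what, " must be in RGB color space, got ", image$color_space,
         call. = FALSE)
  }
  invisible(image)
}

stopifnot_mask_matches <- function(image, mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (!identical(dim(mask), dim(image$pixels)[1:2])) {
    stop("mask dimensions (", paste(dim(mask), collapse = "x"),
         ") do not match image (",
         paste(dim(image$pixels)[1:2], collapse = "x"), ")", call. = FALSE)
  }
  invisible(mask)
}

#' Construct a bounding box
#'
#' Boxes are 0-based and half-open: `[x0, x1) x [y0, y1)` in pixel units,
#' x along image columns, y along rows. Area is `(x1 - x0) * (y1 - y0)`.
#'
#' @param x0,y0,x1,y1 integer corner coordinates, `0 <= x0 < x1`,
#'   `0 <= y0 < y1`
#' @return object of class `bbox`
#' @export
bbox <- function(x0, y0, x1, y1) {
  v <- as.integer(c(x0, y0, x1, y1))
  if (anyNA(v)) stop("bbox coordinates must be integers", call. = FALSE)
  if (v[1] < 0L || v[2] < 0L || v[1] >= v[3] || v[2] >= v[4]) {
    stop(sprintf("invalid bbox (%d, %d, %d, %d): need 0 <= x0 < x1, 0 <= y0 < y1",
                 v[1], v[2], v[3], v[4]), call. = FALSE)
  }
  structure(list(x0 = v[1], y0 = v[2], x1 = v[3], y1 = v[4]), class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox (%d, %d, %d, %d)>\n", x$x0, x$y0, x$x1, x$y1))
  invisible(x)
}

#' @rdname bbox
#' @param box a `bbox`
#' @export
bbox_width <- function(box) box$x1 - box$x0

#' @rdname bbox
#' @export
bbox_height <- function(box) box$y1 - box$y0

#' @rdname bbox
#' @export
bbox_area <- function(box) (box$x1 - box$x0) * (box$y1 - box$y0)

# rows/cols of a box as 1-based index vectors into an array
bbox_rows <- function(box) (box$y0 + 1L):box$y1
bbox_cols <- function(box) (box$x0 + 1L):box$x1

#' Construct a plant cutout
#'
#' A masked single-plant image: the currency passed from segmentation into
#' compositing. The mask marks plant pixels; everything else is backdrop.
#'
#' @param image `raster_image` in RGB
#' @param mask logical matrix matching the image, at least one `TRUE` pixel
#' @param species class label (default `"plant"`)
#' @param source_id provenance string identifying the source image
#' @return object of class `plant_cutout`
#' @export
plant_cutout <- function(image, mask, species = "plant", source_id = "") {
  stopifnot_rgb(image, "cutout image")
  stopifnot_mask_matches(image, mask)
  if (!any(mask)) stop("cutout mask must contain at least one TRUE pixel",
                       call. = FALSE)
  structure(list(image = image, mask = mask,
                 species = as.character(species),
                 source_id = as.character(source_id)),
            class = "plant_cutout")
}

#' @export
print.plant_cutout <- function(x, ...) {
  cat(sprintf("<plant_cutout %dx%d species=%s pixels=%d>\n",
              img_height(x$image), img_width(x$image), x$species,
              sum(x$mask)))
  invisible(x)
}

# ---- image file I/O --------------------------------------------------------

#' Read an RGB image from a PNG file
#'
#' Grayscale files are expanded to 3 channels; an alpha channel is dropped.
#'
#' @param path file path
#' @return `raster_image` in RGB
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  raster_image(round(a * 255), "RGB")
}

#' Write a raster image to a PNG file
#'
#' @param image `raster_image` (RGB)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_image <- function(image, path) {
  stopifnot_rgb(image)
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Read a mask from a single-channel PNG (nonzero = TRUE)
#' @param path file path
#' @return logical matrix
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}

#' Write a mask as a single-channel PNG (0/255)
#' @param mask logical matrix
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# ---- seeded randomness -----------------------------------------------------

#' Derive a child seed from a master seed and counters
#'
#' A counter-based multiplicative-congruential fan-out (MINSTD constants,
#' modulus 2^31 - 1) so each pipeline element gets an independent,
#' reproducible stream: adding an element never perturbs the seeds of
#' earlier ones.
#'
#' @param seed master seed (integer)
#' @param ... one or more integer counters (e.g. scene index, plant index)
#' @return derived seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  s <- as.numeric(seed) %% m
  for (k in c(...)) {
    s <- (48271 * s + (as.numeric(k) %% m) + 1) %% m
    s <- (48271 * s) %% m
  }
  as.integer(s)
}

# run code under a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
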