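#' Single-plant composite formation
#'
#' A composite tile is a fixed-size (default 256 x 256) image holding one
#' rescaled plant cutout pasted at a random position over a soil background.
#' The plant's scale is the ratio of its longest side to the tile side and
#' is drawn uniformly from a configured range; random padding around the
#' rescaled plant gives the effect of random placement within the tile.
#'
#' @name compositing
NULL

#' Scale range for plant rescaling
#'
#' @param s_min,s_max minimum and maximum plant scale as a fraction of the
#'   tile side; `0 < s_min <= s_max <= 1`. Defaults 0.50 and 0.85.
#' @return list of class `scale_range`
#' @export
scale_range <- function(s_min = 0.50, s_max = 0.85) {
  if (!(s_min > 0 && s_min <= s_max && s_max <= 1)) {
    stop("need 0 < s_min <= s_max <= 1", call. = FALSE)
  }
  structure(list(s_min = s_min, s_max = s_max), class = "scale_range")
}

#' Plant scale of a cutout relative to the output tile
#'
#' The scale is the longest side of the single-plant image divided by the
#' output tile side: a 150 x 200 px plant in a 256 px tile has scale
#' 200/256 = 0.78 (to two decimals).
#'
#' @param plant_h,plant_w plant image dimensions in pixels
#' @param out_side output tile side in pixels
#' @return scale fraction
#' @export
compute_scale <- function(plant_h, plant_w, out_side) {
  if (plant_h <= 0 || plant_w <= 0 || out_side <= 0) {
    stop("dimensions must be positive", call. = FALSE)
  }
  max(plant_h, plant_w) / out_side
}

# resize an H x W x 3 integer pixel array; EBImage works width-major so we
# transpose in and out. filter "bilinear" for images, "none" (nearest) for masks.
resize_pixels <- function(px, new_h, new_w, filter) {
  im <- EBImage::Image(aperm(px / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(im, w = new_w, h = new_h, filter = filter)
  out <- aperm(EBImage::imageData(out), c(2, 1, 3))
  array(pmin(pmax(round(out * 255), 0), 255), dim = c(new_h, new_w, 3))
}

resize_mask <- function(mask, new_h, new_w) {
  im <- EBImage::Image(t(mask) * 1)
  out <- EBImage::resize(im, w = new_w, h = new_h, filter = "none")
  t(EBImage::imageData(out)) > 0.5
}

#' Rescale a plant cutout to a target scale
#'
#' The longest side of the result equals `round(target_scale * out_side)`;
#' the aspect ratio is preserved to within one pixel. The image is resampled
#' bilinearly, the mask with nearest-neighbor so it stays boolean.
#'
#' @param cutout a [plant_cutout()]
#' @param target_scale fraction in `(0, 1]`
#' @param out_side tile side in pixels
#' @return rescaled [plant_cutout()]
#' @export
rescale_cutout <- function(cutout, target_scale, out_side = 256L) {
  if (!(target_scale > 0 && target_scale <= 1)) {
    stop("target_scale must lie in (0, 1]", call. = FALSE)
  }
  h <- img_height(cutout$image)
  w <- img_width(cutout$image)
  new_long <- round(target_scale * out_side)
  if (new_long < 1) stop("degenerate scale: result smaller than 1 px",
                         call. = FALSE)
  if (h >= w) {
    new_h <- as.integer(new_long)
    new_w <- max(1L, as.integer(round(w * new_long / h)))
  } else {
    new_w <- as.integer(new_long)
    new_h <- max(1L, as.integer(round(h * new_long / w)))
  }
  img <- raster_image(resize_pixels(cutout$image$pixels, new_h, new_w,
                                    "bilinear"), "RGB")
  msk <- resize_mask(cutout$mask, new_h, new_w)
  if (!any(msk)) stop("rescaling removed every plant pixel", call. = FALSE)
  plant_cutout(img, msk, species = cutout$species,
               source_id = cutout$source_id)
}

#' Pad a cutout into a tile at a random position
#'
#' The plant is placed at a uniformly random feasible offset inside an
#' `out_side` x `out_side` tile padded with black pixels; random padding
#' gives the effect of random plant placement.
#'
#' @param cutout a [plant_cutout()] no larger than the tile
#' @param out_side tile side in pixels
#' @param seed integer seed making the placement reproducible
#' @return list with `image` (tile-sized `raster_image`), `mask`
#'   (tile-sized logical), and `box` (the cutout's extent as a [bbox()])
#' @export
pad_to_tile <- function(cutout, out_side = 256L, seed = 0L) {
  h <- img_height(cutout$image)
  w <- img_width(cutout$image)
  if (h > out_side || w > out_side) {
    stop("cutout does not fit in the tile", call. = FALSE)
  }
  off <- with_seed(seed, c(
    x = sample.int(out_side - w + 1L, 1L) - 1L,
    y = sample.int(out_side - h + 1L, 1L) - 1L
  ))
  px <- array(0L, dim = c(out_side, out_side, 3L))
  msk <- matrix(FALSE, out_side, out_side)
  rows <- (off[["y"]] + 1L):(off[["y"]] + h)
  cols <- (off[["x"]] + 1L):(off[["x"]] + w)
  px[rows, cols, ] <- cutout$image$pixels
  msk[rows, cols] <- cutout$mask
  list(image = raster_image(px, "RGB"), mask = msk,
       box = bbox(off[["x"]], off[["y"]], off[["x"]] + w, off[["y"]] + h))
}

#' Construct a composite tile
#'
#' @param image tile-sized `raster_image` (RGB)
#' @param mask tile-sized logical matrix, `TRUE` on plant pixels
#' @param plant_bbox the plant's [bbox()] within the tile
#' @param scale the drawn plant scale
#' @param background_id provenance string of the soil background
#' @return object of class `composite_tile`
#' @export
composite_tile <- function(image, mask, plant_bbox, scale, background_id = "") {
  stopifnot_rgb(image, "tile image")
  stopifnot_mask_matches(image, mask)
  if (img_height(image) != img_width(image)) {
    stop("composite tile must be square", call. = FALSE)
  }
  structure(list(image = image, mask = mask, plant_bbox = plant_bbox,
                 scale = scale, background_id = as.character(background_id)),
            class = "composite_tile")
}

#' @export
print.composite_tile <- function(x, ...) {
  cat(sprintf("<composite_tile %dpx scale=%.3f bg=%s>\n",
              img_height(x$image), x$scale, x$background_id))
  invisible(x)
}

#' Combine a plant cutout with a soil background into a composite tile
#'
#' Draws a scale uniformly from `range`, rescales the cutout, places it at
#' a random offset, and paints it over the background: composite pixels are
#' plant where the mask is true and soil elsewhere. Backgrounds larger than
#' the tile are randomly cropped (never resized) so soil texture keeps its
#' scale.
#'
#' @param cutout a [plant_cutout()]
#' @param background soil `raster_image`, at least `out_side` on both sides
#' @param range a [scale_range()]
#' @param out_side tile side in pixels (default 256)
#' @param seed integer seed; the same seed reproduces the tile bit-exactly
#' @param background_id provenance string recorded in the tile
#' @return a [composite_tile()]
#' @export
make_composite <- function(cutout, background, range = scale_range(),
                           out_side = 256L, seed = 0L, background_id = "") {
  stopifnot_rgb(background, "background")
  if (img_height(background) < out_side || img_width(background) < out_side) {
    stop("background smaller than the tile", call. = FALSE)
  }
  draws <- with_seed(seed, list(
    scale = stats::runif(1, range$s_min, range$s_max),
    bg_x = sample.int(img_width(background) - out_side + 1L, 1L) - 1L,
    bg_y = sample.int(img_height(background) - out_side + 1L, 1L) - 1L
  ))
  scaled <- rescale_cutout(cutout, draws$scale, out_side)
  placed <- pad_to_tile(scaled, out_side, seed = derive_seed(seed, 1L))
  bg <- crop_image(background,
                   bbox(draws$bg_x, draws$bg_y,
                        draws$bg_x + out_side, draws$bg_y + out_side))
  px <- bg$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    src <- placed$image$pixels[, , k]
    ch[placed$mask] <- src[placed$mask]
    px[, , k] <- ch
  }
  composite_tile(raster_image(px, "RGB"), placed$mask,
                 plant_bbox = tight_bbox(placed$mask, 0L),
                 scale = draws$scale, background_id = background_id)
}
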