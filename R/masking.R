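#' Chroma-key segmentation of blue-screen plant images
#'
#' Indoor plant photographs are taken against a blue keying backdrop, which
#' makes foreground extraction a thresholding problem: a pixel belongs to
#' the backdrop when its blue channel dominates both red and green by at
#' least a threshold. The plant mask is the complement. An optional
#' connected-component cleanup removes speckle below a minimum area.
#'
#' @param image `raster_image` in RGB
#' @param rule chroma rule from [chroma_rule()]
#' @return logical matrix, `TRUE` on plant (non-blue) pixels
#' @seealso [tight_bbox()], [apply_mask()]
#' @export
segment_bluescreen <- function(image, rule = chroma_rule()) {
  stopifnot_rgb(image)
  px <- image$pixels
  dominance <- px[, , 3] - pmax(px[, , 1], px[, , 2])
  mask <- dominance < rule$threshold
  if (rule$min_area > 0L && any(mask)) {
    mask <- drop_small_components(mask, rule$min_area)
  }
  mask
}

#' Chroma rule parameters
#'
#' @param threshold blue-dominance threshold in intensity levels: a pixel
#'   is classified backdrop when `B - max(R, G) >= threshold`. Default 30.
#' @param min_area connected components of plant pixels smaller than this
#'   (in px) are removed as speckle; 0 disables cleanup (the default, since
#'   noise-free sources need none).
#' @return list of class `chroma_rule`
#' @export
chroma_rule <- function(threshold = 30, min_area = 0L) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.numeric(min_area), min_area >= 0)
  structure(list(threshold = threshold, min_area = as.integer(min_area)),
            class = "chroma_rule")
}

drop_small_components <- function(mask, min_area) {
  lab <- EBImage::bwlabel(t(mask))  # EBImage works x-major
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  t(matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab)))
}

#' Tight bounding box of a mask
#'
#' Smallest half-open box containing every `TRUE` pixel, optionally grown
#' by a margin and clipped to the image grid.
#'
#' @param mask logical matrix with at least one `TRUE` pixel
#' @param margin non-negative integer margin in pixels (default 0)
#' @return a [bbox()]
#' @export
tight_bbox <- function(mask, margin = 0L) {
  if (!any(mask)) stop("cannot take the bounding box of an all-false mask",
                       call. = FALSE)
  stopifnot(margin >= 0)
  margin <- as.integer(margin)
  rows <- which(rowSums(mask) > 0L)
  cols <- which(colSums(mask) > 0L)
  bbox(max(0L, cols[1] - 1L - margin),
       max(0L, rows[1] - 1L - margin),
       min(ncol(mask), cols[length(cols)] + margin),
       min(nrow(mask), rows[length(rows)] + margin))
}

#' Replace unmasked pixels with a fill color
#'
#' Output equals the image where the mask is `TRUE` and the fill color
#' elsewhere; used to strip the blue screen from a cutout.
#'
#' @param image `raster_image`
#' @param mask logical matrix matching the image
#' @param fill length-3 vector of 8-bit values (default black)
#' @return `raster_image` in the same color space
#' @export
apply_mask <- function(image, mask, fill = c(0, 0, 0)) {
  stopifnot_mask_matches(image, mask)
  stopifnot(length(fill) == 3L, all(fill >= 0), all(fill <= 255))
  px <- image$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    ch[!mask] <- as.integer(round(fill[k]))
    px[, , k] <- ch
  }
  raster_image(px, image$color_space)
}

#' Crop an image (and optionally a mask) to a bounding box
#'
#' @param image `raster_image`
#' @param box a [bbox()] inside the image bounds
#' @return `raster_image` of size `bbox_height(box)` x `bbox_width(box)`
#' @export
crop_image <- function(image, box) {
  if (box$x1 > img_width(image) || box$y1 > img_height(image)) {
    stop("bbox exceeds image bounds", call. = FALSE)
  }
  raster_image(image$pixels[bbox_rows(box), bbox_cols(box), , drop = FALSE],
               image$color_space)
}

#' @rdname crop_image
#' @param mask logical matrix
#' @export
crop_mask <- function(mask, box) {
  if (box$x1 > ncol(mask) || box$y1 > nrow(mask)) {
    stop("bbox exceeds mask bounds", call. = FALSE)
  }
  mask[bbox_rows(box), bbox_cols(box), drop = FALSE]
}

#' Extract a tightly-cropped plant cutout from a blue-screen image
#'
#' Convenience wrapper: segment, take the tight box, crop image and mask.
#'
#' @inheritParams segment_bluescreen
#' @param margin margin passed to [tight_bbox()]
#' @param species,source_id provenance for the resulting [plant_cutout()]
#' @return a [plant_cutout()]
#' @export
extract_cutout <- function(image, rule = chroma_rule(), margin = 0L,
                           species = "plant", source_id = "") {
  mask <- segment_bluescreen(image, rule)
  if (!any(mask)) stop("no plant pixels found in image", call. = FALSE)
  box <- tight_bbox(mask, margin)
  plant_cutout(crop_image(image, box), crop_mask(mask, box),
               species = species, source_id = source_id)
}
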