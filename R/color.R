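#' Color correction in 8-bit CIELAB and RGB offset correction
#'
#' Two corrections keep synthetic composites visually consistent. Before
#' translation, plant pixels are shifted in CIELAB so their per-channel
#' means match fixed targets chosen to resemble field-grown plants
#' (enhanced lightness, greenness, and yellowness); unmasked pixels are
#' untouched. After translation, the whole tile is shifted per RGB channel
#' by the mean difference to the pre-translation composite over the region
#' outside the plant's bounding box, so the pasted tile's soil blends with
#' the surrounding field image.
#'
#' The CIELAB encoding here is the common 8-bit convention (`CIELAB8`):
#' L scaled from `[0, 100]` to `[0, 255]`, a and b offset by +128. Under
#' it, green plant pixels have a below 128 and yellowish pixels b above.
#' Conversions assume sRGB with the D65 white point.
#'
#' @name color-correction
NULL

#' Target CIELAB8 channel means for plant color correction
#'
#' Defaults (L = 170, a = 100, b = 160) give plants the lightness,
#' greenness and yellowness typical of field imagery.
#'
#' @param L,A,B target channel means in `[0, 255]`
#' @return list of class `color_targets`
#' @export
color_targets <- function(L = 170, A = 100, B = 160) {
  v <- c(L, A, B)
  if (any(v < 0) || any(v > 255)) stop("targets must lie in [0, 255]",
                                       call. = FALSE)
  structure(list(L = L, A = A, B = B), class = "color_targets")
}

#' Convert between RGB and the 8-bit CIELAB encoding
#'
#' @param image `raster_image` in RGB (`rgb_to_lab8`) or CIELAB8
#'   (`lab8_to_rgb`)
#' @return `raster_image` in the other space
#' @export
rgb_to_lab8 <- function(image) {
  stopifnot_rgb(image)
  d <- dim(image$pixels)
  flat <- matrix(as.numeric(image$pixels), ncol = 3L) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  lab8 <- cbind(lab[, 1] * 255 / 100, lab[, 2] + 128, lab[, 3] + 128)
  lab8 <- pmin(pmax(round(lab8), 0), 255)
  raster_image(array(lab8, dim = d), "CIELAB8")
}

#' @rdname rgb_to_lab8
#' @export
lab8_to_rgb <- function(image) {
  if (image$color_space != "CIELAB8") {
    stop("image must be in CIELAB8", call. = FALSE)
  }
  d <- dim(image$pixels)
  flat <- matrix(as.numeric(image$pixels), ncol = 3L)
  lab <- cbind(flat[, 1] * 100 / 255, flat[, 2] - 128, flat[, 3] - 128)
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  raster_image(array(pmin(pmax(round(srgb * 255), 0), 255), dim = d), "RGB")
}

#' Mean of one channel over the true pixels of a mask
#'
#' The mask-weighted average of channel `k`: the sum of channel values at
#' true-mask pixels divided by the number of true pixels.
#'
#' @param image `raster_image`
#' @param mask logical matrix with at least one `TRUE` pixel
#' @param k channel index (1..3)
#' @return the masked mean as a double
#' @export
masked_channel_mean <- function(image, mask, k) {
  stopifnot_mask_matches(image, mask)
  stopifnot(k %in% 1:3)
  if (!any(mask)) stop("mask has no TRUE pixels: masked mean is undefined",
                       call. = FALSE)
  mean(image$pixels[, , k][mask])
}

#' Shift plant pixels so their CIELAB8 channel means hit the targets
#'
#' Each channel of every masked pixel is shifted by the constant
#' `target - masked mean`, rounded half-even and clamped to `[0, 255]`.
#' Unmasked pixels are returned bit-identical.
#'
#' @param image `raster_image` in CIELAB8
#' @param mask logical matrix, at least one `TRUE` pixel
#' @param targets a [color_targets()]
#' @return corrected `raster_image` in CIELAB8
#' @export
correct_plant_color <- function(image, mask, targets = color_targets()) {
  if (image$color_space != "CIELAB8") {
    stop("correct_plant_color expects a CIELAB8 image", call. = FALSE)
  }
  stopifnot_mask_matches(image, mask)
  if (!any(mask)) stop("mask has no TRUE pixels", call. = FALSE)
  tgt <- c(targets$L, targets$A, targets$B)
  px <- image$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    offset <- tgt[k] - mean(ch[mask])
    ch[mask] <- pmin(pmax(as.integer(round(ch[mask] + offset)), 0L), 255L)
    px[, , k] <- ch
  }
  raster_image(px, "CIELAB8")
}

#' Complement mask of a bounding box
#'
#' False inside the box, true everywhere else: the region used to measure
#' background offsets.
#'
#' @param h,w mask dimensions
#' @param box a [bbox()] within the `h` x `w` grid
#' @return logical matrix
#' @export
exterior_mask <- function(h, w, box) {
  if (box$x1 > w || box$y1 > h) stop("bbox exceeds the grid", call. = FALSE)
  m <- matrix(TRUE, h, w)
  m[bbox_rows(box), bbox_cols(box)] <- FALSE
  m
}

#' Shrink an exterior mask to a band of given width around the box
#'
#' Variant region for background-offset estimation: only pixels within
#' `band` px (Chebyshev distance) of the box are kept.
#'
#' @inheritParams exterior_mask
#' @param band band width in pixels
#' @return logical matrix
#' @export
exterior_band_mask <- function(h, w, box, band) {
  stopifnot(band >= 1)
  outer_box <- bbox(max(0L, box$x0 - band), max(0L, box$y0 - band),
                    min(w, box$x1 + band), min(h, box$y1 + band))
  m <- matrix(FALSE, h, w)
  m[bbox_rows(outer_box), bbox_cols(outer_box)] <- TRUE
  m[bbox_rows(box), bbox_cols(box)] <- FALSE
  m
}

#' Per-channel background offsets between composite and translated images
#'
#' `d_k` is the mean of `composite - translated` for channel `k` over the
#' region (normally the plant bbox exterior). Adding `d_k` back to the
#' translated image matches its background statistics to the composite's.
#'
#' @param composite,translated same-size `raster_image`s in RGB
#' @param region logical matrix with at least one `TRUE` pixel
#' @return list of class `channel_offsets` with field `d` (length-3 double)
#' @export
background_offsets <- function(composite, translated, region) {
  stopifnot_rgb(composite, "composite")
  stopifnot_rgb(translated, "translated")
  if (!identical(dim(composite$pixels), dim(translated$pixels))) {
    stop("composite and translated images differ in shape", call. = FALSE)
  }
  stopifnot_mask_matches(composite, region)
  if (!any(region)) stop("region has no TRUE pixels", call. = FALSE)
  d <- vapply(1:3, function(k) {
    mean(composite$pixels[, , k][region] - translated$pixels[, , k][region])
  }, numeric(1))
  structure(list(d = d), class = "channel_offsets")
}

#' Apply uniform per-channel offsets to an image
#'
#' Every pixel of channel `k` is shifted by `d_k`, rounded half-even and
#' clamped to `[0, 255]`.
#'
#' @param translated `raster_image` in RGB
#' @param offsets a `channel_offsets` from [background_offsets()]
#' @return corrected `raster_image`
#' @export
correct_background <- function(translated, offsets) {
  stopifnot_rgb(translated, "translated")
  if (!all(is.finite(offsets$d))) stop("offsets must be finite", call. = FALSE)
  px <- translated$pixels
  for (k in 1:3) {
    px[, , k] <- pmin(pmax(round(px[, , k] + offsets$d[k]), 0), 255)
  }
  raster_image(px, "RGB")
}
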