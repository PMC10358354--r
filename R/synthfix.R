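#' Procedural fixtures: blue-screen plants, soil textures, detection sets
#'
#' Every stage of the pipeline can be exercised without external imagery.
#' The fixture generator paints rosettes of elliptical "leaves" on a
#' uniform reference-blue backdrop and records exactly which pixels it
#' painted, giving a noise-free ground-truth mask that the chroma rule
#' must recover exactly. Soil textures are low-frequency correlated noise
#' around a base brown with optional speckle, constructed so that no soil
#' pixel is ever blue-dominant. Detection scenarios jitter, drop, and
#' spuriously augment ground-truth boxes at stated rates to exercise the
#' evaluation metrics end to end. All fixtures are bit-reproducible from
#' their style and seed.
#'
#' @name fixtures
NULL

#' Reference blue of the synthetic keying backdrop
#'
#' Chosen so that the blue channel dominates red and green by far more
#' than the default chroma threshold, while resembling keying fabric.
#'
#' @return integer RGB triple `(40, 60, 200)`
#' @export
reference_blue <- function() c(40L, 60L, 200L)

#' Style of a synthetic blue-screen plant
#'
#' @param n_leaves number of elliptical leaves (>= 1)
#' @param leaf_eccentricity leaf elongation in `[0, 0.9]`: the semi-minor
#'   axis is `(1 - e)` times the semi-major
#' @param base_green leaf color as a CIELAB8 triple; the default
#'   `(120, 110, 150)` is a mid-dark green, so correction toward the
#'   standard targets produces a visible lightening/yellowing shift
#' @param hue_jitter per-leaf uniform CIELAB8 channel jitter (levels)
#' @param size_px image side in px (>= 16)
#' @param noise per-pixel gaussian intensity noise sd applied to the whole
#'   image (0 = noise-free; mask exactness holds only at 0)
#' @param seed integer seed
#' @return list of class `plant_style`
#' @export
plant_style <- function(n_leaves = 7L, leaf_eccentricity = 0.5,
                        base_green = c(120, 110, 150), hue_jitter = 8,
                        size_px = 128L, noise = 0, seed = 0L) {
  stopifnot(n_leaves >= 1L, size_px >= 16L, leaf_eccentricity >= 0,
            leaf_eccentricity <= 0.9, hue_jitter >= 0, noise >= 0,
            length(base_green) == 3L)
  structure(list(n_leaves = as.integer(n_leaves),
                 leaf_eccentricity = leaf_eccentricity,
                 base_green = base_green, hue_jitter = hue_jitter,
                 size_px = as.integer(size_px), noise = noise,
                 seed = as.integer(seed)),
            class = "plant_style")
}

lab8_triple_to_rgb <- function(lab8) {
  lab <- matrix(c(lab8[1] * 100 / 255, lab8[2] - 128, lab8[3] - 128),
                nrow = 1L)
  pmin(pmax(round(grDevices::convertColor(lab, from = "Lab",
                                          to = "sRGB") * 255), 0), 255)
}

#' Generate a blue-screen plant image and its ground-truth mask
#'
#' Paints `n_leaves` rotated ellipses radiating from the image center onto
#' a uniform reference-blue backdrop. The returned mask marks exactly the
#' painted pixels. Leaf semi-major axis is fixed at 0.24 of the image side
#' (the rosette then always fits inside the frame), so a single leaf's
#' area follows the analytic ellipse formula; only leaf angles and colors
#' are randomized.
#'
#' @param style a [plant_style()]
#' @return list with `image` (`raster_image` RGB) and `mask` (logical)
#' @export
gen_plant <- function(style) {
  S <- style$size_px
  a <- 0.24 * S
  b <- max(2, a * (1 - style$leaf_eccentricity))
  blue <- reference_blue()
  px <- array(0L, dim = c(S, S, 3L))
  for (k in 1:3) px[, , k] <- blue[k]
  mask <- matrix(FALSE, S, S)
  cx <- S / 2
  cy <- S / 2
  grid_x <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)  # col coord
  grid_y <- matrix(rep(seq_len(S) - 0.5, times = S), S, S) # row coord
  with_seed(style$seed, {
    base_angle <- stats::runif(1, 0, 2 * pi)
    for (i in seq_len(style$n_leaves)) {
      theta <- base_angle + 2 * pi * (i - 1) / style$n_leaves +
        stats::runif(1, -0.2, 0.2) * 2 * pi / style$n_leaves
      ecx <- cx + 0.95 * a * cos(theta)
      ecy <- cy + 0.95 * a * sin(theta)
      dx <- grid_x - ecx
      dy <- grid_y - ecy
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      inside <- (u / a)^2 + (v / b)^2 <= 1
      lab8 <- style$base_green +
        stats::runif(3, -style$hue_jitter, style$hue_jitter)
      rgb <- lab8_triple_to_rgb(pmin(pmax(lab8, 0), 255))
      # keep leaves chroma-separable whatever the jitter drew
      rgb[3] <- min(rgb[3], max(rgb[1], rgb[2]))
      for (k in 1:3) {
        ch <- px[, , k]
        ch[inside] <- rgb[k]
        px[, , k] <- ch
      }
      mask <- mask | inside
    }
    if (style$noise > 0) {
      px <- px + array(round(stats::rnorm(length(px), 0, style$noise)),
                       dim = dim(px))
      px <- pmin(pmax(px, 0), 255)
    }
  })
  list(image = raster_image(px, "RGB"), mask = mask)
}

#' Style of a synthetic soil texture
#'
#' @param base_brown mean soil color, RGB triple (default `(120, 85, 60)`)
#' @param roughness amplitude of the low-frequency color variation, in
#'   `[0, 1]` (1 corresponds to a +-50 level swing)
#' @param speckle_density fraction of pixels receiving a bright/dark
#'   speckle, in `[0, 1]`
#' @param seed integer seed
#' @return list of class `soil_style`
#' @export
soil_style <- function(base_brown = c(120, 85, 60), roughness = 0.4,
                       speckle_density = 0.01, seed = 0L) {
  stopifnot(length(base_brown) == 3L, roughness >= 0, roughness <= 1,
            speckle_density >= 0, speckle_density <= 1)
  structure(list(base_brown = base_brown, roughness = roughness,
                 speckle_density = speckle_density,
                 seed = as.integer(seed)),
            class = "soil_style")
}

#' Generate a soil texture image
#'
#' Correlated low-frequency noise (a coarse gaussian grid, bilinearly
#' upsampled, shared across channels) around the base brown, plus random
#' bright/dark speckles. A final guard clamps the blue channel below
#' `max(R, G)` so no soil pixel can ever trip the blue-dominance chroma
#' rule.
#'
#' @param style a [soil_style()]
#' @param h,w output dimensions in px
#' @return `raster_image` in RGB
#' @export
gen_soil <- function(style, h, w) {
  stopifnot(h >= 1L, w >= 1L)
  base <- style$base_brown
  px <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) px[, , k] <- base[k]
  with_seed(style$seed, {
    if (style$roughness > 0) {
      gh <- max(2L, ceiling(h / 16))
      gw <- max(2L, ceiling(w / 16))
      coarse <- matrix(stats::rnorm(gh * gw, 0, 50 * style$roughness),
                       gh, gw)
      coarse3 <- array(128 + pmin(pmax(coarse, -100), 100),
                       dim = c(gh, gw, 3L))
      field <- resize_pixels(pmin(pmax(coarse3, 0), 255), h, w,
                             "bilinear")[, , 1] - 128
      for (k in 1:3) {
        px[, , k] <- px[, , k] + field * c(1, 0.85, 0.7)[k]
      }
    }
    if (style$speckle_density > 0) {
      n_spk <- round(h * w * style$speckle_density)
      if (n_spk > 0) {
        idx <- sample.int(h * w, n_spk)
        amp <- stats::runif(n_spk, -45, 45)
        for (k in 1:3) {
          ch <- px[, , k]
          ch[idx] <- ch[idx] + amp
          px[, , k] <- ch
        }
      }
    }
  })
  px <- pmin(pmax(round(px), 0), 255)
  # blue-dominance guard: soil must never classify as backdrop
  px[, , 3] <- pmin(px[, , 3], pmax(px[, , 1], px[, , 2]))
  raster_image(px, "RGB")
}

#' Generate pools of fixture cutouts and soils
#'
#' Convenience builder used by tests, the command-line tools, and
#' examples: `n_cutouts` plants with sizes varied across a range (so
#' composites exercise the scale logic) and `n_soils` full-scale soil
#' images.
#'
#' @param n_cutouts,n_soils pool sizes
#' @param soil_h,soil_w soil image dimensions
#' @param seed master seed
#' @param species species labels cycled over the cutouts
#' @return list with `cutouts` (list of [plant_cutout()]) and `soils`
#'   (named list of `raster_image`s)
#' @export
gen_fixture_pools <- function(n_cutouts = 8L, n_soils = 2L,
                              soil_h = 1024L, soil_w = 1024L, seed = 0L,
                              species = c("canola", "oat", "soybean",
                                          "wheat")) {
  cutouts <- lapply(seq_len(n_cutouts), function(i) {
    s <- derive_seed(seed, 10L, i)
    size <- c(96L, 128L, 160L, 192L)[(i - 1L) %% 4L + 1L]
    st <- plant_style(n_leaves = 5L + (i %% 4L), size_px = size, seed = s)
    pl <- gen_plant(st)
    box <- tight_bbox(pl$mask, 0L)
    plant_cutout(crop_image(pl$image, box), crop_mask(pl$mask, box),
                 species = species[(i - 1L) %% length(species) + 1L],
                 source_id = sprintf("fixture_plant_%03d", i))
  })
  soils <- lapply(seq_len(n_soils), function(j) {
    gen_soil(soil_style(seed = derive_seed(seed, 20L, j)), soil_h, soil_w)
  })
  names(soils) <- sprintf("fixture_soil_%03d", seq_len(n_soils))
  list(cutouts = cutouts, soils = soils)
}

#' Generate a synthetic detection scenario
#'
#' Ground-truth boxes are drawn at random positions and sizes; predictions
#' are derived by jittering corners with gaussian noise, dropping each
#' ground truth with probability `drop_rate` (false negatives), and adding
#' spurious low-confidence boxes at `spurious_rate` per ground truth
#' (false positives). Prediction confidence decreases with the realized
#' jitter magnitude, emulating a detector that is less sure about its
#' worse localizations.
#'
#' @param n_gt number of ground-truth boxes
#' @param jitter_sd corner jitter standard deviation in px
#' @param drop_rate probability a ground truth has no prediction
#' @param spurious_rate expected spurious predictions per ground truth
#' @param canvas canvas side in px
#' @param seed integer seed
#' @return list with `gts` (list of [bbox()]) and `preds` (list of
#'   [detection()])
#' @export
gen_detection_scenario <- function(n_gt, jitter_sd = 0, drop_rate = 0,
                                   spurious_rate = 0, canvas = 320L,
                                   seed = 0L) {
  stopifnot(n_gt >= 0L, jitter_sd >= 0, drop_rate >= 0, drop_rate <= 1,
            spurious_rate >= 0)
  with_seed(seed, {
    gts <- lapply(seq_len(n_gt), function(i) {
      w <- sample(20:60, 1L)
      h <- sample(20:60, 1L)
      x0 <- sample.int(canvas - w, 1L) - 1L
      y0 <- sample.int(canvas - h, 1L) - 1L
      bbox(x0, y0, x0 + w, y0 + h)
    })
    preds <- list()
    for (i in seq_len(n_gt)) {
      if (stats::runif(1) < drop_rate) next
      g <- gts[[i]]
      j <- if (jitter_sd > 0) round(stats::rnorm(4, 0, jitter_sd)) else
        rep(0, 4)
      x0 <- max(0, g$x0 + j[1]); y0 <- max(0, g$y0 + j[2])
      x1 <- min(canvas, g$x1 + j[3]); y1 <- min(canvas, g$y1 + j[4])
      if (x1 <= x0) x1 <- x0 + 1
      if (y1 <= y0) y1 <- y0 + 1
      conf <- min(1, max(0.05,
        0.95 - 0.05 * mean(abs(j)) + stats::runif(1, -0.02, 0.02)))
      preds[[length(preds) + 1L]] <- detection(bbox(x0, y0, x1, y1), conf)
    }
    n_spur <- if (spurious_rate > 0 && n_gt > 0)
      stats::rbinom(1L, n_gt, min(1, spurious_rate)) else 0L
    for (i in seq_len(n_spur)) {
      w <- sample(20:60, 1L)
      h <- sample(20:60, 1L)
      x0 <- sample.int(canvas - w, 1L) - 1L
      y0 <- sample.int(canvas - h, 1L) - 1L
      preds[[length(preds) + 1L]] <- detection(
        bbox(x0, y0, x0 + w, y0 + h), stats::runif(1, 0.05, 0.4))
    }
    list(gts = gts, preds = preds)
  })
}
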