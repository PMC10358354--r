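#' Multi-plant scene assembly with automatic labels
#'
#' A labeled scene is built over a full-scale soil image: for each plant a
#' sub-window of the soil is cropped as the composite background, a cutout
#' is composited onto it, optionally color-corrected, passed through the
#' translator, background-corrected against the pre-translation composite,
#' and the window is replaced by the result. The pasted plant's bounding
#' box (in scene coordinates) and class become a ground-truth label, so the
#' dataset is labeled by construction. Placement is either random
#' non-overlapping or row-aligned. Everything is a pure function of the
#' scene spec's seed.
#'
#' @name scene-assembly
NULL

#' Specification of one synthetic scene
#'
#' @param n_plants number of plants to place (>= 1)
#' @param seed master seed; per-plant seeds are derived by counter so the
#'   first k plants are identical across specs differing only in
#'   `n_plants`
#' @param soil_id name of the soil image in the soil pool (`NULL` = pick
#'   one at random)
#' @param placement `"random"` (rejection-sampled non-overlapping tiles)
#'   or `"rows"` (evenly spaced grid sites)
#' @param rows number of rows when `placement = "rows"`
#' @param jitter per-site uniform perturbation in px (rows mode)
#' @param range a [scale_range()]
#' @param species_filter optional character vector restricting the cutout
#'   pool
#' @param color_correct apply plant color correction before translation?
#' @param single_class collapse all species into one `"plant"` class?
#' @param tile_side composite tile side in px (default 256)
#' @param max_attempts rejection-sampling budget per plant (random mode)
#' @return list of class `scene_spec`
#' @export
scene_spec <- function(n_plants, seed, soil_id = NULL,
                       placement = c("random", "rows"), rows = 1L,
                       jitter = 0L, range = scale_range(),
                       species_filter = NULL, color_correct = TRUE,
                       single_class = TRUE, tile_side = 256L,
                       max_attempts = 100L) {
  placement <- match.arg(placement)
  stopifnot(n_plants >= 1L, rows >= 1L, jitter >= 0L, tile_side >= 1L,
            max_attempts >= 1L)
  structure(list(n_plants = as.integer(n_plants), seed = as.integer(seed),
                 soil_id = soil_id, placement = placement,
                 rows = as.integer(rows), jitter = as.integer(jitter),
                 range = range, species_filter = species_filter,
                 color_correct = isTRUE(color_correct),
                 single_class = isTRUE(single_class),
                 tile_side = as.integer(tile_side),
                 max_attempts = as.integer(max_attempts)),
            class = "scene_spec")
}

#' Random sub-window of a soil image
#'
#' @param soil `raster_image`, at least `side` on both dimensions
#' @param side window side in px
#' @param seed integer seed
#' @return list with `window` (`raster_image`) and `box` (its location in
#'   the soil image)
#' @export
sample_background_window <- function(soil, side, seed = 0L) {
  if (img_height(soil) < side || img_width(soil) < side) {
    stop("soil image smaller than the requested window", call. = FALSE)
  }
  off <- with_seed(seed, c(
    x = sample.int(img_width(soil) - side + 1L, 1L) - 1L,
    y = sample.int(img_height(soil) - side + 1L, 1L) - 1L
  ))
  box <- bbox(off[["x"]], off[["y"]], off[["x"]] + side, off[["y"]] + side)
  list(window = crop_image(soil, box), box = box)
}

boxes_disjoint <- function(a, b) {
  min(a$x1, b$x1) <= max(a$x0, b$x0) || min(a$y1, b$y1) <= max(a$y0, b$y0)
}

#' Place a tile-sized box avoiding overlap with existing boxes
#'
#' Rejection sampling: uniformly random in-bounds positions are drawn
#' until one has zero-area intersection with every existing box.
#'
#' @param existing list of [bbox()]s already placed
#' @param tile_side tile side in px
#' @param canvas_h,canvas_w canvas dimensions
#' @param seed integer seed
#' @param max_attempts attempts before giving up
#' @return a [bbox()]
#' @export
place_nonoverlap <- function(existing, tile_side, canvas_h, canvas_w,
                             seed = 0L, max_attempts = 100L) {
  if (tile_side > canvas_h || tile_side > canvas_w) {
    stop("tile does not fit in the canvas", call. = FALSE)
  }
  found <- with_seed(seed, {
    hit <- NULL
    for (i in seq_len(max_attempts)) {
      x0 <- sample.int(canvas_w - tile_side + 1L, 1L) - 1L
      y0 <- sample.int(canvas_h - tile_side + 1L, 1L) - 1L
      cand <- bbox(x0, y0, x0 + tile_side, y0 + tile_side)
      if (all(vapply(existing, boxes_disjoint, logical(1), b = cand))) {
        hit <- cand
        break
      }
    }
    hit
  })
  if (is.null(found)) {
    stop("placement failed after ", max_attempts,
         " attempts; reduce n_plants or enlarge the canvas", call. = FALSE)
  }
  found
}

#' Row-aligned tile sites
#'
#' Sites are centered in an even grid of `rows` x `ceil(n/rows)` cells,
#' filled row-major, each perturbed by at most `jitter` px. For jitter
#' below the inter-site gap the sites cannot overlap.
#'
#' @param n_plants number of sites
#' @param rows number of rows
#' @param tile_side tile side in px
#' @param canvas_h,canvas_w canvas dimensions
#' @param jitter max uniform perturbation in px
#' @param seed integer seed
#' @return list of [bbox()]s, row-major order
#' @export
place_rows <- function(n_plants, rows, tile_side, canvas_h, canvas_w,
                       jitter = 0L, seed = 0L) {
  n_cols <- ceiling(n_plants / rows)
  cell_w <- canvas_w / n_cols
  cell_h <- canvas_h / rows
  if (cell_w < tile_side || cell_h < tile_side) {
    stop(sprintf("a %dx%d grid of %dpx tiles does not fit a %dx%d canvas",
                 rows, n_cols, tile_side, canvas_h, canvas_w),
         call. = FALSE)
  }
  with_seed(seed, {
    boxes <- vector("list", n_plants)
    for (i in seq_len(n_plants)) {
      r <- (i - 1L) %/% n_cols
      cc <- (i - 1L) %% n_cols
      x0 <- floor(cc * cell_w + (cell_w - tile_side) / 2)
      y0 <- floor(r * cell_h + (cell_h - tile_side) / 2)
      if (jitter > 0L) {
        x0 <- x0 + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
        y0 <- y0 + sample.int(2L * jitter + 1L, 1L) - jitter - 1L
      }
      x0 <- min(max(x0, 0L), canvas_w - tile_side)
      y0 <- min(max(y0, 0L), canvas_h - tile_side)
      boxes[[i]] <- bbox(x0, y0, x0 + tile_side, y0 + tile_side)
    }
    boxes
  })
}

# color-correct only the plant pixels of a composite tile, leaving the
# background bit-identical in RGB (the CIELAB round trip is confined to
# masked pixels)
color_correct_tile <- function(tile, targets) {
  lab <- rgb_to_lab8(tile$image)
  corrected <- correct_plant_color(lab, tile$mask, targets)
  out <- lab8_to_rgb(corrected)
  px <- tile$image$pixels
  for (k in 1:3) {
    ch <- px[, , k]
    src <- out$pixels[, , k]
    ch[tile$mask] <- src[tile$mask]
    px[, , k] <- ch
  }
  tile$image <- raster_image(px, "RGB")
  tile
}

#' Assemble one labeled multi-plant scene
#'
#' Runs, per plant: cutout selection, soil-window sampling, composite
#' formation, optional plant color correction, translation, background
#' offset correction, and rectangular window replacement into the canvas.
#' The result carries one label per plant and full per-plant provenance
#' (cutout id, tile box, scale, and the tile-local plant mask).
#'
#' @param spec a [scene_spec()]
#' @param cutout_pool non-empty list of [plant_cutout()]s
#' @param soil_pool non-empty named list of full-scale soil
#'   `raster_image`s
#' @param tr a [translator()] (default identity)
#' @param targets [color_targets()] for plant color correction
#' @return list of class `labeled_scene`: `image`, `labels` (list of
#'   `list(box, class)`), `provenance`
#' @export
build_scene <- function(spec, cutout_pool, soil_pool,
                        tr = identity_translator(),
                        targets = color_targets()) {
  if (length(cutout_pool) == 0L) stop("empty cutout pool", call. = FALSE)
  if (length(soil_pool) == 0L) stop("empty soil pool", call. = FALSE)
  if (!is.null(spec$species_filter)) {
    keep <- vapply(cutout_pool, function(co) co$species %in%
                     spec$species_filter, logical(1))
    cutout_pool <- cutout_pool[keep]
    if (length(cutout_pool) == 0L) {
      stop("species filter leaves an empty cutout pool", call. = FALSE)
    }
  }
  soil_id <- spec$soil_id
  if (is.null(soil_id)) {
    idx <- with_seed(derive_seed(spec$seed, 0L),
                     sample.int(length(soil_pool), 1L))
    soil_id <- if (!is.null(names(soil_pool))) names(soil_pool)[idx] else
      as.character(idx)
    soil <- soil_pool[[idx]]
  } else {
    soil <- soil_pool[[soil_id]]
    if (is.null(soil)) stop("soil_id '", soil_id, "' not in the pool",
                            call. = FALSE)
  }
  H <- img_height(soil)
  W <- img_width(soil)
  side <- spec$tile_side

  row_boxes <- if (spec$placement == "rows") {
    place_rows(spec$n_plants, spec$rows, side, H, W, spec$jitter,
               seed = derive_seed(spec$seed, 999L))
  }

  canvas <- soil$pixels
  labels <- vector("list", spec$n_plants)
  provenance <- vector("list", spec$n_plants)
  placed <- list()
  for (i in seq_len(spec$n_plants)) {
    s <- derive_seed(spec$seed, i)
    cut_idx <- with_seed(derive_seed(s, 1L),
                         sample.int(length(cutout_pool), 1L))
    cutout <- cutout_pool[[cut_idx]]
    box <- if (spec$placement == "rows") row_boxes[[i]] else
      place_nonoverlap(placed, side, H, W, seed = derive_seed(s, 2L),
                       max_attempts = spec$max_attempts)
    placed[[length(placed) + 1L]] <- box
    window <- raster_image(canvas[bbox_rows(box), bbox_cols(box), ,
                                  drop = FALSE], "RGB")
    tile <- make_composite(cutout, window, spec$range, side,
                           seed = derive_seed(s, 3L),
                           background_id = soil_id)
    if (spec$color_correct) tile <- color_correct_tile(tile, targets)
    translated <- translate_tile(tr, tile$image)
    region <- exterior_mask(side, side, tile$plant_bbox)
    offs <- background_offsets(tile$image, translated, region)
    corrected <- correct_background(translated, offs)
    canvas[bbox_rows(box), bbox_cols(box), ] <- corrected$pixels
    pb <- tile$plant_bbox
    labels[[i]] <- list(
      box = bbox(box$x0 + pb$x0, box$y0 + pb$y0,
                 box$x0 + pb$x1, box$y0 + pb$y1),
      class = if (spec$single_class) "plant" else cutout$species
    )
    provenance[[i]] <- list(cutout_id = cutout$source_id,
                            species = cutout$species, tile_box = box,
                            scale = tile$scale, mask = tile$mask,
                            offsets = offs$d)
  }
  structure(list(image = raster_image(canvas, "RGB"), labels = labels,
                 provenance = provenance, soil_id = soil_id,
                 spec = spec),
            class = "labeled_scene")
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat(sprintf("<labeled_scene %dx%d, %d labels>\n", img_height(x$image),
              img_width(x$image), length(x$labels)))
  invisible(x)
}

# ---- label export / import -------------------------------------------------

#' Export scene labels
#'
#' Dialects: `"yolo"` writes one line per object, `class_id cx cy w h`,
#' centers and sizes normalized by the image dimensions, fixed 6 decimals;
#' `"voc-xml"` writes Pascal VOC XML with 1-based inclusive corners;
#' `"csv"` writes 0-based half-open corners.
#'
#' @param scene a `labeled_scene`
#' @param path output file path
#' @param dialect `"yolo"`, `"voc-xml"` or `"csv"`
#' @param classes class vocabulary defining YOLO class ids (default: the
#'   sorted unique classes present)
#' @return `path`, invisibly
#' @export
export_labels <- function(scene, path, dialect = c("yolo", "voc-xml", "csv"),
                          classes = NULL) {
  dialect <- match.arg(dialect)
  w <- img_width(scene$image)
  h <- img_height(scene$image)
  cls <- vapply(scene$labels, function(l) l$class, character(1))
  if (is.null(classes)) classes <- sort(unique(cls))
  boxes <- lapply(scene$labels, function(l) l$box)
  switch(dialect,
    yolo = {
      lines <- character(length(boxes))
      for (i in seq_along(boxes)) {
        b <- boxes[[i]]
        id <- match(cls[i], classes) - 1L
        if (is.na(id)) stop("class '", cls[i], "' not in vocabulary",
                            call. = FALSE)
        lines[i] <- sprintf("%d %.6f %.6f %.6f %.6f", id,
                            (b$x0 + b$x1) / 2 / w, (b$y0 + b$y1) / 2 / h,
                            (b$x1 - b$x0) / w, (b$y1 - b$y0) / h)
      }
      writeLines(lines, path)
    },
    `voc-xml` = {
      doc <- xml2::xml_new_root("annotation")
      sz <- xml2::xml_add_child(doc, "size")
      xml2::xml_add_child(sz, "width", as.character(w))
      xml2::xml_add_child(sz, "height", as.character(h))
      for (i in seq_along(boxes)) {
        b <- boxes[[i]]
        ob <- xml2::xml_add_child(doc, "object")
        xml2::xml_add_child(ob, "name", cls[i])
        bb <- xml2::xml_add_child(ob, "bndbox")
        xml2::xml_add_child(bb, "xmin", as.character(b$x0 + 1L))
        xml2::xml_add_child(bb, "ymin", as.character(b$y0 + 1L))
        xml2::xml_add_child(bb, "xmax", as.character(b$x1))
        xml2::xml_add_child(bb, "ymax", as.character(b$y1))
      }
      xml2::write_xml(doc, path)
    },
    csv = {
      df <- data.frame(
        class = cls,
        x0 = vapply(boxes, function(b) b$x0, integer(1)),
        y0 = vapply(boxes, function(b) b$y0, integer(1)),
        x1 = vapply(boxes, function(b) b$x1, integer(1)),
        y1 = vapply(boxes, function(b) b$y1, integer(1))
      )
      utils::write.csv(df, path, row.names = FALSE)
    }
  )
  invisible(path)
}

#' Read YOLO-dialect labels back into boxes
#'
#' An optional sixth column is read as a detection confidence (prediction
#' files); without it, confidence is `NA`.
#'
#' @param path label file
#' @param img_w,img_h image dimensions used for denormalization
#' @return data.frame with `class_id`, `x0`, `y0`, `x1`, `y1`,
#'   `confidence`
#' @export
import_labels_yolo <- function(path, img_w, img_h) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(class_id = integer(0), x0 = integer(0),
                      y0 = integer(0), x1 = integer(0), y1 = integer(0),
                      confidence = numeric(0)))
  }
  parts <- lapply(strsplit(lines, "\\s+"), as.numeric)
  do.call(rbind, lapply(parts, function(p) {
    cx <- p[2] * img_w; cy <- p[3] * img_h
    bw <- p[4] * img_w; bh <- p[5] * img_h
    data.frame(class_id = as.integer(p[1]),
               x0 = as.integer(round(cx - bw / 2)),
               y0 = as.integer(round(cy - bh / 2)),
               x1 = as.integer(round(cx + bw / 2)),
               y1 = as.integer(round(cy + bh / 2)),
               confidence = if (length(p) >= 6L) p[6] else NA_real_)
  }))
}

# ---- dataset splitting -----------------------------------------------------

#' Train/validation/test split proportions
#'
#' @param train,val,test positive fractions summing to 1 (defaults
#'   0.8/0.1/0.1)
#' @return list of class `split_spec`
#' @export
split_spec <- function(train = 0.8, val = 0.1, test = 0.1) {
  p <- c(train, val, test)
  if (any(p <= 0)) stop("split proportions must be positive", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("split proportions must sum to 1",
                                   call. = FALSE)
  structure(list(train = train, val = val, test = test),
            class = "split_spec")
}

#' Split item indices into train/validation/test sets
#'
#' Validation and test sizes are `round(n * p)`; the remainder goes to
#' train. Items are shuffled deterministically by the seed; the three sets
#' are disjoint and cover `1..n`.
#'
#' @param n_items number of items (>= 3)
#' @param spec a [split_spec()]
#' @param seed shuffle seed
#' @return list with integer vectors `train`, `val`, `test`
#' @export
split_dataset <- function(n_items, spec = split_spec(), seed = 0L) {
  if (n_items < 3L) stop("need at least 3 items to split", call. = FALSE)
  n_val <- round(n_items * spec$val)
  n_test <- round(n_items * spec$test)
  n_train <- n_items - n_val - n_test
  if (n_train < 1L || n_val < 0L || n_test < 0L) {
    stop("degenerate split proportions for n = ", n_items, call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n_items))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}
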