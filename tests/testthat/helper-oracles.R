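# Independent brute-force re-implementations used as oracles. These are
# deliberately written in a different style from the package code (pixel
# enumeration, explicit loops) and must never call the functions they check.

# IoU by enumerating integer pixels of each half-open box
oracle_iou_pixels <- function(a, b) {
  cells <- function(z) {
    if (z$x1 <= z$x0 || z$y1 <= z$y0) return(character(0))
    g <- expand.grid(x = z$x0:(z$x1 - 1L), y = z$y0:(z$y1 - 1L))
    paste(g$x, g$y)
  }
  ca <- cells(a)
  cb <- cells(b)
  inter <- length(intersect(ca, cb))
  uni <- length(union(ca, cb))
  if (uni == 0) 0 else inter / uni
}

# IoU by interval arithmetic, independent of the package implementation
oracle_iou <- function(a, b) {
  ov_x <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0))
  ov_y <- max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
  inter <- ov_x * ov_y
  area_a <- (a$x1 - a$x0) * (a$y1 - a$y0)
  area_b <- (b$x1 - b$x0) * (b$y1 - b$y0)
  if (inter == 0) 0 else inter / (area_a + area_b - inter)
}

# greedy matcher re-derived from scratch: confidence-descending order,
# each prediction takes the unmatched gt of max IoU >= threshold
oracle_match <- function(preds, gts, thr) {
  conf <- sapply(preds, function(p) p$confidence)
  ord <- if (length(conf)) order(conf, decreasing = TRUE) else integer(0)
  used <- rep(FALSE, length(gts))
  flags <- logical(length(preds))
  for (idx in seq_along(ord)) {
    p <- preds[[ord[idx]]]
    ious <- sapply(seq_along(gts), function(j) {
      if (used[j]) -1 else oracle_iou(p$box, gts[[j]])
    })
    if (length(ious) && max(ious) >= thr) {
      j <- which.max(ious)
      used[j] <- TRUE
      flags[idx] <- TRUE
    }
  }
  list(tp = sum(flags), fp = sum(!flags), fn = sum(!used), flags = flags)
}

# AP from the PR staircase and a direct suffix-max over the 101 grid
oracle_ap <- function(preds, gts, thr) {
  if (length(gts) == 0L || length(preds) == 0L) return(0)
  m <- oracle_match(preds, gts, thr)
  tp_cum <- cumsum(m$flags)
  rec <- tp_cum / length(gts)
  prec <- tp_cum / seq_along(tp_cum)
  grid <- seq(0, 1, by = 0.01)
  vals <- sapply(grid, function(r) {
    sel <- which(rec >= r - 1e-12)
    if (length(sel) == 0L) 0 else max(prec[sel])
  })
  mean(vals)
}

# shared fixture pools, built once per test run
fixture_pools <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_fixture_pools(6L, 2L, soil_h = 1024L, soil_w = 1024L,
                                  seed = 11L)
    }
    cache
  }
})

# a small uniform-color raster image
uniform_image <- function(h, w, rgb, space = "RGB") {
  px <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) px[, , k] <- rgb[k]
  raster_image(px, space)
}

random_rgb_image <- function(h, w, seed) {
  withr::with_seed(seed, {
    raster_image(array(sample(0:255, h * w * 3, TRUE), dim = c(h, w, 3L)),
                 "RGB")
  })
}
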