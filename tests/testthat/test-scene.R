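test_that("background windows are in-bounds, exact and reproducible", {
  soil <- uniform_image(300, 400, c(120, 85, 60))
  exact <- sample_background_window(uniform_image(64, 64, c(1, 2, 3)), 64)
  expect_equal(c(exact$box$x0, exact$box$y0, exact$box$x1, exact$box$y1),
               c(0, 0, 64, 64))

  w1 <- sample_background_window(soil, 64, seed = 9)
  w2 <- sample_background_window(soil, 64, seed = 9)
  expect_identical(w1$box, w2$box)

  for (i in 1:200) {
    b <- sample_background_window(soil, 64, seed = i)$box
    expect_true(b$x0 >= 0 && b$y0 >= 0 && b$x1 <= 400 && b$y1 <= 300)
    expect_equal(bbox_area(b), 64 * 64)
  }
  expect_error(sample_background_window(soil, 500), "smaller")
})

test_that("non-overlap placement returns disjoint tiles or fails cleanly", {
  b <- place_nonoverlap(list(), 64, 256, 256, seed = 1)
  expect_equal(bbox_area(b), 64 * 64)

  blocker <- bbox(0, 0, 64, 64)
  expect_error(place_nonoverlap(list(blocker), 64, 64, 64, seed = 1),
               "placement failed")

  for (s in 1:25) {
    placed <- list()
    for (i in 1:3) {
      placed[[i]] <- place_nonoverlap(placed, 96, 512, 512,
                                      seed = s * 100 + i)
    }
    for (i in 1:2) for (j in (i + 1):3) {
      expect_equal(iou(placed[[i]], placed[[j]]), 0)
    }
  }
})

test_that("row placement gives a centered symmetric grid at zero jitter", {
  boxes <- place_rows(4, 2, 100, 400, 400, jitter = 0, seed = 1)
  xs <- sapply(boxes, function(b) b$x0)
  ys <- sapply(boxes, function(b) b$y0)
  expect_equal(xs, c(50, 250, 50, 250))
  expect_equal(ys, c(50, 50, 250, 250))
  # determinism
  expect_identical(place_rows(4, 2, 100, 400, 400, jitter = 0, seed = 2),
                   boxes)

  # row membership recoverable by clustering y coordinates
  jboxes <- place_rows(6, 2, 80, 500, 600, jitter = 10, seed = 5)
  y0s <- sapply(jboxes, function(b) b$y0)
  km <- stats::kmeans(y0s, centers = 2)
  expect_equal(km$cluster[1:3], rep(km$cluster[1], 3))
  expect_equal(km$cluster[4:6], rep(km$cluster[4], 3))

  expect_error(place_rows(4, 2, 300, 400, 400), "does not fit")
})

test_that("row placement with jitter below the gap never overlaps", {
  for (s in 1:10) {
    boxes <- place_rows(4, 2, 100, 400, 400, jitter = 20, seed = s)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(iou(boxes[[i]], boxes[[j]]), 0)
    }
  }
})

test_that("scenes are deterministic and labels equal coordinate arithmetic", {
  pools <- fixture_pools()
  spec <- scene_spec(n_plants = 1, seed = 31, color_correct = FALSE)
  sc <- build_scene(spec, pools$cutouts, pools$soils)
  expect_length(sc$labels, 1)
  p <- sc$provenance[[1]]
  inner <- tight_bbox(p$mask, 0)
  lbl <- sc$labels[[1]]$box
  expect_equal(lbl$x0, p$tile_box$x0 + inner$x0)
  expect_equal(lbl$y0, p$tile_box$y0 + inner$y0)
  expect_equal(lbl$x1, p$tile_box$x0 + inner$x1)
  expect_equal(lbl$y1, p$tile_box$y0 + inner$y1)

  sc2 <- build_scene(spec, pools$cutouts, pools$soils)
  expect_identical(sc$image$pixels, sc2$image$pixels)
  expect_identical(sc$labels, sc2$labels)
})

test_that("identity translation without color correction is pure copy-paste", {
  pools <- fixture_pools()
  spec <- scene_spec(n_plants = 3, seed = 8, color_correct = FALSE)
  soil <- pools$soils[[1]]
  sc <- build_scene(spec, pools$cutouts,
                    pools$soils[1], tr = identity_translator())
  # pixels outside every tile box equal the untouched soil
  untouched <- matrix(TRUE, img_height(soil), img_width(soil))
  for (p in sc$provenance) {
    tb <- p$tile_box
    untouched[(tb$y0 + 1):tb$y1, (tb$x0 + 1):tb$x1] <- FALSE
  }
  for (k in 1:3) {
    expect_identical(sc$image$pixels[, , k][untouched],
                     soil$pixels[, , k][untouched])
  }
  # background correction was a no-op (identity translator => zero offsets)
  for (p in sc$provenance) expect_equal(p$offsets, c(0, 0, 0))
})

test_that("first plants are stable when n_plants grows (counter seeding)", {
  pools <- fixture_pools()
  s2 <- build_scene(scene_spec(n_plants = 2, seed = 77, color_correct = FALSE),
                    pools$cutouts, pools$soils)
  s3 <- build_scene(scene_spec(n_plants = 3, seed = 77, color_correct = FALSE),
                    pools$cutouts, pools$soils)
  for (i in 1:2) {
    expect_identical(s2$provenance[[i]]$tile_box, s3$provenance[[i]]$tile_box)
    expect_identical(s2$labels[[i]], s3$labels[[i]])
  }
})

test_that("species filter and class vocabulary behave", {
  pools <- fixture_pools()
  spec <- scene_spec(n_plants = 2, seed = 4, species_filter = "oat",
                     single_class = FALSE, color_correct = FALSE)
  sc <- build_scene(spec, pools$cutouts, pools$soils)
  expect_true(all(sapply(sc$labels, function(l) l$class) == "oat"))
  expect_error(build_scene(
    scene_spec(n_plants = 1, seed = 1, species_filter = "nosuch"),
    pools$cutouts, pools$soils), "empty cutout pool")
  expect_error(build_scene(spec, list(), pools$soils), "empty")
})

test_that("yolo export writes the documented fixed-point lines", {
  img <- uniform_image(100, 200, c(0, 0, 0))
  scene <- structure(list(image = img,
                          labels = list(list(box = bbox(0, 0, 200, 100),
                                             class = "plant"))),
                     class = "labeled_scene")
  tmp <- withr::local_tempfile(fileext = ".txt")
  export_labels(scene, tmp, "yolo")
  expect_equal(readLines(tmp), "0 0.500000 0.500000 1.000000 1.000000")

  # empty label list -> empty file, no error
  empty <- structure(list(image = img, labels = list()),
                     class = "labeled_scene")
  export_labels(empty, tmp, "yolo")
  expect_length(readLines(tmp), 0)
  expect_equal(nrow(import_labels_yolo(tmp, 200, 100)), 0)
})

test_that("yolo round trip recovers boxes within a pixel", {
  pools <- fixture_pools()
  sc <- build_scene(scene_spec(n_plants = 3, seed = 15,
                               color_correct = FALSE),
                    pools$cutouts, pools$soils)
  tmp <- withr::local_tempfile(fileext = ".txt")
  export_labels(sc, tmp, "yolo")
  got <- import_labels_yolo(tmp, img_width(sc$image), img_height(sc$image))
  expect_equal(nrow(got), 3)
  for (i in 1:3) {
    b <- sc$labels[[i]]$box
    expect_lte(abs(got$x0[i] - b$x0), 1)
    expect_lte(abs(got$y0[i] - b$y0), 1)
    expect_lte(abs(got$x1[i] - b$x1), 1)
    expect_lte(abs(got$y1[i] - b$y1), 1)
  }
})

test_that("voc-xml and csv dialects carry their own corner conventions", {
  img <- uniform_image(50, 60, c(0, 0, 0))
  scene <- structure(list(image = img,
                          labels = list(list(box = bbox(4, 9, 24, 39),
                                             class = "plant"))),
                     class = "labeled_scene")
  xmlf <- withr::local_tempfile(fileext = ".xml")
  export_labels(scene, xmlf, "voc-xml")
  doc <- xml2::read_xml(xmlf)
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//xmin")), "5")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//ymin")), "10")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//xmax")), "24")
  expect_equal(xml2::xml_text(xml2::xml_find_first(doc, "//ymax")), "39")

  csvf <- withr::local_tempfile(fileext = ".csv")
  export_labels(scene, csvf, "csv")
  df <- read.csv(csvf)
  expect_equal(c(df$x0, df$y0, df$x1, df$y1), c(4, 9, 24, 39))

  expect_error(export_labels(scene, csvf, "coco"))
})

test_that("dataset splitting partitions items at the documented sizes", {
  big <- split_dataset(80000, split_spec(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(big), c(train = 64000, val = 8000, test = 8000))

  small <- split_dataset(10, split_spec(0.8, 0.1, 0.1), seed = 1)
  expect_equal(lengths(small), c(train = 8, val = 1, test = 1))

  withr::with_seed(3, {
    for (i in 1:10) {
      n <- sample(3:500, 1)
      sp <- split_dataset(n, seed = i)
      all_idx <- sort(c(sp$train, sp$val, sp$test))
      expect_equal(all_idx, seq_len(n))
      expect_equal(length(intersect(sp$train, sp$val)), 0)
      expect_equal(length(intersect(sp$val, sp$test)), 0)
    }
  })
  expect_error(split_dataset(2), "at least 3")
  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
  expect_error(split_spec(-0.1, 0.6, 0.5), "positive")
})
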