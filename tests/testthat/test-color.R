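test_that("masked_channel_mean equals a naive double loop", {
  img <- uniform_image(5, 5, c(100, 100, 100))
  m <- matrix(FALSE, 5, 5); m[2, 3] <- TRUE; m[4, 1] <- TRUE
  expect_equal(masked_channel_mean(img, m, 1), 100)

  two <- uniform_image(1, 2, c(0, 0, 0))
  two$pixels[1, 1, 2] <- 10L; two$pixels[1, 2, 2] <- 20L
  expect_equal(masked_channel_mean(two, matrix(TRUE, 1, 2), 2), 15)

  withr::with_seed(8, {
    for (rep in 1:10) {
      img <- random_rgb_image(7, 9, seed = rep)
      m <- matrix(runif(63) < 0.4, 7, 9)
      if (!any(m)) next
      for (k in 1:3) {
        acc <- 0; n <- 0
        for (r in 1:7) for (c in 1:9) if (m[r, c]) {
          acc <- acc + img$pixels[r, c, k]; n <- n + 1
        }
        expect_equal(masked_channel_mean(img, m, k), acc / n)
      }
    }
  })
  expect_error(masked_channel_mean(img, matrix(FALSE, 7, 9), 1), "TRUE")
})

test_that("correct_plant_color maps a uniform region to the targets exactly", {
  img <- uniform_image(6, 6, c(100, 90, 150), space = "CIELAB8")
  m <- matrix(FALSE, 6, 6); m[2:4, 2:4] <- TRUE
  out <- correct_plant_color(img, m, color_targets(170, 100, 160))
  for (k in 1:3) {
    expect_true(all(out$pixels[, , k][m] == c(170, 100, 160)[k]))
    expect_true(all(out$pixels[, , k][!m] == c(100, 90, 150)[k]))
  }
})

test_that("correct_plant_color is identity at zero offset and clamps at 255", {
  img <- uniform_image(4, 4, c(170, 100, 160), space = "CIELAB8")
  m <- matrix(TRUE, 4, 4)
  expect_identical(correct_plant_color(img, m)$pixels, img$pixels)

  hot <- uniform_image(2, 2, c(250, 10, 10), space = "CIELAB8")
  hot$pixels[1, 1, 1] <- 230L  # mean 245, offset to target 255 would be +10
  out <- correct_plant_color(hot, matrix(TRUE, 2, 2),
                             color_targets(255, 10, 10))
  expect_equal(max(out$pixels[, , 1]), 255)
})

test_that("unmasked pixels survive correction bit-exactly", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      img <- raster_image(array(sample(30:220, 8 * 8 * 3, TRUE),
                                dim = c(8, 8, 3)), "CIELAB8")
      m <- matrix(runif(64) < 0.5, 8, 8)
      if (!any(m)) next
      out <- correct_plant_color(img, m)
      for (k in 1:3) {
        expect_identical(out$pixels[, , k][!m], img$pixels[, , k][!m])
      }
    }
  })
})

test_that("exterior_mask complements the box with correct area", {
  expect_false(any(exterior_mask(5, 7, bbox(0, 0, 7, 5))))
  one <- exterior_mask(4, 6, bbox(2, 1, 3, 2))
  expect_equal(sum(one), 4 * 6 - 1)
  withr::with_seed(4, {
    for (i in 1:20) {
      x0 <- sample(0:5, 1); y0 <- sample(0:5, 1)
      x1 <- x0 + sample(1:4, 1); y1 <- y0 + sample(1:4, 1)
      m <- exterior_mask(10, 10, bbox(x0, y0, x1, y1))
      expect_equal(sum(m), 100 - (x1 - x0) * (y1 - y0))
      expect_false(any(m[(y0 + 1):y1, (x0 + 1):x1]))
    }
  })
  expect_error(exterior_mask(4, 4, bbox(0, 0, 5, 2)), "exceeds")
})

test_that("exterior_band_mask keeps only a band around the box", {
  m <- exterior_band_mask(20, 20, bbox(8, 8, 12, 12), band = 2)
  expect_equal(sum(m), 8 * 8 - 4 * 4)
  expect_false(any(m[9:12, 9:12]))
  expect_false(m[1, 1])
})

test_that("background_offsets match a naive loop and basic identities", {
  comp <- random_rgb_image(10, 10, seed = 20)
  expect_equal(background_offsets(comp, comp, matrix(TRUE, 10, 10))$d,
               c(0, 0, 0))

  shifted <- raster_image(pmin(comp$pixels + 10, 255), "RGB")
  # keep values below clamp so the shift is exact
  comp2 <- raster_image(pmin(comp$pixels, 200), "RGB")
  shifted2 <- raster_image(comp2$pixels + 10, "RGB")
  expect_equal(background_offsets(comp2, shifted2,
                                  matrix(TRUE, 10, 10))$d, c(-10, -10, -10))

  withr::with_seed(30, {
    for (rep in 1:5) {
      a <- random_rgb_image(6, 8, seed = 100 + rep)
      b <- random_rgb_image(6, 8, seed = 200 + rep)
      region <- matrix(runif(48) < 0.6, 6, 8)
      if (!any(region)) next
      offs <- background_offsets(a, b, region)
      for (k in 1:3) {
        acc <- 0; n <- 0
        for (r in 1:6) for (c in 1:8) if (region[r, c]) {
          acc <- acc + a$pixels[r, c, k] - b$pixels[r, c, k]; n <- n + 1
        }
        expect_equal(offs$d[k], acc / n)
      }
    }
  })
})

test_that("correct_background undoes a uniform shift bit-exactly", {
  comp <- raster_image(pmin(pmax(random_rgb_image(12, 12, seed = 7)$pixels,
                                 30), 220), "RGB")
  translated <- raster_image(comp$pixels + 10, "RGB")
  offs <- background_offsets(comp, translated, matrix(TRUE, 12, 12))
  fixed <- correct_background(translated, offs)
  expect_identical(fixed$pixels, comp$pixels)

  zero <- structure(list(d = c(0, 0, 0)), class = "channel_offsets")
  expect_identical(correct_background(comp, zero)$pixels, comp$pixels)
})

test_that("offset correction recenters region means within rounding", {
  withr::with_seed(44, {
    for (rep in 1:10) {
      comp <- raster_image(array(sample(40:215, 300, TRUE),
                                 dim = c(10, 10, 3)), "RGB")
      noise <- array(round(rnorm(300, 0, 6)), dim = c(10, 10, 3))
      translated <- raster_image(pmin(pmax(comp$pixels + noise, 0), 255),
                                 "RGB")
      region <- matrix(runif(100) < 0.7, 10, 10)
      if (sum(region) < 5) next
      offs <- background_offsets(comp, translated, region)
      fixed <- correct_background(translated, offs)
      for (k in 1:3) {
        expect_lt(abs(masked_channel_mean(fixed, region, k) -
                        masked_channel_mean(comp, region, k)), 0.5)
      }
    }
  })
})

test_that("RGB/CIELAB8 conversion round trip is tight on the working gamut", {
  pools <- fixture_pools()
  tile <- make_composite(pools$cutouts[[1]], pools$soils[[1]], seed = 3)
  back <- lab8_to_rgb(rgb_to_lab8(tile$image))
  err <- abs(back$pixels - tile$image$pixels)
  expect_lte(max(err), 4)                 # worst case from a/b quantization
  expect_lte(stats::quantile(err, 0.99), 2)
  expect_lt(mean(err), 0.5)
})

test_that("CIELAB8 encodes greenness below 128 for green pixels", {
  green <- uniform_image(2, 2, c(60, 150, 60))
  lab <- rgb_to_lab8(green)
  expect_lt(lab$pixels[1, 1, 2], 128)  # a channel: green side
})
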