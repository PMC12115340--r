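# Segmentation pipeline: crop, thresholding, morphology, fusion, and the
# composed plant isolation.

test_that("crop honours anchors, identity and bounds", {
  img <- array(0L, dim = c(40L, 60L, 3L))
  img[, , 1] <- matrix(rep(1:60, each = 40L), 40L)  # column index as R

  out <- crop_image(img, seg_config(crop_width = 20, crop_height = 10))
  expect_identical(dim(out), c(10L, 20L, 3L))
  expect_identical(out[1, 1, 1], 21L)  # centred: cols 21..40

  anch <- crop_image(img, seg_config(crop_width = 5, crop_height = 5,
                                     crop_anchor = c(2, 3)))
  expect_identical(anch[1, , 1], 3:7)

  ident <- crop_image(img, seg_config(crop_width = 60, crop_height = 40))
  expect_identical(ident, img)

  expect_error(crop_image(img, seg_config(crop_width = 61,
                                          crop_height = 40)),
               "crop_width", class = "pg_config_error")
  expect_error(crop_image(img, seg_config(crop_width = 60,
                                          crop_height = 41)),
               "crop_height", class = "pg_config_error")
  expect_error(crop_image(img, seg_config(crop_width = 60,
                                          crop_height = 40,
                                          crop_anchor = c(2, 1))),
               class = "pg_config_error")
})

test_that("binarize applies strict 'above' and inclusive 'at_or_below'", {
  ch <- matrix(c(44, 46), 1, 2)
  expect_identical(binarize(ch, 45, "above"), matrix(c(FALSE, TRUE), 1, 2))
  expect_identical(binarize(matrix(45, 2, 2), 45, "above"),
                   matrix(FALSE, 2, 2))
  a8 <- matrix(c(120, 124, 130), 1, 3)
  expect_identical(binarize(a8, 124, "at_or_below"),
                   matrix(c(TRUE, TRUE, FALSE), 1, 3))
})

test_that("clean_mask = 5x5 closing then 3x3 cruciform opening", {
  # an isolated pixel survives the closing but not the cross opening
  m1 <- matrix(FALSE, 11, 11); m1[6, 6] <- TRUE
  expect_false(any(clean_mask(m1, seg_config())))

  # a filled square keeps everything except its 4 corners
  m2 <- matrix(FALSE, 20, 20); m2[6:15, 6:15] <- TRUE
  out2 <- clean_mask(m2, seg_config())
  expected <- m2
  expected[cbind(c(6, 6, 15, 15), c(6, 15, 6, 15))] <- FALSE
  expect_identical(out2, expected)

  # two pixels 2 apart on a row merge into one component after closing
  m3 <- matrix(FALSE, 11, 11); m3[6, c(5, 7)] <- TRUE
  closed <- phenogreen:::binary_erode(
    phenogreen:::binary_dilate(m3, phenogreen:::square_offsets(5L)),
    phenogreen:::square_offsets(5L))
  expect_identical(max(phenogreen:::label_components(closed)), 1L)
})

test_that("fill_small removes components below min_size only", {
  m <- matrix(FALSE, 30, 30)
  m[2:3, 2] <- TRUE; m[2, 3] <- TRUE          # 3-px component
  m[10:19, 10:17] <- TRUE                     # 80-px component
  out <- fill_small(m, 50)
  expect_identical(sum(out), 80L)
  expect_true(all(out[10:19, 10:17]))

  expect_identical(fill_small(m, 1), m)
  empty <- matrix(FALSE, 5, 5)
  expect_identical(fill_small(empty, 10), empty)
  expect_error(fill_small(m, 0), class = "pg_config_error")
})

test_that("or_masks is a commutative, associative, idempotent union", {
  expect_error(or_masks(matrix(TRUE, 2, 2), matrix(TRUE, 2, 3)),
               class = "pg_config_error")
  set.seed(11)
  for (i in 1:10) {
    a <- random_mask(15, 15); b <- random_mask(15, 15)
    c <- random_mask(15, 15)
    expect_identical(or_masks(a, b), or_masks(b, a))
    expect_identical(or_masks(a, or_masks(b, c)),
                     or_masks(or_masks(a, b), c))
    expect_identical(or_masks(a, a), a)
    expect_identical(or_masks(a, matrix(FALSE, 15, 15)), a)
    # disjoint additivity
    disj <- b & !a
    expect_identical(sum(or_masks(a, disj)), sum(a) + sum(disj))
  }
})

test_that("cleaning steps are anti-extensive beyond the closing", {
  set.seed(12)
  cfg <- seg_config()
  sq <- phenogreen:::square_offsets(5L)
  cr <- phenogreen:::cross_offsets()
  for (i in 1:8) {
    m <- random_mask(25, 25, "blob")
    # keep shapes clear of the canvas border: with border-as-background
    # erosion, closing is only extensive away from the edges
    m[c(1:3, 23:25), ] <- FALSE
    m[, c(1:3, 23:25)] <- FALSE
    if (!any(m)) m[13, 13] <- TRUE
    expect_true(all(fill_small(m, 5) <= m))
    closed <- phenogreen:::binary_erode(phenogreen:::binary_dilate(m, sq), sq)
    opened <- phenogreen:::binary_dilate(phenogreen:::binary_erode(m, cr), cr)
    expect_true(all(opened <= closed))
    expect_true(all(clean_mask(m, cfg) <= closed))
  }
})

test_that("segment_plant recovers synthetic plants and flags empty scenes", {
  cfg <- scene_cfg()
  sc <- generate_scene(scene_spec(seed = 7))
  seg <- segment_plant(sc$image, cfg)
  truth <- sc$truth$mask
  iou <- sum(seg$mask & truth) / sum(seg$mask | truth)
  expect_gt(iou, 0.85)
  # every truth pixel at least 2 px inside its component is recovered
  interior <- phenogreen:::binary_erode(truth,
                                        phenogreen:::square_offsets(5L))
  expect_identical(sum(interior & !seg$mask), 0L)
  # background stays zeroed in the masked image, foreground untouched
  expect_true(all(seg$masked[!array(seg$mask, dim(seg$masked))] == 0L))
  expect_identical(seg$masked[array(seg$mask, dim(seg$masked))],
                   seg$cropped[array(seg$mask, dim(seg$masked))])

  # all-background scene: empty mask plus a warning, not an error
  blank <- generate_scene(scene_spec(seed = 1, n_tillers = 0))
  expect_warning(seg0 <- segment_plant(blank$image, cfg), "empty mask")
  expect_false(any(seg0$mask))
})

test_that("segment_plant is deterministic", {
  cfg <- scene_cfg()
  sc <- generate_scene(scene_spec(seed = 3))
  s1 <- segment_plant(sc$image, cfg)
  s2 <- segment_plant(sc$image, cfg)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$masked, s2$masked)
})
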