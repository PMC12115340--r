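# Batch processing, summaries and file round-trips.

write_scene_dir <- function(n_rows = 4, seed = 60) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  design <- default_experiment_design()[seq_len(n_rows), ]
  res <- generate_experiment(design, seed = seed, out_dir = dir)
  list(dir = dir, res = res)
}

test_that("filename metadata parsing follows <treatment>_<id>_day<D>", {
  md <- parse_image_metadata("/x/GA3-TDZ_p07_day57.png")
  expect_identical(md, list(treatment = "GA3-TDZ", plant_id = "p07",
                            day = 57L))
  expect_null(parse_image_metadata("IMG_1234.png"))
})

test_that("process_image reproduces ground truth within tolerances", {
  ws <- write_scene_dir(2)
  truth <- ws$res$truth_table
  f <- file.path(ws$dir, truth$image[1])
  rec <- process_image(f, cfg = scene_cfg())
  expect_identical(rec$plant_id, truth$plant_id[1])
  expect_identical(rec$day, truth$day[1])
  expect_lt(abs(rec$area / truth$area[1] - 1), 0.05)
  expect_lt(abs(rec$greenness - truth$greenness[1]), 1.0)
  expect_identical(rec$area_above + rec$area_below, rec$area)
  expect_true(rec$solidity > 0 && rec$solidity <= 1)
})

test_that("process_image flags empty scenes instead of failing", {
  dir <- withr::local_tempdir()
  blank <- generate_scene(scene_spec(seed = 8, n_tillers = 0))
  f <- file.path(dir, "Control_p01_day30.png")
  write_image(blank$image, f)
  rec <- process_image(f, cfg = scene_cfg())
  expect_identical(rec$area, 0L)
  expect_true(is.na(rec$solidity) && is.na(rec$greenness) &&
                is.na(rec$perimeter))
  expect_match(rec$warnings, "empty mask")
})

test_that("summarize_traits computes n, mean, SE and the 95% CI half-width", {
  rec <- function(tr, day, g) data.frame(
    plant_id = "p", treatment = tr, day = day, image = "i",
    area = NA_integer_, hull_area = NA_integer_, perimeter = NA_real_,
    solidity = NA_real_, greenness = g, n_qualifying = 1L,
    area_above = NA_integer_, area_below = NA_integer_, warnings = "")
  records <- rbind(rec("A", 1L, 10), rec("A", 1L, 20), rec("A", 1L, 30),
                   rec("B", 1L, 10), rec("B", 1L, 20), rec("B", 1L, 30),
                   rec("C", 2L, 7))
  s <- summarize_traits(records)
  a <- s[s$treatment == "A" & s$trait == "greenness", ]
  expect_identical(a$n, 3L)
  expect_equal(a$mean, 20)
  expect_equal(a$se, 10 / sqrt(3))
  expect_equal(a$ci95_halfwidth, 1.96 * 10 / sqrt(3))
  # identical groups under different labels summarise identically
  b <- s[s$treatment == "B" & s$trait == "greenness", ]
  expect_equal(a[, c("n", "mean", "se", "ci95_halfwidth")],
               b[, c("n", "mean", "se", "ci95_halfwidth")],
               ignore_attr = TRUE)
  # degenerate single-record group: SE = 0 convention
  cc <- s[s$treatment == "C" & s$trait == "greenness", ]
  expect_identical(cc$n, 1L)
  expect_identical(cc$se, 0)
  # missing traits never contribute to n
  expect_false(any(s$trait == "solidity"))
  expect_identical(nrow(summarize_traits(records[0, ])), 0L)
})

test_that("run_batch writes deterministic, round-trippable tables", {
  ws <- write_scene_dir(4)
  out1 <- file.path(ws$dir, "out1"); out2 <- file.path(ws$dir, "out2")
  r1 <- run_batch(ws$dir, cfg = scene_cfg(), out_dir = out1)
  r2 <- run_batch(ws$dir, cfg = scene_cfg(), out_dir = out2)
  expect_identical(nrow(r1$traits), 4L)
  expect_identical(readLines(file.path(out1, "traits.csv")),
                   readLines(file.path(out2, "traits.csv")))
  expect_identical(readLines(file.path(out1, "summary.csv")),
                   readLines(file.path(out2, "summary.csv")))
  # CSV round-trip preserves every field
  back <- utils::read.csv(file.path(out1, "traits.csv"),
                          stringsAsFactors = FALSE)
  back$warnings[is.na(back$warnings)] <- ""
  expect_equal(back, r1$traits, ignore_attr = TRUE)
  # summary conservation: group n sums to non-missing record count
  s <- r1$summary
  for (tr in unique(s$trait))
    expect_identical(sum(s$n[s$trait == tr]),
                     sum(!is.na(r1$traits[[tr]])))
})

test_that("run_batch isolates per-file failures and honours manifests", {
  ws <- write_scene_dir(3)
  writeLines("not a png", file.path(ws$dir, "broken_p09_day30.png"))
  file.copy(file.path(ws$dir, ws$res$truth_table$image[1]),
            file.path(ws$dir, "unparseable-name.png"))
  man <- data.frame(image = "unparseable-name.png", plant_id = "p99",
                    treatment = "Manifested", day = 86L)
  man_path <- file.path(ws$dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  out <- file.path(ws$dir, "out")
  res <- run_batch(ws$dir, manifest = man_path, cfg = scene_cfg(),
                   out_dir = out)
  expect_identical(nrow(res$traits), 4L)  # 3 scenes + 1 manifest entry
  expect_identical(length(res$failures), 1L)
  expect_match(res$failures, "broken")
  expect_true("Manifested" %in% res$traits$treatment)
  log <- readLines(file.path(out, "run.log"))
  expect_true(any(grepl("FAIL broken", log)))
})

test_that("debug images and config files round-trip", {
  ws <- write_scene_dir(1)
  out <- file.path(ws$dir, "out")
  run_batch(ws$dir, cfg = scene_cfg(), out_dir = out, debug_images = TRUE)
  stem <- tools::file_path_sans_ext(ws$res$truth_table$image[1])
  expect_true(file.exists(file.path(out, paste0(stem, "_mask.png"))))

  cfg_path <- file.path(ws$dir, "cfg.json")
  jsonlite::write_json(list(crop_width = 480, crop_height = 420,
                            medium_row = 360, y_threshold = 45),
                       cfg_path, auto_unbox = TRUE)
  cfg <- read_seg_config(cfg_path)
  expect_identical(cfg$crop_width, 480L)
  expect_identical(cfg$medium_row, 360L)
  expect_identical(cfg$a_threshold, 124)
  bad <- file.path(ws$dir, "bad.json")
  jsonlite::write_json(list(nonsense = 1), bad, auto_unbox = TRUE)
  expect_error(read_seg_config(bad), class = "pg_config_error")
})
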