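## Batch processing: image -> TraitRecord row, grouped summaries, and the
## directory-level driver behind the command-line interface.

.trait_cols <- c("area", "hull_area", "perimeter", "solidity",
                 "greenness", "n_qualifying", "area_above", "area_below")

#' Parse plant metadata from an image filename
#'
#' Expects the pattern `<treatment>_<plant id>_day<D>` in the file's base
#' name, e.g. `TDZ_p07_day57.png`. Returns `NULL` when the name does not
#' match (callers then need a manifest entry).
#'
#' @param path image path.
#' @return list with `treatment`, `plant_id`, `day`, or `NULL`.
#' @export
parse_image_metadata <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(base, regexec("^(.+)_([^_]+)_day([0-9]+)$", base))[[1]]
  if (length(m) != 4L) return(NULL)
  list(treatment = m[2], plant_id = m[3], day = as.integer(m[4]))
}

#' Process one image into a trait record
#'
#' Runs segmentation, shape traits and the greenness index, and collects
#' any per-trait failures (empty mask, no qualifying pixels) as missing
#' values plus a warnings string instead of aborting.
#'
#' @param path image file path.
#' @param metadata list with `treatment`, `plant_id`, `day`; `NULL` to
#'   parse them from the filename via [parse_image_metadata()].
#' @param cfg a [seg_config()]; its `medium_row` drives the area split.
#' @return one-row data.frame with identifier, trait and `warnings`
#'   columns.
#' @export
process_image <- function(path, metadata = NULL, cfg = seg_config()) {
  if (is.null(metadata)) metadata <- parse_image_metadata(path)
  if (is.null(metadata))
    pg_config_error(sprintf(
      "cannot parse metadata from '%s'; supply a manifest", basename(path)))
  img <- read_image(path)
  warnings <- character(0)

  seg <- withCallingHandlers(
    segment_plant(img, cfg),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  traits <- shape_traits(seg$mask, cfg$medium_row)
  if (traits$area == 0L)
    warnings <- c(warnings, "shape traits undefined: empty mask")
  else if (is.null(cfg$medium_row))
    warnings <- c(warnings, "no medium_row configured; area split missing")

  gre <- tryCatch(greenness_index(seg$cropped, seg$mask),
                  pg_undefined_trait = function(e) {
                    warnings <<- c(warnings,
                                   paste("greenness undefined:",
                                         conditionMessage(e)))
                    NULL
                  })

  data.frame(
    plant_id = metadata$plant_id,
    treatment = metadata$treatment,
    day = as.integer(metadata$day),
    image = basename(path),
    area = traits$area,
    hull_area = traits$hull_area,
    perimeter = traits$perimeter,
    solidity = traits$solidity,
    greenness = if (is.null(gre)) NA_real_ else gre$index,
    n_qualifying = if (is.null(gre)) 0L else gre$n_qualifying,
    area_above = traits$area_above,
    area_below = traits$area_below,
    warnings = paste(unique(warnings), collapse = "; "),
    stringsAsFactors = FALSE
  )
}

#' Summarise trait records by treatment and day
#'
#' Per (treatment, day) group and per trait: the count of non-missing
#' values, their mean, the standard error (sample SD over sqrt(n); 0 by
#' convention when n = 1) and the 95% confidence half-width `1.96 * SE`
#' (normal approximation).
#'
#' @param records data.frame of rows from [process_image()].
#' @return long-format data.frame with columns `treatment`, `day`,
#'   `trait`, `n`, `mean`, `se`, `ci95_halfwidth`, ordered by treatment,
#'   day, trait.
#' @export
summarize_traits <- function(records) {
  out_cols <- c("treatment", "day", "trait", "n", "mean", "se",
                "ci95_halfwidth")
  if (nrow(records) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(out_cols)), out_cols))
    out$treatment <- character(0); out$trait <- character(0)
    return(out)
  }
  traits <- intersect(.trait_cols, names(records))
  groups <- unique(records[, c("treatment", "day")])
  groups <- groups[order(groups$treatment, groups$day), , drop = FALSE]
  rows <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- records$treatment == groups$treatment[g] &
      records$day == groups$day[g]
    for (tr in traits) {
      v <- records[[tr]][sel]
      v <- v[!is.na(v)]
      n <- length(v)
      if (n == 0L) next
      se <- if (n > 1L) stats::sd(v) / sqrt(n) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = groups$treatment[g], day = groups$day[g], trait = tr,
        n = n, mean = mean(v), se = se, ci95_halfwidth = 1.96 * se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Batch-process a directory of images into trait and summary tables
#'
#' Every readable PNG/JPEG in `input_dir` is segmented and measured;
#' per-file failures are logged and skipped without aborting the batch.
#' Writes `traits.csv`, `summary.csv` and `run.log` (config echo plus
#' per-image status) into `out_dir`; with `debug_images = TRUE` also a
#' mask and a masked-image PNG per input.
#'
#' @param input_dir directory of `.png` / `.jpg` / `.jpeg` images.
#' @param manifest optional path to a CSV with columns `image`,
#'   `plant_id`, `treatment`, `day`, overriding filename metadata; images
#'   without a parseable name or manifest row are listed and skipped.
#' @param cfg a [seg_config()].
#' @param out_dir output directory (created if needed).
#' @param debug_images write per-stage debug PNGs.
#' @return invisibly, a list with `traits`, `summary` (data.frames) and
#'   `failures` (character vector of skipped files with reasons).
#' @export
run_batch <- function(input_dir, manifest = NULL, cfg = seg_config(),
                      out_dir, debug_images = FALSE) {
  if (!dir.exists(input_dir))
    pg_config_error(sprintf("input directory not found: %s", input_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(input_dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  man <- NULL
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("image", "plant_id", "treatment", "day")
    if (!all(need %in% names(man)))
      pg_config_error(paste("manifest must have columns",
                            paste(need, collapse = ", ")))
  }
  log_lines <- c("phenogreen batch run",
                 utils::capture.output(print(cfg)),
                 sprintf("input: %s (%d images)", input_dir, length(files)))
  records <- list()
  failures <- character(0)
  for (f in files) {
    meta <- NULL
    if (!is.null(man)) {
      hit <- which(man$image == basename(f))
      if (length(hit) == 1L)
        meta <- list(treatment = man$treatment[hit],
                     plant_id = man$plant_id[hit],
                     day = man$day[hit])
    }
    rec <- tryCatch(process_image(f, meta, cfg), error = function(e) {
      conditionMessage(e)
    })
    if (is.character(rec)) {
      failures <- c(failures, sprintf("%s: %s", basename(f), rec))
      log_lines <- c(log_lines, sprintf("FAIL %s: %s", basename(f), rec))
      next
    }
    records[[length(records) + 1L]] <- rec
    log_lines <- c(log_lines, sprintf(
      "OK   %s: area=%d greenness=%s%s", basename(f), rec$area,
      ifelse(is.na(rec$greenness), "NA", sprintf("%.1f", rec$greenness)),
      ifelse(nzchar(rec$warnings), paste0(" [", rec$warnings, "]"), "")))
    if (debug_images) {
      seg <- segment_plant(read_image(f), cfg)
      stem <- tools::file_path_sans_ext(basename(f))
      write_mask(seg$mask, file.path(out_dir, paste0(stem, "_mask.png")))
      write_image(seg$masked,
                  file.path(out_dir, paste0(stem, "_masked.png")))
    }
  }
  traits <- if (length(records) > 0) do.call(rbind, records) else
    data.frame()
  smry <- summarize_traits(traits)
  utils::write.csv(traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  utils::write.csv(smry, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(traits = traits, summary = smry, failures = failures))
}
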