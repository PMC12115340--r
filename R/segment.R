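## Plant isolation: crop, dual-channel binarisation, morphological
## cleaning, mask fusion, and masking of the original image.

#' Segmentation configuration
#'
#' Collects every tunable parameter of the plant-isolation pipeline. The
#' defaults reproduce the published side-view vessel workflow: a centred
#' 2800 x 2600 crop out of a 6000 x 4000 photograph, a CMYK Y-channel
#' threshold of 45, an 8-bit a*-channel threshold of 124 (signed a* = -4),
#' a 5 x 5 closing followed by a 3 x 3 cruciform opening on the Y branch,
#' and removal of a*-branch components smaller than 50 px.
#'
#' @param crop_width,crop_height crop box size in pixels.
#' @param crop_anchor optional `c(row, col)` of the crop box's top-left
#'   corner (1-based); `NULL` centres the box in the image.
#' @param y_threshold CMYK Y-channel threshold (0-255); pixels strictly
#'   above it are foreground candidates.
#' @param a_threshold 8-bit a*-channel threshold (0-255); pixels at or
#'   below it (the green side) are foreground candidates, which is the
#'   one-step equivalent of thresholding above and inverting.
#' @param close_kernel side of the square closing kernel (odd, >= 3).
#' @param fill_min_size minimum component size (px) kept on the a* branch.
#' @param medium_row optional row index of the culture-medium surface,
#'   used for the above/below-medium area split.
#' @return object of class `"seg_config"` (a validated list).
#' @export
seg_config <- function(crop_width = 2800L, crop_height = 2600L,
                       crop_anchor = NULL,
                       y_threshold = 45L, a_threshold = 124L,
                       close_kernel = 5L, fill_min_size = 50L,
                       medium_row = NULL) {
  cfg <- list(
    crop_width = as.integer(crop_width),
    crop_height = as.integer(crop_height),
    crop_anchor = if (!is.null(crop_anchor)) as.integer(crop_anchor),
    y_threshold = as.numeric(y_threshold),
    a_threshold = as.numeric(a_threshold),
    close_kernel = as.integer(close_kernel),
    fill_min_size = as.integer(fill_min_size),
    medium_row = if (!is.null(medium_row)) as.integer(medium_row)
  )
  if (cfg$crop_width < 1L || cfg$crop_height < 1L)
    pg_config_error("crop dimensions must be positive")
  if (cfg$y_threshold < 0 || cfg$y_threshold > 255)
    pg_config_error("y_threshold must be in [0, 255]")
  if (cfg$a_threshold < 0 || cfg$a_threshold > 255)
    pg_config_error("a_threshold must be in [0, 255]")
  if (cfg$close_kernel < 3L || cfg$close_kernel %% 2L == 0L)
    pg_config_error("close_kernel must be odd and >= 3")
  if (cfg$fill_min_size < 1L)
    pg_config_error("fill_min_size must be >= 1")
  if (!is.null(cfg$crop_anchor) && length(cfg$crop_anchor) != 2L)
    pg_config_error("crop_anchor must be c(row, col)")
  class(cfg) <- "seg_config"
  cfg
}

#' @export
print.seg_config <- function(x, ...) {
  cat("Segmentation configuration\n")
  cat(sprintf("  crop: %d x %d (%s)\n", x$crop_width, x$crop_height,
              if (is.null(x$crop_anchor)) "centred"
              else sprintf("anchor row %d, col %d", x$crop_anchor[1],
                           x$crop_anchor[2])))
  cat(sprintf("  Y threshold (keep >): %g   a* threshold (keep <=): %g\n",
              x$y_threshold, x$a_threshold))
  cat(sprintf("  closing kernel: %d x %d   min a*-component: %d px\n",
              x$close_kernel, x$close_kernel, x$fill_min_size))
  cat(sprintf("  medium row: %s\n",
              if (is.null(x$medium_row)) "unset" else x$medium_row))
  invisible(x)
}

#' Crop an RGB image to the configured analysis window
#'
#' @param img H x W x 3 RGB array.
#' @param cfg a [seg_config()].
#' @return the `crop_height` x `crop_width` x 3 sub-array.
#' @export
crop_image <- function(img, cfg = seg_config()) {
  validate_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (cfg$crop_height > h)
    pg_config_error(sprintf(
      "crop_height %d exceeds image height %d", cfg$crop_height, h))
  if (cfg$crop_width > w)
    pg_config_error(sprintf(
      "crop_width %d exceeds image width %d", cfg$crop_width, w))
  anchor <- cfg$crop_anchor
  if (is.null(anchor))
    anchor <- c((h - cfg$crop_height) %/% 2L + 1L,
                (w - cfg$crop_width) %/% 2L + 1L)
  r1 <- anchor[1L]; c1 <- anchor[2L]
  r2 <- r1 + cfg$crop_height - 1L
  c2 <- c1 + cfg$crop_width - 1L
  if (r1 < 1L || r2 > h)
    pg_config_error(sprintf(
      "crop rows %d..%d fall outside image height %d", r1, r2, h))
  if (c1 < 1L || c2 > w)
    pg_config_error(sprintf(
      "crop cols %d..%d fall outside image width %d", c1, c2, w))
  img[r1:r2, c1:c2, , drop = FALSE]
}

#' Threshold a channel image into a binary mask
#'
#' @param channel H x W numeric matrix of 0-255 intensities.
#' @param threshold scalar in \[0, 255\].
#' @param keep `"above"` marks values strictly greater than the threshold
#'   as foreground; `"at_or_below"` marks values `<=` threshold, the
#'   one-step equivalent of thresholding above and then inverting.
#' @return logical H x W mask.
#' @export
binarize <- function(channel, threshold, keep = c("above", "at_or_below")) {
  keep <- match.arg(keep)
  if (!is.matrix(channel))
    pg_config_error("`channel` must be a matrix")
  if (keep == "above") channel > threshold else channel <= threshold
}

#' Morphologically clean a mask (closing then cruciform opening)
#'
#' Dilation with a `close_kernel` square followed by erosion with the same
#' kernel (a morphological closing, bridging small gaps), then opening
#' with the fixed 3 x 3 cruciform element (erosion then dilation with the
#' 4-connected cross), which removes isolated pixels and 1-px spurs.
#'
#' @inheritParams crop_image
#' @param mask logical matrix.
#' @return logical matrix of the same dimensions.
#' @export
clean_mask <- function(mask, cfg = seg_config()) {
  validate_mask(mask)
  sq <- square_offsets(cfg$close_kernel)
  closed <- binary_erode(binary_dilate(mask, sq), sq)
  cr <- cross_offsets()
  binary_dilate(binary_erode(closed, cr), cr)
}

#' Remove small connected components
#'
#' Deletes every 8-connected foreground component with fewer than
#' `min_size` pixels; larger components are untouched.
#'
#' @param mask logical matrix.
#' @param min_size minimum component pixel count to keep (>= 1).
#' @return logical matrix of the same dimensions.
#' @export
fill_small <- function(mask, min_size) {
  validate_mask(mask)
  if (min_size < 1) pg_config_error("min_size must be >= 1")
  if (min_size == 1 || !any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  out
}

#' Pixelwise logical OR of two masks
#'
#' @param m1,m2 logical matrices of equal dimensions.
#' @return logical matrix.
#' @export
or_masks <- function(m1, m2) {
  validate_mask(m1, "m1"); validate_mask(m2, "m2")
  if (!identical(dim(m1), dim(m2)))
    pg_config_error("mask dimensions differ")
  m1 | m2
}

#' Segment a plant from a blue-background vessel photograph
#'
#' The full isolation pipeline: crop; convert the crop to the CMYK Y
#' channel, threshold strictly above `y_threshold` and clean
#' morphologically ([clean_mask()]); in parallel convert to CIELAB, take
#' the 8-bit a* channel, keep values at or below `a_threshold` (the green
#' side, recovering tissue dulled by the culture medium) and drop
#' components smaller than `fill_min_size` px; fuse the two masks with a
#' logical OR; zero background pixels of the cropped image.
#'
#' @inheritParams crop_image
#' @return a list of class `"pg_segmentation"` with elements `mask`
#'   (logical matrix), `masked` (RGB array, background zeroed) and
#'   `cropped` (the cropped RGB array).
#' @export
segment_plant <- function(img, cfg = seg_config()) {
  cropped <- crop_image(img, cfg)

  ych <- rgb_to_cmyk_channel(cropped, "Y")
  y_mask <- clean_mask(binarize(ych, cfg$y_threshold, "above"), cfg)

  lab <- rgb_to_lab_signed(cropped)
  a8 <- lab_signed_to_8bit(lab, "a8")
  a_mask <- fill_small(binarize(a8, cfg$a_threshold, "at_or_below"),
                       cfg$fill_min_size)

  mask <- or_masks(y_mask, a_mask)
  if (!any(mask))
    warning("segmentation produced an empty mask", call. = FALSE)

  masked <- cropped
  masked[!array(mask, dim(cropped))] <- 0L
  structure(list(mask = mask, masked = masked, cropped = cropped),
            class = "pg_segmentation")
}
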