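## The greenness index: qualify foreground pixels in signed CIELAB
## (a* < 0 and b* > 0), average the green and yellow chromaticities, take
## the chromaticity angle theta = arctan(|a|/b) in degrees, and rescale it
## linearly so that theta = 0 maps to 0 (fully chlorotic) and theta = 90
## maps to 100 (fully verdant).

#' Extract signed CIELAB values of foreground pixels
#'
#' Mask membership (not non-zero testing) defines the foreground, so black
#' plant pixels are kept and zeroed background cannot leak in.
#'
#' @param img H x W x 3 RGB array.
#' @param mask logical H x W mask aligned with `img`.
#' @return numeric matrix with columns `L`, `a`, `b`, one row per
#'   foreground pixel (column-major pixel order).
#' @export
extract_lab_pixels <- function(img, mask) {
  validate_rgb(img)
  validate_mask(mask)
  if (!identical(dim(img)[1:2], dim(mask)))
    pg_config_error("image and mask dimensions differ")
  lab <- rgb_to_lab_signed(img)
  d <- dim(lab)
  cbind(L = matrix(lab[, , 1], d[1], d[2])[mask],
        a = matrix(lab[, , 2], d[1], d[2])[mask],
        b = matrix(lab[, , 3], d[1], d[2])[mask])
}

#' Keep pixels that qualify for the greenness index
#'
#' Retains rows with strictly `a* < 0` (green side of the green-red axis)
#' and strictly `b* > 0` (yellow side of the blue-yellow axis); row order
#' is preserved. Neutral pixels (a* = 0 or b* = 0) never qualify.
#'
#' @param table matrix with columns `L`, `a`, `b` from
#'   [extract_lab_pixels()].
#' @return the filtered matrix.
#' @export
qualifying_pixels <- function(table) {
  if (!is.matrix(table) || !all(c("L", "a", "b") %in% colnames(table)))
    pg_config_error("`table` must be a matrix with columns L, a, b")
  table[table[, "a"] < 0 & table[, "b"] > 0, , drop = FALSE]
}

#' Chromaticity angle of a qualifying pixel table
#'
#' With `a_bar = |mean(a*)|` and `b_bar = mean(b*)` over the qualifying
#' pixels, the angle between the point `(b_bar, a_bar)` and the origin of
#' the chromaticity plane is `theta = arctan(a_bar / b_bar) * 180 / pi`
#' degrees. Both means are positive after qualification, so theta lies in
#' (0, 90) and no quadrant handling is needed.
#'
#' @param table qualifying-pixel matrix (see [qualifying_pixels()]); must
#'   be non-empty.
#' @return theta in degrees.
#' @export
greenness_theta <- function(table) {
  if (nrow(table) == 0L)
    pg_undefined_trait("no qualifying pixels (a* < 0, b* > 0)",
                       n_qualifying = 0L)
  a_bar <- abs(mean(table[, "a"]))
  b_bar <- mean(table[, "b"])
  atan(a_bar / b_bar) * 180 / pi
}

#' Rescale the chromaticity angle to the 0-100 greenness scale
#'
#' Linear with fixed endpoints: 0 degrees -> 0 (chlorotic), 90 degrees
#' -> 100 (verdant).
#'
#' @param theta angle in degrees, in \[0, 90\].
#' @return index in \[0, 100\].
#' @export
rescale_theta <- function(theta) {
  if (any(theta < 0 | theta > 90))
    pg_config_error("theta must be in [0, 90] degrees")
  theta * 100 / 90
}

#' Greenness index of a masked plant image
#'
#' Composition of [extract_lab_pixels()], [qualifying_pixels()],
#' [greenness_theta()] and [rescale_theta()]. A low index indicates
#' chlorosis, a high index verdancy. When no foreground pixel qualifies
#' the index is undefined and an error of class `"pg_undefined_trait"` is
#' signalled (batch processing records it as a missing trait).
#'
#' @inheritParams extract_lab_pixels
#' @return list of class `"pg_greenness"`: `a_bar`, `b_bar`, `theta`
#'   (degrees), `index` (0-100), `n_qualifying`.
#' @export
greenness_index <- function(img, mask) {
  tab <- qualifying_pixels(extract_lab_pixels(img, mask))
  theta <- greenness_theta(tab)
  structure(list(
    a_bar = abs(mean(tab[, "a"])),
    b_bar = mean(tab[, "b"]),
    theta = theta,
    index = rescale_theta(theta),
    n_qualifying = nrow(tab)
  ), class = "pg_greenness")
}

#' @export
print.pg_greenness <- function(x, ...) {
  cat(sprintf(
    "Greenness index: %.1f (theta = %.2f deg, |a|=%.2f, b=%.2f, n=%d)\n",
    x$index, x$theta, x$a_bar, x$b_bar, x$n_qualifying))
  invisible(x)
}
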