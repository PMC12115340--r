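## Colour-space conversions: 8-bit sRGB -> CMYK channels and CIELAB.
##
## All conversions are pure, vectorised functions over H x W x 3 arrays.
## CIELAB uses the D65 white point with the 2-degree observer, the common
## default in imaging toolkits; the 8-bit a*/b* encodings use the
## offset-128 convention so that published thresholds on 0-255 a* values
## (e.g. 124) are meaningful.

# sRGB (IEC 61966-2-1) -> linear RGB, input in [0, 1]
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

# linear sRGB -> XYZ, D65 white
.srgb_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.d65_white <- c(0.95047, 1.00000, 1.08883)

#' Extract a CMYK channel from an RGB image
#'
#' Converts an 8-bit sRGB image to the subtractive CMYK decomposition and
#' returns one channel rescaled to 0-255. With `R' = R/255` etc., the
#' decomposition is `K = 1 - max(R', G', B')` and
#' `C = (1 - R' - K) / (1 - K)` (M, Y analogous). Pixels with `K = 1`
#' (pure black) return 0 for C, M and Y by convention.
#'
#' The Y (yellow) channel is high for plant tissue and zero for any pixel
#' whose blue component is the channel maximum, which is what makes it an
#' effective separator of plants from a blue imaging background.
#'
#' @param img H x W x 3 array of 8-bit sRGB intensities (0-255).
#' @param channel one of `"C"`, `"M"`, `"Y"`, `"K"`.
#' @return H x W integer matrix with values in 0-255.
#' @examples
#' px <- array(c(0, 0, 255), dim = c(1, 1, 3))   # pure blue
#' rgb_to_cmyk_channel(px, "Y")                  # 0
#' @export
rgb_to_cmyk_channel <- function(img, channel = c("C", "M", "Y", "K")) {
  channel <- match.arg(channel)
  validate_rgb(img)
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2]) / 255
  g <- matrix(img[, , 2], d[1], d[2]) / 255
  b <- matrix(img[, , 3], d[1], d[2]) / 255
  k <- 1 - pmax(r, g, b)
  if (channel == "K") {
    out <- k
  } else {
    den <- 1 - k
    num <- switch(channel,
      C = 1 - r - k,
      M = 1 - g - k,
      Y = 1 - b - k
    )
    out <- ifelse(den == 0, 0, num / den)
  }
  m <- round_half_up(out * 255)
  storage.mode(m) <- "integer"
  m
}

#' Convert an RGB image to signed CIELAB
#'
#' Standard sRGB decoding (IEC 61966-2-1 transfer), linear RGB to XYZ under
#' the D65 white point, then CIELAB with the 2-degree observer. Output is
#' signed floating point: L* in \[0, 100\], a* and b* roughly in
#' \[-128, 127\]. Negative a* is green, positive b* is yellow.
#'
#' @param img H x W x 3 array of 8-bit sRGB intensities (0-255).
#' @return H x W x 3 double array; slices are L*, a*, b* in that order.
#' @export
rgb_to_lab_signed <- function(img) {
  validate_rgb(img)
  d <- dim(img)
  v <- srgb_decode(matrix(img, ncol = 3L) / 255)
  xyz <- v %*% t(.srgb_xyz)
  ratio <- sweep(xyz, 2L, .d65_white, "/")
  delta <- 6 / 29
  f <- ifelse(ratio > delta^3, ratio^(1 / 3), ratio / (3 * delta^2) + 4 / 29)
  L <- 116 * f[, 2] - 16
  a <- 500 * (f[, 1] - f[, 2])
  b <- 200 * (f[, 2] - f[, 3])
  array(c(L, a, b), dim = c(d[1], d[2], 3L),
        dimnames = list(NULL, NULL, c("L", "a", "b")))
}

#' Encode a signed CIELAB channel as 8-bit
#'
#' `L8 = round(L* * 255 / 100)`; `a8 = round(a* + 128)`;
#' `b8 = round(b* + 128)`; all clamped to \[0, 255\]. The offset-128
#' encoding of a*/b* is the convention under which a published a*
#' threshold of 124 corresponds to signed a* = -4.
#'
#' @param lab H x W x 3 signed CIELAB array from [rgb_to_lab_signed()].
#' @param channel one of `"L8"`, `"a8"`, `"b8"`.
#' @return H x W integer matrix with values in 0-255.
#' @export
lab_signed_to_8bit <- function(lab, channel = c("L8", "a8", "b8")) {
  channel <- match.arg(channel)
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    pg_config_error("`lab` must be an H x W x 3 array")
  d <- dim(lab)
  out <- switch(channel,
    L8 = matrix(lab[, , 1], d[1], d[2]) * 255 / 100,
    a8 = matrix(lab[, , 2], d[1], d[2]) + 128,
    b8 = matrix(lab[, , 3], d[1], d[2]) + 128
  )
  m <- clamp255(round_half_up(out))
  storage.mode(m) <- "integer"
  m
}
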