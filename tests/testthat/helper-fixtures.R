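# Shared fixtures: random masks and the segmentation config matched to
# the synthetic generator's default canvas.

# mix of blobby and sparse random masks (always at least one pixel)
random_mask <- function(h, w, style = c("sparse", "blob")) {
  style <- match.arg(style)
  m <- matrix(stats::runif(h * w) < 0.12, h, w)
  if (style == "blob") {
    offs <- phenogreen:::square_offsets(3L)
    m <- phenogreen:::binary_dilate(m, offs)
  }
  if (!any(m)) m[sample(h, 1L), sample(w, 1L)] <- TRUE
  m
}

# config aligned with scene_spec() defaults: identity crop over the
# 840 x 960 canvas, medium at row 720
scene_cfg <- function() {
  seg_config(crop_width = 960L, crop_height = 840L, medium_row = 720L)
}

# a tiny uniform-colour image with a given foreground mask on blue
uniform_scene <- function(mask, fg_rgb, bg_rgb = c(40L, 70L, 160L)) {
  h <- nrow(mask); w <- ncol(mask)
  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(bg_rgb[ch], h, w)
    plane[mask] <- fg_rgb[ch]
    img[, , ch] <- plane
  }
  storage.mode(img) <- "integer"
  img
}
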