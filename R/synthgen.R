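## Synthetic tissue-culture scenes with exact ground truth.
##
## A scene emulates what the segmentation pipeline actually relies on in a
## vessel photograph: grass-like tillers (curved, tapered strokes rising
## from a base point) whose colour interpolates from a verdant green to a
## chlorotic yellow-green, painted over a deep blue background with an
## optional pale medium band at the vessel base. The default palette is
## chosen so that every foreground pixel (any chlorosis level, jitter up
## to +/-10) keeps CMYK Y > 45 while background and medium sit at Y = 0
## and 8-bit a* > 124 -- the separation the blue imaging background was
## designed to provide.

#' Specify a synthetic vessel scene
#'
#' @param seed integer seed; the scene is a pure function of the spec.
#' @param height,width canvas size in px (default 840 x 960, a roughly
#'   1:3 down-scaled stand-in for the 2600 x 2800 analysis window; the
#'   default stroke geometry keeps the tiller width-to-kernel ratio, and
#'   with it the truth solidity range, close to the full-scale regime).
#' @param background_rgb deep blue background colour.
#' @param medium_row first canvas row of the medium band; `NULL` for none.
#' @param medium_rgb pale medium colour (kept on the non-green, zero-Y
#'   side of both thresholds).
#' @param n_tillers number of tillers to draw (0 allowed).
#' @param base_point `c(row, col)` where tillers originate; defaults to
#'   just above the medium band, horizontally centred.
#' @param length_range tiller length range in px.
#' @param base_width tiller width at the base in px (tapers towards tip).
#' @param curvature_range sideways quadratic bend at the tip, px.
#' @param leaf_green_rgb,leaf_yellow_rgb colour endpoints of the
#'   verdant-to-chlorotic gradient.
#' @param chlorosis interpolation weight c in \[0, 1\]: foreground colour
#'   is `(1 - c) * green + c * yellow` before jitter.
#' @param colour_jitter half-width of the uniform integer per-pixel,
#'   per-channel colour noise (0-10; the palette's threshold-separation
#'   guarantee is stated up to 10).
#' @return object of class `"scene_spec"`.
#' @export
scene_spec <- function(seed = 1L, height = 840L, width = 960L,
                       background_rgb = c(40L, 70L, 160L),
                       medium_row = 720L,
                       medium_rgb = c(205L, 200L, 225L),
                       n_tillers = 8L,
                       base_point = NULL,
                       length_range = c(180, 400),
                       base_width = 16,
                       curvature_range = c(-80, 80),
                       leaf_green_rgb = c(55L, 140L, 45L),
                       leaf_yellow_rgb = c(175L, 195L, 40L),
                       chlorosis = 0,
                       colour_jitter = 6L) {
  if (is.null(base_point))
    base_point <- c(if (is.null(medium_row)) height - 4L
                    else medium_row - 1L,
                    width %/% 2L)
  spec <- list(seed = as.integer(seed), height = as.integer(height),
               width = as.integer(width),
               background_rgb = as.integer(background_rgb),
               medium_row = if (!is.null(medium_row)) as.integer(medium_row),
               medium_rgb = as.integer(medium_rgb),
               n_tillers = as.integer(n_tillers),
               base_point = as.integer(base_point),
               length_range = as.numeric(length_range),
               base_width = as.numeric(base_width),
               curvature_range = as.numeric(curvature_range),
               leaf_green_rgb = as.integer(leaf_green_rgb),
               leaf_yellow_rgb = as.integer(leaf_yellow_rgb),
               chlorosis = as.numeric(chlorosis),
               colour_jitter = as.integer(colour_jitter))
  if (spec$chlorosis < 0 || spec$chlorosis > 1)
    pg_config_error("chlorosis must be in [0, 1]")
  if (spec$colour_jitter < 0 || spec$colour_jitter > 10)
    pg_config_error("colour_jitter must be in 0..10")
  if (any(c(spec$background_rgb, spec$medium_rgb, spec$leaf_green_rgb,
            spec$leaf_yellow_rgb) < 0) ||
      any(c(spec$background_rgb, spec$medium_rgb, spec$leaf_green_rgb,
            spec$leaf_yellow_rgb) > 255))
    pg_config_error("colours must be 8-bit triples in [0, 255]")
  # conservative reach check: the full stroke (plus half the base width)
  # must fit on the canvas for every admissible draw
  reach <- max(spec$length_range)
  spread <- reach * sin(35 * pi / 180) + max(abs(spec$curvature_range)) +
    spec$base_width
  if (spec$base_point[1L] - reach - spec$base_width < 1 ||
      spec$base_point[2L] - spread < 1 ||
      spec$base_point[2L] + spread > spec$width ||
      spec$base_point[1L] > spec$height)
    pg_config_error("tiller geometry exceeds the canvas")
  class(spec) <- "scene_spec"
  spec
}

# disc offsets for integer radius r (Euclidean, includes centre)
.disc_offsets <- function(r) {
  r <- max(0L, as.integer(r))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Render a synthetic scene with exact ground truth
#'
#' Deterministic given the spec (including its seed). Tillers are drawn as
#' quadratic curves from the base point with tapering width; the truth
#' mask marks exactly the painted pixels. The global RNG state is
#' restored on exit.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W x 3 integer RGB array) and `truth`, a
#'   list holding `mask` (logical matrix), `pixels` (signed CIELAB table
#'   of the rendered foreground, as [extract_lab_pixels()] returns),
#'   `area`, `area_above`, `area_below` (exact counts; the split is `NA`
#'   without a medium row), `greenness` (index computed from `pixels`, or
#'   `NA` if undefined) and `spec` (the input, echoed).
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec"))
    pg_config_error("`spec` must come from scene_spec()")
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(spec$seed)

  h <- spec$height; w <- spec$width
  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch]
  if (!is.null(spec$medium_row) && spec$medium_row <= h)
    for (ch in 1:3) img[spec$medium_row:h, , ch] <- spec$medium_rgb[ch]

  mask <- matrix(FALSE, h, w)
  if (spec$n_tillers > 0L) {
    for (t in seq_len(spec$n_tillers)) {
      len <- stats::runif(1, spec$length_range[1], spec$length_range[2])
      ang <- stats::runif(1, -35, 35) * pi / 180     # from vertical
      curv <- stats::runif(1, spec$curvature_range[1],
                           spec$curvature_range[2])
      n_steps <- max(2L, ceiling(2 * len))
      tt <- seq(0, 1, length.out = n_steps)
      # upward stroke with a quadratic sideways bend
      rr <- spec$base_point[1L] - tt * len * cos(ang)
      cc <- spec$base_point[2L] + tt * len * sin(ang) + curv * tt^2
      rad <- pmax(0, spec$base_width / 2 * (1 - 0.75 * tt))
      for (i in seq_len(n_steps)) {
        offs <- .disc_offsets(rad[i])
        pr <- round(rr[i]) + offs$dr
        pc <- round(cc[i]) + offs$dc
        ok <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
        mask[cbind(pr[ok], pc[ok])] <- TRUE
      }
    }
  }

  n_fg <- sum(mask)
  if (n_fg > 0L) {
    base_col <- (1 - spec$chlorosis) * spec$leaf_green_rgb +
      spec$chlorosis * spec$leaf_yellow_rgb
    j <- spec$colour_jitter
    for (ch in 1:3) {
      jit <- if (j > 0) sample.int(2L * j + 1L, n_fg, replace = TRUE) -
        (j + 1L) else 0L
      plane <- img[, , ch]
      plane[mask] <- clamp255(round_half_up(base_col[ch] + jit))
      img[, , ch] <- plane
    }
  }
  storage.mode(img) <- "integer"

  pixels <- extract_lab_pixels(img, mask)
  gre <- tryCatch(
    rescale_theta(greenness_theta(qualifying_pixels(pixels))),
    pg_undefined_trait = function(e) NA_real_)
  split <- if (!is.null(spec$medium_row))
    split_area_at_row(mask, spec$medium_row)
  else list(area_above = NA_integer_, area_below = NA_integer_)

  list(image = img,
       truth = list(mask = mask, pixels = pixels, area = n_fg,
                    area_above = split$area_above,
                    area_below = split$area_below,
                    greenness = gre, spec = spec))
}

#' Default synthetic experiment design
#'
#' Emulates the contrasts of a six-treatment by three-imaging-day hormone
#' trial: chlorosis increases with day and with cytokinin-like treatments
#' (strongest for TDZ), tiller counts are highest in the TDZ-containing
#' treatments (driving solidity up), and plants grow between imaging days
#' (size scale increasing with day, largest in the control-like
#' open-architecture treatments).
#'
#' @return data.frame with columns `treatment`, `day`, `chlorosis`,
#'   `n_tillers`, `size_scale` (18 rows).
#' @export
default_experiment_design <- function() {
  treatments <- c("Control", "BA", "GA3", "TDZ", "GA3-TDZ", "GA3-BA")
  chl_boost <- c(Control = 0, BA = 0.10, GA3 = 0, TDZ = 0.25,
                 `GA3-TDZ` = 0.20, `GA3-BA` = 0.10)
  tillers <- c(Control = 6L, BA = 10L, GA3 = 6L, TDZ = 14L,
               `GA3-TDZ` = 16L, `GA3-BA` = 10L)
  scale_boost <- c(Control = 1.2, BA = 1.0, GA3 = 1.2, TDZ = 0.8,
                   `GA3-TDZ` = 0.8, `GA3-BA` = 1.0)
  days <- c(30L, 57L, 86L)
  day_chl <- c(`30` = 0.15, `57` = 0.35, `86` = 0.55)
  day_scale <- c(`30` = 0.6, `57` = 0.85, `86` = 1.0)
  g <- expand.grid(treatment = treatments, day = days,
                   stringsAsFactors = FALSE)
  g$chlorosis <- pmin(1, day_chl[as.character(g$day)] +
                        chl_boost[g$treatment])
  g$n_tillers <- tillers[g$treatment]
  g$size_scale <- day_scale[as.character(g$day)] * scale_boost[g$treatment]
  rownames(g) <- NULL
  g
}

#' Generate a full synthetic experiment
#'
#' One scene per design row, with per-row seeds derived as
#' `seed + row index` so any single scene can be regenerated
#' independently. Optionally writes PNG scenes (named
#' `<treatment>_<plant id>_day<day>.png`) and a `truth.csv` table.
#'
#' @param design data.frame with columns `treatment`, `day`, `chlorosis`,
#'   `n_tillers`, `size_scale`; see [default_experiment_design()].
#' @param seed integer base seed.
#' @param out_dir optional directory for PNG scenes and `truth.csv`.
#' @param ... further arguments passed to [scene_spec()] (canvas size,
#'   palette, ...).
#' @return list with `scenes` (list of [generate_scene()] results) and
#'   `truth_table` (data.frame, one row per scene: identifiers plus exact
#'   area, split and greenness).
#' @export
generate_experiment <- function(design = default_experiment_design(),
                                seed = 1L, out_dir = NULL, ...) {
  if (nrow(design) == 0L) pg_config_error("design must be non-empty")
  needed <- c("treatment", "day", "chlorosis", "n_tillers", "size_scale")
  if (!all(needed %in% names(design)))
    pg_config_error(paste("design must have columns",
                          paste(needed, collapse = ", ")))
  scenes <- vector("list", nrow(design))
  rows <- vector("list", nrow(design))
  base_len <- c(180, 400)
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    spec <- scene_spec(seed = seed + i,
                       chlorosis = d$chlorosis,
                       n_tillers = d$n_tillers,
                       length_range = base_len * d$size_scale,
                       ...)
    sc <- generate_scene(spec)
    scenes[[i]] <- sc
    plant_id <- sprintf("p%02d", i)
    rows[[i]] <- data.frame(
      image = sprintf("%s_%s_day%d.png", d$treatment, plant_id, d$day),
      plant_id = plant_id, treatment = d$treatment, day = d$day,
      chlorosis = d$chlorosis,
      area = sc$truth$area,
      area_above = sc$truth$area_above, area_below = sc$truth$area_below,
      greenness = sc$truth$greenness,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(truth)))
      write_image(scenes[[i]]$image, file.path(out_dir, truth$image[i]))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(scenes = scenes, truth_table = truth)
}
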