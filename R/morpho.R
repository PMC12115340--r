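## Shape traits of a binary mask. All retained foreground is treated as
## one composite object: a single convex hull over every foreground pixel
## centre, perimeter summed over the external boundaries of all
## components. Area and hull area are pixel counts (not polygon areas), so
## solidity is provably in (0, 1].

#' Foreground pixel count
#'
#' @param mask logical matrix.
#' @return integer count of `TRUE` pixels.
#' @export
pixel_area <- function(mask) {
  validate_mask(mask)
  sum(mask)
}

#' Convex hull area of a mask, in pixels
#'
#' The number of pixel centres lying inside or on the convex hull polygon
#' of all foreground pixel centres (rasterised-hull convention). Under
#' this shared pixel-count convention a filled convex shape has hull area
#' equal to its area, so solidity cannot exceed 1.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return integer pixel count.
#' @export
convex_hull_area <- function(mask) {
  validate_mask(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L)
    pg_undefined_trait("convex hull area undefined on an empty mask")
  if (nrow(pts) == 1L) return(1L)
  x <- pts[, 2L]; y <- pts[, 1L]      # planar coords: x = col, y = row
  hull <- grDevices::chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  # candidate lattice points: bounding box of the hull
  cx <- seq(min(hx), max(hx))
  cy <- seq(min(hy), max(hy))
  grid_x <- rep(cx, times = length(cy))
  grid_y <- rep(cy, each = length(cx))
  inside <- rep(TRUE, length(grid_x))
  nh <- length(hull)
  # orientation sign from the shoelace sum; 0 when all points collinear
  x2 <- c(hx[-1L], hx[1L]); y2 <- c(hy[-1L], hy[1L])
  orient <- sign(sum(hx * y2 - x2 * hy))
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (grid_y - hy[i]) -
             (hy[j] - hy[i]) * (grid_x - hx[i])
    inside <- inside & if (orient == 0) cross == 0 else orient * cross >= 0
  }
  sum(inside)
}

#' Perimeter of a mask, in pixels
#'
#' Sum over all external component boundaries of the polygonal arc length
#' through 8-connected boundary pixel centres: axial steps contribute 1,
#' diagonal steps sqrt(2). A single-pixel component contributes 0. The
#' boundary of each 8-connected component is walked by Moore-neighbour
#' tracing, so 1-px-wide structures are traversed out and back.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return numeric perimeter.
#' @export
perimeter <- function(mask) {
  validate_mask(mask)
  if (!any(mask))
    pg_undefined_trait("perimeter undefined on an empty mask")
  lab <- label_components(mask)
  total <- 0
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    total <- total + trace_perimeter_one(comp)
  }
  total
}

#' Solidity: ratio of area to convex hull area
#'
#' A size-independent measure of plant density ("bushiness"): sparse, open
#' architectures score low, compact tillering plants score high. Both
#' numerator and denominator are pixel counts, so the value is in (0, 1]
#' with equality exactly for filled convex shapes.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return numeric in (0, 1].
#' @export
solidity <- function(mask) {
  a <- pixel_area(mask)
  if (a == 0L)
    pg_undefined_trait("solidity undefined on an empty mask")
  a / convex_hull_area(mask)
}

#' Split foreground area at the culture-medium row
#'
#' @param mask logical matrix.
#' @param medium_row 1-based row index of the first medium row, in
#'   `1..H+1`; foreground rows strictly above it (index `< medium_row`)
#'   count as above-medium. `1` puts everything below, `H+1` everything
#'   above.
#' @return named list with integer elements `area_above` and `area_below`;
#'   the two always sum to [pixel_area()].
#' @export
split_area_at_row <- function(mask, medium_row) {
  validate_mask(mask)
  h <- nrow(mask)
  if (medium_row < 1 || medium_row > h + 1)
    pg_config_error(sprintf(
      "medium_row %s outside 1..%d", format(medium_row), h + 1))
  rows <- row(mask)
  list(area_above = sum(mask & rows < medium_row),
       area_below = sum(mask & rows >= medium_row))
}

#' All shape traits of a mask
#'
#' Convenience wrapper returning area, convex hull area, perimeter,
#' solidity and (when `medium_row` is given) the above/below-medium area
#' split in one list. On an empty mask, area is 0 and every other trait is
#' `NA`.
#'
#' @param mask logical matrix.
#' @param medium_row optional medium surface row for the area split.
#' @return named list: `area`, `hull_area`, `perimeter`, `solidity`,
#'   `area_above`, `area_below`.
#' @export
shape_traits <- function(mask, medium_row = NULL) {
  a <- pixel_area(mask)
  if (a == 0L)
    return(list(area = 0L, hull_area = NA_integer_, perimeter = NA_real_,
                solidity = NA_real_, area_above = NA_integer_,
                area_below = NA_integer_))
  hull <- convex_hull_area(mask)
  per <- perimeter(mask)
  split <- if (!is.null(medium_row)) split_area_at_row(mask, medium_row)
           else list(area_above = NA_integer_, area_below = NA_integer_)
  list(area = a, hull_area = hull, perimeter = per, solidity = a / hull,
       area_above = split$area_above, area_below = split$area_below)
}
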