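# Independent oracles used to cross-check the package's morphometry.
# These deliberately share no code with R/: the hull oracle decides point
# membership through shoelace-area invariance under point insertion, and
# the perimeter oracle is a clean-room Moore tracer with direction-table
# bookkeeping (the package version tracks backtrack positions instead).

# signed shoelace area of the convex hull of a point set (cols x, y)
.hull_shoelace <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  if (length(h) < 3L) return(0)
  x2 <- c(hx[-1L], hx[1L]); y2 <- c(hy[-1L], hy[1L])
  abs(sum(hx * y2 - x2 * hy)) / 2
}

# pixel-count convex hull area: a lattice point is inside the hull iff
# adding it leaves the hull's shoelace area unchanged and it lies in the
# point set's bounding box (the bbox clause settles degenerate/collinear
# hulls, where every area is zero)
oracle_hull_area <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(pts) >= 1L)
  if (nrow(pts) == 1L) return(1L)
  x <- pts[, 2L]; y <- pts[, 1L]
  base <- .hull_shoelace(x, y)
  count <- 0L
  for (px in seq(min(x), max(x))) {
    for (py in seq(min(y), max(y))) {
      if (abs(.hull_shoelace(c(x, px), c(y, py)) - base) < 1e-9)
        count <- count + 1L
    }
  }
  count
}

# BFS connected components, 8-connectivity
oracle_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue) > 0L) {
      q <- queue[1L]; queue <- queue[-1L]
      r0 <- (q - 1L) %% h + 1L; c0 <- (q - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r <- r0 + dr; c <- c0 + dc
        if (r >= 1L && r <= h && c >= 1L && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue <- c(queue, (c - 1L) * h + r)
        }
      }
    }
  }
  lab
}

# Moore tracing with the direction-table rule: after a move in direction
# d (1=N clockwise to 8=NW), the next scan starts from the fixed backtrack
# direction bd[d] as seen from the new pixel.
oracle_perimeter <- function(mask) {
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  bd <- c(7L, 7L, 1L, 1L, 3L, 3L, 5L, 5L)
  h <- nrow(mask); w <- ncol(mask)
  lab <- oracle_components(mask)
  total <- 0
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    idx <- which(comp, arr.ind = TRUE)
    if (nrow(idx) == 1L) next
    ord <- order(idx[, 1L], idx[, 2L])
    sr <- idx[ord[1L], 1L]; sc <- idx[ord[1L], 2L]
    cur_r <- sr; cur_c <- sc
    scan_dir <- 7L  # west of the start pixel is background
    first_move <- NA_integer_
    guard <- 0L
    repeat {
      move <- NA_integer_
      for (s in 1:8) {
        d <- ((scan_dir + s - 1L) %% 8L) + 1L
        r <- cur_r + dr[d]; c <- cur_c + dc[d]
        if (r >= 1L && r <= h && c >= 1L && c <= w && comp[r, c]) {
          move <- d
          break
        }
      }
      if (is.na(move)) break
      if (!is.na(first_move) && cur_r == sr && cur_c == sc &&
          move == first_move)
        break
      if (is.na(first_move)) first_move <- move
      total <- total + if (dr[move] != 0L && dc[move] != 0L) sqrt(2) else 1
      cur_r <- cur_r + dr[move]; cur_c <- cur_c + dc[move]
      scan_dir <- bd[move]
      guard <- guard + 1L
      if (guard > 8L * nrow(idx) + 8L) stop("oracle tracer did not close")
    }
  }
  total
}

# greenness index straight from a signed Lab pixel table (the definition,
# written out once more without the package's intermediate functions)
oracle_greenness <- function(lab_table) {
  q <- lab_table[lab_table[, "a"] < 0 & lab_table[, "b"] > 0, , drop = FALSE]
  if (nrow(q) == 0L) return(NA_real_)
  atan(abs(mean(q[, "a"])) / mean(q[, "b"])) * (180 / pi) * 100 / 90
}
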