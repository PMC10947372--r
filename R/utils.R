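# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rbd <- function(...) stop(..., call. = FALSE)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_rbd(msg)
  invisible(TRUE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "seed must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Scanline rasterization of a simple polygon into an H x W logical mask.
# Pixel (row r, col c) represents the unit square [c-1, c) x [r-1, r);
# membership is decided at the pixel centre (c - 0.5, r - 0.5) by the
# even-odd rule.
rasterize_polygon <- function(poly, width, height) {
  poly <- as.matrix(poly)
  assert_that(ncol(poly) == 2 && nrow(poly) >= 3,
              "polygon must be a matrix of >= 3 (x, y) vertices")
  mask <- matrix(FALSE, nrow = height, ncol = width)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- length(xs)
  jj <- c(n, seq_len(n - 1L))
  for (r in seq_len(height)) {
    yc <- r - 0.5
    crossing <- (ys > yc) != (ys[jj] > yc)
    if (!any(crossing)) next
    xint <- xs[crossing] +
      (yc - ys[crossing]) / (ys[jj][crossing] - ys[crossing]) *
        (xs[jj][crossing] - xs[crossing])
    xint <- sort(xint)
    for (k in seq(1L, length(xint) - 1L, by = 2L)) {
      c0 <- max(1L, ceiling(xint[k] + 0.5))
      c1 <- min(width, floor(xint[k + 1L] + 0.5))
      if (c0 <= c1) mask[r, c0:c1] <- TRUE
    }
  }
  mask
}

# TRUE if any two non-adjacent edges of the polygon properly intersect.
polygon_self_intersects <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  seg <- function(i) rbind(poly[i, ], poly[if (i == n) 1L else i + 1L, ])
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  intersects <- function(p1, p2, p3, p4) {
    d1 <- cross2(p3, p4, p1); d2 <- cross2(p3, p4, p2)
    d3 <- cross2(p1, p2, p3); d4 <- cross2(p1, p2, p4)
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  if (n < 4) return(FALSE)
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next  # adjacent through closure
      s1 <- seg(i); s2 <- seg(j)
      if (intersects(s1[1, ], s1[2, ], s2[1, ], s2[2, ])) return(TRUE)
    }
  }
  FALSE
}

# Rectangle box c(x, y, w, h) -> logical H x W mask (clipped to frame).
box_mask <- function(box, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  c0 <- max(1L, floor(box[1]) + 1L)
  c1 <- min(width, floor(box[1] + box[3]))
  r0 <- max(1L, floor(box[2]) + 1L)
  r1 <- min(height, floor(box[2] + box[4]))
  if (c0 <= c1 && r0 <= r1) mask[r0:r1, c0:c1] <- TRUE
  mask
}
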