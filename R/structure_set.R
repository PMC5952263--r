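#' Planar structure set (z-ordered closed contours of one organ)
#'
#' A `structure_set` stores one named organ as a list of closed planar
#' polygons, each living on an axial plane at a stated z (mm). Polygons are
#' stored without repeating the first vertex; closure is implicit. Several
#' polygons may share one plane. Contours are kept sorted by z.
#'
#' @param name organ name (e.g. `"spinal_cord"`).
#' @param contours list of `list(z = <mm>, points = <n x 2 matrix of (x, y)
#'   mm>)`.
#' @param frame optional frame-of-reference label tying the contours to an
#'   image volume.
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(name, contours, frame = NULL) {
  if (length(contours) == 0) stop("no contours")
  contours <- lapply(contours, function(ct) {
    if (is.null(ct$z) || is.null(ct$points)) stop("each contour needs z and points")
    pts <- to_point_matrix(ct$points, ncol = 2L)
    # drop an explicitly repeated closing vertex
    n <- nrow(pts)
    if (n >= 2 && all(abs(pts[1, ] - pts[n, ]) < 1e-12)) pts <- pts[-n, , drop = FALSE]
    if (nrow(pts) < 3) stop("contour polygon has fewer than 3 vertices")
    if (polygon_area(pts) <= 1e-9) stop("contour polygon has zero area")
    out <- list(z = as.numeric(ct$z), points = pts)
    if (!is_simple_polygon(pts)) {
      warning("self-intersecting contour at z = ", ct$z, " flagged")
      out$simple <- FALSE
    }
    out
  })
  ord <- order(vapply(contours, `[[`, 0, "z"))
  structure(list(name = as.character(name), contours = contours[ord],
                 frame = frame),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  zs <- contour_zs(x)
  cat(sprintf("structure_set '%s': %d contour(s) on %d plane(s), z in [%.3g, %.3g] mm\n",
              x$name, length(x$contours), length(unique(zs)), min(zs), max(zs)))
  invisible(x)
}

is_structure_set <- function(x) inherits(x, "structure_set")

#' Contour plane positions
#' @param ss a [structure_set].
#' @return Numeric vector of z (mm), one entry per contour polygon.
#' @export
contour_zs <- function(ss) {
  vapply(ss$contours, `[[`, 0, "z")
}

# polygons (list of n x 2 matrices) on the plane nearest z within tol
slice_polygons <- function(ss, z, tol) {
  zs <- contour_zs(ss)
  keep <- abs(zs - z) <= tol
  lapply(ss$contours[keep], `[[`, "points")
}

#' Signed-area (shoelace) polygon measures
#'
#' `polygon_area` returns the absolute enclosed area of a closed polygon
#' given without a repeated first vertex; `polygon_centroid` its area
#' centroid.
#'
#' @param pts n x 2 matrix of vertices.
#' @return Area in mm^2, or centroid as length-2 vector (mm).
#' @export
polygon_area <- function(pts) {
  abs(polygon_area_signed(pts))
}

polygon_area_signed <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' @rdname polygon_area
#' @export
polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# O(n^2) segment-intersection test for polygon simplicity (small polygons).
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  if (n > 400) return(TRUE)  # skip the quadratic check for huge polygons
  seg <- cbind(pts, rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(FALSE)
    }
  }
  TRUE
}

#' Regular polygon approximation of a circle
#'
#' @param center length-2 (x, y) mm.
#' @param radius mm.
#' @param n number of vertices.
#' @return n x 2 vertex matrix (closed polygon, first vertex not repeated).
#' @export
circle_polygon <- function(center, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
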