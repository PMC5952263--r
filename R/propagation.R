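#' Propagate a structure set through a transform chain onto a target grid
#'
#' Every contour vertex (x, y, z) drawn on the chain's fixed frame is mapped
#' by [transform_point()]. Mapped vertices of one source polygon generally
#' leave their plane, so each mapped polygon is reassigned to the nearest
#' target slice plane (within half a slice spacing of its mean mapped z) and
#' its vertices are orthogonally projected onto that plane. When several
#' source polygons land on one target slice (e.g. 3 mm planning slices onto
#' 6 mm guidance slices) and overlap, their union is taken by radial
#' compositing about the common centroid (exact for star-shaped
#' cross-sections such as the cord); non-overlapping polygons are kept as
#' separate contours on the plane. Target slices with no mapped polygon are
#' left empty. Polygons degenerating to fewer than 3 distinct vertices or
#' to area below 1 mm^2 are dropped with a warning.
#'
#' @param ss a [structure_set] on the chain's fixed frame.
#' @param chain a [transform_chain].
#' @param target an [image_volume] giving the output slice planes.
#' @return A [structure_set] on the target frame.
#' @export
propagate_contours <- function(ss, chain, target) {
  if (!is_structure_set(ss)) stop("expected a 'structure_set'")
  stopifnot_volume(target)
  chain <- as_chain(chain)
  zs_target <- slice_positions(target)
  dz <- target$spacing[3]

  mapped <- list()
  n_dropped <- 0
  for (ct in ss$contours) {
    pts3 <- transform_point(chain, cbind(ct$points, ct$z))
    zbar <- mean(pts3[, 3])
    k <- which.min(abs(zs_target - zbar))
    if (abs(zs_target[k] - zbar) > dz / 2 + 1e-9) {
      n_dropped <- n_dropped + 1
      next
    }
    poly <- unique(round(pts3[, 1:2, drop = FALSE], 9))
    if (nrow(poly) < 3 || polygon_area(poly) < 1) {
      n_dropped <- n_dropped + 1
      next
    }
    mapped[[length(mapped) + 1]] <- list(slice = k, points = poly)
  }
  if (n_dropped > 0)
    warning(n_dropped, " mapped polygon(s) dropped (degenerate or outside ",
            "the target slice range)")
  if (length(mapped) == 0) stop("all propagated polygons were dropped")

  out <- list()
  for (k in sort(unique(vapply(mapped, `[[`, 0L, "slice")))) {
    polys <- lapply(mapped[vapply(mapped, `[[`, 0L, "slice") == k],
                    `[[`, "points")
    polys <- merge_coplanar_polygons(polys)
    for (p in polys)
      out[[length(out) + 1]] <- list(z = zs_target[k], points = p)
  }
  structure_set(ss$name, out, frame = attr(target, "frame_uid") %||% NULL)
}

# Merge overlapping coplanar polygons by radial compositing about their
# common area-weighted centroid; keep disjoint ones separate.
merge_coplanar_polygons <- function(polys, n_angles = 64) {
  if (length(polys) <= 1) return(polys)
  groups <- as.list(seq_along(polys))
  # union-find on bounding-box + vertex-in-polygon overlap
  overlaps <- function(a, b) {
    any(cpp_points_in_poly(a, b, 1e-9)) || any(cpp_points_in_poly(b, a, 1e-9))
  }
  merged <- TRUE
  while (merged && length(groups) > 1) {
    merged <- FALSE
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        hit <- any(vapply(groups[[i]], function(a)
          any(vapply(groups[[j]], function(b) overlaps(polys[[a]], polys[[b]]),
                     TRUE)), TRUE))
        if (hit) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }
  lapply(groups, function(g) {
    if (length(g) == 1) return(polys[[g]])
    radial_union(polys[g], n_angles)
  })
}

radial_union <- function(polys, n_angles = 64) {
  areas <- vapply(polys, polygon_area, 0)
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))
  center <- colSums(cents * areas) / sum(areas)
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  r <- rep(0, n_angles)
  for (poly in polys) {
    n <- nrow(poly)
    p1 <- poly
    p2 <- poly[c(2:n, 1), , drop = FALSE]
    for (a in seq_len(n_angles)) {
      dx <- cos(th[a]); dy <- sin(th[a])
      # ray center + t*(dx,dy) vs each edge p1 + s*(p2-p1)
      ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
      den <- dx * ey - dy * ex
      okd <- abs(den) > 1e-12
      tt <- ((p1[, 1] - center[1]) * ey - (p1[, 2] - center[2]) * ex) / den
      ss <- (dx * (p1[, 2] - center[2]) - dy * (p1[, 1] - center[1])) / -den
      hit <- okd & tt > 0 & ss >= -1e-9 & ss <= 1 + 1e-9
      if (any(hit)) r[a] <- max(r[a], max(tt[hit]))
    }
  }
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
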