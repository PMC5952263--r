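#' Slice-wise contour conformity metrics
#'
#' Compares two regions on one axial plane, each given as a polygon
#' (n x 2 matrix of mm vertices) or a list of disjoint polygons:
#'
#' * `conformity_index`: Jaccard ratio area(a intersect b) / area(a union b),
#'   between 0 and 1, equal to 1 iff the regions coincide.
#' * `distance_between_centres`: Euclidean in-plane distance (mm) between
#'   the area centroids.
#' * `distance_to_conformity`: mean, over rasterised pixels of the symmetric
#'   difference, of the distance (mm) to the nearest pixel of the
#'   intersection; 0 when the regions coincide. When the intersection is
#'   empty, distances are taken to the other region's pixels and the result
#'   is flagged with attribute `empty_intersection`.
#' * `dimension_differences`: signed test-minus-reference differences of the
#'   axis-aligned extents; x is the patient left-right axis and y the
#'   anterior-posterior axis (DICOM patient coordinates).
#'
#' Areas and centroids use exact polygon formulas (with Sutherland-Hodgman
#' clipping when both regions are single convex polygons); general shapes
#' and all distance-to-conformity computations fall back to rasterisation
#' at `pitch` (default 0.1 mm).
#'
#' @param a,b polygon (n x 2 matrix) or list of polygons; `a` is the test
#'   region, `b` the reference.
#' @param pitch raster pitch in mm.
#' @return A scalar (mm or dimensionless), or for `dimension_differences`
#'   a named vector `c(lr_diff, ap_diff)`.
#' @name conformity_metrics
NULL

as_region <- function(x) {
  if (is.matrix(x)) list(x)
  else if (is.list(x) && length(x) > 0 && all(vapply(x, is.matrix, TRUE))) x
  else stop("expected a polygon matrix or a non-empty list of them")
}

region_area <- function(r) sum(vapply(r, polygon_area, 0))

is_convex_polygon <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  nx2 <- nxt[nxt]
  cr <- (pts[nxt, 1] - pts[, 1]) * (pts[nx2, 2] - pts[nxt, 2]) -
        (pts[nxt, 2] - pts[, 2]) * (pts[nx2, 1] - pts[nxt, 1])
  all(cr >= -1e-9) || all(cr <= 1e-9)
}

# Sutherland-Hodgman clip of polygon `subject` by convex polygon `clip`.
convex_clip <- function(subject, clip) {
  if (polygon_area_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), ]
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]
    b <- clip[if (i == n) 1 else i + 1, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    side <- function(p) ex * (p[2] - a[2]) - ey * (p[1] - a[1])
    inp <- out
    m <- nrow(inp)
    keep <- matrix(0, 0, 2)
    sides <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])
    for (j in seq_len(m)) {
      k <- if (j == m) 1 else j + 1
      cur <- inp[j, ]; nxt <- inp[k, ]
      sc <- sides[j]; sn <- sides[k]
      if (sc >= -1e-12) keep <- rbind(keep, cur)
      if ((sc >= -1e-12) != (sn >= -1e-12)) {
        t <- sc / (sc - sn)
        keep <- rbind(keep, cur + t * (nxt - cur))
      }
    }
    out <- keep
  }
  out
}

region_bbox <- function(r) {
  allp <- do.call(rbind, r)
  c(min(allp[, 1]), max(allp[, 1]), min(allp[, 2]), max(allp[, 2]))
}

# raster both regions on a common grid of cell centres; returns logical
# matrices plus the centre coordinates
raster_pair <- function(a, b, pitch) {
  bb_a <- region_bbox(a); bb_b <- region_bbox(b)
  lo <- c(min(bb_a[1], bb_b[1]), min(bb_a[3], bb_b[3])) - pitch
  hi <- c(max(bb_a[2], bb_b[2]), max(bb_a[4], bb_b[4])) + pitch
  xs <- seq(lo[1] + pitch / 2, hi[1], by = pitch)
  ys <- seq(lo[2] + pitch / 2, hi[2], by = pitch)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  rasterise <- function(region) {
    m <- rep(FALSE, nrow(grid))
    for (poly in region) {
      bb <- region_bbox(list(poly))
      cand <- grid[, 1] >= bb[1] - pitch & grid[, 1] <= bb[2] + pitch &
              grid[, 2] >= bb[3] - pitch & grid[, 2] <= bb[4] + pitch
      if (any(cand))
        m[cand] <- m[cand] | cpp_points_in_poly(grid[cand, , drop = FALSE],
                                                poly, 1e-9)
    }
    m
  }
  list(a = rasterise(a), b = rasterise(b), grid = grid,
       nx = length(xs), ny = length(ys))
}

#' @rdname conformity_metrics
#' @export
conformity_index <- function(a, b, pitch = 0.1) {
  a <- as_region(a); b <- as_region(b)
  if (length(a) == 1 && length(b) == 1 &&
      is_convex_polygon(a[[1]]) && is_convex_polygon(b[[1]])) {
    inter <- convex_clip(a[[1]], b[[1]])
    ia <- if (nrow(inter) >= 3) polygon_area(inter) else 0
    u <- polygon_area(a[[1]]) + polygon_area(b[[1]]) - ia
    return(if (u > 0) ia / u else 0)
  }
  r <- raster_pair(a, b, pitch)
  u <- sum(r$a | r$b)
  if (u == 0) return(0)
  sum(r$a & r$b) / u
}

#' @rdname conformity_metrics
#' @export
distance_between_centres <- function(a, b, pitch = 0.1) {
  a <- as_region(a); b <- as_region(b)
  cent <- function(region) {
    if (length(region) == 1) return(polygon_centroid(region[[1]]))
    w <- vapply(region, polygon_area, 0)
    colSums(t(vapply(region, polygon_centroid, numeric(2))) * w) / sum(w)
  }
  sqrt(sum((cent(a) - cent(b))^2))
}

#' @rdname conformity_metrics
#' @export
distance_to_conformity <- function(a, b, pitch = 0.1) {
  a <- as_region(a); b <- as_region(b)
  r <- raster_pair(a, b, pitch)
  inter <- r$a & r$b
  sym <- (r$a | r$b) & !inter
  if (!any(sym)) return(0)
  sym_pts <- r$grid[sym, , drop = FALSE]
  if (any(inter)) {
    bnd <- raster_boundary(inter, r$nx, r$ny)
    d <- cpp_nearest_dist(sym_pts, r$grid[bnd, , drop = FALSE])
    return(mean(d))
  }
  # disjoint regions: measure each side to the other region, flagged
  da <- cpp_nearest_dist(r$grid[r$a, , drop = FALSE], r$grid[r$b, , drop = FALSE])
  db <- cpp_nearest_dist(r$grid[r$b, , drop = FALSE], r$grid[r$a, , drop = FALSE])
  structure(mean(c(da, db)), empty_intersection = TRUE)
}

# pixels of `mask` (logical vector over an nx x ny grid) with at least one
# 4-neighbour outside the mask
raster_boundary <- function(mask, nx, ny) {
  m <- matrix(mask, nx, ny)
  inner <- m
  inner[] <- FALSE
  if (nx > 2 && ny > 2)
    inner[2:(nx - 1), 2:(ny - 1)] <-
      m[2:(nx - 1), 2:(ny - 1)] &
      m[1:(nx - 2), 2:(ny - 1)] & m[3:nx, 2:(ny - 1)] &
      m[2:(nx - 1), 1:(ny - 2)] & m[2:(nx - 1), 3:ny]
  as.vector(m & !inner)
}

#' @rdname conformity_metrics
#' @export
dimension_differences <- function(a, b) {
  a <- as_region(a); b <- as_region(b)
  ba <- region_bbox(a); bb <- region_bbox(b)
  c(lr_diff = (ba[2] - ba[1]) - (bb[2] - bb[1]),
    ap_diff = (ba[4] - ba[3]) - (bb[4] - bb[3]))
}

#' Slice-by-slice comparison of two structure sets
#'
#' Slice planes are matched by nearest z within `z_tol` (default half the
#' smallest slice gap present); each matched pair of planes yields one
#' record with all five conformity metrics, `test` playing the test role
#' for the signed dimension differences. Planes where only one set has a
#' contour are excluded from the paired metrics and reported in the
#' `unmatched` attribute.
#'
#' @param test,reference [structure_set]s on a common frame.
#' @param z_tol plane-matching tolerance (mm).
#' @param pitch raster pitch (mm) passed to the metrics.
#' @return A data.frame with columns `z, ci, dtc, dbc, lr_diff, ap_diff`
#'   and attribute `unmatched` (data.frame of z and side).
#' @export
compare_structure_sets <- function(test, reference, z_tol = NULL,
                                   pitch = 0.1) {
  if (!is_structure_set(test) || !is_structure_set(reference))
    stop("expected structure_sets")
  zt <- sort(unique(round(contour_zs(test), 6)))
  zr <- sort(unique(round(contour_zs(reference), 6)))
  if (is.null(z_tol)) {
    gaps <- c(diff(zt), diff(zr))
    z_tol <- if (length(gaps)) min(gaps) / 2 else 0.5
  }
  used_t <- rep(FALSE, length(zt))
  rows <- list()
  unmatched <- list()
  for (z in zr) {
    cand <- which(!used_t & abs(zt - z) <= z_tol)
    if (length(cand) == 0) {
      unmatched[[length(unmatched) + 1]] <- data.frame(z = z, side = "reference")
      next
    }
    k <- cand[which.min(abs(zt[cand] - z))]
    used_t[k] <- TRUE
    a <- slice_polygons(test, zt[k], 1e-6)
    b <- slice_polygons(reference, z, 1e-6)
    dd <- dimension_differences(a, b)
    rows[[length(rows) + 1]] <- data.frame(
      z = z,
      ci = conformity_index(a, b, pitch),
      dtc = as.numeric(distance_to_conformity(a, b, pitch)),
      dbc = distance_between_centres(a, b, pitch),
      lr_diff = dd[["lr_diff"]],
      ap_diff = dd[["ap_diff"]])
  }
  for (z in zt[!used_t])
    unmatched[[length(unmatched) + 1]] <- data.frame(z = z, side = "test")
  if (length(rows) == 0)
    stop("zero matched slices between the structure sets")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unmatched") <- if (length(unmatched))
    do.call(rbind, unmatched) else data.frame(z = numeric(0), side = character(0))
  out
}

#' Aggregate per-slice conformity records
#'
#' Per metric: median, mean, sample standard deviation, the statistical
#' uncertainty on the mean (sd / sqrt(n)) and on the median (standard
#' deviation of a seeded bootstrap of medians).
#'
#' @param records data.frame from [compare_structure_sets()] (possibly
#'   several, row-bound).
#' @param bootstrap number of bootstrap resamples for the median
#'   uncertainty.
#' @param seed RNG seed for the bootstrap.
#' @return A data.frame with one row per metric; columns `metric, n,
#'   median, mean, sd, se_mean, se_median`. With a single record the sd and
#'   uncertainties are `NA`.
#' @export
aggregate_conformity <- function(records, bootstrap = 2000, seed = 1) {
  if (is.null(records) || nrow(records) == 0) stop("no records to aggregate")
  metrics <- c("ci", "dtc", "dbc", "lr_diff", "ap_diff")
  rows <- lapply(metrics, function(m) {
    v <- records[[m]]
    n <- length(v)
    if (n > 1) {
      se_med <- with_seed(seed, {
        meds <- vapply(seq_len(bootstrap), function(i)
          median(sample(v, n, replace = TRUE)), 0)
        sd(meds)
      })
      data.frame(metric = m, n = n, median = median(v), mean = mean(v),
                 sd = sd(v), se_mean = sd(v) / sqrt(n), se_median = se_med)
    } else {
      data.frame(metric = m, n = n, median = v, mean = v,
                 sd = NA_real_, se_mean = NA_real_, se_median = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-observer conformity analysis
#'
#' Compares the contours from each observer with those from every other
#' observer: all N(N-1)/2 unordered pairs are evaluated (15 pairs for six
#' observers). Symmetric metrics (CI, DTC, DBC) are computed once per pair;
#' the signed dimension differences use each ordered orientation. Each
#' observer's summary is the mean of their N-1 pairwise mean values per
#' metric; the overall best estimate is the mean over all pairs. Observers
#' with no overlapping slices against anyone are excluded with a warning.
#'
#' @param contour_sets list of [structure_set]s, one per observer.
#' @param pitch raster pitch (mm).
#' @return List with `pairwise` (one row per unordered pair, slice-mean
#'   metrics), `per_observer` (mean over that observer's comparisons) and
#'   `overall` (mean over all pairs).
#' @export
interobserver_analysis <- function(contour_sets, pitch = 0.1) {
  n <- length(contour_sets)
  if (n < 2) stop("need at least 2 observers")
  if (is.null(names(contour_sets)))
    names(contour_sets) <- paste0("observer", seq_len(n))
  pair_rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rec <- tryCatch(
        compare_structure_sets(contour_sets[[i]], contour_sets[[j]],
                               pitch = pitch),
        error = function(e) NULL)
      if (is.null(rec)) next
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        a = names(contour_sets)[i], b = names(contour_sets)[j],
        n_slices = nrow(rec),
        ci = mean(rec$ci), dtc = mean(rec$dtc), dbc = mean(rec$dbc),
        lr_diff_ab = mean(rec$lr_diff), ap_diff_ab = mean(rec$ap_diff))
    }
  }
  if (length(pair_rows) == 0) stop("no observer pair has overlapping slices")
  pairwise <- do.call(rbind, pair_rows)
  per_obs <- lapply(names(contour_sets), function(o) {
    rows_a <- pairwise[pairwise$a == o, , drop = FALSE]
    rows_b <- pairwise[pairwise$b == o, , drop = FALSE]
    k <- nrow(rows_a) + nrow(rows_b)
    if (k == 0) return(NULL)
    data.frame(observer = o, n_comparisons = k,
               ci = mean(c(rows_a$ci, rows_b$ci)),
               dtc = mean(c(rows_a$dtc, rows_b$dtc)),
               dbc = mean(c(rows_a$dbc, rows_b$dbc)),
               lr_diff = mean(c(rows_a$lr_diff_ab, -rows_b$lr_diff_ab)),
               ap_diff = mean(c(rows_a$ap_diff_ab, -rows_b$ap_diff_ab)))
  })
  dropped <- names(contour_sets)[vapply(per_obs, is.null, TRUE)]
  if (length(dropped))
    warning("observers excluded (no overlapping slices): ",
            paste(dropped, collapse = ", "))
  per_observer <- do.call(rbind, per_obs[!vapply(per_obs, is.null, TRUE)])
  overall <- data.frame(n_pairs = nrow(pairwise),
                        ci = mean(pairwise$ci), dtc = mean(pairwise$dtc),
                        dbc = mean(pairwise$dbc))
  list(pairwise = pairwise, per_observer = per_observer, overall = overall)
}
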