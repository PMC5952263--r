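#' Cord voxels of a planning volume enclosed by a structure set
#'
#' Selects voxels of `frame` whose in-plane centre lies inside (or exactly
#' on the boundary of: closed-region rule) a contour polygon on the
#' matching slice (|dz| <= dz/2).
#'
#' @param structure a [structure_set] on the frame.
#' @param frame an [image_volume] (planning kVCT).
#' @return A data.frame with 0-based voxel indices `i, j, k` and mm centres
#'   `x, y, z`.
#' @export
cord_voxels <- function(structure, frame) {
  if (!is_structure_set(structure)) stop("expected a 'structure_set'")
  stopifnot_volume(frame)
  d <- dim(frame$voxels)
  zs <- slice_positions(frame)
  dz <- frame$spacing[3]
  xs <- frame$origin[1] + (seq_len(d[1]) - 1) * frame$spacing[1]
  ys <- frame$origin[2] + (seq_len(d[2]) - 1) * frame$spacing[2]
  rows <- list()
  czs <- contour_zs(structure)
  small <- FALSE
  for (k in seq_along(zs)) {
    sel <- abs(czs - zs[k]) <= dz / 2 + 1e-9
    if (!any(sel)) next
    polys <- lapply(structure$contours[sel], `[[`, "points")
    bb <- region_bbox(polys)
    ix <- which(xs >= bb[1] - 1e-9 & xs <= bb[2] + 1e-9)
    iy <- which(ys >= bb[3] - 1e-9 & ys <= bb[4] + 1e-9)
    if (length(ix) == 0 || length(iy) == 0) {
      small <- TRUE
      next
    }
    grid <- cbind(rep(xs[ix], times = length(iy)),
                  rep(ys[iy], each = length(ix)))
    inside <- rep(FALSE, nrow(grid))
    for (p in polys)
      inside <- inside | cpp_points_in_poly(grid, p, 1e-9)
    if (!any(inside)) {
      small <- TRUE
      next
    }
    gi <- rep(ix, times = length(iy))[inside]
    gj <- rep(iy, each = length(ix))[inside]
    rows[[length(rows) + 1]] <- data.frame(
      i = gi - 1L, j = gj - 1L, k = k - 1L,
      x = xs[gi], y = ys[gj], z = zs[k])
  }
  if (small)
    warning("some contours enclose no voxel centre (smaller than one voxel)")
  if (length(rows) == 0) stop("no voxels inside the structure")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accumulate per-fraction delivered dose to planning-frame voxels
#'
#' Each planning voxel centre is mapped into every fraction's guidance
#' frame by that fraction's registration transform (with any recorded
#' post-imaging couch shift composed after it), the fraction's dose grid is
#' sampled there by trilinear interpolation, and the samples are summed.
#' Voxels whose mapped position falls outside any fraction's dose grid are
#' flagged not covered and excluded from summaries: only the region covered
#' by all fractions is considered. Out-of-grid samples are never
#' zero-filled.
#'
#' @param voxels data.frame from [cord_voxels()].
#' @param transforms list of [transform_chain]s, one per fraction, mapping
#'   planning-frame points to that fraction's frame.
#' @param grids list of [image_volume]s of per-fraction dose (Gy), one per
#'   fraction.
#' @param couch_shifts optional list (or n x 3 matrix) of per-fraction
#'   post-imaging couch shifts (mm), composed after each registration
#'   transform.
#' @return A `delivered_dose_map`: the voxel data.frame extended with
#'   `dose` (Gy, sum over fractions of the sampled dose), `coverage`
#'   (number of fractions covering the voxel) and logical `included`
#'   (covered by all fractions); the fraction count is kept in attribute
#'   `n_fractions`.
#' @export
accumulate_dose <- function(voxels, transforms, grids, couch_shifts = NULL) {
  nfrac <- length(grids)
  if (length(transforms) != nfrac)
    stop("mismatched fraction counts: ", length(transforms), " transforms vs ",
         nfrac, " dose grids")
  if (nfrac == 0) stop("no fractions")
  if (!is.null(couch_shifts)) {
    if (is.matrix(couch_shifts)) {
      couch_shifts <- lapply(seq_len(nrow(couch_shifts)),
                             function(i) couch_shifts[i, ])
    }
    if (length(couch_shifts) != nfrac)
      stop("mismatched fraction counts: couch shifts")
  }
  pts <- as.matrix(voxels[, c("x", "y", "z")])
  total <- numeric(nrow(pts))
  coverage <- integer(nrow(pts))
  for (f in seq_len(nfrac)) {
    chain <- as_chain(transforms[[f]])
    if (!is.null(couch_shifts))
      chain <- compose_chains(chain, couch_shift_transform(couch_shifts[[f]]))
    mapped <- transform_point(chain, pts)
    s <- sample_volume(grids[[f]], mapped)
    hit <- s$inside
    total[hit] <- total[hit] + s$values[hit]
    coverage <- coverage + as.integer(hit)
  }
  out <- voxels
  out$dose <- ifelse(coverage > 0, total, NA_real_)
  out$coverage <- coverage
  out$included <- coverage == nfrac
  attr(out, "n_fractions") <- nfrac
  class(out) <- c("delivered_dose_map", class(out))
  out
}

#' Dose-volume summary with near-maximum dose D2%
#'
#' The near-maximum dose D2% is the minimum dose to the 2% of the organ
#' volume where dose is highest; with n equal-volume voxels it is the
#' smallest dose among the ceiling(0.02 n) highest-dose voxels. The
#' cumulative DVH is tabulated on a 0.1 Gy grid. A DVH-interpolated D2%
#' variant is available via `interpolate = TRUE`.
#'
#' @param doses a `delivered_dose_map` (only voxels flagged `included` are
#'   used) or a bare numeric vector of per-voxel doses (Gy, equal voxel
#'   volumes).
#' @param percent the near-maximum percentile (default 2).
#' @param dvh_step DVH dose grid step (Gy).
#' @param interpolate if `TRUE`, compute D\eqn{p}\% by linear interpolation
#'   of the sorted dose quantile instead of the voxel-count rule.
#' @return A list of class `dose_summary`: `d2`, `mean`, `max`, `n_voxels`
#'   and data.frame `dvh` (`dose`, `volume_fraction`, monotone
#'   non-increasing).
#' @export
dvh_summary <- function(doses, percent = 2, dvh_step = 0.1,
                        interpolate = FALSE) {
  if (inherits(doses, "delivered_dose_map"))
    doses <- doses$dose[doses$included]
  doses <- as.numeric(doses)
  doses <- doses[is.finite(doses)]
  n <- length(doses)
  if (n == 0) stop("zero included voxels")
  srt <- sort(doses, decreasing = TRUE)
  d2 <- if (interpolate) {
    as.numeric(quantile(doses, probs = 1 - percent / 100, type = 7))
  } else {
    srt[ceiling(percent / 100 * n)]
  }
  grid <- seq(0, max(doses) + dvh_step, by = dvh_step)
  vf <- vapply(grid, function(g) mean(doses >= g), 0)
  structure(list(d2 = d2, mean = mean(doses), max = max(doses),
                 n_voxels = n,
                 dvh = data.frame(dose = grid, volume_fraction = vf)),
            class = "dose_summary")
}

#' @export
print.dose_summary <- function(x, ...) {
  cat(sprintf("dose_summary: n = %d voxels, mean %.3f Gy, max %.3f Gy, D2%% %.3f Gy\n",
              x$n_voxels, x$mean, x$max, x$d2))
  invisible(x)
}

#' Planned-versus-delivered near-maximum dose comparison
#'
#' For a single patient, returns the signed difference delivered - planned
#' of D2%. For a cohort of such differences, `summarise_d2_differences`
#' reports how many patients were delivered more/less than planned and the
#' mean excess and deficit.
#'
#' @param planned,delivered `dose_summary` objects.
#' @return `planned_vs_delivered`: a one-row data.frame with `planned_d2`,
#'   `delivered_d2`, `delta` (Gy).
#' @export
planned_vs_delivered <- function(planned, delivered) {
  if (!inherits(planned, "dose_summary") || !inherits(delivered, "dose_summary"))
    stop("expected dose_summary objects")
  data.frame(planned_d2 = planned$d2, delivered_d2 = delivered$d2,
             delta = delivered$d2 - planned$d2)
}

#' @rdname planned_vs_delivered
#' @param deltas numeric vector of per-patient delivered - planned D2%
#'   differences (Gy).
#' @export
summarise_d2_differences <- function(deltas) {
  deltas <- as.numeric(deltas)
  higher <- deltas[deltas > 0]
  lower <- deltas[deltas < 0]
  data.frame(n = length(deltas),
             n_higher = length(higher),
             mean_excess = if (length(higher)) mean(higher) else NA_real_,
             n_lower = length(lower),
             mean_deficit = if (length(lower)) mean(-lower) else NA_real_)
}
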