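#' Synthetic neck phantom specification
#'
#' Describes a neck-like planning (kVCT-style) volume — an elliptical soft
#' tissue body containing an air passage, a segmented vertebral ring (bone
#' interrupted by disc levels along z) around a CSF-filled spinal canal and
#' a cylindrical cord — with a detached treatment couch slab, plus
#' guidance (MVCT-style) fractions produced from it by a known rigid +
#' smooth B-spline deformation, resampling onto a finer in-plane / coarser
#' axial grid, and added Gaussian noise. Defaults use the archival planning
#' voxel size 2.148 x 2.148 x 3.000 mm and the guidance voxel size
#' 0.754 x 0.754 x 6.000 mm.
#'
#' @param kvct_dim,kvct_spacing planning grid (voxels, mm).
#' @param mvct_dim,mvct_spacing guidance grid (voxels, mm).
#' @param body_semiaxes in-plane body ellipse semi-axes (mm).
#' @param cord_center,cord_radius cord cylinder centre (x, y mm) and radius
#'   (mm).
#' @param canal_radius,ring_outer spinal canal and vertebral ring outer
#'   radii (mm).
#' @param airway_center,airway_radius air passage centre and mean radius
#'   (mm).
#' @param hu named HU levels of the tissue classes.
#' @param vertebra_period vertebral segmentation period along z (mm): ring
#'   HU oscillates smoothly between bone and disc levels with this period.
#' @param couch_y,couch_halfwidth couch slab y-range and half width (mm).
#' @param deform_translation mean per-fraction rigid shift (mm).
#' @param translation_jitter_sd per-fraction shift variability (mm, per
#'   axis).
#' @param deform_max peak B-spline displacement magnitude (mm); 0 disables
#'   the nonrigid component. Must stay below 0.4 x `deform_spacing` so the
#'   ground-truth deformation remains invertible.
#' @param deform_spacing knot spacing (mm) of the ground-truth displacement
#'   field.
#' @param couch_error_sd accuracy (mm sd) of the recorded radiographer
#'   couch shift relative to the true rigid component.
#' @param texture_amp,texture_scale amplitude (HU sd) and correlation
#'   length (mm) of the smooth soft-tissue texture field fixed to the
#'   anatomy (it deforms with the ground-truth warp, as real tissue
#'   heterogeneity does).
#' @param noise_sd_kvct,noise_sd_mvct additive Gaussian intensity noise
#'   (HU).
#' @param dose_peak,dose_sigma per-fraction dose model: peak dose (Gy) on
#'   the deformed cord axis and transverse Gaussian falloff scale (mm).
#' @param contour_vertices vertices per cord contour circle.
#' @param seed master RNG seed; fixed seed gives bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(kvct_dim = c(72, 72, 32),
                         kvct_spacing = c(2.148, 2.148, 3.0),
                         mvct_dim = c(176, 176, 14),
                         mvct_spacing = c(0.754, 0.754, 6.0),
                         body_semiaxes = c(55, 45),
                         cord_center = c(0, 15),
                         cord_radius = 4,
                         canal_radius = 8,
                         ring_outer = 14,
                         airway_center = c(0, -25),
                         airway_radius = 6,
                         hu = c(air = -1000, tissue = 40, cord = 45,
                                csf = 15, bone = 700, disc = 150,
                                airway = -800, couch = 200),
                         vertebra_period = 24,
                         couch_y = c(48, 58),
                         couch_halfwidth = 65,
                         deform_translation = c(3, -2, 4),
                         translation_jitter_sd = 1,
                         deform_max = 4,
                         deform_spacing = 30,
                         couch_error_sd = 0.5,
                         texture_amp = 30,
                         texture_scale = 12,
                         noise_sd_kvct = 5,
                         noise_sd_mvct = 20,
                         dose_peak = 1.1,
                         dose_sigma = 20,
                         contour_vertices = 64,
                         seed = 1) {
  spec <- as.list(environment())
  if (any(spec$kvct_spacing <= 0) || any(spec$mvct_spacing <= 0))
    stop("spacings must be positive")
  if (spec$cord_radius <= 0 || spec$canal_radius <= spec$cord_radius ||
      spec$ring_outer <= spec$canal_radius)
    stop("need cord_radius < canal_radius < ring_outer")
  lim <- sqrt(sum((spec$cord_center / spec$body_semiaxes)^2))
  if (lim + spec$ring_outer / min(spec$body_semiaxes) >= 1)
    stop("cord/vertebra outside the body ellipse")
  if (spec$deform_max > 0.4 * spec$deform_spacing)
    stop("deform_max too large for deform_spacing: ground-truth field may ",
         "not be invertible")
  class(spec) <- "phantom_spec"
  spec
}

# analytic HU at mm coordinates (vectorised)
phantom_hu <- function(x, y, z, spec) {
  zmax <- (spec$kvct_dim[3] - 1) * spec$kvct_spacing[3]
  zmid <- zmax / 2
  taper <- 1 - 0.1 * ((z - zmid) / zmid)^2
  a <- spec$body_semiaxes[1] * taper
  b <- spec$body_semiaxes[2] * taper
  hu <- rep(spec$hu[["air"]], length(x))
  body <- (x / a)^2 + (y / b)^2 <= 1
  hu[body] <- spec$hu[["tissue"]]
  r_air <- spec$airway_radius + 2 * sin(2 * pi * z / 60)
  airway <- body &
    (x - spec$airway_center[1])^2 + (y - spec$airway_center[2])^2 <= r_air^2
  hu[airway] <- spec$hu[["airway"]]
  r2 <- (x - spec$cord_center[1])^2 + (y - spec$cord_center[2])^2
  ring <- body & r2 <= spec$ring_outer^2 & r2 > spec$canal_radius^2
  # smooth bone/disc alternation along z: a raised cosine rather than a hard
  # switch, so the axial structure survives the coarse guidance-grid
  # sampling without phase distortion
  ringval <- spec$hu[["disc"]] + (spec$hu[["bone"]] - spec$hu[["disc"]]) *
    (0.5 + 0.5 * cos(2 * pi * z / spec$vertebra_period))
  hu[ring] <- ringval[ring]
  canal <- body & r2 <= spec$canal_radius^2
  hu[canal] <- spec$hu[["csf"]]
  hu[body & r2 <= spec$cord_radius^2] <- spec$hu[["cord"]]
  couch <- !body & y >= spec$couch_y[1] & y <= spec$couch_y[2] &
    abs(x) <= spec$couch_halfwidth
  hu[couch] <- spec$hu[["couch"]]
  hu
}

#' Generate the planning-side phantom
#'
#' Rasterises the analytic phantom geometry onto the planning grid. The
#' planning volume is produced by block-averaging a 2x finer lattice,
#' emulating archival down-sampling of the planning scan, then adding
#' Gaussian noise. Cord contours are exact circles sampled at
#' `spec$contour_vertices` vertices on every planning slice, and the truth
#' body mask is the analytic body region.
#'
#' @param spec a [phantom_spec].
#' @return A list of class `phantom` with `kvct` ([image_volume]), `cord`
#'   ([structure_set]), `mask_truth` (`binary_mask`) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec")
  d <- spec$kvct_dim
  sp <- spec$kvct_spacing
  origin <- c(-(d[1] - 1) * sp[1] / 2, -(d[2] - 1) * sp[2] / 2, 0)
  # 2x finer lattice whose 2x2x2 blocks average to the planning voxels
  fine_sp <- sp / 2
  fine_origin <- origin - sp / 4
  fd <- d * 2L
  xs <- fine_origin[1] + (seq_len(fd[1]) - 1) * fine_sp[1]
  ys <- fine_origin[2] + (seq_len(fd[2]) - 1) * fine_sp[2]
  zs <- fine_origin[3] + (seq_len(fd[3]) - 1) * fine_sp[3]
  gx <- rep(xs, times = fd[2] * fd[3])
  gy <- rep(rep(ys, each = fd[1]), times = fd[3])
  gz <- rep(zs, each = fd[1] * fd[2])
  fine <- phantom_hu(gx, gy, gz, spec)
  if (spec$texture_amp > 0) {
    # smooth soft-tissue heterogeneity: trilinear interpolation of a seeded
    # coarse random grid (correlation length ~ texture_scale); applied only
    # where the base class is plain tissue so organ contrasts are untouched
    tdim <- as.integer(ceiling((fd * fine_sp) / spec$texture_scale) + 2L)
    torigin <- fine_origin - spec$texture_scale
    tex_coarse <- with_seed(spec$seed + 1L,
                            rnorm(prod(tdim), 0, spec$texture_amp))
    tex <- cpp_trilinear(tex_coarse, tdim, rep(spec$texture_scale, 3),
                         torigin, cbind(gx, gy, gz), FALSE)$values
    soft <- fine == spec$hu[["tissue"]]
    fine[soft] <- fine[soft] + tex[soft]
  }
  avg <- cpp_block_average(fine, fd, c(2L, 2L, 2L))
  vox <- array(avg$values, dim = d)
  if (spec$noise_sd_kvct > 0)
    vox <- vox + with_seed(spec$seed,
                           array(rnorm(prod(d), 0, spec$noise_sd_kvct), dim = d))
  kvct <- image_volume(vox, sp, origin)

  slice_z <- origin[3] + (seq_len(d[3]) - 1) * sp[3]
  contours <- lapply(slice_z, function(z)
    list(z = z, points = circle_polygon(spec$cord_center, spec$cord_radius,
                                        spec$contour_vertices)))
  cord <- structure_set("spinal_cord", contours)

  cx <- kvct$origin[1] + (seq_len(d[1]) - 1) * sp[1]
  cy <- kvct$origin[2] + (seq_len(d[2]) - 1) * sp[2]
  cz <- slice_z
  bx <- rep(cx, times = d[2] * d[3])
  by <- rep(rep(cy, each = d[1]), times = d[3])
  bz <- rep(cz, each = d[1] * d[2])
  zmid <- (d[3] - 1) * sp[3] / 2
  taper <- 1 - 0.1 * ((bz - zmid) / zmid)^2
  body <- (bx / (spec$body_semiaxes[1] * taper))^2 +
    (by / (spec$body_semiaxes[2] * taper))^2 <= 1
  mask_truth <- structure(list(voxels = array(body, dim = d), spacing = sp,
                               origin = origin),
                          class = "binary_mask")
  structure(list(kvct = kvct, cord = cord, mask_truth = mask_truth,
                 spec = spec),
            class = "phantom")
}

# Seeded ground-truth deformation for one fraction: rigid shift plus a
# smooth B-spline field scaled to the requested peak displacement.
phantom_truth_chain <- function(phantom, fraction_index) {
  spec <- phantom$spec
  seed <- spec$seed + 7919L * as.integer(fraction_index)
  with_seed(seed, {
    shift <- spec$deform_translation + rnorm(3, 0, spec$translation_jitter_sd)
    stages <- list(translation_transform(shift))
    if (spec$deform_max > 0) {
      d <- dim(phantom$kvct$voxels)
      lo <- phantom$kvct$origin
      hi <- phantom$kvct$origin + (d - 1) * phantom$kvct$spacing
      grid <- bspline_grid_covering(lo, hi, spec$deform_spacing)
      coef <- array(rnorm(prod(grid$dim) * 3), dim = c(grid$dim, 3))
      # zero the outermost shells so the field decays to identity at the edge
      coef[c(1, dim(coef)[1]), , , ] <- 0
      coef[, c(1, dim(coef)[2]), , ] <- 0
      coef[, , c(1, dim(coef)[3]), ] <- 0
      st <- bspline_transform(grid$origin, grid$spacing, grid$dim,
                              as.numeric(coef))
      # scale so the peak displacement magnitude equals deform_max
      probe <- voxel_center_grid(phantom$kvct)
      probe <- probe[seq(1, nrow(probe), by = 17), , drop = FALSE]
      disp <- cpp_apply_chain(probe, list(st)) - probe
      peak <- max(sqrt(rowSums(disp^2)))
      st$params <- st$params * (spec$deform_max / peak)
      stages <- c(stages, list(st))
    }
    transform_chain(stages)
  })
}

#' Generate one guidance fraction from a phantom
#'
#' Builds the fraction's ground-truth deformation (planning frame to
#' guidance frame), resamples the planning volume through its numerical
#' inverse onto the guidance grid, adds Gaussian noise, maps the cord
#' contours by the exact ground-truth chain, and evaluates the analytic
#' per-fraction dose model (Gaussian transverse falloff about the deformed
#' cord axis) on the guidance grid. A recorded radiographer couch shift —
#' the true rigid component plus a small seeded error — is attached for
#' couch-shift registration strategies.
#'
#' @param phantom result of [generate_phantom()].
#' @param fraction_index 1-based fraction number (drives the per-fraction
#'   seed).
#' @param deformation optional [transform_chain] overriding the generated
#'   ground-truth deformation.
#' @return A list of class `phantom_fraction`: `mvct`, `truth_chain`,
#'   `truth_contours`, `dose` ([image_volume], Gy), `couch_shift`
#'   (length-3 mm) and `fraction_index`.
#' @export
generate_fraction <- function(phantom, fraction_index = 1,
                              deformation = NULL) {
  if (!inherits(phantom, "phantom")) stop("expected a phantom")
  spec <- phantom$spec
  truth <- if (is.null(deformation)) phantom_truth_chain(phantom, fraction_index)
           else as_chain(deformation)

  d <- spec$mvct_dim
  sp <- spec$mvct_spacing
  kd <- dim(phantom$kvct$voxels)
  kz <- (kd[3] - 1) * phantom$kvct$spacing[3]
  origin <- c(-(d[1] - 1) * sp[1] / 2, -(d[2] - 1) * sp[2] / 2,
              (kz - (d[3] - 1) * sp[3]) / 2)
  target <- image_volume(array(0, dim = d), sp, origin)

  pts <- voxel_center_grid(target)
  src <- if (length(truth) > 0) {
    inv <- cpp_invert_chain(pts, unclass(truth), 60L, 1e-9)
    inv$points
  } else pts
  s <- cpp_trilinear(as.numeric(phantom$kvct$voxels), kd,
                     phantom$kvct$spacing, phantom$kvct$origin, src, FALSE)
  v <- s$values
  v[!s$inside] <- spec$hu[["air"]]
  seed <- spec$seed + 7919L * as.integer(fraction_index) + 13L
  if (spec$noise_sd_mvct > 0)
    v <- v + with_seed(seed, rnorm(length(v), 0, spec$noise_sd_mvct))
  mvct <- image_volume(array(v, dim = d), sp, origin)

  # planning slices beyond the guidance z coverage are dropped by design
  truth_contours <- suppressWarnings(propagate_contours(phantom$cord, truth,
                                                        mvct))
  bb <- region_bbox(lapply(truth_contours$contours, `[[`, "points"))
  xext <- c(origin[1], origin[1] + (d[1] - 1) * sp[1])
  yext <- c(origin[2], origin[2] + (d[2] - 1) * sp[2])
  if (bb[1] < xext[1] || bb[2] > xext[2] || bb[3] < yext[1] || bb[4] > yext[2])
    stop("deformation pushes the cord outside the guidance grid")

  # dose: Gaussian transverse falloff about the deformed cord axis
  axis_z <- seq(0, kz, by = 1)
  axis_pts <- cbind(spec$cord_center[1], spec$cord_center[2], axis_z)
  axis_mapped <- transform_point(truth, axis_pts)
  ord <- order(axis_mapped[, 3])
  ax <- stats::approx(axis_mapped[ord, 3], axis_mapped[ord, 1], xout = pts[, 3],
                      rule = 2)$y
  ay <- stats::approx(axis_mapped[ord, 3], axis_mapped[ord, 2], xout = pts[, 3],
                      rule = 2)$y
  r2 <- (pts[, 1] - ax)^2 + (pts[, 2] - ay)^2
  dose_v <- spec$dose_peak * exp(-r2 / (2 * spec$dose_sigma^2))
  dose <- image_volume(array(dose_v, dim = d), sp, origin)

  shift <- if (length(truth) > 0 && truth[[1]]$kind == "translation")
    truth[[1]]$params else c(0, 0, 0)
  couch_shift <- shift + with_seed(seed + 1L, rnorm(3, 0, spec$couch_error_sd))

  structure(list(mvct = mvct, truth_chain = truth,
                 truth_contours = truth_contours, dose = dose,
                 couch_shift = couch_shift,
                 fraction_index = fraction_index),
            class = "phantom_fraction")
}
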