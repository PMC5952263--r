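# Histogram set-up shared by the metric and the registration engine.
# Bin width leaves a 3-bin margin at each end so the cubic Parzen window
# used during optimisation never clips at the histogram edges.
mi_bin_setup <- function(values, bins) {
  rng <- range(values, finite = TRUE)
  width <- (rng[2] - rng[1] + 1e-6) / (bins - 6)
  if (!is.finite(width) || width <= 0) width <- 1e-6
  list(min = rng[1] - 3 * width, width = width)
}

mi_bin_index <- function(values, setup, bins) {
  b <- floor((values - setup$min) / setup$width)
  as.integer(pmin(pmax(b, 0), bins - 1))
}

clamp_hu <- function(x, clamp) pmin(pmax(x, clamp[1]), clamp[2])

#' Mutual information between a fixed and a transformed moving volume
#'
#' Estimates the mutual information (in nats) between fixed-image
#' intensities at sample points and moving-image intensities at the
#' transformed sample points, from a joint intensity histogram with
#' `config$bins` bins per image. Intensities are clamped to `config$clamp`
#' (default -1024 to 3071 HU) before binning; moving intensities are
#' obtained by trilinear interpolation and samples mapping outside the
#' moving volume are discarded rather than zero-filled. Sampling is
#' deterministic given `config$seed`.
#'
#' This hard-binned estimator is the reported metric value; during
#' registration the optimiser climbs a Parzen-smoothed version of the same
#' quantity (cubic B-spline window on the moving intensity) so that
#' analytic gradients exist.
#'
#' @param fixed,moving [image_volume]s.
#' @param transform a [transform_chain] mapping fixed-frame mm points to
#'   moving-frame mm points (`NULL` = identity).
#' @param mask optional `binary_mask` on the fixed grid restricting the
#'   sample domain (default: whole fixed grid).
#' @param config a [registration_config]; `bins`, `samples`, `seed` and
#'   `clamp` are used. `samples = Inf` uses every candidate voxel.
#' @return MI in nats, with attributes `n_used` and `n_attempted`.
#' @export
mattes_mutual_information <- function(fixed, moving, transform = NULL,
                                      mask = NULL,
                                      config = registration_config()) {
  stopifnot_volume(fixed)
  stopifnot_volume(moving)
  if (!is.null(mask)) {
    if (!is_binary_mask(mask)) stop("mask must be a binary_mask")
    pts <- mask_points(mask)
    fvals <- fixed$voxels[mask$voxels]
  } else {
    pts <- voxel_center_grid(fixed)
    fvals <- as.numeric(fixed$voxels)
  }
  n <- nrow(pts)
  if (is.finite(config$samples) && config$samples < n) {
    keep <- with_seed(config$seed, sample.int(n, config$samples))
    pts <- pts[keep, , drop = FALSE]
    fvals <- fvals[keep]
  }
  fvals <- clamp_hu(fvals, config$clamp)
  # bin edges from the whole volume, so the same volume on both sides gets
  # identical binning
  fsetup <- mi_bin_setup(clamp_hu(as.numeric(fixed$voxels), config$clamp),
                         config$bins)
  fbin <- mi_bin_index(fvals, fsetup, config$bins)
  mvals <- clamp_hu(as.numeric(moving$voxels), config$clamp)
  msetup <- mi_bin_setup(mvals, config$bins)
  chain <- if (is.null(transform)) list() else unclass(as_chain(transform))
  res <- cpp_chain_mi(pts, fbin, chain,
                      mvals, dim(moving$voxels), moving$spacing, moving$origin,
                      msetup$min, msetup$width, config$bins, config$bins,
                      FALSE)
  if (res$n_used < 0.1 * res$n_attempted)
    stop(sprintf("insufficient overlap: only %d of %d samples map inside the moving volume",
                 res$n_used, res$n_attempted))
  structure(res$mi, n_used = res$n_used, n_attempted = res$n_attempted)
}

# run code with a temporary RNG state so library calls do not disturb the
# caller's random stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
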