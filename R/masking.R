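#' Patient body mask excluding the treatment couch
#'
#' Thresholds the volume at `threshold_hu` and keeps the largest connected
#' component of above-threshold voxels, which isolates the patient's head
#' and upper body and discards the (spatially detached) treatment couch and
#' any other debris. Connectivity is 26-neighbour in 3D by default, which
#' tolerates thin necks in noisy guidance images.
#'
#' @param volume an [image_volume] in HU.
#' @param threshold_hu threshold separating patient/couch from air; the
#'   default -400 HU sits between air (about -1000 HU) and soft tissue
#'   (above about -200 HU).
#' @param connectivity 26 (default) or 6.
#' @param closing if `TRUE`, apply one pass of 3x3x3 binary closing to the
#'   selected component (off by default).
#' @return A `binary_mask`: logical array plus the parent geometry.
#' @export
build_body_mask <- function(volume, threshold_hu = -400, connectivity = 26,
                            closing = FALSE) {
  stopifnot_volume(volume)
  above <- volume$voxels >= threshold_hu
  if (!any(above)) stop("empty mask: no voxels at or above ", threshold_hu, " HU")
  lab <- cpp_label3d(as.logical(above), dim(volume$voxels),
                     as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  sizes <- tabulate(lab, nbins = ncomp)
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    # deterministic tie-break: component first encountered in linear scan
    # order, i.e. the one containing the lowest voxel index
    warning("tie between equal-size largest components; keeping the one ",
            "with the lowest voxel index")
    biggest <- min(biggest)
  }
  mask <- array(lab == biggest, dim = dim(volume$voxels))
  if (closing) mask <- binary_close(mask)
  structure(list(voxels = mask, spacing = volume$spacing,
                 origin = volume$origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels set of %s\n",
              format(sum(x$voxels)), format(length(x$voxels))))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

# one dilation followed by one erosion with a 3x3x3 box element
binary_close <- function(mask) {
  shift_or <- function(m, combine) {
    out <- m
    d <- dim(m)
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sh <- array(combine == "all", dim = d)
      xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
      ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
      zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
      sh[xs, ys, zs] <- m[xs - dx, ys - dy, zs - dz]
      out <- if (combine == "any") out | sh else out & sh
    }
    out
  }
  shift_or(shift_or(mask, "any"), "all")
}

# mm centres of all voxels set in a mask
mask_points <- function(mask) {
  idx <- which(mask$voxels) - 1L
  d <- dim(mask$voxels)
  i <- idx %% d[1]
  j <- (idx %/% d[1]) %% d[2]
  k <- idx %/% (d[1] * d[2])
  cbind(mask$origin[1] + i * mask$spacing[1],
        mask$origin[2] + j * mask$spacing[2],
        mask$origin[3] + k * mask$spacing[3])
}
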