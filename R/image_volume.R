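#' 3D scalar image volume in patient-millimetre coordinates
#'
#' An `image_volume` holds a 3D scalar grid (Hounsfield units for CT, Gy for
#' dose) together with its geometry: voxel spacing, and the patient-mm
#' position of the centre of voxel index (0,0,0) (the DICOM
#' ImagePositionPatient convention). All geometry in the package uses DICOM
#' patient coordinates: +x towards patient left, +y towards posterior,
#' +z towards superior. Only axial, axis-aligned volumes are supported;
#' oblique direction matrices are rejected on input rather than resampled.
#'
#' @param voxels 3D numeric array, indexed `[x, y, z]`.
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm,
#'   strictly positive.
#' @param origin numeric length-3, mm coordinates of the centre of voxel
#'   (0,0,0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_volume: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %.4g x %.4g x %.4g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm):  (%.4g, %.4g, %.4g)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  rng <- range(x$voxels, na.rm = TRUE)
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_volume <- function(x) {
  if (!is_image_volume(x)) stop("expected an 'image_volume'")
  invisible(x)
}

#' Map 0-based voxel indices to patient mm and back
#'
#' The index-to-mm mapping is affine: `mm = origin + index * spacing`,
#' applied per axis. `mm_to_voxel` is its exact inverse (continuous indices,
#' not rounded).
#'
#' @param volume an [image_volume].
#' @param index numeric matrix (n x 3) or length-3 vector of 0-based indices.
#' @param xyz numeric matrix (n x 3) or length-3 vector of mm coordinates.
#' @return A matrix (n x 3) of mm coordinates or continuous voxel indices.
#' @export
voxel_to_mm <- function(volume, index) {
  stopifnot_volume(volume)
  index <- to_point_matrix(index)
  sweep(sweep(index, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' @rdname voxel_to_mm
#' @export
mm_to_voxel <- function(volume, xyz) {
  stopifnot_volume(volume)
  xyz <- to_point_matrix(xyz)
  sweep(sweep(xyz, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

to_point_matrix <- function(p, ncol = 3L) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = ncol, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

#' Slice plane z positions of a volume
#' @param volume an [image_volume].
#' @return Numeric vector of slice-centre z coordinates (mm), increasing.
#' @export
slice_positions <- function(volume) {
  stopifnot_volume(volume)
  volume$origin[3] + (seq_len(dim(volume$voxels)[3]) - 1) * volume$spacing[3]
}

# mm coordinates of every voxel centre, as an (nx*ny*nz) x 3 matrix in
# R array order (x fastest).
voxel_center_grid <- function(volume) {
  d <- dim(volume$voxels)
  xs <- volume$origin[1] + (seq_len(d[1]) - 1) * volume$spacing[1]
  ys <- volume$origin[2] + (seq_len(d[2]) - 1) * volume$spacing[2]
  zs <- volume$origin[3] + (seq_len(d[3]) - 1) * volume$spacing[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

#' Sample a volume at arbitrary mm points by trilinear interpolation
#'
#' Points outside the box spanned by the first and last voxel centres are
#' reported as not inside and receive `NA` values; they are never zero-filled.
#'
#' @param volume an [image_volume].
#' @param points n x 3 matrix of mm coordinates.
#' @param gradient if `TRUE`, also return the spatial gradient of the
#'   interpolant (per mm).
#' @return A list with `values`, logical `inside`, and optionally `grad`.
#' @export
sample_volume <- function(volume, points, gradient = FALSE) {
  stopifnot_volume(volume)
  points <- to_point_matrix(points)
  cpp_trilinear(as.numeric(volume$voxels), dim(volume$voxels),
                volume$spacing, volume$origin, points, gradient)
}

#' Resample a source volume onto a target grid, optionally through a transform
#'
#' The value at each target voxel centre x is the trilinear interpolation of
#' `source` at `chain(x)`; with `chain = NULL` the mapping is the identity.
#' Target voxels mapping outside the source grid receive `fill`.
#'
#' @param source an [image_volume] to sample from.
#' @param target an [image_volume] (only its geometry is used).
#' @param chain a [transform_chain] mapping target-frame mm points to
#'   source-frame mm points, or `NULL`.
#' @param fill value for unmapped voxels.
#' @return An [image_volume] on the target grid.
#' @export
resample_volume <- function(source, target, chain = NULL, fill = NA_real_) {
  stopifnot_volume(source)
  stopifnot_volume(target)
  pts <- voxel_center_grid(target)
  if (!is.null(chain) && length(chain) > 0)
    pts <- cpp_apply_chain(pts, unclass(chain))
  s <- cpp_trilinear(as.numeric(source$voxels), dim(source$voxels),
                     source$spacing, source$origin, pts, FALSE)
  v <- s$values
  v[!s$inside] <- fill
  image_volume(array(v, dim = dim(target$voxels)), target$spacing,
               target$origin)
}

#' Write and read volumes as NIfTI-1
#'
#' Volumes are stored with a diagonal affine. Because this package works in
#' DICOM patient coordinates (LPS) while NIfTI uses RAS, the x and y axes are
#' sign-flipped when writing the qform/sform and flipped back when reading,
#' so the files carry a conformant NIfTI orientation while round trips
#' preserve geometry exactly. Integer HU volumes are stored as int16
#' (lossless); other data as float64.
#'
#' @param volume an [image_volume].
#' @param path output file, `.nii` or `.nii.gz`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns an
#'   [image_volume].
#' @export
write_nifti <- function(volume, path) {
  stopifnot_volume(volume)
  arr <- volume$voxels
  integral <- max(abs(arr - round(arr))) < 1e-9 &&
    max(abs(arr)) < 32000
  if (integral) storage.mode(arr) <- "integer"
  attr(arr, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(arr)
  aff <- diag(c(-volume$spacing[1], -volume$spacing[2], volume$spacing[3], 1))
  aff[1:3, 4] <- c(-volume$origin[1], -volume$origin[2], volume$origin[3])
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = if (integral) "int16" else "double")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(img)), " dimensions")
  aff <- RNifti::xform(img)
  # RAS -> LPS: negate the first two rows
  lps <- aff
  lps[1:2, ] <- -lps[1:2, ]
  rot <- lps[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 || any(diag(rot) <= 0))
    stop("non-axial NIfTI orientation is not supported")
  arr <- as.array(img)
  voxels <- array(as.numeric(arr), dim = dim(arr))
  image_volume(voxels, spacing = diag(rot), origin = lps[1:3, 4])
}
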