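test_that("image_volume validates its geometry", {
  expect_error(image_volume(array(0, c(2, 2, 2)), c(1, 0, 1)), "positive")
  expect_error(image_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  v <- image_volume(array(0, c(2, 3, 4)), c(1, 2, 3), c(-1, -2, -3))
  expect_equal(dim(v$voxels), c(2, 3, 4))
})

test_that("index/mm mapping is affine, invertible and exact on voxel corners", {
  set.seed(11)
  for (rep in 1:5) {
    sp <- runif(3, 0.3, 5)
    org <- runif(3, -100, 100)
    v <- image_volume(array(0, c(4, 5, 6)), sp, org)
    idx <- as.matrix(expand.grid(0:3, 0:4, 0:5))
    back <- mm_to_voxel(v, voxel_to_mm(v, idx))
    expect_equal(back, unname(idx), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(voxel_to_mm(v, c(0, 0, 0))[1, ], org)
  }
})

test_that("NIfTI round trip preserves voxels, spacing and origin", {
  vol <- small_phantom()$kvct
  vol$voxels <- round(vol$voxels)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol, path)
  back <- read_nifti(path)
  expect_identical(back$voxels, vol$voxels)     # integer HU bitwise
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-5)
  expect_equal(back$origin, vol$origin, tolerance = 1e-4)

  aniso <- image_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                        c(0.754, 0.754, 6.0), c(-100, -100, 0))
  p2 <- withr::local_tempfile(fileext = ".nii")
  write_nifti(aniso, p2)
  b2 <- read_nifti(p2)
  expect_equal(b2$spacing, c(0.754, 0.754, 6.0), tolerance = 1e-5)
  expect_equal(b2$origin, c(-100, -100, 0), tolerance = 1e-4)
  expect_equal(b2$voxels, aniso$voxels, tolerance = 1e-9)
})

test_that("DICOM CT series round trips and sorts slices by z", {
  vol <- small_phantom()$kvct
  vol$voxels <- round(vol$voxels)
  dir <- withr::local_tempdir()
  write_ct_series(vol, dir)
  back <- load_ct_series(dir)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$origin, vol$origin)
  expect_equal(back$spacing[3], 3.0)

  # shuffled file names load to the identical volume
  files <- list.files(dir, full.names = TRUE)
  shuf <- withr::local_tempdir()
  set.seed(2)
  perm <- sample(length(files))
  for (i in seq_along(files))
    file.copy(files[i], file.path(shuf, sprintf("slice_%04d.dcm", perm[i])))
  expect_identical(load_ct_series(shuf)$voxels, vol$voxels)
})

test_that("degenerate and incoherent CT series are rejected", {
  vol <- small_phantom()$kvct
  dir <- withr::local_tempdir()
  write_ct_series(vol, dir)
  files <- sort(list.files(dir, full.names = TRUE))

  single <- withr::local_tempdir()
  file.copy(files[1], single)
  expect_error(load_ct_series(single), "fewer than 2 slices")

  gap <- withr::local_tempdir()
  file.copy(files[-3], gap)  # remove an interior slice
  expect_error(load_ct_series(gap), "non-uniform|missing")

  mixed <- withr::local_tempdir()
  for (i in seq_along(files))
    file.copy(files[i], file.path(mixed, sprintf("other_%04d.dcm", i)))
  write_ct_series(vol, mixed)  # second series alongside the first
  expect_error(load_ct_series(mixed), "mixed series")
})

test_that("the same phantom loads identically from DICOM and NIfTI", {
  vol <- small_phantom()$kvct
  vol$voxels <- round(vol$voxels)
  dir <- withr::local_tempdir()
  nii <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_series(vol, dir)
  write_nifti(vol, nii)
  a <- load_ct_series(dir)
  b <- read_nifti(nii)
  expect_identical(a$voxels, b$voxels)
  expect_equal(a$spacing, b$spacing, tolerance = 1e-5)
  expect_equal(a$origin, b$origin, tolerance = 1e-4)
})

test_that("RTSTRUCT round trips contours in patient mm", {
  zs <- seq(0, 27, by = 3)
  contours <- lapply(zs, function(z)
    list(z = z, points = circle_polygon(c(3, -12), 4, 64)))
  ss <- structure_set("spinal_cord", contours)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_structure_set(ss, path)
  back <- read_structure_set(path)
  expect_equal(length(back$contours), 10)
  for (k in seq_along(back$contours)) {
    expect_equal(back$contours[[k]]$z, ss$contours[[k]]$z, tolerance = 1e-6)
    expect_lt(max(abs(back$contours[[k]]$points - ss$contours[[k]]$points)),
              1e-3)
    # 64-vertex polygon area approximates the analytic circle within 2%
    expect_equal(polygon_area(back$contours[[k]]$points), pi * 16,
                 tolerance = 0.02)
  }
})

test_that("empty structures and arbitrary polygons are handled", {
  expect_error(structure_set("x", list()), "no contours")
  poly <- matrix(c(0, 0, 5, 1, 6, 4, 2, 7, -1, 3), ncol = 2, byrow = TRUE)
  ss <- structure_set("roi", list(list(z = 1.5, points = poly)))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_structure_set(ss, path)
  back <- read_structure_set(path)
  expect_equal(back$contours[[1]]$points, poly, tolerance = 1e-9)
})

test_that("RTDOSE round trips dose grids", {
  dose <- image_volume(array(runif(8 * 7 * 5, 0, 2.5), c(8, 7, 5)),
                       c(0.754, 0.754, 6), c(-10, -20, 5))
  path <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(dose, path)
  back <- read_rtdose(path)
  expect_lt(max(abs(back$voxels - dose$voxels)), 1e-8)
  expect_equal(back$spacing, dose$spacing)
  expect_equal(back$origin, dose$origin)
  expect_error(write_rtdose(image_volume(array(-1, c(2, 2, 2)), c(1, 1, 1)),
                            path), "non-negative")
})
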