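test_that("phantom geometry honours the specified voxel sizes and contours", {
  ph <- default_phantom()
  expect_equal(ph$kvct$spacing, c(2.148, 2.148, 3.0))
  fr <- fixture("phantom_fr2", function() generate_fraction(default_phantom(), 2))
  expect_equal(fr$mvct$spacing, c(0.754, 0.754, 6.0))
  for (ct in ph$cord$contours)
    expect_equal(polygon_area(ct$points), pi * 16, tolerance = 0.02)
})

test_that("phantom generation is bit-reproducible under a fixed seed", {
  a <- generate_phantom(phantom_spec(kvct_dim = c(32, 32, 8), seed = 5))
  b <- generate_phantom(phantom_spec(kvct_dim = c(32, 32, 8), seed = 5))
  expect_identical(a$kvct$voxels, b$kvct$voxels)
  fa <- generate_fraction(a, 3)
  fb <- generate_fraction(b, 3)
  expect_identical(fa$mvct$voxels, fb$mvct$voxels)
  expect_identical(lapply(unclass(fa$truth_chain), `[[`, "params"),
                   lapply(unclass(fb$truth_chain), `[[`, "params"))
  c_seed <- generate_phantom(phantom_spec(kvct_dim = c(32, 32, 8), seed = 6))
  expect_false(identical(a$kvct$voxels, c_seed$kvct$voxels))
})

test_that("a noise-free phantom has exact air background", {
  spec <- phantom_spec(kvct_dim = c(48, 48, 8), noise_sd_kvct = 0)
  ph <- generate_phantom(spec)
  corner <- ph$kvct$voxels[1:3, 1:3, ]
  expect_true(all(corner == -1000))
})

test_that("zero deformation with zero noise reproduces plain resampling", {
  spec <- phantom_spec(kvct_dim = c(48, 48, 10), mvct_dim = c(96, 96, 4),
                       noise_sd_kvct = 0, noise_sd_mvct = 0,
                       deform_translation = c(0, 0, 0),
                       translation_jitter_sd = 0, deform_max = 0)
  ph <- generate_phantom(spec)
  fr <- generate_fraction(ph, 1)
  expect_equal(transform_point(fr$truth_chain, cbind(1, 2, 3)),
               cbind(1, 2, 3))
  direct <- resample_volume(ph$kvct, fr$mvct, NULL, fill = -1000)
  expect_equal(fr$mvct$voxels, direct$voxels, tolerance = 1e-12)
})

test_that("a pure in-plane shift moves the truth contour centroids with it", {
  ph <- default_phantom()
  fr <- generate_fraction(ph, 1, deformation = transform_chain(list(
    translation_transform(c(5, 0, 0)))))
  src_centroid <- polygon_centroid(ph$cord$contours[[1]]$points)
  for (ct in fr$truth_contours$contours)
    expect_equal(polygon_centroid(ct$points), src_centroid + c(5, 0),
                 tolerance = 1e-6)
})

test_that("fractions carry distinct reproducible deformations", {
  ph <- default_phantom()
  chains <- lapply(1:5, function(i)
    corddose:::phantom_truth_chain(ph, i))
  shifts <- t(vapply(chains, function(ch) ch[[1]]$params, numeric(3)))
  expect_equal(nrow(unique(shifts)), 5)
  again <- corddose:::phantom_truth_chain(ph, 3)
  expect_identical(again[[1]]$params, chains[[3]][[1]]$params)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(deform_max = 20, deform_spacing = 30),
               "invertible")
  expect_error(phantom_spec(cord_center = c(0, 44)), "outside the body")
  expect_error(phantom_spec(cord_radius = 9), "cord_radius")
})

test_that("deformations that push the cord off the guidance grid error", {
  ph <- generate_phantom(phantom_spec(kvct_dim = c(72, 72, 16),
                                      mvct_dim = c(96, 96, 6)))
  # the small guidance grid spans about +/- 36 mm in-plane
  expect_error(
    suppressWarnings(generate_fraction(ph, 1, deformation = transform_chain(
      list(translation_transform(c(40, 0, 0)))))),
    "outside the guidance grid")
})
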