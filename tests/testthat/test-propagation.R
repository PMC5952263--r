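test_that("the identity chain reproduces contours on matching planes", {
  ph <- small_phantom()
  out <- propagate_contours(ph$cord, transform_chain(), ph$kvct)
  expect_equal(length(out$contours), length(ph$cord$contours))
  for (k in seq_along(out$contours)) {
    expect_equal(out$contours[[k]]$z, ph$cord$contours[[k]]$z)
    expect_equal(out$contours[[k]]$points, ph$cord$contours[[k]]$points,
                 tolerance = 1e-9)
  }
})

test_that("an in-plane translation shifts every polygon; DBC equals 5 mm", {
  ph <- small_phantom()
  chain <- transform_chain(list(translation_transform(c(3, 4, 0))))
  out <- propagate_contours(ph$cord, chain, ph$kvct)
  for (k in seq_along(out$contours)) {
    src <- ph$cord$contours[[k]]$points
    expect_equal(out$contours[[k]]$points,
                 sweep(src, 2, c(3, 4), "+"), tolerance = 1e-9)
    expect_equal(distance_between_centres(out$contours[[k]]$points, src), 5,
                 tolerance = 1e-9)
  }
})

test_that("point mapping before slice snapping composes exactly", {
  ph <- small_phantom()
  a <- transform_chain(list(translation_transform(c(1, -2, 0.4))))
  set.seed(12)
  b <- transform_chain(list(
    bspline_transform(c(-60, -60, -20), 25, c(8, 8, 6),
                      rnorm(8 * 8 * 6 * 3, 0, 0.8))))
  vertices <- do.call(rbind, lapply(ph$cord$contours, function(ct)
    cbind(ct$points, ct$z)))
  via_two <- transform_point(b, transform_point(a, vertices))
  via_one <- transform_point(compose_chains(a, b), vertices)
  expect_lt(max(abs(via_two - via_one)), 1e-6)
})

test_that("propagation onto a coarser grid keeps one union polygon per plane", {
  ph <- default_phantom()
  fr <- fixture("shift_fraction", function()
    generate_fraction(default_phantom(), 1,
                      deformation = transform_chain(list(
                        translation_transform(c(5, -3, 6))))))
  out <- suppressWarnings(
    propagate_contours(ph$cord, fr$truth_chain, fr$mvct))
  zs <- contour_zs(out)
  expect_equal(zs, unique(zs))                   # one polygon per plane
  expect_true(all(zs %in% slice_positions(fr$mvct)))
  # centroids shifted by the in-plane components of the truth translation
  for (ct in out$contours)
    expect_equal(polygon_centroid(ct$points), c(0 + 5, 15 - 3),
                 tolerance = 0.05)
})

test_that("radial union of overlapping polygons matches analytic areas", {
  a <- circle_polygon(c(0, 0), 5, 128)
  b <- circle_polygon(c(3, 0), 5, 128)
  u <- corddose:::radial_union(list(a, b), n_angles = 512)
  # analytic union area of two equal circles (r = 5, d = 3)
  r <- 5; d <- 3
  lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  expect_equal(polygon_area(u), 2 * pi * r^2 - lens, tolerance = 0.01)
})

test_that("degenerate mapped polygons are dropped with a warning", {
  ph <- small_phantom()
  # collapse everything onto a line: degenerate affine
  squash <- transform_chain(list(
    affine_transform(diag(c(1e-4, 1, 1)), c(0, 0, 0), c(0, 0, 0))))
  expect_error(suppressWarnings(
    propagate_contours(ph$cord, squash, ph$kvct)), "dropped")
})
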