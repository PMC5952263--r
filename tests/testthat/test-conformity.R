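test_that("identical regions give CI 1 and zero distances", {
  poly <- circle_polygon(c(2, -3), 6, 48)
  expect_equal(conformity_index(poly, poly), 1)
  expect_equal(distance_between_centres(poly, poly), 0)
  expect_equal(as.numeric(distance_to_conformity(poly, poly)), 0)
  expect_equal(unname(dimension_differences(poly, poly)), c(0, 0))
})

test_that("offset squares give the analytic CI of 1/3 on both backends", {
  a <- square_polygon(0, 0, 10, 10)
  b <- square_polygon(5, 0, 10, 10)
  expect_equal(conformity_index(a, b), 1 / 3, tolerance = 1e-12)
  # force the raster backend by splitting one square into two rectangles
  a_split <- list(square_polygon(0, 0, 10, 5), square_polygon(0, 5, 10, 5))
  expect_equal(conformity_index(a_split, b), 1 / 3, tolerance = 0.01)
  expect_equal(conformity_index(a, a), 1)
  disjoint <- square_polygon(100, 100, 5, 5)
  expect_equal(conformity_index(a, disjoint), 0)
})

test_that("raster and exact-clipping areas agree within 1% on convex shapes", {
  set.seed(31)
  for (rep in 1:8) {
    a <- random_convex_polygon(10, c(0, 0), 8)
    b <- random_convex_polygon(12, c(runif(1, -4, 4), runif(1, -4, 4)), 8)
    exact <- conformity_index(a, b)
    raster <- conformity_index(list(a, square_polygon(50, 50, 1e-3, 1e-3)),
                               b)  # tiny far-away satellite forces raster
    if (exact > 0.05)
      expect_equal(raster, exact, tolerance = 0.01)
  }
})

test_that("distance between centres is Euclidean on area centroids", {
  a <- random_convex_polygon(14, c(0, 0), 7)
  b <- sweep(a, 2, c(3, 4), "+")
  expect_equal(distance_between_centres(a, b), 5, tolerance = 1e-9)
  outer_sq <- square_polygon(-5, -5, 10, 10)
  inner_sq <- square_polygon(-2, -2, 4, 4)
  expect_equal(distance_between_centres(outer_sq, inner_sq), 0,
               tolerance = 1e-9)
})

# brute-force DTC oracle: every pixel of the symmetric difference to its
# nearest pixel of the intersection, by exhaustive search at 0.1 mm
dtc_oracle <- function(a, b, pitch = 0.1) {
  bb <- corddose:::region_bbox(list(a, b))
  xs <- seq(bb[1] - pitch + pitch / 2, bb[2] + pitch, by = pitch)
  ys <- seq(bb[3] - pitch + pitch / 2, bb[4] + pitch, by = pitch)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  ina <- corddose:::cpp_points_in_poly(grid, a, 1e-9)
  inb <- corddose:::cpp_points_in_poly(grid, b, 1e-9)
  inter <- grid[ina & inb, , drop = FALSE]
  sym <- grid[xor(ina, inb), , drop = FALSE]
  if (nrow(sym) == 0) return(0)
  mean(vapply(seq_len(nrow(sym)), function(i)
    min(sqrt((inter[, 1] - sym[i, 1])^2 + (inter[, 2] - sym[i, 2])^2)), 0))
}

test_that("DTC matches the exhaustive pixel-distance oracle", {
  a <- square_polygon(0, 0, 10, 10)
  b <- square_polygon(1, 0, 10, 10)
  expect_equal(as.numeric(distance_to_conformity(a, b)), dtc_oracle(a, b),
               tolerance = 1e-3)
  nested_out <- square_polygon(-5, -5, 10, 10)
  nested_in <- square_polygon(-4, -4, 8, 8)
  expect_equal(as.numeric(distance_to_conformity(nested_in, nested_out)),
               dtc_oracle(nested_in, nested_out), tolerance = 1e-3)
  disjoint <- distance_to_conformity(square_polygon(0, 0, 4, 4),
                                     square_polygon(20, 0, 4, 4))
  expect_true(isTRUE(attr(disjoint, "empty_intersection")))
  expect_gt(as.numeric(disjoint), 10)
})

test_that("dimension differences are signed bounding-box extents", {
  a <- square_polygon(0, 0, 12, 8)
  b <- square_polygon(30, 2, 10, 8)
  expect_equal(unname(dimension_differences(a, b)), c(2, 0))
  # rotating the reference by 90 degrees swaps the roles of lr and ap
  b_rot <- cbind(-b[, 2], b[, 1])
  dd <- dimension_differences(a, b_rot)
  expect_equal(unname(dd), c(12 - 8, 8 - 10))
})

test_that("metric symmetries and scale behaviour hold", {
  set.seed(17)
  for (rep in 1:5) {
    a <- random_convex_polygon(11, c(0, 0), 6)
    b <- random_convex_polygon(9, c(1.5, -1), 6)
    expect_equal(conformity_index(a, b), conformity_index(b, a),
                 tolerance = 1e-12)
    expect_equal(distance_between_centres(a, b),
                 distance_between_centres(b, a), tolerance = 1e-12)
    expect_equal(dimension_differences(a, b)[["lr_diff"]],
                 -dimension_differences(b, a)[["lr_diff"]])
    s <- 2.5
    expect_equal(conformity_index(a * s, b * s), conformity_index(a, b),
                 tolerance = 1e-9)
    expect_equal(distance_between_centres(a * s, b * s),
                 s * distance_between_centres(a, b), tolerance = 1e-9)
    expect_equal(as.numeric(distance_to_conformity(a * s, b * s)),
                 s * as.numeric(distance_to_conformity(a, b)),
                 tolerance = 0.05)
  }
})

test_that("structure sets compare slice by slice with unmatched bookkeeping", {
  zs <- seq(0, 27, 3)
  mk <- function(zs, shift = c(0, 0)) structure_set("cord", lapply(zs, function(z)
    list(z = z, points = circle_polygon(c(0, 15) + shift, 4, 48))))
  ss <- mk(zs)
  self <- compare_structure_sets(ss, ss)
  expect_equal(nrow(self), 10)
  expect_true(all(self$ci == 1))
  expect_true(all(self$dbc == 0) && all(self$dtc == 0))

  trimmed <- mk(zs[1:8])           # test missing the 2 superior slices
  rec <- compare_structure_sets(trimmed, ss)
  expect_equal(nrow(rec), 8)
  un <- attr(rec, "unmatched")
  expect_equal(nrow(un), 2)
  expect_true(all(un$side == "reference"))
  expect_equal(sort(un$z), c(24, 27))

  far <- mk(zs + 1000)
  expect_error(compare_structure_sets(far, ss), "zero matched")
})

test_that("aggregation reproduces hand-computed statistics", {
  rec <- data.frame(z = 1:3, ci = c(0.7, 0.8, 0.9), dtc = c(0, 0, 0),
                    dbc = c(1, 2, 3), lr_diff = c(0, 0, 0),
                    ap_diff = c(0, 0, 0))
  s <- aggregate_conformity(rec, seed = 1)
  ci_row <- s[s$metric == "ci", ]
  expect_equal(ci_row$mean, 0.8)
  expect_equal(ci_row$median, 0.8)
  expect_equal(ci_row$sd, 0.1)
  expect_equal(ci_row$se_mean, 0.1 / sqrt(3))
  s2 <- aggregate_conformity(rec, seed = 1)
  expect_identical(s$se_median, s2$se_median)   # seeded bootstrap
  one <- aggregate_conformity(rec[1, ], seed = 1)
  expect_true(all(is.na(one$sd)))
  expect_true(all(is.na(one$se_median)))
})

test_that("inter-observer analysis compares all unordered pairs", {
  zs <- seq(0, 12, 3)
  mk <- function(shift) structure_set("cord", lapply(zs, function(z)
    list(z = z, points = circle_polygon(c(0, 15) + shift, 4, 48))))
  obs6 <- lapply(1:6, function(i) mk(c(0, 0)))
  res <- interobserver_analysis(obs6)
  expect_equal(nrow(res$pairwise), 15)
  expect_true(all(res$per_observer$ci == 1))
  expect_equal(res$per_observer$n_comparisons, rep(5, 6))

  obs4 <- lapply(1:4, function(i) mk(c(0.3 * i, 0)))
  res4 <- interobserver_analysis(obs4)
  expect_equal(nrow(res4$pairwise), 6)
  # signed differences: mean lr_diff per observer sums to zero across the cohort
  expect_equal(sum(res4$per_observer$lr_diff * res4$per_observer$n_comparisons),
               0, tolerance = 1e-9)
})
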