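test_that("cord voxel selection matches the analytic cross-section area", {
  ph <- default_phantom()
  vox <- cord_voxels(ph$cord, ph$kvct)
  area_per_voxel <- prod(ph$kvct$spacing[1:2])
  expected <- pi * ph$spec$cord_radius^2 / area_per_voxel
  for (k in unique(vox$k)) {
    n_k <- sum(vox$k == k)
    expect_lte(abs(n_k - expected), 2)
  }
  # boundary voxel centres are included (closed-region rule)
  sq <- structure_set("sq", list(list(z = 0, points =
    square_polygon(-1.074, -1.074, 2.148, 2.148))))
  v2 <- cord_voxels(sq, ph$kvct)
  # the square's edges pass exactly through the 4 neighbouring voxel centres
  expect_equal(nrow(v2), 4)

  tiny <- structure_set("pt", list(list(z = 0, points =
    circle_polygon(c(1.05, 0.4), 0.2, 16))))
  expect_error(suppressWarnings(cord_voxels(tiny, ph$kvct)), "no voxels")
})

test_that("identity transforms with uniform 2 Gy fractions accumulate to 60 Gy", {
  ph <- default_phantom()
  vox <- cord_voxels(ph$cord, ph$kvct)
  grid <- image_volume(array(2, c(40, 40, 25)), c(4, 4, 4), c(-78, -78, 0))
  dm <- accumulate_dose(vox,
                        replicate(30, transform_chain(), simplify = FALSE),
                        replicate(30, grid, simplify = FALSE))
  expect_true(all(dm$dose == 60))
  expect_true(all(dm$included))
  expect_equal(dvh_summary(dm)$d2, 60)
})

test_that("fractions with truncated grids exclude exactly the predicted voxels", {
  ph <- default_phantom()
  vox <- cord_voxels(ph$cord, ph$kvct)
  full <- image_volume(array(2, c(40, 40, 25)), c(4, 4, 4), c(-78, -78, 0))
  cut <- image_volume(array(2, c(40, 40, 13)), c(4, 4, 4), c(-78, -78, 0))
  # truncated superiorly: grid covers z in [0, 48] only
  dm <- accumulate_dose(vox, replicate(3, transform_chain(), simplify = FALSE),
                        list(full, full, cut))
  expect_equal(dm$included, vox$z <= 48)
  expect_equal(dm$coverage, ifelse(vox$z <= 48, 3L, 2L))
  expect_error(accumulate_dose(vox, list(transform_chain()), list(full, full)),
               "mismatched fraction counts")
})

test_that("sampled doses follow an axial ramp through known translations", {
  ph <- default_phantom()
  vox <- cord_voxels(ph$cord, ph$kvct)
  d <- c(40, 40, 40)
  zs <- (seq_len(d[3]) - 1) * 3
  ramp <- image_volume(
    array(rep(zs / 10, each = d[1] * d[2]), dim = d), c(4, 4, 3),
    c(-78, -78, 0))
  shift <- c(2, -1, 4.5)
  dm <- accumulate_dose(vox, list(transform_chain(list(
    translation_transform(shift)))), list(ramp))
  expect_lt(max(abs(dm$dose[dm$included] -
                    (vox$z[dm$included] + shift[3]) / 10)), 1e-6)
})

test_that("couch shifts compose after the registration transform", {
  ph <- default_phantom()
  vox <- cord_voxels(ph$cord, ph$kvct)
  d <- c(40, 40, 40)
  zs <- (seq_len(d[3]) - 1) * 3
  ramp <- image_volume(array(rep(zs / 10, each = d[1] * d[2]), dim = d),
                       c(4, 4, 3), c(-78, -78, 0))
  dm <- accumulate_dose(vox, list(transform_chain(list(
    translation_transform(c(0, 0, 2))))), list(ramp),
    couch_shifts = matrix(c(0, 0, 3), 1))
  expect_lt(max(abs(dm$dose[dm$included] -
                    (vox$z[dm$included] + 5) / 10)), 1e-6)
})

test_that("D2% equals the sorted-voxel oracle on random dose vectors", {
  expect_equal(dvh_summary(1:100)$d2, 99)
  expect_equal(dvh_summary(c(rep(10, 49), 50))$d2, 50)
  expect_equal(dvh_summary(rep(2, 77))$d2, 2)
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(3:10000, 1)
    doses <- runif(n, 0, 70)
    oracle <- sort(doses, decreasing = TRUE)[ceiling(0.02 * n)]
    expect_identical(dvh_summary(doses)$d2, oracle)
  }
})

test_that("the DVH is monotone and bounds D2% by the maximum", {
  set.seed(14)
  doses <- rgamma(500, 20, 0.5)
  s <- dvh_summary(doses)
  expect_true(all(diff(s$dvh$volume_fraction) <= 0))
  expect_lte(s$d2, s$max)
  expect_equal(s$dvh$volume_fraction[1], 1)
})

test_that("dose accumulation is linear and fraction-order invariant", {
  ph <- default_phantom()
  vox <- cord_voxels(ph$cord, ph$kvct)
  set.seed(15)
  grids <- lapply(1:4, function(i)
    image_volume(array(runif(40 * 40 * 25, 0, 2.5), c(40, 40, 25)),
                 c(4, 4, 4), c(-78, -78, 0)))
  chains <- lapply(1:4, function(i)
    transform_chain(list(translation_transform(rnorm(3)))))
  base <- accumulate_dose(vox, chains, grids)
  scaled_grids <- lapply(grids, function(g) {
    g$voxels <- g$voxels * 3
    g
  })
  tripled <- accumulate_dose(vox, chains, scaled_grids)
  expect_equal(tripled$dose, 3 * base$dose, tolerance = 1e-12)
  expect_equal(dvh_summary(tripled)$d2, 3 * dvh_summary(base)$d2,
               tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  shuffled <- accumulate_dose(vox, chains[perm], grids[perm])
  expect_equal(shuffled$dose, base$dose, tolerance = 1e-12)
})

test_that("planned-versus-delivered differences summarise a cohort", {
  s <- dvh_summary(c(10, 20, 30))
  expect_equal(planned_vs_delivered(s, s)$delta, 0)
  coh <- summarise_d2_differences(c(1, 2, -1))
  expect_equal(coh$n_higher, 2)
  expect_equal(coh$mean_excess, 1.5)
  expect_equal(coh$n_lower, 1)
  expect_equal(coh$mean_deficit, 1)
})
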