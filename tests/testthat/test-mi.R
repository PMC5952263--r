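test_that("MI of a volume with itself equals the joint-histogram entropy", {
  ph <- default_phantom()
  mask <- default_mask()
  cfg <- registration_config(samples = Inf, bins = 32)
  mi <- mattes_mutual_information(ph$kvct, ph$kvct, NULL, mask, cfg)

  # independent oracle: bin the masked voxel values, build the joint
  # histogram with table(), compute MI = sum p log(p / pf pm)
  v <- pmin(pmax(ph$kvct$voxels[mask$voxels], cfg$clamp[1]), cfg$clamp[2])
  all_v <- pmin(pmax(as.numeric(ph$kvct$voxels), cfg$clamp[1]), cfg$clamp[2])
  width <- (max(all_v) - min(all_v) + 1e-6) / (cfg$bins - 6)
  lo <- min(all_v) - 3 * width
  b <- pmin(pmax(floor((v - lo) / width), 0), cfg$bins - 1)
  joint <- table(fixed = b, moving = b) / length(b)
  pf <- rowSums(joint); pm <- colSums(joint)
  mi_oracle <- 0
  for (i in seq_along(pf)) for (j in seq_along(pm)) {
    if (joint[i, j] > 0)
      mi_oracle <- mi_oracle +
        joint[i, j] * log(joint[i, j] / (pf[i] * pm[j]))
  }
  expect_lt(abs(as.numeric(mi) - mi_oracle), 1e-6)
  # for identical inputs that MI is the marginal entropy
  expect_lt(abs(mi_oracle - (-sum(pf[pf > 0] * log(pf[pf > 0])))), 1e-12)
})

test_that("MI against a spatially constant volume is zero", {
  ph <- default_phantom()
  const <- image_volume(array(100, dim = dim(ph$kvct$voxels)),
                        ph$kvct$spacing, ph$kvct$origin)
  mi <- mattes_mutual_information(ph$kvct, const, NULL, default_mask(),
                                  registration_config(samples = Inf))
  expect_equal(as.numeric(mi), 0)
})

test_that("MI against a voxel-wise permutation of itself is near zero", {
  ph <- default_phantom()
  perm <- ph$kvct
  set.seed(9)
  perm$voxels <- array(sample(as.numeric(ph$kvct$voxels)),
                       dim = dim(ph$kvct$voxels))
  # dense sampling over the whole grid: > 1e5 paired samples
  mi <- mattes_mutual_information(ph$kvct, perm, NULL, NULL,
                                  registration_config(samples = Inf))
  expect_gte(attr(mi, "n_used"), 1e5)
  expect_lt(as.numeric(mi), 0.05)
})

test_that("MI is deterministic given the seed and errors on no overlap", {
  ph <- default_phantom()
  fr <- fixture("mi_fraction", function() generate_fraction(default_phantom(), 1))
  cfg <- registration_config(samples = 2000, seed = 42)
  m1 <- mattes_mutual_information(ph$kvct, fr$mvct, NULL, default_mask(), cfg)
  m2 <- mattes_mutual_information(ph$kvct, fr$mvct, NULL, default_mask(), cfg)
  expect_identical(as.numeric(m1), as.numeric(m2))

  off <- transform_chain(list(translation_transform(c(1000, 0, 0))))
  expect_error(
    mattes_mutual_information(ph$kvct, fr$mvct, off, default_mask(), cfg),
    "insufficient overlap")
})

test_that("the Parzen MI gradient matches finite differences", {
  ph <- small_phantom()
  fr <- fixture("small_fraction", function() generate_fraction(small_phantom(), 1))
  mask <- build_body_mask(ph$kvct)
  set.seed(3)
  idx <- sample(which(mask$voxels), 1500)
  d <- dim(ph$kvct$voxels)
  i0 <- (idx - 1) %% d[1]
  j0 <- ((idx - 1) %/% d[1]) %% d[2]
  k0 <- (idx - 1) %/% (d[1] * d[2])
  pts <- cbind(ph$kvct$origin[1] + i0 * ph$kvct$spacing[1],
               ph$kvct$origin[2] + j0 * ph$kvct$spacing[2],
               ph$kvct$origin[3] + k0 * ph$kvct$spacing[3])
  clamp <- c(-1024, 3071)
  fv <- pmin(pmax(ph$kvct$voxels[idx], clamp[1]), clamp[2])
  fsu <- corddose:::mi_bin_setup(
    pmin(pmax(as.numeric(ph$kvct$voxels), clamp[1]), clamp[2]), 32)
  fbin <- corddose:::mi_bin_index(fv, fsu, 32)
  mv <- pmin(pmax(as.numeric(fr$mvct$voxels), clamp[1]), clamp[2])
  msu <- corddose:::mi_bin_setup(mv, 32)
  grid <- corddose:::bspline_grid_covering(apply(pts, 2, min),
                                           apply(pts, 2, max), 20)
  set.seed(4)
  st <- bspline_transform(grid$origin, grid$spacing, grid$dim,
                          rnorm(prod(grid$dim) * 3, 0, 0.5))
  mdim <- dim(fr$mvct$voxels)
  eval_mi <- function(p) {
    s <- st; s$params <- p
    corddose:::cpp_bspline_mi_grad(pts, fbin, s, mv, mdim, fr$mvct$spacing,
                                   fr$mvct$origin, msu$min, msu$width,
                                   32L, 32L)
  }
  r <- eval_mi(st$params)
  set.seed(5)
  check_idx <- sample(which(abs(r$grad) > quantile(abs(r$grad), 0.9)), 12)
  h <- 0.05
  for (ti in check_idx) {
    pu <- st$params; pu[ti] <- pu[ti] + h
    pd <- st$params; pd[ti] <- pd[ti] - h
    fd <- (eval_mi(pu)$mi - eval_mi(pd)$mi) / (2 * h)
    expect_equal(r$grad[ti], fd, tolerance = 0.15)
  }
})
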