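test_that("identity, translation and couch-shift chains map points exactly", {
  p <- matrix(c(0, 0, 0, 1, 1, 1, -5, 2, 7), ncol = 3, byrow = TRUE)
  expect_equal(transform_point(transform_chain(), p), p)
  tr <- transform_chain(list(translation_transform(c(1, 2, 3))))
  expect_equal(transform_point(tr, c(0, 0, 0)), matrix(c(1, 2, 3), 1))
  expect_equal(transform_point(couch_shift_transform(c(2, 0, 0)),
                               c(1, 1, 1)), matrix(c(3, 1, 1), 1))
  expect_equal(transform_point(couch_shift_transform(c(0, 0, 0)), p), p)
  expect_error(transform_point(tr, c(Inf, 0, 0)), "finite")
})

test_that("a couch shift chained before a zero B-spline equals the shift alone", {
  st <- bspline_transform(c(-50, -50, -50), 25, c(6, 6, 6))
  chain <- compose_chains(couch_shift_transform(c(2, 0, 0)),
                          transform_chain(list(st)))
  p <- matrix(rnorm(30, 0, 20), 10)
  expect_equal(transform_point(chain, p),
               transform_point(couch_shift_transform(c(2, 0, 0)), p))
})

test_that("B-spline displacement matches a brute-force tensor-product oracle", {
  set.seed(42)
  grid_origin <- c(-10, -10, -10)
  h <- c(10, 10, 10)
  gd <- c(6L, 6L, 6L)
  coef <- rnorm(prod(gd) * 3)
  st <- bspline_transform(grid_origin, h, gd, coef)
  pts <- matrix(runif(300, 5, 25), 100, 3)
  got <- transform_point(transform_chain(list(st)), pts)

  b3 <- function(u) c((1 - 3 * u + 3 * u^2 - u^3) / 6,
                      (4 - 6 * u^2 + 3 * u^3) / 6,
                      (1 + 3 * u + 3 * u^2 - 3 * u^3) / 6,
                      u^3 / 6)
  carr <- array(coef, dim = c(gd, 3))
  oracle <- t(apply(pts, 1, function(p) {
    t <- (p - grid_origin) / h
    i <- floor(t)
    wx <- b3(t[1] - i[1]); wy <- b3(t[2] - i[2]); wz <- b3(t[3] - i[3])
    d <- c(0, 0, 0)
    for (l in 0:3) for (m in 0:3) for (n in 0:3) {
      ci <- i[1] + l; cj <- i[2] + m; ck <- i[3] + n  # 0-based base = i-1
      if (ci >= 1 && cj >= 1 && ck >= 1 && ci <= gd[1] && cj <= gd[2] &&
          ck <= gd[3])
        d <- d + wx[l + 1] * wy[m + 1] * wz[n + 1] * carr[ci, cj, ck, ]
    }
    p + d
  }))
  expect_lt(max(abs(got - oracle)), 1e-9)
})

test_that("points beyond the control lattice get identity displacement", {
  st <- bspline_transform(c(0, 0, 0), 10, c(5, 5, 5),
                          rnorm(5 * 5 * 5 * 3))
  far <- matrix(c(500, 500, 500, -400, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(transform_point(transform_chain(list(st)), far), far)
})

test_that("chain composition equals sequential application", {
  set.seed(5)
  a <- transform_chain(list(
    rigid_transform(c(0.02, -0.01, 0.03), c(1, -2, 3), c(10, 10, 10))))
  b <- transform_chain(list(
    affine_transform(diag(3) + matrix(rnorm(9, 0, 0.02), 3), c(0.5, 0, -1),
                     c(0, 0, 0)),
    bspline_transform(c(-40, -40, -40), 20, c(7, 7, 7),
                      rnorm(7^3 * 3, 0, 0.5))))
  p <- matrix(rnorm(60, 0, 15), 20, 3)
  expect_equal(transform_point(compose_chains(a, b), p),
               transform_point(b, transform_point(a, p)), tolerance = 1e-12)
})

test_that("numerical chain inversion reaches the fixed-point tolerance", {
  set.seed(6)
  chain <- transform_chain(list(
    translation_transform(c(3, -2, 4)),
    bspline_transform(c(-80, -80, -20), 30, c(8, 8, 6),
                      rnorm(8 * 8 * 6 * 3, 0, 1.2))))
  y <- matrix(rnorm(150, 0, 30), 50, 3)
  x <- invert_chain_points(chain, y)
  expect_lt(max(abs(transform_point(chain, x) - y)), 1e-6)
})

test_that("transform serialisation round trips exactly", {
  set.seed(7)
  chain <- transform_chain(list(
    affine_transform(diag(3) + matrix(rnorm(9, 0, 0.05), 3),
                     c(1.5, -0.25, 2), c(3, 4, 5)),
    bspline_transform(c(-60, -60, -10), 15, c(10, 10, 8),
                      rnorm(10 * 10 * 8 * 3))),
    fixed_frame = "plan", moving_frame = "fx01")
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(chain, path)
  back <- read_transform(path)
  expect_identical(lapply(unclass(back), `[[`, "params"),
                   lapply(unclass(chain), `[[`, "params"))
  expect_identical(attr(back, "fixed_frame"), "plan")
  p <- matrix(rnorm(30, 0, 25), 10, 3)
  expect_identical(transform_point(back, p), transform_point(chain, p))
})
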