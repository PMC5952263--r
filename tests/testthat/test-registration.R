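test_that("registering a volume to itself recovers a sub-0.1 mm translation", {
  ph <- default_phantom()
  cfg <- registration_config(stages = "translation", seed = 1)
  chain <- register(ph$kvct, ph$kvct, default_mask(), cfg)
  expect_lt(sqrt(sum(chain[[1]]$params^2)), 0.1)
})

test_that("a known 3D shift is recovered within 0.5 mm per component", {
  ph <- default_phantom()
  fr <- fixture("shift_fraction", function()
    generate_fraction(default_phantom(), 1,
                      deformation = transform_chain(list(
                        translation_transform(c(5, -3, 6))))))
  cfg <- registration_config(stages = "translation", seed = 1)
  chain <- register(ph$kvct, fr$mvct, default_mask(), cfg)
  expect_lt(max(abs(chain[[1]]$params - c(5, -3, 6))), 0.5)
})

test_that("the metric never decreases within a stage and runs are reproducible", {
  ph <- default_phantom()
  fr <- fixture("shift_fraction", function()
    generate_fraction(default_phantom(), 1,
                      deformation = transform_chain(list(
                        translation_transform(c(5, -3, 6))))))
  cfg <- registration_config(stages = c("translation", "affine"), seed = 7)
  c1 <- register(ph$kvct, fr$mvct, default_mask(), cfg)
  for (stage_log in attr(c1, "log"))
    for (lev in stage_log) {
      expect_gte(lev$mi_final, lev$mi_initial - 1e-12)
      expect_true(all(diff(lev$trajectory) >= -1e-12))
    }
  c2 <- register(ph$kvct, fr$mvct, default_mask(), cfg)
  expect_identical(lapply(unclass(c1), `[[`, "params"),
                   lapply(unclass(c2), `[[`, "params"))
})

test_that("doubling the sample count moves the recovered shift by < 0.2 mm", {
  ph <- default_phantom()
  fr <- fixture("shift_fraction", function()
    generate_fraction(default_phantom(), 1,
                      deformation = transform_chain(list(
                        translation_transform(c(5, -3, 6))))))
  a <- register(ph$kvct, fr$mvct, default_mask(),
                registration_config(stages = "translation", seed = 1,
                                    samples = 4096))
  b <- register(ph$kvct, fr$mvct, default_mask(),
                registration_config(stages = "translation", seed = 1,
                                    samples = 8192))
  expect_lt(max(abs(a[[1]]$params - b[[1]]$params)), 0.2)
})

test_that("adding stages does not worsen ground-truth field recovery", {
  ph <- warp_phantom()
  fr <- warp_fraction()
  mask <- warp_mask()
  set.seed(21)
  mp <- corddose:::mask_points(mask)
  lm <- mp[sample(nrow(mp), 300), ]
  truth <- transform_point(fr$truth_chain, lm)
  cfg_t <- registration_config(stages = "translation", seed = 1)
  cfg_ab <- registration_config(stages = c("affine", "bspline"), seed = 1)
  ch_t <- register(ph$kvct, fr$mvct, mask, cfg_t)
  ch_ab <- fixture("warp_chain", function()
    register(warp_phantom()$kvct, warp_fraction()$mvct, warp_mask(), cfg_ab))
  err_t <- mean(sqrt(rowSums((transform_point(ch_t, lm) - truth)^2)))
  err_ab <- mean(sqrt(rowSums((transform_point(ch_ab, lm) - truth)^2)))
  err_0 <- mean(sqrt(rowSums((lm - truth)^2)))
  expect_lt(err_t, err_0)      # translation beats identity
  expect_lt(err_ab, err_t)     # affine + B-spline beats translation
})
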