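test_that("degenerate phantom with no vessels is pure background", {
  spec <- phantom_spec(shape = c(3, 16, 16), geometry = voxel_geometry(0.4, 5),
                       vessels = list(), background_level = 7,
                       background_texture_sd = 0,
                       attenuation = attenuation_model("none"),
                       noise = noise_model("none"), seed = 1)
  ph <- generate_phantom(spec)
  expect_true(all(ph$stack$intensities == 7))
  expect_false(any(ph$truth$vessel_mask))
  expect_equal(ph$truth$expected_mean_intensity, rep(7, 3))
})

test_that("without attenuation or noise the columnar profile is depth-constant", {
  spec <- columnar_phantom_spec(seed = 5, n_slices = 7, size = 64,
                                n_vessels = 3, rate = 0, noise_sd = 0,
                                texture_sd = 0)
  spec$attenuation <- attenuation_model("none")
  ph <- generate_phantom(spec)
  means <- apply(ph$stack$intensities, 3, mean)
  expect_equal(means, rep(means[1], 7))

  # with heterogeneous texture the zero-mean field keeps slice means
  # nearly constant: residual variation comes only from the vessel-edge
  # compositing against the random background
  spec2 <- columnar_phantom_spec(seed = 5, n_slices = 7, size = 64,
                                 n_vessels = 3, rate = 0, noise_sd = 0,
                                 texture_sd = 3)
  spec2$attenuation <- attenuation_model("none")
  m2 <- apply(generate_phantom(spec2)$stack$intensities, 3, mean)
  expect_lt(max(abs(m2 / mean(m2) - 1)), 0.01)
})

test_that("the same spec and seed reproduce a bit-identical phantom", {
  spec <- toy_network_spec(seed = 42, noise = noise_model("gaussian", sd = 1),
                           texture_sd = 4)
  ph1 <- suppressWarnings(generate_phantom(spec))
  ph2 <- suppressWarnings(generate_phantom(spec))
  expect_identical(ph1$stack$intensities, ph2$stack$intensities)
  expect_identical(ph1$truth$vessel_mask, ph2$truth$vessel_mask)
})

test_that("a vessel tube is rasterized at its radius with a soft edge", {
  # one in-plane vessel along the row axis at col 32; at 0.4 um/px a
  # 1.8-um radius spans 4.5 px and the 1-voxel edge ends at 2.2 um
  v <- vessel_spec(rbind(c(2, 10, 32), c(2, 54, 32)), radius_um = 1.8,
                   intensity = 100)
  spec <- phantom_spec(shape = c(3, 64, 64), geometry = voxel_geometry(0.4, 5),
                       vessels = list(v), background_level = 0,
                       background_texture_sd = 0,
                       attenuation = attenuation_model("none"),
                       noise = noise_model("none"), seed = 1)
  ph <- generate_phantom(spec)
  mid <- ph$stack$intensities[, , 2]
  expect_equal(mid[30, 32], 100)           # on the centerline
  expect_equal(mid[30, 32 + 4], 100)       # 1.6 um: inside the radius
  expect_equal(mid[30, 32 + 5], 50)        # 2.0 um: halfway down the edge
  expect_equal(mid[30, 32 + 6], 0)         # 2.4 um: beyond radius + edge
  expect_true(ph$truth$vessel_mask[30, 32, 2])
  expect_true(ph$truth$vessel_mask[30, 32 + 4, 2])
  expect_false(ph$truth$vessel_mask[30, 32 + 5, 2])
  expect_false(any(ph$stack$intensities[, , 1] > 0))  # other slices untouched
})

test_that("vessels leaving the volume are clipped with a warning", {
  v <- vessel_spec(rbind(c(1, 5, 5), c(1, 5, 200)), 2, 50)
  spec <- phantom_spec(shape = c(1, 32, 32), geometry = voxel_geometry(0.4, 5),
                       vessels = list(v), background_level = 0,
                       background_texture_sd = 0,
                       attenuation = attenuation_model("none"),
                       noise = noise_model("none"), seed = 1)
  expect_warning(ph <- generate_phantom(spec), "clipped")
  expect_true(any(ph$truth$vessel_mask))
})

test_that("attenuation fitting recovers closed-form profiles", {
  d <- seq(0, 150, by = 5)
  expect_equal(fit_attenuation(80 * exp(-0.004 * d), 5, "exponential"), 0.004,
               tolerance = 1e-10)
  expect_equal(fit_attenuation(rep(50, 10), 5, "exponential"), 0)
  expect_equal(fit_attenuation(rep(50, 10), 5, "linear"), 0)
  expect_equal(fit_attenuation(100 - 0.3 * d, 5, "linear"), -0.3,
               tolerance = 1e-10)
  expect_error(fit_attenuation(c(1, 0, 1), 5, "exponential"), "positive")
  expect_error(fit_attenuation(c(1, 2), 5, "linear"), ">= 3")
})

test_that("poisson noise respects the gain and stays nonnegative", {
  spec <- phantom_spec(shape = c(2, 48, 48), geometry = voxel_geometry(0.4, 5),
                       vessels = list(), background_level = 50,
                       background_texture_sd = 0,
                       attenuation = attenuation_model("none"),
                       noise = noise_model("poisson", gain = 2), seed = 9)
  ph <- generate_phantom(spec)
  x <- ph$stack$intensities
  expect_true(all(x >= 0))
  expect_true(all(x %% 2 == 0))  # counts times gain
  expect_equal(mean(x), 50, tolerance = 0.05)
})
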