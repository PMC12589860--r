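test_that("per-pair SNR is the log10 bright/dark ratio with degeneracy flagged", {
  expect_equal(pair_snr(100, 10), 1.0)
  expect_equal(pair_snr(1000, 1), 3.0)
  expect_true(is.na(pair_snr(50, 0)))
  expect_error(pair_snr(0, 1), "mu_bright")
  expect_error(pair_snr(-5, 1), "mu_bright")
})

test_that("bright-region selection handles blob spacing as the greedy rule dictates", {
  p <- toy_snr_params(n_regions = 3L)
  base <- matrix(1, 64, 64)

  # one bright square blob: first region sits on the blob (several fully
  # interior windows tie at mean 50; the top-left-most wins)
  one <- base; one[20:24, 30:34] <- 50
  sel <- suppressWarnings(select_bright_regions(one, p))
  expect_equal(unlist(sel[1, c("row", "col")]), c(row = 21, col = 31))

  # two equal blobs 12 px apart (>= 10): both accepted
  two <- base; two[20:22, 10:12] <- 50; two[20:22, 22:24] <- 50
  sel2 <- suppressWarnings(select_bright_regions(two, p))
  expect_equal(unlist(sel2[1, c("row", "col")]), c(row = 21, col = 11))
  expect_equal(unlist(sel2[2, c("row", "col")]), c(row = 21, col = 23))

  # two blobs 8 px apart (< 10): only one from that neighborhood
  near <- base; near[20:22, 10:12] <- 50; near[20:22, 18:20] <- 50
  near[50:52, 50:52] <- 40
  sel3 <- suppressWarnings(select_bright_regions(near, p))
  d12 <- sqrt(sum((unlist(sel3[1, 1:2]) - unlist(sel3[2, 1:2]))^2))
  expect_gte(d12, p$min_distance)
  expect_equal(unlist(sel3[2, c("row", "col")]), c(row = 51, col = 51))
})

test_that("bright and dark searches match the exhaustive oracle on random slices", {
  p <- toy_snr_params()
  set.seed(101)
  for (i in 1:8) {
    sl <- matrix(runif(64 * 64, 0, 100), 64, 64)
    fast <- suppressWarnings(select_bright_regions(sl, p))
    slow <- oracle_select_bright(sl, p)
    expect_equal(fast$row, slow$row)
    expect_equal(fast$col, slow$col)
    expect_equal(fast$mean_intensity, slow$mean_intensity)

    center <- c(sample(64, 1), sample(64, 1))
    fd <- find_dark_region(sl, center, p)
    od <- oracle_find_dark(sl, center, p)
    expect_identical(fd$top_left, od$top_left)
    expect_equal(fd$sd_intensity, od$sd)
  }
})

test_that("dark-region search prefers the quiet half and breaks ties top-left", {
  p <- toy_snr_params()
  # left half uniform, right half textured
  sl <- matrix(5, 40, 40)
  set.seed(7)
  sl[, 21:40] <- matrix(runif(40 * 20, 0, 50), 40)
  dk <- find_dark_region(sl, c(20, 20), p)
  expect_lte(dk$top_left[["col"]] + p$dark_window - 1L, 20)
  expect_equal(dk$sd_intensity, 0)

  # fully uniform slice: top-left-most window of the clamped box
  un <- matrix(3, 40, 40)
  dk2 <- find_dark_region(un, c(20, 20), p)
  expect_equal(dk2$top_left, c(row = 13, col = 13))

  # center near the corner: box clamped to the image
  dk3 <- find_dark_region(sl, c(3, 3), p)
  od3 <- oracle_find_dark(sl, c(3, 3), p)
  expect_identical(dk3$top_left, od3$top_left)
})

test_that("slice SNR averages pairs and matches a brute-force pipeline", {
  p <- toy_snr_params()
  set.seed(55)
  for (i in 1:4) {
    sl <- matrix(runif(64 * 64, 1, 100), 64, 64)
    res <- suppressWarnings(slice_snr(sl, p))
    bright <- oracle_select_bright(sl, p)
    snr_i <- vapply(seq_len(nrow(bright)), function(j) {
      dk <- oracle_find_dark(sl, c(bright$row[j], bright$col[j]), p)
      log10(bright$mean_intensity[j] / dk$sd)
    }, numeric(1))
    expect_equal(res$snr, mean(snr_i))
    expect_equal(res$pairs$snr_i, snr_i)
  }
})

test_that("slice SNR is invariant to gain and monotone in offset", {
  p <- toy_snr_params()
  set.seed(31)
  sl <- matrix(runif(64 * 64, 1, 100), 64, 64)
  base <- suppressWarnings(slice_snr(sl, p))
  for (c in c(0.5, 3, 10)) {
    scaled <- suppressWarnings(slice_snr(c * sl, p))
    expect_equal(scaled$snr, base$snr)
    expect_equal(scaled$pairs$snr_i, base$pairs$snr_i)
  }
  shifted <- suppressWarnings(slice_snr(sl + 25, p))
  expect_true(all(shifted$pairs$snr_i > base$pairs$snr_i))
})

test_that("degenerate slices raise the declared errors", {
  p <- toy_snr_params()
  expect_error(slice_snr(matrix(4, 30, 30), p), "no valid")  # sd = 0 everywhere
  expect_error(select_bright_regions(matrix(1, 2, 2), p), "window")
})

test_that("stack SNR walks slices below the surface in depth order", {
  spec <- columnar_phantom_spec(seed = 12, n_slices = 31, size = 64,
                                n_vessels = 3, rate = 0, noise_sd = 0,
                                texture_sd = 0)
  spec$attenuation <- attenuation_model("none")
  ph <- generate_phantom(spec)
  vol <- analysis_volume(ph$stack, 1)
  res <- suppressWarnings(stack_snr(vol, toy_snr_params()))
  expect_equal(nrow(res$summary), 31)
  expect_equal(res$summary$depth_um, seq(0, 150, by = 5))
  # depth-constant phantom: every slice reports the same snr
  expect_equal(res$summary$snr, rep(res$summary$snr[1], 31))

  # surface designation excludes shallower slices
  vol5 <- analysis_volume(ph$stack, 5)
  res5 <- suppressWarnings(stack_snr(vol5, toy_snr_params()))
  expect_equal(nrow(res5$summary), 27)
  expect_equal(res5$summary$depth_um[1], 0)
})

test_that("snr decays with depth on an attenuated phantom with fixed noise", {
  spec <- columnar_phantom_spec(seed = 3, n_slices = 16, size = 96,
                                n_vessels = 5, rate = 0.008, noise_sd = 1,
                                texture_sd = 0)
  ph <- generate_phantom(spec)
  res <- stack_snr(analysis_volume(ph$stack, 1), toy_snr_params())
  fit <- lm(res$summary$snr ~ res$summary$depth_um)
  expect_lt(coef(fit)[2], 0)
  expect_gt(res$summary$snr[1], res$summary$snr[16])
})

test_that("bright regions on a noiseless phantom lie on true vessels", {
  spec <- toy_network_spec(seed = 77, n_vessels = 8)
  ph <- suppressWarnings(generate_phantom(spec))
  p <- toy_snr_params()
  for (z in c(3, 5, 7)) {
    sel <- tryCatch(
      suppressWarnings(select_bright_regions(get_slice(ph$stack, z), p)),
      error = function(e) NULL)
    if (is.null(sel)) next
    truth <- dilate1(ph$truth$vessel_mask[, , z])
    hit <- mapply(function(r, c) truth[round(r), round(c)], sel$row, sel$col)
    expect_true(all(hit))
  }
})
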