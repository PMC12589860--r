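test_that("the window threshold is mean minus population sd", {
  expect_equal(niblack_threshold_window(rep(4, 9)), 4)
  expect_equal(niblack_threshold_window(c(0, 2)), 0)
  expect_equal(niblack_threshold_window(1:9), 5 - sqrt(60 / 9))
  expect_error(niblack_threshold_window(numeric(0)), "empty")
})

test_that("niblack binarization matches the per-pixel oracle", {
  nib <- niblack_params(15)
  set.seed(202)
  for (i in 1:5) {
    sl <- matrix(runif(48 * 48, 0, 100), 48, 48)
    expect_identical(binarize_niblack(sl, nib)$mask, oracle_niblack_mask(sl, 15))
  }
  # step edge (low cols 1..20, high cols 21..40), window 15 (reach 7):
  # uniform interiors are background on both sides (sd = 0, strict
  # inequality); within reach of the edge the mixed-window threshold
  # mu - sigma drops below the pixel value on the high side always and on
  # the low side wherever the high fraction p of the window is < 1/2
  # (0 > 100 (p - sqrt(p (1 - p))) iff p < 1/2), so the whole boundary
  # band cols 14..27 is foreground
  step <- cbind(matrix(0, 40, 20), matrix(100, 40, 20))
  m <- binarize_niblack(step, nib)$mask
  expect_identical(m, oracle_niblack_mask(step, 15))
  expect_false(any(m[, c(1:13, 28:40)]))
  expect_true(all(m[, 14:27]))
})

test_that("niblack masks are invariant to gain and to additive offsets", {
  nib <- niblack_params(15)
  set.seed(203)
  sl <- matrix(runif(48 * 48, 0, 100), 48, 48)
  base <- binarize_niblack(sl, nib)$mask
  expect_identical(binarize_niblack(3 * sl, nib)$mask, base)
  expect_identical(binarize_niblack(0.5 * sl, nib)$mask, base)
  # the mean shifts with the offset while the sd does not, so the
  # comparison is unchanged
  expect_identical(binarize_niblack(sl + 40, nib)$mask, base)
})

test_that("uniform regions binarize to background under the strict inequality", {
  expect_false(any(binarize_niblack(matrix(9, 30, 30), niblack_params(15))$mask))
})

test_that("dice score behaves as a set-overlap measure", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, 1:2] <- TRUE
  r <- dice_score(a, b)
  expect_equal(r$score, 0.5)  # |A| = |B| = 4, common = 2
  expect_equal(r$pixels_common, 2)
  expect_equal(dice_score(a, a)$score, 1)
  disj <- matrix(FALSE, 4, 4); disj[4, 4] <- TRUE
  expect_equal(dice_score(a, disj)$score, 0)
  # symmetry and monotonicity under adding a shared pixel
  expect_equal(dice_score(b, a)$score, dice_score(a, b)$score)
  a2 <- a; b2 <- b; a2[4, 4] <- TRUE; b2[4, 4] <- TRUE
  expect_gte(dice_score(a2, b2)$score, r$score)
  # both empty: undefined, not 0/0
  e <- matrix(FALSE, 4, 4)
  expect_true(dice_score(e, e)$undefined)
  expect_true(is.na(dice_score(e, e)$score))
  expect_error(dice_score(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("identical channels give dice 1 through the full pipeline", {
  set.seed(204)
  ch <- matrix(runif(64 * 64, 5, 50), 64, 64)
  ch[20:24, 30:34] <- 200
  res <- suppressWarnings(
    coloc_pipeline(ch, ch, niblack_params(15), toy_snr_params()))
  expect_equal(res$dice$score, 1)
  expect_equal(res$snr_a$snr, res$snr_b$snr)
})

test_that("independent channels match the analytic overlap expectation", {
  # under independence E[DICE] ~ 2 p_a p_b / (p_a + p_b) with p the
  # foreground fractions of the realized masks
  nib <- niblack_params(15)
  set.seed(205)
  scores <- obs <- numeric(10)
  for (i in 1:10) {
    a <- matrix(runif(64 * 64), 64, 64)
    b <- matrix(runif(64 * 64), 64, 64)
    ma <- binarize_niblack(a, nib)$mask
    mb <- binarize_niblack(b, nib)$mask
    pa <- mean(ma); pb <- mean(mb)
    scores[i] <- 2 * pa * pb / (pa + pb)
    obs[i] <- dice_score(ma, mb)$score
  }
  expect_equal(mean(obs), mean(scores), tolerance = 0.02)
})

test_that("dice increases with the shared-vessel fraction of two channels", {
  g <- voxel_geometry(0.4, 5)
  mk_channel <- function(shared, own, seed) {
    spec <- phantom_spec(shape = c(1, 96, 96), geometry = g,
                         vessels = c(shared, own), background_level = 10,
                         background_texture_sd = 2,
                         attenuation = attenuation_model("none"),
                         noise = noise_model("none"), seed = seed)
    generate_phantom(spec)$stack$intensities[, , 1]
  }
  set.seed(206)
  vs <- lapply(1:6, function(i) {
    r <- runif(2, 10, 86); c <- runif(2, 10, 86)
    vessel_spec(rbind(c(1, r[1], c[1]), c(1, r[2], c[2])), 2.5, 120)
  })
  nib <- niblack_params(15)
  # channel a always holds vessels 1..4; channel b holds the first k of
  # them (shared) plus its own vessels 5..6
  a_chan <- mk_channel(vs[1:4], list(), 1)
  dice_at <- function(k) {
    b_chan <- mk_channel(vs[seq_len(k)], vs[5:6], 1)
    dice_score(binarize_niblack(a_chan, nib), binarize_niblack(b_chan, nib))$score
  }
  d0 <- dice_at(0); d2 <- dice_at(2); d4 <- dice_at(4)
  expect_true(d0 < d2 && d2 < d4)
  expect_lt(d4, 1)
})
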