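test_that("the spectral-slope estimator recovers constructed exponents with low bias", {
  ks <- c(-2, -1.5, -1, -0.5, 0)
  for (k in ks) {
    est <- sapply(1:5, function(s)
      spectral_slope(make_onef_noise(k, size = 256, seed = 100 + s))$k)
    expect_lt(abs(mean(est) - k), 0.1)
  }
})

test_that("periodic and degenerate images are flagged slope-invalid", {
  g <- make_grating(3, ppd = 30, size = 128)
  sl <- spectral_slope(g)
  expect_false(sl$valid)
  expect_true(is.na(sl$k))

  stripe <- make_stripe_texture(3, ppd = 30, size = 128,
                                wobble_amplitude_deg = 0.1)
  expect_false(spectral_slope(stripe)$valid)

  expect_false(spectral_slope(vd_image(matrix(0.5, 64, 64), 44))$valid)

  # isotropic surrogates stay valid across the exponent range
  for (k in c(0, -1, -2)) {
    expect_true(spectral_slope(make_onef_noise(k, 128, seed = 2))$valid)
  }
})

test_that("box counting reproduces known fractal dimensions and the padding rule", {
  plane <- vd_image(matrix(1, 300, 300), 44)
  fp <- fractal_dimension(plane)
  expect_equal(fp$D, 2, tolerance = 0.05)
  expect_identical(fp$padded_size, 2^9)   # 300 px pads to 512

  line <- matrix(0, 256, 256); line[, 100] <- 1
  fl <- fractal_dimension(vd_image(line, 44))
  expect_equal(fl$D, 1, tolerance = 0.1)

  sp <- vd_image(sierpinski_raster(512), 44)
  fs <- fractal_dimension(sp)
  expect_equal(fs$D, log(3) / log(2), tolerance = 0.05)

  # dimension ordering on matched raster sizes
  plane512 <- fractal_dimension(vd_image(matrix(1, 512, 512), 44))
  line512 <- matrix(0, 512, 512); line512[, 256] <- 1
  fl512 <- fractal_dimension(vd_image(line512, 44))
  expect_gt(plane512$D, fs$D)
  expect_gt(fs$D, fl512$D)

  # box-count curve invariants
  expect_true(all(diff(fs$curve$count_n) <= 0))
  expect_identical(fs$curve$box_size_r, 2^(0:9))

  # empty foreground is invalid, not an error
  fe <- fractal_dimension(vd_image(matrix(0.1, 32, 32), 44))
  expect_false(fe$valid)
})

test_that("posterization keeps the documented threshold side", {
  # 128/255 = 0.502: values at the tie go to the foreground
  m <- matrix(128 / 255, 8, 8)
  expect_true(fractal_dimension(vd_image(m, 44))$valid)
  m2 <- matrix(127 / 255, 8, 8)
  expect_false(fractal_dimension(vd_image(m2, 44))$valid)
})

test_that("CSF weighting matches the published sensitivity profile", {
  # the implemented curve peaks near 8 c/deg (independent 1-D optimization)
  pk <- optimize(csf_mannos_sakrison, c(0.5, 30), maximum = TRUE)$maximum
  expect_equal(pk, 8, tolerance = 1)
  expect_identical(csf_mannos_sakrison(61), 0)
  expect_gt(csf_mannos_sakrison(59.9), 0)

  expect_equal(csf_filter_contrast(vd_image(matrix(0.5, 64, 64), 44)), 0)

  # content above 60 c/deg contributes exactly nothing (integer cycle
  # count keeps all energy above the cut-off)
  hi <- make_grating(200 * 45 / 128, ppd = 200, size = 128)
  expect_gt(rms_contrast(hi), 0.5)
  expect_lt(csf_filter_contrast(hi), 1e-10)

  # CSF contrast bounded by max gain times RMS contrast; both vanish only
  # for constant images
  img <- make_onef_noise(-1, 128, seed = 3)
  expect_lt(csf_filter_contrast(img),
            max(csf_mannos_sakrison(seq(0, 60, 0.01))) * rms_contrast(img) * 1.05)
  expect_gt(csf_filter_contrast(img), 0)
})

test_that("RMS contrast follows the closed-form sinusoid value", {
  expect_identical(rms_contrast(vd_image(matrix(0.3, 16, 16), 44)), 0)
  g <- integer_cycle_grating(4, ppd = 32, size = 128)
  expect_equal(rms_contrast(g), 1 / sqrt(2), tolerance = 1e-9)
})

test_that("edge extraction respects orientation, top-k and border rules", {
  cfg <- edge_extraction_config(top_edges = 2000)
  g <- make_grating(3, ppd = 30, size = 128)
  ed <- extract_edges(g, cfg)
  # a vertical grating loads one orientation bin almost exclusively
  expect_gt(max(table(ed$ori_bin)) / nrow(ed), 0.95)

  # top-k: a rich image offers more candidates than the cap
  noise <- make_onef_noise(-1, size = 150, seed = 8)
  cfg_k <- edge_extraction_config(top_edges = 10000)
  ed_k <- extract_edges(noise, cfg_k)
  expect_identical(nrow(ed_k), 10000L)   # 14400 interior candidates capped
  expect_true(all(diff(ed_k$intensity) <= 0))

  # border rule: structure only within 15 px of the boundary leaves nothing
  m <- matrix(0.5, 120, 120)
  ring <- make_onef_noise(0, 120, seed = 9)$pixels
  m[c(1:8, 113:120), ] <- ring[c(1:8, 113:120), ]
  m[, c(1:8, 113:120)] <- ring[, c(1:8, 113:120)]
  ed_b <- extract_edges(vd_image(m, 44), edge_extraction_config())
  expect_identical(nrow(ed_b), 0L)

  expect_error(extract_edges(vd_image(matrix(0.5, 20, 20), 44)), "border")
})

test_that("edge extraction downscales large images", {
  big <- make_onef_noise(-1, size = 400, seed = 4)
  ed <- extract_edges(big, edge_extraction_config(top_edges = 500))
  expect_lte(max(attr(ed, "image_dim")), 340)
})

test_that("orientation entropies honour their analytic bounds", {
  cfg <- edge_extraction_config()
  # all mass in a single orientation: both entropies collapse to zero
  one <- synthetic_edges(x = seq(20, 80, 2), y = rep(50, 31),
                         ori_bin = 5, theta_deg = 30, intensity = 1)
  ent1 <- edge_orientation_entropy(one)
  expect_identical(ent1$entropy_first, 0)
  expect_identical(ent1$entropy_second, 0)

  # uniform orientations with equal intensities: first-order entropy is
  # maximal, log2(24) bits
  uni <- synthetic_edges(x = rep(50, 24), y = rep(50, 24),
                         ori_bin = 1:24, theta_deg = (0:23) * 7.5,
                         intensity = 1)
  entu <- edge_orientation_entropy(uni)
  expect_equal(entu$entropy_first, log2(24), tolerance = 1e-12)

  # an even spread of orientations within a (d, alpha) section gives
  # exactly 1/24 per orientation and the maximal per-cell entropy:
  # co-located same-orientation pairs all land in the alpha = 0 cell
  rep3 <- synthetic_edges(x = rep(rep(50, 24), 3), y = rep(rep(50, 24), 3),
                          ori_bin = rep(1:24, 3),
                          theta_deg = rep((0:23) * 7.5, 3),
                          intensity = 1)
  entr <- edge_orientation_entropy(rep3)
  cell <- entr$pair_histogram[1, 1, ]
  expect_equal(cell / sum(cell), rep(1 / 24, 24), tolerance = 1e-12)
  expect_equal(entr$cell_entropy[1, 1], log2(24), tolerance = 1e-12)

  # bounds on a real extraction
  ed <- extract_edges(make_onef_noise(-1, 100, seed = 12),
                      edge_extraction_config(top_edges = 400))
  ent <- edge_orientation_entropy(ed)
  expect_gte(ent$entropy_first, 0); expect_lte(ent$entropy_first, log2(24))
  expect_gte(ent$entropy_second, 0); expect_lte(ent$entropy_second, log2(24))
})

test_that("second-order entropy equals the brute-force pairwise oracle", {
  cfg <- edge_extraction_config(top_edges = 300)
  for (seed in c(21, 22)) {
    ed <- extract_edges(make_onef_noise(-1, 100, seed = seed), cfg)
    expect_lte(nrow(ed), 300)
    got <- edge_orientation_entropy(ed, cfg)$entropy_second
    d_max <- sqrt(sum(attr(ed, "image_dim")^2))
    want <- brute_force_pair_entropy(ed, cfg, d_max)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("entropies are invariant to a 90-degree image rotation", {
  img <- make_onef_noise(-1, size = 100, seed = 30)
  rot <- vd_image(t(img$pixels)[ncol(img$pixels):1, ], img$ppd, img$category)
  cfg <- edge_extraction_config(top_edges = 100000)   # keep all edges
  e1 <- edge_orientation_entropy(extract_edges(img, cfg), cfg)
  e2 <- edge_orientation_entropy(extract_edges(rot, cfg), cfg)
  expect_equal(e1$entropy_first, e2$entropy_first, tolerance = 0.02)
  expect_equal(e1$entropy_second, e2$entropy_second, tolerance = 0.02)
})

test_that("the aggregate statistics record flags rather than aborts, and round-trips CSV", {
  cfg <- edge_extraction_config(top_edges = 400)
  b <- make_bump_noise(3, ppd = 44, size = 128, seed = 2)
  g <- make_grating(3, ppd = 44, size = 128)
  tab <- compute_image_stats_batch(list(b, g), ids = c("bump1", "grat1"),
                                   edge_config = cfg)
  expect_equal(nrow(tab), 2)
  expect_true(tab$slope_valid[1])
  expect_false(tab$slope_valid[2])
  expect_true(is.na(tab$slope_k[2]))
  expect_match(tab$flags[2], "slope_invalid")
  expect_true(all(tab$rms_contrast > 0))
  expect_true(all(is.finite(tab$entropy_first)))

  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tab, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  back$flags[is.na(back$flags)] <- ""
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)
})
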