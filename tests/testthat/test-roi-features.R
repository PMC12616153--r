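test_that("nyquist frequency follows 1/(2 tr)", {
  expect_equal(round(nyquist(1.65), 3), 0.303)
  expect_equal(nyquist(1.0), 0.5)
  expect_equal(nyquist(0.5), 1.0)
  expect_error(nyquist(0), "positive")
})

test_that("gaussian smoothing is the identity at fwhm 0 and preserves constants", {
  set.seed(4)
  vol <- volume3d(array(rnorm(6 * 5 * 4), c(6, 5, 4)), c(2, 2, 2))
  expect_identical(gaussian_smooth(vol, 0)$data, vol$data)
  sm <- gaussian_smooth(volume3d(array(7, c(8, 8, 8)), c(3, 3, 3)), 8)
  expect_equal(range(sm$data), c(7, 7))
  expect_error(gaussian_smooth(vol, -1), "nonnegative")
})

test_that("smoothed delta matches the closed-form gaussian kernel", {
  dims <- c(31, 31, 31)
  arr <- array(0, dims); arr[16, 16, 16] <- 1
  sm <- gaussian_smooth(volume3d(arr, c(2, 2, 2)), fwhm = 8)
  sigma <- 8 / (2 * sqrt(2 * log(2)))
  # evaluate the continuous kernel times voxel volume on the interior
  # (rows there have their full 6-sigma support inside the grid)
  rng <- 12:20
  grid <- expand.grid(i = rng, j = rng, k = rng)
  d2 <- ((grid$i - 16) * 2)^2 + ((grid$j - 16) * 2)^2 + ((grid$k - 16) * 2)^2
  oracle <- (2 / (sqrt(2 * pi) * sigma))^3 * exp(-d2 / (2 * sigma^2))
  got <- as.vector(sm$data[rng, rng, rng])
  expect_lt(max(abs(got - oracle) / oracle), 1e-6)
})

test_that("roi aggregation equals a voxel-by-voxel loop", {
  fx <- make_test_atlas(seed = 11)
  agg <- roi_aggregate(fx$vol, fx$atlas)
  for (i in seq_len(nrow(agg))) {
    tot <- 0; cnt <- 0
    for (x in 1:dim(fx$vol$data)[1]) for (y in 1:dim(fx$vol$data)[2])
      for (z in 1:dim(fx$vol$data)[3]) {
        if (fx$atlas$data[x, y, z] == agg$label[i]) {
          tot <- tot + fx$vol$data[x, y, z]; cnt <- cnt + 1
        }
      }
    expect_equal(agg$value[i], tot / cnt, tolerance = 1e-13)
  }
  cvol <- volume3d(array(7, dim(fx$vol$data)), fx$vol$voxel_mm)
  expect_true(all(roi_aggregate(cvol, fx$atlas)$value == 7))
  expect_error(roi_aggregate(fx$vol, fx$atlas, labels = 99), "not in")
  expect_error(roi_aggregate(fx$vol, fx$atlas, labels = integer(0)), "empty")
  # label in the map but absent from the array
  map2 <- rbind(fx$atlas$label_map,
                data.frame(label = 4L, roi = "R_AG", hemisphere = "R"))
  atlas2 <- atlas_volume(fx$atlas$data, map2, fx$atlas$voxel_mm)
  expect_error(roi_aggregate(fx$vol, atlas2, labels = 4L), "no voxels")
})

test_that("pALFF separates in-band, out-of-band, and noise signals", {
  nt <- 427; tr <- 1.65
  tt <- (seq_len(nt) - 1) * tr
  set.seed(21)
  n_noise <- 300
  arr <- array(0, c(n_noise + 2, 1, 1, nt))
  arr[1, 1, 1, ] <- sin(2 * pi * 0.05 * tt + 0.7)
  arr[2, 1, 1, ] <- sin(2 * pi * 0.20 * tt + 0.2)
  for (v in 3:(n_noise + 2)) arr[v, 1, 1, ] <- rnorm(nt)
  bold <- volume4d(arr, tr = tr)
  mask <- array(1, c(n_noise + 2, 1, 1))
  raw <- compute_palff(bold, mask, normalize = FALSE)$data
  expect_gte(raw[1, 1, 1], 0.99)
  expect_lte(raw[2, 1, 1], 0.01)
  # flat-spectrum oracle: expected ratio is the in-band bin fraction
  f <- (1:floor(nt / 2)) / (nt * tr)
  frac <- sum(f >= 0.01 & f <= 0.08) / length(f)
  noise_mean <- mean(raw[3:(n_noise + 2), 1, 1])
  mc_se <- sd(raw[3:(n_noise + 2), 1, 1]) / sqrt(n_noise)
  expect_lt(abs(noise_mean - frac), 4 * mc_se)

  # masked-mean normalization and scale invariance
  norm <- compute_palff(bold, mask)$data
  expect_lt(abs(mean(norm[mask != 0]) - 1), 1e-10)
  raw10 <- compute_palff(volume4d(arr * 10, tr = tr), mask,
                         normalize = FALSE)$data
  expect_equal(raw10, raw, tolerance = 1e-12)
})

test_that("periodogram satisfies Parseval's identity", {
  set.seed(6)
  for (n in c(16, 427)) {
    x <- rnorm(n)
    pg <- periodogram(x, 1.65)
    expect_lt(abs(sum(pg$power) - sum(x^2)) / sum(x^2), 1e-8)
  }
})

test_that("pALFF validates its inputs", {
  set.seed(3)
  bold <- volume4d(array(rnorm(2 * 2 * 2 * 32), c(2, 2, 2, 32)), tr = 2)
  expect_error(compute_palff(bold, array(0, c(2, 2, 2))), "empty mask")
  expect_error(
    compute_palff(bold, array(1, c(2, 2, 2)),
                  palff_config(band_high = 0.3)),
    "Nyquist")
  expect_error(palff_config(band_low = 0.1, band_high = 0.05), "band_low")
  arr0 <- array(rnorm(2 * 2 * 2 * 32), c(2, 2, 2, 32))
  arr0[1, 1, 1, ] <- 0
  expect_warning(
    compute_palff(volume4d(arr0, tr = 2), array(1, c(2, 2, 2)),
                  palff_config(detrend = FALSE)),
    "all-zero")
})

test_that("phantom pALFF ranks in-band > noise > out-of-band across seeds", {
  for (seed in c(1, 2, 3)) {
    cfg <- synthetic_config(seed = seed, phantom_n_volumes = 200L)
    ph <- generate_phantom_bold(cfg)
    raw <- compute_palff(ph$bold, ph$mask, normalize = FALSE)
    agg <- roi_aggregate(raw, ph$atlas)
    v <- setNames(agg$value, agg$roi)
    expect_gt(v["inband"], v["noise"])
    expect_gt(v["noise"], v["outband"])
  }
})

test_that("volumes round-trip through NIfTI", {
  ph <- generate_phantom_bold(synthetic_config(seed = 2,
                                               phantom_n_volumes = 16L))
  tmp4 <- tempfile(fileext = ".nii.gz")
  write_volume(ph$bold, tmp4)
  back <- read_volume4d(tmp4)
  expect_equal(back$data, ph$bold$data, tolerance = 1e-6)
  expect_equal(back$tr, 1.65)
  tmp3 <- tempfile(fileext = ".nii.gz")
  write_volume(ph$mask, tmp3)
  expect_equal(read_volume3d(tmp3)$data, ph$mask$data, tolerance = 1e-6)
  unlink(c(tmp3, tmp4))
})
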