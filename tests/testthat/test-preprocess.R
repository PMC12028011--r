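test_that("resample_volume honours the shape arithmetic and identity case", {
  v <- tiny_volume(c(10L, 8L, 8L), spacing = c(6, 1, 1))
  r <- resample_volume(v, c(3, 1, 1))
  expect_equal(dim(r$voxels), c(20L, 8L, 8L))
  expect_equal(r$spacing, c(3, 1, 1))
  # identity: same spacing returns values unchanged
  same <- resample_volume(v, c(6, 1, 1))
  expect_equal(same$voxels, v$voxels)
  expect_error(resample_volume(v, c(0, 1, 1)), "positive")
})

test_that("resampling preserves constant images", {
  v <- sequence_volume(array(3.7, c(7, 9, 11)), c(2.5, 0.8, 1.3), "ADC")
  r <- resample_volume(v, c(1.0, 0.5, 0.5))
  expect_lt(max(abs(r$voxels - 3.7)), 1e-6)
})

test_that("central_crop slices, pads, and honours a mask-centroid center", {
  v <- with_seed(3, array(rnorm(40 * 30 * 30), c(40, 30, 30)))
  out <- central_crop(v, c(8L, 20L, 20L))
  expect_equal(dim(out), c(8L, 20L, 20L))
  # interior crop must be a contiguous block of the input
  expect_true(all(out %in% v))

  small <- array(1, c(4L, 10L, 10L))
  padded <- central_crop(small, c(8L, 20L, 20L))
  expect_equal(dim(padded), c(8L, 20L, 20L))
  expect_equal(sum(padded), sum(small))  # zero padding adds nothing
  expect_equal(sum(padded[3:6, 6:15, 6:15]), sum(small))  # data centred

  # off-centre blob: crop centred on brute-force centroid keeps it whole
  mask <- array(0, c(20L, 40L, 40L))
  mask[3:6, 5:12, 30:37] <- 1
  ctr_brute <- colMeans(which(mask > 0, arr.ind = TRUE))
  expect_equal(unname(mask_centroid(mask)), unname(ctr_brute))
  crop <- central_crop(mask, c(8L, 16L, 16L), center = mask_centroid(mask))
  expect_equal(sum(crop), sum(mask))
})

test_that("minmax_normalize maps to [0,1], is idempotent, zeros constants", {
  v <- sequence_volume(array(c(0, 5, 10, 2, 7, 4, 9, 1), c(2, 2, 2)),
                       c(1, 1, 1), "T2W")
  n <- minmax_normalize(v)
  expect_equal(range(n$voxels), c(0, 1))
  expect_equal(sort(unique(n$voxels))[1:3], c(0, 0.1, 0.2))
  expect_equal(minmax_normalize(n)$voxels, n$voxels)  # idempotent
  rnd <- tiny_volume(c(5L, 7L, 7L), seed = 9)
  expect_equal(range(minmax_normalize(rnd)$voxels), c(0, 1))
  expect_warning(out <- minmax_normalize(array(2, c(2, 2, 2))), "constant")
  expect_true(all(out == 0))
})

test_that("prostate_volume: arithmetic, analytic ellipsoid, invariances", {
  m <- array(0, c(50L, 40L, 40L)); m[seq_len(25), , ] <- 1  # 40000 voxels
  expect_equal(prostate_volume(m, c(3.0, 0.5, 0.5)), 30.0)
  m2 <- array(0, c(10L, 10L, 10L)); m2[] <- 1               # 1000 voxels
  expect_equal(prostate_volume(m2, c(1, 1, 1)), 1.0)
  expect_error(prostate_volume(array(0, c(3, 3, 3)), c(1, 1, 1)), "empty")

  # analytic oracle: ellipsoid of semi-axes (a,b,c) has volume 4/3 pi abc
  sp <- c(0.5, 0.5, 0.5)
  grid <- bpfusion:::ellipsoid_mask(c(120L, 120L, 120L), sp, c(0, 0, 0),
                                    c(14, 20, 17))
  analytic <- 4 / 3 * pi * 14 * 20 * 17 / 1000
  expect_lt(abs(prostate_volume(grid, sp) - analytic) / analytic, 0.02)

  # translation invariance
  shifted <- array(0, dim(m)); shifted[26:50, , ] <- 1
  expect_equal(prostate_volume(m, c(3, 0.5, 0.5)),
               prostate_volume(shifted, c(3, 0.5, 0.5)))
  # spacing equivariance: doubling each spacing scales volume by 8
  expect_equal(prostate_volume(m, 2 * c(3, 0.5, 0.5)),
               8 * prostate_volume(m, c(3, 0.5, 0.5)))
})

test_that("psa_density is the plain ratio with guards", {
  expect_equal(psa_density(6, 30), 0.2)
  expect_equal(psa_density(0, 25), 0)
  expect_equal(psa_density(4, 40), 0.1)
  expect_error(psa_density(4, 0), "> 0")
})

test_that("scale_clinical maps endpoints, midpoint, clips, degenerates", {
  recs <- lapply(c(50, 60, 70), function(a)
    clinical_record(age = a, psa = a / 10, psa_density = a / 500))
  b <- fit_clinical_bounds(recs)
  expect_equal(b$age, c(min = 50, max = 70))
  r <- scale_clinical(clinical_record(age = 50, psa = 5, psa_density = 0.1), b)
  expect_equal(r$age_norm, -1)
  r <- scale_clinical(clinical_record(age = 70, psa = 7, psa_density = 0.14), b)
  expect_equal(r$age_norm, 1)
  r <- scale_clinical(clinical_record(age = 60, psa = 6, psa_density = 0.12), b)
  expect_equal(r$age_norm, 0)
  # clipping beyond training bounds
  r <- scale_clinical(clinical_record(age = 85, psa = 99, psa_density = 1), b)
  expect_equal(c(r$age_norm, r$psa_norm, r$psad_norm), c(1, 1, 1))
  # degenerate bounds on one variable only
  b2 <- b
  b2$age <- c(min = 60, max = 60)
  expect_warning(r2 <- scale_clinical(recs[[2]], b2), "degenerate.*age")
  expect_equal(r2$age_norm, 0)
})

test_that("pipeline output shape is exactly crop_shape for every sequence", {
  cfg <- preprocess_config(target_spacing = c(4, 2, 2),
                           crop_shape = c(6L, 12L, 12L))
  for (seed in 1:3) {
    cs <- tiny_case(sprintf("c%d", seed), dim = c(5L, 9L, 9L), seed = seed)
    # give the volumes anisotropic spacing so resampling actually acts
    for (k in names(cs$volumes)) cs$volumes[[k]]$spacing <- c(6, 1.5, 1.5)
    out <- preprocess_case(cs, cfg)
    for (k in names(out$volumes)) {
      expect_equal(dim(out$volumes[[k]]$voxels), c(6L, 12L, 12L))
      expect_gte(min(out$volumes[[k]]$voxels), 0)
      expect_lte(max(out$volumes[[k]]$voxels), 1)
    }
    expect_equal(dim(out$gland_mask), c(6L, 12L, 12L))
  }
})

test_that("MASK_CENTROID cropping requires and uses the mask", {
  cfg <- preprocess_config(target_spacing = c(3, 1, 1),
                           crop_shape = c(4L, 6L, 6L),
                           crop_center_policy = "MASK_CENTROID")
  cs <- tiny_case(with_mask = FALSE)
  expect_error(preprocess_case(cs, cfg), "requires a gland mask")
  cs2 <- tiny_case(with_mask = TRUE)
  out <- preprocess_case(cs2, cfg)
  expect_equal(dim(out$volumes$T2W$voxels), c(4L, 6L, 6L))
})
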