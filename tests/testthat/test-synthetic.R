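test_that("planted fractions are exact-count at pixel resolution", {
  sp <- phantom_spec(c(120, 120), 0.40, seed = 801)
  ph <- make_mammogram_phantom(sp)
  expect_identical(ph$truth$n_gland,
                   as.integer(round(0.40 * ph$truth$n_roi)))
  expect_equal(ph$truth$gland_fraction, ph$truth$n_gland / ph$truth$n_roi)
  # noise-free classes: direct pixel count reproduces the planted count
  sp0 <- phantom_spec(c(120, 120), 0.40, gland_sd = 0, fat_sd = 0, seed = 802)
  ph0 <- make_mammogram_phantom(sp0)
  mid <- (sp0$gland_mean + sp0$fat_mean) / 2
  expect_identical(sum(ph0$record$pixels[ph0$mask] >= mid), ph0$truth$n_gland)
})

test_that("generators are pure functions of seed and spec", {
  sp <- phantom_spec(c(64, 64), 0.3, seed = 803)
  ph1 <- make_mammogram_phantom(sp)
  ph2 <- make_mammogram_phantom(sp)
  expect_identical(ph1, ph2)
  m1 <- make_mri_phantom(phantom_spec(c(16, 16, 16), 0.3, seed = 804), "STIR")
  m2 <- make_mri_phantom(phantom_spec(c(16, 16, 16), 0.3, seed = 804), "STIR")
  expect_identical(m1, m2)
  t1 <- make_measure_table(30, 0.9, seed = 805)
  t2 <- make_measure_table(30, 0.9, seed = 805)
  expect_identical(t1, t2)
  # written fixtures are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_mammogram_fixture(ph1, d1, format = "dicom")
  p2 <- write_mammogram_fixture(ph2, d2, format = "dicom")
  expect_identical(unname(tools::md5sum(p1[["image"]])),
                   unname(tools::md5sum(p2[["image"]])))
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- .Random.seed
  invisible(make_mammogram_phantom(sp))
  expect_identical(.Random.seed, before)
})

test_that("noise-free phantoms round-trip exactly through the HSM pipeline", {
  sp <- phantom_spec(c(100, 100), 0.62, gland_sd = 0, fat_sd = 0, seed = 806)
  ph <- make_mammogram_phantom(sp)
  res <- hsm_density(ph$record)
  expect_equal(res$composition$pct_g / 100, ph$truth$gland_fraction)
})

test_that("MRI phantom intensity ordering follows the protocol", {
  sp <- phantom_spec(c(20, 20, 20), 0.3, gland_mean = 80, fat_mean = 200,
                     gland_sd = 5, fat_sd = 5, seed = 807)
  for (proto in c("3DGRE", "STIR")) {
    ph <- make_mri_phantom(sp, proto)
    lab <- ph$truth$labels
    gl <- mean(ph$volume$voxels[which(lab)])
    ft <- mean(ph$volume$voxels[which(!lab)])
    if (proto == "3DGRE") expect_lt(gl, ft) else expect_gt(gl, ft)
  }
})

test_that("true total volume follows the voxel geometry", {
  sp <- phantom_spec(c(20, 20, 20), 0.3, geometry = voxel_geometry(1, 1),
                     seed = 808)
  ph <- make_mri_phantom(sp, "3DGRE")
  expect_equal(ph$truth$tv_ml, sum(ph$volume$breast_mask) * 1 / 1000)
  sp2 <- phantom_spec(c(20, 20, 20), 0.3, geometry = voxel_geometry(0.7, 2),
                      seed = 808)
  ph2 <- make_mri_phantom(sp2, "3DGRE")
  expect_equal(ph2$truth$tv_ml, sum(ph2$volume$breast_mask) * 0.686 / 1000)
})

test_that("measure tables honour correlation and offset structure", {
  # degenerate: perfect correlation, no offsets -> identical columns
  tab1 <- make_measure_table(20, 1, seed = 809)
  w <- breastdens:::measures_wide(tab1, "tv_ml")
  expect_true(all(abs(w - w[, 1]) < 1e-9))
  # rho = 0.9, n = 300: sample correlation within the sampling band
  tab2 <- make_measure_table(300, 0.9, seed = 810)
  r <- correlation_matrix(tab2, "tv_ml")
  off_diag <- r[upper.tri(r)]
  expect_true(all(off_diag > 0.85 & off_diag < 0.95))
  # a planted 50 mL offset appears as ~50 mL pairwise difference
  tab3 <- make_measure_table(400, 0.9, offsets = c(STIR = 50), seed = 811)
  cmp <- pairwise_mean_differences(tab3, "tv_ml")
  hs <- cmp[cmp$method_a == "HSM" & cmp$method_b == "STIR", ]
  expect_lt(abs(hs$mean_diff + 50), 15)  # CLT bound: se ~ 150*sqrt(0.2)/20
  expect_error(make_measure_table(10, 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(make_measure_table(10, 0.5, offsets = c(XX = 1), seed = 1),
               "not among methods")
})

test_that("phantom specs validate their invariants", {
  expect_error(phantom_spec(c(10, 10), 0.5), "seed is mandatory")
  expect_error(phantom_spec(c(10, 10), 1.5, seed = 1), "\\[0, 1\\]")
  expect_error(phantom_spec(c(10, 10), 0.5, gland_mean = 60, fat_mean = 60,
                            seed = 1), "distinct")
  expect_error(make_mri_phantom(phantom_spec(c(10, 10), 0.5, seed = 1)),
               "3-axis")
  expect_error(make_mammogram_phantom(phantom_spec(c(8, 8, 8), 0.5, seed = 1)),
               "2-axis")
})
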