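test_that("ROI isolation keeps the disk phantom exactly", {
  px <- matrix(0, 60, 60)
  disk <- (row(px) - 30)^2 + (col(px) - 30)^2 <= 15^2
  px[disk] <- 100
  expect_identical(isolate_breast_roi(px), disk)
  expect_error(isolate_breast_roi(matrix(0, 10, 10)), "no breast found")
})

test_that("ROI isolation keeps only the larger of two components", {
  sp <- phantom_spec(c(80, 80), 0.4, seed = 201)
  ph <- make_mammogram_phantom(sp, add_label_artifact = TRUE)
  mask <- isolate_breast_roi(ph$record$pixels)
  lab <- oracle_label_components(ph$record$pixels > 0)
  sizes <- table(lab[lab > 0])
  expect_identical(sum(mask), as.integer(max(sizes)))  # artifact dropped
  largest <- as.integer(names(sizes)[which.max(sizes)])
  expect_identical(mask, lab == largest)
})

test_that("chest-wall margin columns are excluded from the ROI", {
  px <- matrix(100, 20, 20)
  mask <- isolate_breast_roi(px, chest_margin = 5, chest_side = "left")
  expect_false(any(mask[, 1:5]))
  expect_true(all(mask[, 6:20]))
})

test_that("Otsu threshold separates a bimodal histogram and matches the exhaustive scan", {
  vals <- c(rep(50, 500), rep(200, 500))
  h <- intensity_histogram(vals)
  thr <- select_threshold(h, "otsu")
  expect_gt(thr, 50)
  expect_lt(thr, 200)
  expect_equal(thr, oracle_otsu(h))
})

test_that("Otsu equals the exhaustive between-class-variance maximiser on random histograms", {
  for (s in 1:30) {
    set.seed(3000 + s)
    f <- runif(1, 0.1, 0.9)
    n <- 2000
    vals <- round(c(rnorm(round(f * n), 180, runif(1, 5, 25)),
                    rnorm(n - round(f * n), 60, runif(1, 5, 25))))
    h <- intensity_histogram(pmax(vals, 0))
    expect_equal(select_threshold(h, "otsu"), oracle_otsu(h))
  }
})

test_that("fixed strategies return their value verbatim; constant images are rejected", {
  h <- intensity_histogram(c(rep(50, 10), rep(200, 10)))
  expect_identical(select_threshold(h, 120), 120)
  expect_identical(select_threshold(h, "fixed:120"), 120)
  hc <- intensity_histogram(rep(7, 100))
  expect_error(select_threshold(hc, "otsu"), "single intensity level")
  expect_error(select_threshold(hc, "median"), "unknown threshold strategy")
})

test_that("segmentation tallies constructed class counts and honours boundaries", {
  px <- matrix(c(rep(200, 250), rep(50, 750)), 40, 25)
  mask <- matrix(TRUE, 40, 25)
  seg <- segment_areas(px, mask, 120)
  expect_identical(seg$g_area_px, 250L)
  expect_identical(seg$f_area_px, 750L)
  expect_identical(seg$t_area_px, 1000L)
  expect_identical(seg$g_area_px + seg$f_area_px, seg$t_area_px)
  # threshold below all intensities: everything is gland
  seg_lo <- segment_areas(px, mask, 0)
  expect_identical(seg_lo$g_area_px, seg_lo$t_area_px)
  expect_identical(seg_lo$f_area_px, 0L)
  # pixels exactly at the threshold are glandular (closed lower bound)
  seg_eq <- segment_areas(px, mask, 200)
  expect_identical(seg_eq$g_area_px, 250L)
  # inverted polarity flips the classes, ties still glandular
  seg_inv <- segment_areas(px, mask, 50, glandular_bright = FALSE)
  expect_identical(seg_inv$g_area_px, 750L)
})

test_that("raising the threshold never increases the glandular area", {
  set.seed(42)
  px <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  g <- vapply(seq(0, 260, by = 5),
              function(t) segment_areas(px, mask, t)$g_area_px, integer(1L))
  expect_true(all(diff(g) <= 0L))
})

test_that("a planted well-separated fraction is recovered exactly from the phantom", {
  sp <- phantom_spec(c(100, 100), 0.40, gland_sd = 0, fat_sd = 0, seed = 202)
  ph <- make_mammogram_phantom(sp)
  res <- hsm_density(ph$record)
  # oracle: direct pixel-class count at the class midpoint
  mid <- (sp$gland_mean + sp$fat_mean) / 2
  direct <- sum(ph$record$pixels[ph$mask] >= mid) / sum(ph$mask)
  expect_equal(res$composition$pct_g / 100, direct)
  expect_equal(res$composition$pct_g / 100, ph$truth$gland_fraction)
})

test_that("areas convert to volumes by factor x area x thickness", {
  px <- matrix(c(rep(200, 25), rep(50, 75)), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  seg <- segment_areas(px, mask, 120)
  comp <- areas_to_composition(seg, preexposure_thickness = 50, factor = 9.96)
  expect_equal(comp$pct_g, 25)        # g/(g+f) structure
  expect_equal(comp$tv_ml, comp$gv_ml + comp$fv_ml)
  # independent multiplication for a 100-gland-pixel segmentation
  seg100 <- segment_areas(matrix(200, 10, 10), matrix(TRUE, 10, 10), 120)
  comp100 <- areas_to_composition(seg100, 50, 9.96)
  expect_equal(comp100$gv_ml, 9.96 * 100 * 50)
  # zero-gland boundary
  seg0 <- segment_areas(matrix(50, 10, 10), matrix(TRUE, 10, 10), 120)
  comp0 <- areas_to_composition(seg0, 50, 9.96)
  expect_equal(comp0$pct_g, 0)
  expect_equal(comp0$gv_ml, 0)
  expect_equal(comp0$tv_ml, comp0$fv_ml)
  # contract errors
  expect_error(areas_to_composition(seg, 0), "positive")
  seg$t_area_px <- 0L; seg$g_area_px <- 0L; seg$f_area_px <- 0L
  expect_error(areas_to_composition(seg, 50), "total area is zero")
})

test_that("volume conservation holds to 1e-9 relative on random compositions", {
  set.seed(77)
  for (i in 1:200) {
    comp <- compose_from_pct(runif(1, 0, 100), runif(1, 1, 2000),
                             method = sample(c("MATH", "FFDM"), 1))
    expect_lt(abs(comp$gv_ml + comp$fv_ml - comp$tv_ml),
              1e-9 * max(1, comp$tv_ml))
  }
})
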