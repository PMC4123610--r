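test_that("voxel histograms conserve mass and match a direct tally", {
  sp <- phantom_spec(c(20, 20, 20), 0.3, gland_mean = 80, fat_mean = 200,
                     gland_sd = 15, fat_sd = 15, seed = 401)
  ph <- make_mri_phantom(sp, "3DGRE")
  h <- build_histogram(ph$volume, n_bins = 64L)
  expect_equal(sum(h$count), sum(ph$volume$breast_mask))
  vals <- ph$volume$voxels[ph$volume$breast_mask]
  expect_equal(h$count, oracle_bin_tally(vals, h$breaks))
})

test_that("a constant volume collapses to one occupied bin", {
  vox <- array(5.5, c(8, 8, 8))
  mask <- array(TRUE, c(8, 8, 8))
  vol <- mri_volume(vox, mask, voxel_geometry(1, 1), "3DGRE")
  h <- build_histogram(vol)
  expect_identical(length(h$mid), 1L)
  expect_equal(sum(h$count), 512)
  expect_error(mri_volume(vox, array(FALSE, c(8, 8, 8)), voxel_geometry(1, 1)),
               "empty")
})

test_that("a noise-free two-Gaussian curve is recovered to 1e-6 relative", {
  x <- seq(0, 300, length.out = 128L)
  truth <- c(A1 = 900, mu1 = 80, sigma1 = 14, A2 = 2200, mu2 = 210, sigma2 = 22)
  y <- truth[["A1"]] * exp(-(x - truth[["mu1"]])^2 / (2 * truth[["sigma1"]]^2)) +
       truth[["A2"]] * exp(-(x - truth[["mu2"]])^2 / (2 * truth[["sigma2"]]^2))
  h <- structure(list(mid = x, count = y,
                      breaks = NULL, type = "uniform"), class = "bd_histogram")
  fit <- fit_two_gaussians(h)
  expect_true(fit$converged)
  expect_equal(coef(fit), truth, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-8 * sum(y^2))
})

test_that("the fitted gland fraction recovers the sampled mixture weight", {
  mx <- make_mixture_histogram(1e5, 0.30, gland_mean = 80, gland_sd = 15,
                               fat_mean = 200, fat_sd = 15, seed = 402)
  fit <- fit_two_gaussians(mx$histogram)
  fit <- assign_gland_component(fit, "3DGRE")  # gland is the low-mean class here
  expect_true(fit$converged)
  expect_lt(abs(fit$fraction_gland - mx$truth), 0.02)
})

test_that("a single-Gaussian histogram yields an honest degenerate result", {
  set.seed(403)
  vals <- rnorm(2e4, 120, 18)
  h <- intensity_histogram(vals, n_bins = 128L)
  res <- withCallingHandlers(
    tryCatch(fit_two_gaussians(h), error = function(e) e),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_false(inherits(res, "error"))
  areas <- res$areas
  # either the fit flags non-convergence, or one component is (near) empty,
  # or both components collapse onto the same peak; never a silent bogus split
  same_peak <- abs(res$coefficients[["mu1"]] - res$coefficients[["mu2"]]) <
    2 * max(res$coefficients[["sigma1"]], res$coefficients[["sigma2"]])
  expect_true(!res$converged || min(areas) / sum(areas) < 0.05 || same_peak)
})

test_that("too few occupied bins is an error, not a fit", {
  h <- intensity_histogram(rep(c(1, 2, 3, 4, 5), each = 10))
  expect_error(fit_two_gaussians(h), "at least 6")
})

test_that("gland assignment follows protocol polarity and the override wins", {
  mx <- make_mixture_histogram(2e4, 0.35, gland_mean = 80, gland_sd = 12,
                               fat_mean = 200, fat_sd = 12, seed = 404)
  fit <- fit_two_gaussians(mx$histogram)
  g3 <- assign_gland_component(fit, "3DGRE")
  gs <- assign_gland_component(fit, "STIR")
  expect_identical(g3$gland, "low")    # fat bright -> gland is the dim class
  expect_identical(gs$gland, "high")   # fat suppressed -> gland is bright
  expect_equal(g3$fraction_gland + gs$fraction_gland, 1)
  expect_warning(ov <- assign_gland_component(fit, "3DGRE", override = "high"),
                 "overridden")
  expect_identical(ov$gland, "high")
  fit$coefficients[["mu2"]] <- fit$coefficients[["mu1"]]
  expect_error(assign_gland_component(fit, "3DGRE"), "equal")
})

test_that("composition arithmetic: tv from voxel count, gv from the fraction", {
  sp <- phantom_spec(c(24, 24, 24), 0.25, gland_mean = 80, fat_mean = 200,
                     gland_sd = 10, fat_sd = 10,
                     geometry = voxel_geometry(0.7, 2), seed = 405)
  ph <- make_mri_phantom(sp, "3DGRE")
  res <- mri_density(ph$volume)
  n <- sum(ph$volume$breast_mask)
  expect_equal(res$composition$tv_ml, n * 0.686 / 1000)
  expect_equal(res$composition$gv_ml,
               res$composition$tv_ml * res$fit$fraction_gland)
  expect_equal(res$composition$tv_ml,
               res$composition$gv_ml + res$composition$fv_ml)
  expect_identical(res$composition$method, "3DGRE")
  # unconverged or unassigned fits are refused
  bad <- res$fit; bad$converged <- FALSE
  expect_error(mri_composition(ph$volume, bad), "converge")
  bad2 <- res$fit; bad2$gland <- NA_character_
  expect_error(mri_composition(ph$volume, bad2), "unassigned")
})

test_that("end-to-end phantom recovery is within 2 percentage points", {
  for (proto in c("3DGRE", "STIR")) {
    sp <- phantom_spec(c(32, 32, 32), 0.30, gland_mean = 80, fat_mean = 200,
                       gland_sd = 20, fat_sd = 20, seed = 406)
    ph <- make_mri_phantom(sp, proto)
    res <- mri_density(ph$volume)
    expect_lt(abs(res$composition$pct_g - 100 * ph$truth$gland_fraction), 2)
  }
})

test_that("the fit is invariant to uniform intensity rescaling", {
  mx <- make_mixture_histogram(5e4, 0.4, gland_mean = 80, gland_sd = 12,
                               fat_mean = 200, fat_sd = 12, seed = 407)
  f1 <- assign_gland_component(fit_two_gaussians(mx$histogram), "3DGRE")
  alpha <- 3.7
  h2 <- mx$histogram
  h2$mid <- h2$mid * alpha
  if (!is.null(h2$breaks)) h2$breaks <- h2$breaks * alpha
  f2 <- assign_gland_component(fit_two_gaussians(h2), "3DGRE")
  expect_equal(f2$fraction_gland, f1$fraction_gland, tolerance = 1e-6)
  expect_equal(f2$coefficients[["mu1"]], alpha * f1$coefficients[["mu1"]],
               tolerance = 1e-5)
  expect_equal(f2$coefficients[["sigma2"]], alpha * f1$coefficients[["sigma2"]],
               tolerance = 1e-5)
})

test_that("mean fraction error stays below 0.02 across seeded simulated histograms", {
  errs <- vapply(1:20, function(s) {
    w <- 0.1 + 0.04 * (s %% 10)
    mx <- make_mixture_histogram(2e4, w, gland_mean = 80, gland_sd = 20,
                                 fat_mean = 200, fat_sd = 20, seed = 500 + s)
    fit <- assign_gland_component(fit_two_gaussians(mx$histogram), "3DGRE")
    abs(fit$fraction_gland - mx$truth)
  }, numeric(1L))
  expect_lt(mean(errs), 0.02)
})
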