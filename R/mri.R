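# MRI pathway: voxel-intensity histogram of a masked 3D breast model,
# two-Gaussian decomposition under the two-compartment (adipose + gland)
# assumption, protocol-dependent gland assignment, and voxel-count -> volume
# conversion via the reconstructed voxel geometry.

#' MRI volume container
#'
#' @param voxels 3D numeric intensity array.
#' @param breast_mask 3D logical array, same shape, `TRUE` on breast tissue;
#'   must be non-empty. Mask generation from raw MRI is out of scope — masks
#'   are inputs.
#' @param geometry a [voxel_geometry].
#' @param protocol `"3DGRE"` (gradient echo, fat bright) or `"STIR"`
#'   (fat-suppressed, fat dark).
#' @return Object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, breast_mask, geometry,
                       protocol = c("3DGRE", "STIR")) {
  protocol <- match.arg(protocol)
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3D array")
  if (!identical(dim(breast_mask), dim(voxels)))
    stopf("breast_mask shape must match voxels")
  storage.mode(breast_mask) <- "logical"
  if (!any(breast_mask)) stopf("breast_mask is empty")
  if (!inherits(geometry, "voxel_geometry"))
    stopf("geometry must be a voxel_geometry")
  structure(list(voxels = voxels, breast_mask = breast_mask,
                 geometry = geometry, protocol = protocol),
            class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("MRI volume [%s]: %d x %d x %d voxels, %d masked, voxel %g mm^3\n",
              x$protocol, d[1L], d[2L], d[3L], sum(x$breast_mask),
              x$geometry$voxel_volume_mm3))
  invisible(x)
}

#' Read an MRI volume, mask and geometry sidecar
#'
#' Volumes and masks are NIfTI files; the JSON sidecar supplies
#' `reconstructed_voxel_size_mm`, `voxel_ratio` and `protocol`.
#'
#' @param volume,mask NIfTI file paths (mask nonzero = breast).
#' @param sidecar JSON sidecar path; defaults to the volume path with its
#'   NIfTI extension replaced by `.json`.
#' @return An [mri_volume].
#' @export
read_mri_volume <- function(volume, mask, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", volume), ".json")
  for (p in c(volume, mask, sidecar))
    if (!file.exists(p)) stopf("file '%s' does not exist", p)
  vox <- as.array(RNifti::readNifti(volume))
  msk <- as.array(RNifti::readNifti(mask)) != 0
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  geom <- voxel_geometry(side$reconstructed_voxel_size_mm, side$voxel_ratio)
  proto <- side$protocol %||% "3DGRE"
  mri_volume(vox, msk, geom, toupper(proto))
}

#' Voxel-intensity histogram of a masked MRI volume
#'
#' @param vol an [mri_volume].
#' @param n_bins bin count for floating-point intensities (default 256);
#'   integer intensities get native integer bins.
#' @return A [bd_histogram][intensity_histogram]; counts sum to the number of
#'   masked voxels.
#' @export
build_histogram <- function(vol, n_bins = 256L) {
  if (!inherits(vol, "mri_volume")) stopf("vol must be an mri_volume")
  intensity_histogram(vol$voxels, vol$breast_mask, n_bins)
}

gauss_curve <- function(x, A, mu, sigma) A * exp(-(x - mu)^2 / (2 * sigma^2))

auto_init <- function(x, y) {
  mu1 <- weighted_quantile(x, y, 0.25)
  mu2 <- weighted_quantile(x, y, 0.75)
  rng <- diff(range(x))
  if (mu1 == mu2) {  # heavily concentrated histogram; spread the means
    mu1 <- mu1 - rng / 4
    mu2 <- mu2 + rng / 4
  }
  s <- rng / 8
  list(A1 = max(y[which.min(abs(x - mu1))], max(y) / 10), mu1 = mu1, sigma1 = s,
       A2 = max(y[which.min(abs(x - mu2))], max(y) / 10), mu2 = mu2, sigma2 = s)
}

#' Fit a two-Gaussian model to an intensity histogram
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded) of
#' `A1*exp(-(x-mu1)^2/(2*s1^2)) + A2*exp(-(x-mu2)^2/(2*s2^2))` to the bin
#' counts, following the peak-fitting treatment of breast MRI histograms under
#' the assumption that breast tissue holds exactly two intensity compartments,
#' adipose and fibroglandular. Component areas are analytic
#' (`A * sigma * sqrt(2*pi)`). If the first attempt does not converge, up to
#' `max_restarts` deterministically jittered restarts are tried (seeded); a
#' fit that never converges is returned with `converged = FALSE`, never
#' silently.
#'
#' @param histogram a [bd_histogram][intensity_histogram] with at least 6
#'   nonzero bins (the model has 6 free parameters).
#' @param init `"auto"` (means at the weighted 25th/75th intensity
#'   percentiles, widths range/8, amplitudes from local histogram height) or a
#'   named list `A1, mu1, sigma1, A2, mu2, sigma2`.
#' @param max_restarts jittered restarts after a failed first attempt.
#' @param seed seed for the restart jitter stream.
#' @return Object of class `two_gaussian_fit` with components sorted by mean:
#'   `coefficients`, `areas`, `rss`, `converged`, `gland` (unassigned until
#'   [assign_gland_component()]), `fraction_gland`. Supports `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`.
#' @export
fit_two_gaussians <- function(histogram, init = "auto", max_restarts = 5L,
                              seed = 1L) {
  if (!inherits(histogram, "bd_histogram")) stopf("histogram must be a bd_histogram")
  x <- histogram$mid; y <- histogram$count
  if (sum(y > 0) < 6L)
    stopf("histogram has %d nonzero bins; at least 6 needed for 6 parameters",
          sum(y > 0))
  start <- if (identical(init, "auto")) auto_init(x, y) else {
    need <- c("A1", "mu1", "sigma1", "A2", "mu2", "sigma2")
    if (!all(need %in% names(init)))
      stopf("explicit init must name %s", paste(need, collapse = ", "))
    as.list(init[need])
  }
  rng <- range(x); span <- max(diff(rng), 1e-12)
  lower <- c(A1 = 0, mu1 = rng[1L] - span, sigma1 = span * 1e-6,
             A2 = 0, mu2 = rng[1L] - span, sigma2 = span * 1e-6)
  upper <- c(A1 = Inf, mu1 = rng[2L] + span, sigma1 = span * 4,
             A2 = Inf, mu2 = rng[2L] + span, sigma2 = span * 4)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-13, ptol = 1e-13, maxiter = 500L)
  attempt <- function(st) {
    tryCatch({
      f <- minpack.lm::nlsLM(
        y ~ A1 * exp(-(x - mu1)^2 / (2 * sigma1^2)) +
            A2 * exp(-(x - mu2)^2 / (2 * sigma2^2)),
        data = list(x = x, y = y), start = st,
        lower = lower, upper = upper, control = ctrl)
      list(coef = coef(f), rss = sum(residuals(f)^2),
           conv = isTRUE(f$convInfo$isConv))
    }, error = function(e) NULL)
  }
  best <- attempt(start)
  n_attempts <- 1L
  while ((is.null(best) || !best$conv) && n_attempts <= max_restarts) {
    jit <- with_seed(seed + n_attempts, {
      st <- start
      st$mu1 <- st$mu1 + stats::rnorm(1L, 0, span / 10)
      st$mu2 <- st$mu2 + stats::rnorm(1L, 0, span / 10)
      st$sigma1 <- st$sigma1 * stats::runif(1L, 0.5, 2)
      st$sigma2 <- st$sigma2 * stats::runif(1L, 0.5, 2)
      st
    })
    cand <- attempt(jit)
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss || cand$conv))
      best <- cand
    n_attempts <- n_attempts + 1L
  }
  if (is.null(best))
    stopf("two-Gaussian fit failed on every attempt (%d tries)", n_attempts)
  co <- best$coef
  if (co[["mu1"]] > co[["mu2"]])  # sort components by mean, low first
    co <- c(A1 = co[["A2"]], mu1 = co[["mu2"]], sigma1 = co[["sigma2"]],
            A2 = co[["A1"]], mu2 = co[["mu1"]], sigma2 = co[["sigma1"]])
  areas <- c(low = co[["A1"]] * co[["sigma1"]] * sqrt(2 * pi),
             high = co[["A2"]] * co[["sigma2"]] * sqrt(2 * pi))
  if (best$conv && sum(areas) > 0 && min(areas) / sum(areas) < 0.01)
    warnf("degenerate fit: one component holds %.2f%% of the total area",
          100 * min(areas) / sum(areas))
  structure(list(coefficients = co, areas = areas, rss = best$rss,
                 converged = best$conv, histogram = histogram,
                 gland = NA_character_, protocol = NA_character_,
                 fraction_gland = NA_real_, n_attempts = n_attempts),
            class = "two_gaussian_fit")
}

#' @export
print.two_gaussian_fit <- function(x, digits = 4L, ...) {
  cat("Two-Gaussian histogram decomposition\n")
  co <- x$coefficients
  cat(sprintf("  component 1 (low):  A = %s, mean = %s, sd = %s, area = %s\n",
              signif(co[["A1"]], digits), signif(co[["mu1"]], digits),
              signif(co[["sigma1"]], digits), signif(x$areas[["low"]], digits)))
  cat(sprintf("  component 2 (high): A = %s, mean = %s, sd = %s, area = %s\n",
              signif(co[["A2"]], digits), signif(co[["mu2"]], digits),
              signif(co[["sigma2"]], digits), signif(x$areas[["high"]], digits)))
  cat(sprintf("  rss = %s, converged = %s\n", signif(x$rss, digits), x$converged))
  if (!is.na(x$gland))
    cat(sprintf("  gland = %s-mean component (%s) -> fraction %.4f\n",
                x$gland, x$protocol, x$fraction_gland))
  invisible(x)
}

#' @export
coef.two_gaussian_fit <- function(object, ...) object$coefficients

#' @export
fitted.two_gaussian_fit <- function(object, ...) {
  predict(object, object$histogram$mid)
}

#' @export
residuals.two_gaussian_fit <- function(object, ...) {
  object$histogram$count - fitted(object)
}

#' Evaluate a fitted two-Gaussian curve
#'
#' @param object a [two_gaussian_fit][fit_two_gaussians].
#' @param newdata intensities at which to evaluate; defaults to the fitted
#'   histogram's bin centres.
#' @param ... unused.
#' @return Predicted bin counts.
#' @export
predict.two_gaussian_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$histogram$mid
       else if (is.data.frame(newdata)) newdata[[1L]] else newdata
  co <- object$coefficients
  gauss_curve(x, co[["A1"]], co[["mu1"]], co[["sigma1"]]) +
    gauss_curve(x, co[["A2"]], co[["mu2"]], co[["sigma2"]])
}

#' @export
summary.two_gaussian_fit <- function(object, ...) {
  total <- sum(object$areas)
  structure(list(fit = object,
                 area_fractions = object$areas / ifelse(total > 0, total, NA),
                 n_bins = length(object$histogram$mid),
                 mass = sum(object$histogram$count)),
            class = "summary.two_gaussian_fit")
}

#' @export
print.summary.two_gaussian_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  histogram: %d bins, %g voxels\n", x$n_bins, x$mass))
  cat(sprintf("  area fractions: low %.4f, high %.4f\n",
              x$area_fractions[["low"]], x$area_fractions[["high"]]))
  invisible(x)
}

#' @export
plot.two_gaussian_fit <- function(x, ...) {
  h <- x$histogram
  graphics::plot(h$mid, h$count, type = "h", col = "grey70",
                 xlab = "signal intensity", ylab = "voxel count",
                 main = "Two-Gaussian histogram decomposition", ...)
  xx <- seq(min(h$mid), max(h$mid), length.out = 400L)
  co <- x$coefficients
  graphics::lines(xx, gauss_curve(xx, co[["A1"]], co[["mu1"]], co[["sigma1"]]),
                  col = "steelblue", lwd = 2)
  graphics::lines(xx, gauss_curve(xx, co[["A2"]], co[["mu2"]], co[["sigma2"]]),
                  col = "firebrick", lwd = 2)
  graphics::lines(xx, predict(x, xx), col = "black", lwd = 1, lty = 2)
  invisible(x)
}

#' Label the glandular component of a mixture fit
#'
#' Which Gaussian is gland depends on the pulse sequence: without fat
#' suppression (3DGRE) fat is bright, so the lower-mean component is gland;
#' under fat suppression (STIR) fat is dark, so the higher-mean component is
#' gland. An explicit `override` wins over the rule, with a warning.
#'
#' @param fit a [two_gaussian_fit][fit_two_gaussians].
#' @param protocol `"3DGRE"` or `"STIR"`.
#' @param override `NULL`, `"low"` or `"high"`.
#' @return The fit with `gland`, `protocol` and `fraction_gland` filled in.
#' @export
assign_gland_component <- function(fit, protocol = c("3DGRE", "STIR"),
                                   override = NULL) {
  protocol <- match.arg(protocol)
  if (!inherits(fit, "two_gaussian_fit")) stopf("fit must be a two_gaussian_fit")
  co <- fit$coefficients
  if (co[["mu1"]] == co[["mu2"]])
    stopf("component means are equal; gland assignment undefined")
  gland <- if (protocol == "3DGRE") "low" else "high"
  if (!is.null(override)) {
    override <- match.arg(override, c("low", "high"))
    if (override != gland)
      warnf("gland assignment overridden to '%s' (protocol rule says '%s')",
            override, gland)
    gland <- override
  }
  fit$gland <- gland
  fit$protocol <- protocol
  total <- sum(fit$areas)
  if (total <= 0) stopf("total component area is zero; fraction undefined")
  fit$fraction_gland <- unname(fit$areas[[gland]] / total)
  fit
}

#' MRI breast composition from a labeled mixture fit
#'
#' Total volume is the masked voxel count times the voxel volume
#' (mm^3 -> mL); glandular volume is the total times the fitted gland area
#' fraction.
#'
#' @param vol an [mri_volume].
#' @param fit a converged [two_gaussian_fit][fit_two_gaussians] labeled by
#'   [assign_gland_component()].
#' @return A [breast_composition] tagged with the volume's protocol.
#' @export
mri_composition <- function(vol, fit) {
  if (!inherits(vol, "mri_volume")) stopf("vol must be an mri_volume")
  if (!inherits(fit, "two_gaussian_fit")) stopf("fit must be a two_gaussian_fit")
  if (!isTRUE(fit$converged)) stopf("mixture fit did not converge")
  if (is.na(fit$gland))
    stopf("gland component unassigned; call assign_gland_component() first")
  tv <- sum(vol$breast_mask) * vol$geometry$voxel_volume_mm3 / 1000
  gv <- tv * fit$fraction_gland
  breast_composition(vol$protocol, 100 * fit$fraction_gland, gv, tv - gv, tv)
}

#' Full MRI density estimate from a volume
#'
#' Convenience pipeline: histogram, two-Gaussian fit, protocol-based gland
#' assignment, composition.
#'
#' @param vol an [mri_volume].
#' @param n_bins histogram bins (default 256).
#' @param init,max_restarts,seed passed to [fit_two_gaussians()].
#' @param override gland-assignment override, see [assign_gland_component()].
#' @return List of class `mri_result`: `composition`, `fit`, `histogram`.
#' @export
mri_density <- function(vol, n_bins = 256L, init = "auto", max_restarts = 5L,
                        seed = 1L, override = NULL) {
  h <- build_histogram(vol, n_bins)
  fit <- fit_two_gaussians(h, init, max_restarts, seed)
  fit <- assign_gland_component(fit, vol$protocol, override)
  structure(list(composition = mri_composition(vol, fit), fit = fit,
                 histogram = h),
            class = "mri_result")
}

#' @export
print.mri_result <- function(x, ...) {
  print(x$fit)
  print(x$composition)
  invisible(x)
}
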