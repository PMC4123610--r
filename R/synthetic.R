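# Ground-truth phantom generation for every pathway. All generators are pure
# functions of (spec, seed): randomness runs through a private RNG stream so
# fixtures are byte-reproducible. Class assignment within an ROI is
# exact-count, not Bernoulli, so planted tissue fractions are exact at pixel
# resolution and segmentation tests are sharp.

#' Phantom specification
#'
#' Describes a synthetic two-compartment breast image: its shape, the planted
#' glandular fraction, the per-class intensity distributions (Gaussian; the
#' two means must be distinct), the compression thickness carried in the
#' metadata, the voxel geometry (3D only) and the mandatory seed.
#'
#' @param shape integer vector of per-axis sizes: length 2 for a mammogram
#'   phantom, length 3 for an MRI phantom.
#' @param gland_fraction planted glandular fraction in \[0, 1\].
#' @param gland_mean,gland_sd,fat_mean,fat_sd class intensity parameters
#'   (raw signal units). Defaults separate the classes by 12 within-class
#'   standard deviations.
#' @param compression_thickness compression thickness, mm (2D metadata).
#' @param geometry a [voxel_geometry] (3D only).
#' @param seed integer seed; mandatory so every fixture is reproducible.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, gland_fraction, gland_mean = 180,
                         gland_sd = 10, fat_mean = 60, fat_sd = 10,
                         compression_thickness = 50,
                         geometry = voxel_geometry(1, 1), seed) {
  if (missing(seed)) stopf("seed is mandatory: all generation must be reproducible")
  if (!is.numeric(shape) || !length(shape) %in% c(2L, 3L) || any(shape < 1))
    stopf("shape must be 2 or 3 positive axis sizes")
  if (!is_scalar_num(gland_fraction) || gland_fraction < 0 || gland_fraction > 1)
    stopf("gland_fraction must lie in [0, 1]")
  if (gland_mean == fat_mean) stopf("class means must be distinct")
  if (gland_sd < 0 || fat_sd < 0) stopf("class sds must be non-negative")
  structure(list(shape = as.integer(shape), gland_fraction = gland_fraction,
                 gland_mean = gland_mean, gland_sd = gland_sd,
                 fat_mean = fat_mean, fat_sd = fat_sd,
                 compression_thickness = compression_thickness,
                 geometry = geometry, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Exact-count split: n_gland = round(fraction * n), reported if the planted
# fraction is not achievable exactly at this ROI size.
exact_count_split <- function(n, fraction) {
  n_gland <- as.integer(round(fraction * n))
  achieved <- n_gland / n
  if (abs(achieved - fraction) > .Machine$double.eps * 4 * max(1, n))
    message(sprintf("planted fraction %g not achievable with %d pixels; using %g",
                    fraction, n, achieved))
  n_gland
}

ellipse_mask <- function(nr, nc, scale = 0.42) {
  r <- row(matrix(0, nr, nc)); c <- col(matrix(0, nr, nc))
  ((r - (nr + 1) / 2) / (scale * nr))^2 + ((c - (nc + 1) / 2) / (scale * nc))^2 <= 1
}

ellipsoid_mask <- function(d, scale = 0.42) {
  ctr <- (d + 1) / 2
  i <- slice.index(array(0, d), 1L)
  j <- slice.index(array(0, d), 2L)
  k <- slice.index(array(0, d), 3L)
  ((i - ctr[1L]) / (scale * d[1L]))^2 + ((j - ctr[2L]) / (scale * d[2L]))^2 +
    ((k - ctr[3L]) / (scale * d[3L]))^2 <= 1
}

# Plausible acquisition metadata for a synthetic mammogram. Ranges are chosen
# so the header linear model evaluates to an in-range percent on typical
# draws, as it does on real acquisitions of the hardware it was fitted to;
# the final exposure thickness tracks the pre-exposure value, as on a real
# compression. Values are rounded to short decimals so DICOM decimal strings
# round-trip bit-exactly.
random_imaging_parameters <- function() {
  pre_thk <- round(stats::runif(1L, 45, 65), 1)
  imaging_parameters(
    preexposure_dose          = round(stats::runif(1L, 4800, 5200), 1),
    preexposure_thickness     = pre_thk,
    radiation_dose            = round(stats::runif(1L, 650, 750), 1),
    preexposure_kvp           = round(stats::runif(1L, 27, 29), 1),
    anatomical_mean_intensity = round(stats::runif(1L, 3400, 4000), 1),
    thresh                    = round(stats::runif(1L, 1800, 2200), 1),
    final_exposure_thickness  = round(pre_thk - stats::runif(1L, 0, 2), 1),
    compression_force         = round(stats::runif(1L, 100, 140), 1),
    detector_sensitivity      = round(stats::runif(1L, 0.005, 0.0054), 7),
    filter_material           = sample(c("molybdenum", "rhodium"), 1L),
    anode_material            = sample(c("molybdenum", "rhodium"), 1L))
}

#' Generate a 2D mammogram phantom with known ground truth
#'
#' Places an elliptical breast ROI on a zero background, splits the ROI pixels
#' into gland and fat classes at the exact planted count, draws per-class
#' Gaussian intensities (rounded to integers, floored at 1 so tissue never
#' touches the background level), and fills a plausible acquisition-metadata
#' record. Optionally adds a small disconnected label artifact to exercise
#' largest-component ROI isolation.
#'
#' @param spec a [phantom_spec] with a 2-axis shape.
#' @param add_label_artifact add a small square artifact in a corner?
#' @param raddose_noise_sd sd of the noise on the simulated FFDM Raddose
#'   estimate around the planted percent (default 2 percentage points).
#' @return List of class `mammogram_phantom`: `record`
#'   ([mammogram_record][read_mammogram]), `truth` (achieved gland fraction,
#'   counts), `mask` (the true ROI), `spec`.
#' @export
make_mammogram_phantom <- function(spec, add_label_artifact = FALSE,
                                   raddose_noise_sd = 2) {
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  if (length(spec$shape) != 2L) stopf("mammogram phantom needs a 2-axis shape")
  with_seed(spec$seed, {
    nr <- spec$shape[1L]; nc <- spec$shape[2L]
    mask <- ellipse_mask(nr, nc)
    n_roi <- sum(mask)
    if (n_roi == 0L) stopf("ROI is empty at shape %d x %d", nr, nc)
    n_gland <- exact_count_split(n_roi, spec$gland_fraction)
    labels <- c(rep(TRUE, n_gland), rep(FALSE, n_roi - n_gland))[sample.int(n_roi)]
    vals <- numeric(n_roi)
    vals[labels] <- stats::rnorm(n_gland, spec$gland_mean, spec$gland_sd)
    vals[!labels] <- stats::rnorm(n_roi - n_gland, spec$fat_mean, spec$fat_sd)
    pixels <- matrix(0, nr, nc)
    pixels[mask] <- pmax(1, round(vals))
    if (add_label_artifact) {
      sz <- max(2L, round(min(nr, nc) / 20))
      pixels[seq_len(sz), seq.int(nc - sz + 1L, nc)] <- round(spec$fat_mean)
    }
    truth_pct <- 100 * n_gland / n_roi
    raddose <- min(100, max(0, round(truth_pct + stats::rnorm(1L, 0, raddose_noise_sd), 1)))
    params <- random_imaging_parameters()
    params$preexposure_thickness <- round(spec$compression_thickness, 1)
    params$final_exposure_thickness <-
      round(spec$compression_thickness - stats::runif(1L, 0, 2), 1)
    rec <- new_mammogram_record(pixels, params, 9.96, raddose,
                                source = "synthetic phantom")
    structure(list(record = rec,
                   truth = list(gland_fraction = n_gland / n_roi,
                                n_gland = n_gland, n_roi = n_roi),
                   mask = mask, spec = spec),
              class = "mammogram_phantom")
  })
}

#' Generate a 3D MRI phantom with known ground truth
#'
#' Builds an ellipsoidal breast mask, splits masked voxels gland/fat at the
#' exact planted count and draws Gaussian intensities with protocol-correct
#' ordering: without fat suppression (3DGRE) fat takes the higher of the two
#' class means, under fat suppression (STIR) gland does. Per-voxel truth
#' labels are retained.
#'
#' @param spec a [phantom_spec] with a 3-axis shape.
#' @param protocol `"3DGRE"` or `"STIR"`.
#' @return List of class `mri_phantom`: `volume` ([mri_volume]), `truth`
#'   (achieved fraction, per-voxel labels, true `tv_ml`), `spec`.
#' @export
make_mri_phantom <- function(spec, protocol = c("3DGRE", "STIR")) {
  protocol <- match.arg(protocol)
  if (!inherits(spec, "phantom_spec")) stopf("spec must be a phantom_spec")
  if (length(spec$shape) != 3L) stopf("MRI phantom needs a 3-axis shape")
  with_seed(spec$seed, {
    mask <- ellipsoid_mask(spec$shape)
    n_roi <- sum(mask)
    if (n_roi == 0L) stopf("mask is empty at this shape")
    n_gland <- exact_count_split(n_roi, spec$gland_fraction)
    labels <- c(rep(TRUE, n_gland), rep(FALSE, n_roi - n_gland))[sample.int(n_roi)]
    means <- sort(c(spec$gland_mean, spec$fat_mean))
    sds <- c(spec$gland_sd, spec$fat_sd)[order(c(spec$gland_mean, spec$fat_mean))]
    if (protocol == "3DGRE") {  # fat bright
      gland_mean <- means[1L]; gland_sd <- sds[1L]
      fat_mean <- means[2L]; fat_sd <- sds[2L]
    } else {                    # STIR: fat suppressed, gland bright
      gland_mean <- means[2L]; gland_sd <- sds[2L]
      fat_mean <- means[1L]; fat_sd <- sds[1L]
    }
    vals <- numeric(n_roi)
    vals[labels] <- stats::rnorm(n_gland, gland_mean, gland_sd)
    vals[!labels] <- stats::rnorm(n_roi - n_gland, fat_mean, fat_sd)
    voxels <- array(0, spec$shape)
    voxels[mask] <- pmax(0, vals)
    label_arr <- array(NA, spec$shape)
    label_arr[mask] <- labels
    vol <- mri_volume(voxels, mask, spec$geometry, protocol)
    structure(list(volume = vol,
                   truth = list(gland_fraction = n_gland / n_roi,
                                labels = label_arr,
                                tv_ml = n_roi * spec$geometry$voxel_volume_mm3 / 1000),
                   spec = spec),
              class = "mri_phantom")
  })
}

#' Sample an intensity histogram from a two-Gaussian mixture
#'
#' Draws `n_voxels` intensities from
#' `w * N(gland_mean, gland_sd) + (1-w) * N(fat_mean, fat_sd)` with the gland
#' count exact (`round(w * n)`), and bins them. Used to exercise the mixture
#' fit without building full volumes.
#'
#' @param n_voxels sample size.
#' @param gland_weight mixture weight of the gland component.
#' @param gland_mean,gland_sd,fat_mean,fat_sd component parameters.
#' @param n_bins histogram bins.
#' @param seed mandatory seed.
#' @return List: `histogram` ([bd_histogram][intensity_histogram]), `truth`
#'   (exact gland fraction of the sample).
#' @export
make_mixture_histogram <- function(n_voxels, gland_weight, gland_mean = 80,
                                   gland_sd = 15, fat_mean = 200, fat_sd = 15,
                                   n_bins = 256L, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  with_seed(seed, {
    n_g <- as.integer(round(gland_weight * n_voxels))
    vals <- c(stats::rnorm(n_g, gland_mean, gland_sd),
              stats::rnorm(n_voxels - n_g, fat_mean, fat_sd))
    list(histogram = intensity_histogram(vals, n_bins = n_bins),
         truth = n_g / n_voxels)
  })
}

#' Generate a correlated multi-method measure table
#'
#' Emulates the structure of a method-comparison study: per-subject density
#' measures that are highly correlated across methods, with method-level mean
#' offsets. Per outcome, each method's values share a latent subject effect:
#' `x_m = sqrt(rho) * z0 + sqrt(1 - rho) * z_m`, giving exchangeable
#' cross-method correlation `rho`. Offsets (in mL) shift the total volume of
#' the named methods; gland and fat volumes are derived so that each row is a
#' valid composition (`gv + fv = tv`).
#'
#' @param n_subjects number of subjects.
#' @param inter_method_rho cross-method correlation in \[0, 1\].
#' @param offsets named numeric vector of per-method TV offsets in mL
#'   (methods not named get 0).
#' @param methods method labels (default the five pathways).
#' @param pct_mean,pct_sd,tv_mean,tv_sd population distribution of percent
#'   density and total volume. Defaults approximate a screening population:
#'   percent density ~ 30 +/- 10, total volume ~ 800 +/- 150 mL.
#' @param seed mandatory seed.
#' @return Long-format data.frame (`subject_id, method, pct_g, gv_ml, fv_ml,
#'   tv_ml`) suitable for [correlation_matrix()] and
#'   [pairwise_mean_differences()].
#' @export
make_measure_table <- function(n_subjects, inter_method_rho, offsets = NULL,
                               methods = c("HSM", "FFDM", "MATH", "3DGRE", "STIR"),
                               pct_mean = 30, pct_sd = 10,
                               tv_mean = 800, tv_sd = 150, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (!is_scalar_num(inter_method_rho) ||
      inter_method_rho < 0 || inter_method_rho > 1)
    stopf("inter_method_rho must lie in [0, 1] (equicorrelation is not positive semi-definite otherwise)")
  k <- length(methods)
  off <- stats::setNames(numeric(k), methods)
  if (!is.null(offsets)) {
    bad <- setdiff(names(offsets), methods)
    if (length(bad) > 0L) stopf("offset names not among methods: %s",
                                paste(bad, collapse = ", "))
    off[names(offsets)] <- offsets
  }
  with_seed(seed, {
    equicorr <- function() {
      z0 <- stats::rnorm(n_subjects)
      sapply(seq_len(k), function(m)
        sqrt(inter_method_rho) * z0 +
          sqrt(1 - inter_method_rho) * stats::rnorm(n_subjects))
    }
    pct <- pmin(pmax(pct_mean + pct_sd * equicorr(), 0.5), 99.5)
    tv <- pmax(tv_mean + tv_sd * equicorr() +
                 matrix(off, n_subjects, k, byrow = TRUE), 50)
    do.call(rbind, lapply(seq_len(k), function(m) {
      gv <- tv[, m] * pct[, m] / 100
      data.frame(subject_id = sprintf("S%03d", seq_len(n_subjects)),
                 method = methods[m], pct_g = pct[, m], gv_ml = gv,
                 fv_ml = tv[, m] - gv, tv_ml = tv[, m],
                 stringsAsFactors = FALSE)
    }))
  })
}

num_to_ds <- function(x) sprintf("%.10g", x)

#' Write a mammogram phantom to disk as a fixture
#'
#' `format = "dicom"` emits a minimal explicit-VR little-endian DICOM carrying
#' the metadata under the tag map plus 16-bit pixel data; `format = "png"`
#' emits an 8-bit PNG (pixel values must fit 0..255) plus a JSON metadata
#' sidecar. Either form is readable by
#' [read_mammogram()], and the metadata round trip is bit-exact.
#'
#' @param phantom a [mammogram_phantom][make_mammogram_phantom] or a
#'   [mammogram_record][read_mammogram].
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @param format `"dicom"` or `"png"`.
#' @param tag_map DICOM tag map (DICOM format only).
#' @return Named character vector of the paths written.
#' @export
write_mammogram_fixture <- function(phantom, dir, basename = "phantom",
                                    format = c("dicom", "png"),
                                    tag_map = default_tag_map()) {
  format <- match.arg(format)
  rec <- if (inherits(phantom, "mammogram_phantom")) phantom$record else phantom
  if (!inherits(rec, "mammogram_record")) stopf("phantom must carry a mammogram_record")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- rec$params
  if (format == "dicom") {
    elements <- list()
    for (f in .BD_CONTINUOUS_FIELDS)
      elements[[tag_map[[f]]]] <- list(vr = "DS", value = num_to_ds(p[[f]]))
    for (f in .BD_CATEGORICAL_FIELDS)
      elements[[tag_map[[f]]]] <- list(vr = "CS", value = toupper(p[[f]]))
    if (!is.null(rec$raddose_pct_g))
      elements[[tag_map[["raddose_pct_g"]]]] <-
        list(vr = "DS", value = num_to_ds(rec$raddose_pct_g))
    path <- file.path(dir, paste0(basename, ".dcm"))
    dcm_write(path, elements, pixels = rec$pixels)
    c(image = path)
  } else {
    img <- file.path(dir, paste0(basename, ".png"))
    if (any(rec$pixels > 255))
      stopf("PNG fixtures are 8-bit; pixel values exceed 255 (use DICOM)")
    png::writePNG(rec$pixels / 255, img)
    side <- file.path(dir, paste0(basename, ".json"))
    payload <- list(imaging_parameters = unclass(p), thickness_units = "mm",
                    pixel_to_ml_factor = rec$pixel_to_ml_factor)
    if (!is.null(rec$raddose_pct_g)) payload$raddose_pct_g <- rec$raddose_pct_g
    jsonlite::write_json(payload, side, auto_unbox = TRUE, digits = NA)
    c(image = img, metadata = side)
  }
}

#' Write an MRI phantom to disk as a fixture
#'
#' Emits NIfTI volume and mask files plus a JSON geometry/protocol sidecar,
#' the form [read_mri_volume()] consumes.
#'
#' @param phantom an [mri_phantom][make_mri_phantom] or [mri_volume].
#' @param dir output directory.
#' @param basename file stem.
#' @return Named character vector of paths (`volume`, `mask`, `sidecar`).
#' @export
write_mri_fixture <- function(phantom, dir, basename = "mri_phantom") {
  vol <- if (inherits(phantom, "mri_phantom")) phantom$volume else phantom
  if (!inherits(vol, "mri_volume")) stopf("phantom must carry an mri_volume")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vpath <- file.path(dir, paste0(basename, ".nii"))
  mpath <- file.path(dir, paste0(basename, "_mask.nii"))
  spath <- file.path(dir, paste0(basename, ".json"))
  RNifti::writeNifti(vol$voxels, vpath)
  RNifti::writeNifti(vol$breast_mask * 1L, mpath)
  jsonlite::write_json(
    list(reconstructed_voxel_size_mm = vol$geometry$reconstructed_voxel_size,
         voxel_ratio = vol$geometry$voxel_ratio, protocol = vol$protocol),
    spath, auto_unbox = TRUE, digits = NA)
  c(volume = vpath, mask = mpath, sidecar = spath)
}
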