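# Histogram segmentation method (HSM): breast ROI isolation, threshold
# selection on the intensity histogram, glandular/fat area tallies, and the
# area -> volume conversion
#   GV = factor * G_AREA * compression thickness,  FV likewise,  TV = GV + FV,
#   %-G = 100 * G_AREA / (G_AREA + F_AREA).

#' Isolate the breast region of interest
#'
#' Thresholds the image at `background_level`, optionally blanks a chest-wall
#' margin band of columns, and keeps the largest connected foreground
#' component. On a craniocaudal view the chest wall lies along one image edge;
#' the margin removes it together with any attached muscle so the retained
#' component is breast tissue only.
#'
#' @param pixels 2D numeric matrix of non-negative intensities.
#' @param background_level intensities strictly above this are foreground.
#' @param chest_margin number of columns to exclude at the chest-wall edge.
#' @param chest_side `"left"`, `"right"`, or `"none"`; which edge the margin
#'   is taken from.
#' @return Logical matrix, `TRUE` on the breast ROI.
#' @export
isolate_breast_roi <- function(pixels, background_level = 0, chest_margin = 0,
                               chest_side = c("left", "right", "none")) {
  chest_side <- match.arg(chest_side)
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stopf("pixels must be a non-empty matrix")
  fg <- pixels > background_level
  if (chest_margin > 0 && chest_side != "none") {
    cols <- if (chest_side == "left") seq_len(min(chest_margin, ncol(fg)))
            else seq.int(max(1L, ncol(fg) - chest_margin + 1L), ncol(fg))
    fg[, cols] <- FALSE
  }
  if (!any(fg)) stopf("no breast found: no pixels above background level %g",
                      background_level)
  lab <- EBImage::bwlabel(fg * 1)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  lab == keep
}

#' Intensity histogram of masked pixels
#'
#' Integer-valued data gets native integer bins (one bin per observed level);
#' floating-point data is binned into `n_bins` uniform bins spanning the
#' observed range. Counts always sum to the number of masked pixels.
#'
#' @param values numeric vector, or a matrix combined with `mask`.
#' @param mask optional logical matrix selecting pixels when `values` is a
#'   matrix.
#' @param n_bins bin count for floating-point data (default 256).
#' @return Object of class `bd_histogram`: `mid` (bin centres / levels),
#'   `count`, `breaks` (uniform binning only), `type`.
#' @export
intensity_histogram <- function(values, mask = NULL, n_bins = 256L) {
  if (is.matrix(values) || length(dim(values)) == 3L) {
    if (is.null(mask)) mask <- array(TRUE, dim(values))
    if (!identical(dim(mask), dim(values)))
      stopf("mask dimensions must match values")
    if (!any(mask)) stopf("empty mask: no pixels to histogram")
    values <- values[mask]
  }
  if (length(values) == 0L) stopf("no values to histogram")
  integerish <- all(values == round(values))
  if (integerish) {
    tab <- table(values)
    h <- list(mid = as.numeric(names(tab)), count = as.numeric(tab),
              breaks = NULL, type = "integer")
  } else {
    rng <- range(values)
    if (rng[1L] == rng[2L]) {
      h <- list(mid = rng[1L], count = length(values), breaks = NULL,
                type = "uniform")
    } else {
      breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
      idx <- findInterval(values, breaks, rightmost.closed = TRUE)
      h <- list(mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
                count = as.numeric(tabulate(idx, nbins = n_bins)),
                breaks = breaks, type = "uniform")
    }
  }
  structure(h, class = "bd_histogram")
}

#' @export
print.bd_histogram <- function(x, ...) {
  cat(sprintf("Intensity histogram: %d %s bins, %g pixels, range [%g, %g]\n",
              length(x$mid), x$type, sum(x$count), min(x$mid), max(x$mid)))
  invisible(x)
}

# Otsu's criterion on a level->count map: the cut maximising the between-class
# variance w0*w1*(mu0-mu1)^2 over all K-1 cut points, computed from cumulative
# moments; ties resolved toward the lowest cut. Returns the midpoint between
# the two levels flanking the winning cut, so the threshold is strictly
# interior and classification at it is unambiguous.
otsu_threshold <- function(hist) {
  v <- hist$mid; n <- hist$count
  keep <- n > 0
  v <- v[keep]; n <- n[keep]
  if (length(v) < 2L)
    stopf("histogram has a single intensity level: no separable classes")
  w <- n / sum(n)
  cw <- cumsum(w)
  cm <- cumsum(w * v)
  mu_t <- cm[length(cm)]
  k <- seq_len(length(v) - 1L)
  w0 <- cw[k]; w1 <- 1 - w0
  between <- ifelse(w0 > 0 & w1 > 0,
                    (mu_t * w0 - cm[k])^2 / (w0 * w1), 0)
  kstar <- which.max(between)  # which.max takes the first maximum: lowest cut
  (v[kstar] + v[kstar + 1L]) / 2
}

#' Select a segmentation threshold from an intensity histogram
#'
#' The analyst-guided threshold choice of interactive density reading is
#' replaced by programmatic strategies: `"otsu"` (default) maximises the
#' between-class variance over all cut points of the histogram; a numeric
#' strategy (or the string form `"fixed:<value>"`) is returned verbatim.
#'
#' @param histogram a [bd_histogram][intensity_histogram].
#' @param strategy `"otsu"`, a single number, or `"fixed:<value>"`.
#' @return The threshold (raw signal units).
#' @export
select_threshold <- function(histogram, strategy = "otsu") {
  if (is.numeric(strategy)) {
    if (!is_scalar_num(strategy)) stopf("fixed threshold must be a single number")
    return(as.numeric(strategy))
  }
  if (grepl("^fixed:", strategy))
    return(as.numeric(sub("^fixed:", "", strategy)))
  if (identical(strategy, "otsu")) return(otsu_threshold(histogram))
  stopf("unknown threshold strategy '%s'", strategy)
}

#' Segment glandular and fat areas at a threshold
#'
#' On raw mammograms dense fibroglandular tissue attenuates more and reads
#' brighter, so glandular pixels are those with intensity at or above the
#' threshold (`glandular_bright = TRUE`, the default); the polarity flag
#' accommodates inverted dialects. Pixels exactly at the threshold count as
#' glandular in either polarity (closed bound on the gland class).
#'
#' @param pixels 2D intensity matrix.
#' @param mask logical breast-ROI matrix (see [isolate_breast_roi()]).
#' @param threshold raw-signal threshold.
#' @param glandular_bright logical polarity flag.
#' @return Object of class `segmentation_result`: `threshold`, `g_area_px`,
#'   `f_area_px`, `t_area_px`, `breast_mask`, `glandular_bright`.
#' @export
segment_areas <- function(pixels, mask, threshold, glandular_bright = TRUE) {
  if (!identical(dim(pixels), dim(mask))) stopf("mask dimensions must match pixels")
  vals <- pixels[mask]
  t_area <- length(vals)
  g_area <- if (glandular_bright) sum(vals >= threshold) else sum(vals <= threshold)
  structure(list(threshold = threshold, g_area_px = g_area,
                 f_area_px = t_area - g_area, t_area_px = t_area,
                 breast_mask = mask, glandular_bright = glandular_bright),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "Segmentation at threshold %g: gland %d px, fat %d px, total %d px (%.1f%% gland)\n",
    x$threshold, x$g_area_px, x$f_area_px, x$t_area_px,
    if (x$t_area_px > 0) 100 * x$g_area_px / x$t_area_px else NA_real_))
  invisible(x)
}

#' Breast composition record
#'
#' The four density outcomes produced by every pathway: percent glandular
#' tissue and the glandular, fat and total volumes in mL, tagged with the
#' measuring method.
#'
#' @param method one of `"HSM"`, `"FFDM"`, `"MATH"`, `"3DGRE"`, `"STIR"`.
#' @param pct_g percent glandular tissue, in \[0, 100\].
#' @param gv_ml,fv_ml,tv_ml glandular, fat and total volume, mL;
#'   `gv_ml + fv_ml` must equal `tv_ml` to numerical tolerance.
#' @return Object of class `breast_composition`.
#' @export
breast_composition <- function(method, pct_g, gv_ml, fv_ml, tv_ml) {
  method <- match.arg(method, c("HSM", "FFDM", "MATH", "3DGRE", "STIR"))
  if (!is_scalar_num(pct_g) || pct_g < 0 || pct_g > 100)
    stopf("pct_g must lie in [0, 100], got %g", pct_g)
  for (v in c(gv_ml, fv_ml, tv_ml))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stopf("volumes must be single non-negative numbers")
  if (abs(gv_ml + fv_ml - tv_ml) > 1e-9 * max(1, tv_ml))
    stopf("volume conservation violated: gv + fv = %g but tv = %g",
          gv_ml + fv_ml, tv_ml)
  structure(list(method = method, pct_g = pct_g, gv_ml = gv_ml,
                 fv_ml = fv_ml, tv_ml = tv_ml),
            class = "breast_composition")
}

#' @export
print.breast_composition <- function(x, ...) {
  cat(sprintf("Breast composition [%s]: %%-G = %.2f, GV = %.1f mL, FV = %.1f mL, TV = %.1f mL\n",
              x$method, x$pct_g, x$gv_ml, x$fv_ml, x$tv_ml))
  invisible(x)
}

#' @export
as.data.frame.breast_composition <- function(x, ...,
                                             subject_id = NA_character_) {
  data.frame(subject_id = subject_id, method = x$method, pct_g = x$pct_g,
             gv_ml = x$gv_ml, fv_ml = x$fv_ml, tv_ml = x$tv_ml,
             stringsAsFactors = FALSE)
}

#' Convert segmented areas to a breast composition
#'
#' Lifts 2D areas to volumes with the pre-exposure compression thickness and
#' the unit correction factor: `GV = factor * g_area * thickness`, `FV`
#' likewise, `TV = GV + FV`, `%-G = 100 * g_area / t_area`.
#'
#' @param seg a [segmentation_result][segment_areas].
#' @param preexposure_thickness compression thickness at pre-exposure, mm.
#' @param factor unit correction factor (pixel area x thickness to mL);
#'   default 9.96 for the reference imaging geometry.
#' @return A [breast_composition] with `method = "HSM"`.
#' @export
areas_to_composition <- function(seg, preexposure_thickness, factor = 9.96) {
  if (!inherits(seg, "segmentation_result")) stopf("seg must be a segmentation_result")
  if (!is_scalar_num(preexposure_thickness) || preexposure_thickness <= 0)
    stopf("preexposure_thickness must be positive")
  if (!is_scalar_num(factor) || factor <= 0) stopf("factor must be positive")
  if (seg$t_area_px == 0L) stopf("empty segmentation: total area is zero")
  gv <- factor * seg$g_area_px * preexposure_thickness
  fv <- factor * seg$f_area_px * preexposure_thickness
  breast_composition("HSM", 100 * seg$g_area_px / seg$t_area_px,
                     gv, fv, gv + fv)
}

#' Full HSM density estimate from a mammogram record
#'
#' Convenience pipeline: ROI isolation, histogram, threshold selection,
#' segmentation, volume conversion.
#'
#' @param record a [mammogram_record][read_mammogram].
#' @param background_level,chest_margin,chest_side passed to
#'   [isolate_breast_roi()].
#' @param strategy threshold strategy, see [select_threshold()].
#' @param glandular_bright polarity flag, see [segment_areas()].
#' @return List of class `hsm_result`: `composition` ([breast_composition]),
#'   `segmentation`, `threshold`, `histogram`, `mask`.
#' @export
hsm_density <- function(record, background_level = 0, strategy = "otsu",
                        chest_margin = 0, chest_side = "none",
                        glandular_bright = TRUE) {
  if (!inherits(record, "mammogram_record")) stopf("record must be a mammogram_record")
  mask <- isolate_breast_roi(record$pixels, background_level,
                             chest_margin, chest_side)
  h <- intensity_histogram(record$pixels, mask)
  thr <- select_threshold(h, strategy)
  seg <- segment_areas(record$pixels, mask, thr, glandular_bright)
  comp <- areas_to_composition(seg, record$params$preexposure_thickness,
                               record$pixel_to_ml_factor)
  structure(list(composition = comp, segmentation = seg, threshold = thr,
                 histogram = h, mask = mask),
            class = "hsm_result")
}

#' @export
print.hsm_result <- function(x, ...) {
  print(x$segmentation)
  print(x$composition)
  invisible(x)
}
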