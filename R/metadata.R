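# Acquisition-metadata records: the eleven predictor variables of the header
# linear model, voxel geometry for MRI volumes, and readers that populate them
# from DICOM headers or JSON sidecars.

.BD_CONTINUOUS_FIELDS <- c(
  "preexposure_dose", "preexposure_thickness", "radiation_dose",
  "preexposure_kvp", "anatomical_mean_intensity", "thresh",
  "final_exposure_thickness", "compression_force", "detector_sensitivity")

.BD_CATEGORICAL_FIELDS <- c("filter_material", "anode_material")

.BD_PARAM_FIELDS <- c(.BD_CONTINUOUS_FIELDS, .BD_CATEGORICAL_FIELDS)

.BD_MATERIALS <- c("molybdenum", "rhodium")

#' Acquisition parameters of a digital mammogram
#'
#' Bundles the eleven exposure-control variables recorded in a mammogram's
#' DICOM header that drive the header linear model of percent density:
#' nine continuous values (doses, thicknesses, kVp, mean signal, an opaque
#' header threshold, compression force, detector sensitivity) and the two
#' categorical beam materials. Thicknesses are millimetres, compression force
#' newtons; dose, sensitivity and signal fields are raw header values with no
#' physical unit attached — they enter the model unchanged.
#'
#' @param preexposure_dose,radiation_dose detector dose readouts (raw header
#'   units).
#' @param preexposure_thickness,final_exposure_thickness compressed breast
#'   thickness in mm at pre-exposure and final exposure.
#' @param preexposure_kvp tube voltage of the pre-exposure, kV.
#' @param anatomical_mean_intensity mean raw signal over the anatomy.
#' @param thresh opaque header threshold value (raw signal units).
#' @param compression_force compression force, N.
#' @param detector_sensitivity detector sensitivity (dimensionless).
#' @param filter_material,anode_material `"molybdenum"` or `"rhodium"`.
#' @return An object of class `imaging_parameters` (a named list).
#' @seealso [math_pct_g()] which consumes these records.
#' @examples
#' imaging_parameters(preexposure_dose = 120, preexposure_thickness = 52,
#'   radiation_dose = 95, preexposure_kvp = 27, anatomical_mean_intensity = 410,
#'   thresh = 300, final_exposure_thickness = 51, compression_force = 110,
#'   detector_sensitivity = 0.0011, filter_material = "rhodium",
#'   anode_material = "molybdenum")
#' @export
imaging_parameters <- function(preexposure_dose, preexposure_thickness,
                               radiation_dose, preexposure_kvp,
                               anatomical_mean_intensity, thresh,
                               final_exposure_thickness, compression_force,
                               detector_sensitivity, filter_material,
                               anode_material) {
  p <- list(
    preexposure_dose = preexposure_dose,
    preexposure_thickness = preexposure_thickness,
    radiation_dose = radiation_dose,
    preexposure_kvp = preexposure_kvp,
    anatomical_mean_intensity = anatomical_mean_intensity,
    thresh = thresh,
    final_exposure_thickness = final_exposure_thickness,
    compression_force = compression_force,
    detector_sensitivity = detector_sensitivity,
    filter_material = filter_material,
    anode_material = anode_material)
  for (f in .BD_CONTINUOUS_FIELDS) {
    if (!is_scalar_num(p[[f]]))
      stopf("field '%s' must be a single finite number", f)
    p[[f]] <- as.numeric(p[[f]])
  }
  for (f in c("preexposure_thickness", "final_exposure_thickness",
              "compression_force"))
    if (p[[f]] < 0) stopf("field '%s' must be non-negative", f)
  for (f in .BD_CATEGORICAL_FIELDS) {
    val <- tolower(as.character(p[[f]]))
    if (length(val) != 1L || !val %in% .BD_MATERIALS)
      stopf("field '%s' must be one of %s", f,
            paste(sQuote(.BD_MATERIALS), collapse = ", "))
    p[[f]] <- val
  }
  structure(p, class = "imaging_parameters")
}

#' @export
print.imaging_parameters <- function(x, ...) {
  cat("Mammogram acquisition parameters\n")
  for (f in .BD_CONTINUOUS_FIELDS)
    cat(sprintf("  %-26s %g\n", f, x[[f]]))
  for (f in .BD_CATEGORICAL_FIELDS)
    cat(sprintf("  %-26s %s (coded %d)\n", f, x[[f]], material_code(x[[f]])))
  invisible(x)
}

#' Numeric coding of beam materials
#'
#' Molybdenum is coded 1 and rhodium 0, the convention used by the header
#' linear model for filter and anode material.
#'
#' @param material `"molybdenum"` or `"rhodium"` (vectorised).
#' @return Integer vector of 0/1 codes.
#' @export
material_code <- function(material) {
  m <- match(tolower(material), .BD_MATERIALS)
  if (anyNA(m)) stopf("unknown material '%s'", material[is.na(m)][1L])
  2L - m
}

#' Default DICOM tag map for mammogram metadata
#'
#' Maps each metadata field name to a `"GGGG,EEEE"` DICOM tag. The defaults
#' follow the GE Senographe dialect (standard tags where the standard defines
#' one, vendor private group 0045 otherwise); tag assignments differ between
#' scanners, so every entry is configuration, overridable per call or via a
#' JSON file `{name: "GGGG,EEEE"}`.
#'
#' @return Named character vector, field name to tag.
#' @export
default_tag_map <- function() {
  c(preexposure_dose        = "0045,1029",
    preexposure_thickness   = "0045,102A",
    radiation_dose          = "0045,1003",
    preexposure_kvp         = "0045,1004",
    anatomical_mean_intensity = "0045,1026",
    thresh                  = "0045,1027",
    final_exposure_thickness = "0018,11A0",
    compression_force       = "0018,11A4",
    detector_sensitivity    = "0045,1028",
    filter_material         = "0018,7050",
    anode_material          = "0018,1191",
    raddose_pct_g           = "0045,1030")
}

#' Read a mammogram with its acquisition metadata
#'
#' Accepts either a DICOM file (header + 16-bit pixel data) or a plain raster
#' (PNG, TIFF) accompanied by a JSON metadata sidecar. All eleven acquisition
#' parameters must be present; the FFDM unit's own density estimate
#' (`raddose_pct_g`) is optional. Thicknesses are standardised to millimetres:
#' a sidecar declaring `"thickness_units": "cm"` is converted on read and the
#' conversion is reported via [message()].
#'
#' @param image path to a DICOM, PNG or TIFF file.
#' @param metadata path to the JSON sidecar; defaults to the image path with
#'   its extension replaced by `.json`. Ignored for DICOM input.
#' @param tag_map named character vector mapping field names to DICOM tags;
#'   see [default_tag_map()]. Ignored for sidecar input.
#' @param pixel_to_ml_factor unit correction factor converting
#'   (pixel area x compression thickness) to mL; the default 9.96 is specific
#'   to one imaging geometry and absorbs all remaining unit conversion.
#'   A sidecar value overrides the argument.
#' @return An object of class `mammogram_record`: fields `pixels` (matrix),
#'   `params` ([imaging_parameters]), `pixel_to_ml_factor`, and
#'   `raddose_pct_g` (`NULL` when absent).
#' @export
read_mammogram <- function(image, metadata = NULL, tag_map = default_tag_map(),
                           pixel_to_ml_factor = 9.96) {
  if (!file.exists(image)) stopf("image file '%s' does not exist", image)
  if (dcm_is_dicom(image)) {
    dcm <- dcm_read(image)
    if (is.null(dcm$pixels)) stopf("'%s' carries no pixel data", image)
    vals <- list()
    for (f in .BD_PARAM_FIELDS) {
      tag <- tag_map[[f]]
      if (is.null(tag) || is.na(tag)) stopf("tag map has no entry for '%s'", f)
      raw_val <- dcm$elements[[toupper(tag)]]
      if (is.null(raw_val))
        stopf("required DICOM tag for '%s' (%s) missing in '%s'", f, tag, image)
      vals[[f]] <- if (f %in% .BD_CATEGORICAL_FIELDS) raw_val
                   else as.numeric(raw_val)
    }
    params <- do.call(imaging_parameters, vals)
    raddose <- NULL
    rd_tag <- tag_map[["raddose_pct_g"]]
    if (!is.null(rd_tag) && !is.null(dcm$elements[[toupper(rd_tag)]]))
      raddose <- as.numeric(dcm$elements[[toupper(rd_tag)]])
    rec <- new_mammogram_record(dcm$pixels, params, pixel_to_ml_factor,
                                raddose, source = image)
    return(rec)
  }
  # raster + sidecar route
  if (is.null(metadata))
    metadata <- paste0(tools::file_path_sans_ext(image), ".json")
  if (!file.exists(metadata))
    stopf("metadata sidecar '%s' does not exist", metadata)
  side <- jsonlite::read_json(metadata, simplifyVector = TRUE)
  ip <- side$imaging_parameters
  if (is.null(ip)) stopf("sidecar '%s' lacks 'imaging_parameters'", metadata)
  missing_fields <- setdiff(.BD_PARAM_FIELDS, names(ip))
  if (length(missing_fields) > 0L)
    stopf("sidecar missing required field(s): %s",
          paste(missing_fields, collapse = ", "))
  units <- side$thickness_units %||% "mm"
  if (identical(units, "cm")) {
    ip$preexposure_thickness <- ip$preexposure_thickness * 10
    ip$final_exposure_thickness <- ip$final_exposure_thickness * 10
    message("thickness fields converted from cm to mm on read")
  } else if (!identical(units, "mm")) {
    stopf("unknown thickness_units '%s' (expected 'mm' or 'cm')", units)
  }
  params <- do.call(imaging_parameters, ip[.BD_PARAM_FIELDS])
  raddose <- side$raddose_pct_g
  if (!is.null(raddose) && (raddose < 0 || raddose > 100))
    stopf("raddose_pct_g must lie in [0, 100], got %g", raddose)
  factor <- side$pixel_to_ml_factor %||% pixel_to_ml_factor
  pixels <- read_raster(image)
  new_mammogram_record(pixels, params, factor, raddose, source = image)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_raster <- function(image) {
  ext <- tolower(tools::file_ext(image))
  px <- switch(ext,
    png = {
      # the png package reads/writes 8-bit samples; convention: 0..255
      arr <- png::readPNG(image)
      if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
      round(arr * 255)
    },
    tif = , tiff = {
      arr <- tiff::readTIFF(image, as.is = TRUE)
      if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
      arr
    },
    stopf("unsupported raster format '.%s' (expected png or tiff)", ext))
  if (any(px < 0)) stopf("negative pixel intensities in '%s'", image)
  px
}

new_mammogram_record <- function(pixels, params, pixel_to_ml_factor,
                                 raddose_pct_g = NULL, source = NA_character_) {
  if (!is.matrix(pixels)) stopf("pixels must be a matrix")
  if (!is_scalar_num(pixel_to_ml_factor) || pixel_to_ml_factor <= 0)
    stopf("pixel_to_ml_factor must be a single positive number")
  if (!is.null(raddose_pct_g) &&
      (!is_scalar_num(raddose_pct_g) || raddose_pct_g < 0 || raddose_pct_g > 100))
    stopf("raddose_pct_g must lie in [0, 100]")
  structure(list(pixels = pixels, params = params,
                 pixel_to_ml_factor = pixel_to_ml_factor,
                 raddose_pct_g = raddose_pct_g, source = source),
            class = "mammogram_record")
}

#' @export
print.mammogram_record <- function(x, ...) {
  cat(sprintf("Mammogram record: %d x %d pixels", nrow(x$pixels), ncol(x$pixels)))
  if (!is.na(x$source)) cat(sprintf(" [%s]", basename(x$source)))
  cat("\n")
  cat(sprintf("  pixel-to-mL factor: %g\n", x$pixel_to_ml_factor))
  cat(sprintf("  FFDM Raddose %%-G:   %s\n",
              if (is.null(x$raddose_pct_g)) "absent" else
                sprintf("%g", x$raddose_pct_g)))
  invisible(x)
}

#' Voxel geometry of a reconstructed MRI breast model
#'
#' @param reconstructed_voxel_size in-plane voxel edge length, mm (x and y).
#' @param voxel_ratio ratio of the z voxel dimension to the x dimension.
#' @return Object of class `voxel_geometry` with the derived
#'   `voxel_volume_mm3 = voxel_ratio * reconstructed_voxel_size^3`.
#' @examples
#' voxel_geometry(0.7, 2.0)$voxel_volume_mm3  # 0.686
#' @export
voxel_geometry <- function(reconstructed_voxel_size, voxel_ratio) {
  if (!is_scalar_num(reconstructed_voxel_size) || reconstructed_voxel_size <= 0)
    stopf("reconstructed_voxel_size must be a single positive number")
  if (!is_scalar_num(voxel_ratio) || voxel_ratio <= 0)
    stopf("voxel_ratio must be a single positive number")
  structure(list(reconstructed_voxel_size = reconstructed_voxel_size,
                 voxel_ratio = voxel_ratio,
                 voxel_volume_mm3 = voxel_ratio * reconstructed_voxel_size^3),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("Voxel geometry: size %g mm, ratio %g -> volume %g mm^3\n",
              x$reconstructed_voxel_size, x$voxel_ratio, x$voxel_volume_mm3))
  invisible(x)
}

#' Read MRI voxel geometry from a header or sidecar
#'
#' Retrieves the reconstructed voxel size and voxel ratio from either a JSON
#' sidecar (keys `reconstructed_voxel_size_mm`, `voxel_ratio`) or a DICOM
#' header (private tags `0045,1040` / `0045,1041` by default) and derives the
#' voxel volume.
#'
#' @param path JSON sidecar or DICOM file.
#' @param size_tag,ratio_tag DICOM tags used on the DICOM route.
#' @return A [voxel_geometry] object.
#' @export
read_mri_geometry <- function(path, size_tag = "0045,1040",
                              ratio_tag = "0045,1041") {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  if (dcm_is_dicom(path)) {
    dcm <- dcm_read(path)
    size <- dcm$elements[[toupper(size_tag)]]
    ratio <- dcm$elements[[toupper(ratio_tag)]]
    if (is.null(size) || is.null(ratio))
      stopf("voxel size/ratio tags missing in '%s'", path)
    return(voxel_geometry(as.numeric(size), as.numeric(ratio)))
  }
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(side$reconstructed_voxel_size_mm) || is.null(side$voxel_ratio))
    stopf("sidecar '%s' lacks reconstructed_voxel_size_mm / voxel_ratio", path)
  voxel_geometry(side$reconstructed_voxel_size_mm, side$voxel_ratio)
}

#' Read a DICOM tag map from a JSON configuration file
#'
#' The file holds an object of `field name: "GGGG,EEEE"` pairs; entries merge
#' over (and override) the defaults from [default_tag_map()].
#'
#' @param path JSON file path.
#' @return Named character vector usable as the `tag_map` of
#'   [read_mammogram()].
#' @export
read_tag_map <- function(path) {
  user <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  tm <- default_tag_map()
  tm[names(user)] <- user
  tm
}
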