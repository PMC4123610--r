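# MATH pathway: percent glandular tissue as a fixed linear function of the
# eleven acquisition-header parameters, plus the volume decomposition
# GV = TV * %-G / 100, FV = TV - GV shared with the FFDM passthrough.

#' Coefficients of the header linear model of percent density
#'
#' Returns the published intercept and per-field coefficients mapping the
#' eleven acquisition parameters to percent glandular tissue. The fit is
#' specific to one mammography unit family; coefficients for other hardware
#' are supplied via `overrides` or a JSON file (see
#' [read_math_coefficients()]).
#'
#' @param overrides named numeric vector/list replacing individual defaults
#'   (names: `intercept` plus the [imaging_parameters] field names).
#' @return Named numeric vector of length 12, class `math_coefficients`.
#' @export
math_coefficients <- function(overrides = NULL) {
  co <- c(intercept                 = 481.33,
          preexposure_dose          = -0.0057,
          preexposure_thickness     = 1.2305,
          radiation_dose            = -0.094,
          preexposure_kvp           = 5.2056,
          anatomical_mean_intensity = -0.0599,
          thresh                    = -0.0192,
          final_exposure_thickness  = -2.0223,
          compression_force         = -0.049,
          detector_sensitivity      = -37220,
          filter_material           = -1.9863,
          anode_material            = 25.314)
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), names(co))
    if (length(bad) > 0L)
      stopf("unknown coefficient name(s): %s", paste(bad, collapse = ", "))
    co[names(overrides)] <- overrides
  }
  structure(co, class = "math_coefficients")
}

#' Read model coefficients from a JSON configuration file
#'
#' Schema: an object with a `schema_version` key and one numeric entry per
#' coefficient name; unspecified names keep their defaults.
#'
#' @param path JSON file path.
#' @return A [math_coefficients] vector.
#' @export
read_math_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stopf("coefficient file '%s' lacks a schema_version key", path)
  obj$schema_version <- NULL
  math_coefficients(overrides = obj)
}

#' Percent glandular tissue from acquisition parameters
#'
#' Evaluates the linear model
#' `%-G = intercept + sum(coef_i * x_i)` over the eleven header parameters,
#' with filter and anode material coded molybdenum = 1, rhodium = 0. The raw
#' linear score can leave the valid percent range, so truncation to
#' \[0, 100\] is on by default and announces itself with a warning.
#'
#' @param params an [imaging_parameters] record.
#' @param coefficients a [math_coefficients] vector.
#' @param clamp truncate the score to \[0, 100\]? Default `TRUE`.
#' @return Percent glandular tissue (scalar).
#' @examples
#' p <- imaging_parameters(0, 0, 0, 0, 0, 0, 0, 0, 0, "rhodium", "rhodium")
#' math_pct_g(p, clamp = FALSE)  # intercept only: 481.33
#' @export
math_pct_g <- function(params, coefficients = math_coefficients(),
                       clamp = TRUE) {
  if (!inherits(params, "imaging_parameters"))
    stopf("params must be an imaging_parameters record")
  if (length(coefficients) != 12L ||
      !setequal(names(coefficients), c("intercept", .BD_PARAM_FIELDS)))
    stopf("coefficients must hold an intercept plus one value per parameter field")
  x <- c(vapply(.BD_CONTINUOUS_FIELDS, function(f) params[[f]], numeric(1L)),
         vapply(.BD_CATEGORICAL_FIELDS,
                function(f) as.numeric(material_code(params[[f]])), numeric(1L)))
  if (any(!is.finite(x))) stopf("non-finite parameter value")
  score <- unname(coefficients[["intercept"]] +
                    sum(coefficients[names(x)] * x))
  if (clamp && (score < 0 || score > 100)) {
    warnf("linear score %.3f outside [0, 100]; truncated", score)
    score <- min(100, max(0, score))
  }
  score
}

#' Decompose a total volume by a percent-density estimate
#'
#' `GV = TV * %-G / 100`, `FV = TV * (1 - %-G / 100)`; total volume is
#' conserved exactly. Percent values outside \[0, 100\] are an error here —
#' any clamping belongs upstream, where the estimate is produced.
#'
#' @param pct_g percent glandular tissue in \[0, 100\].
#' @param tv_ml total breast volume, mL.
#' @param method pathway label for the output record (default `"MATH"`).
#' @return A [breast_composition].
#' @export
compose_from_pct <- function(pct_g, tv_ml, method = "MATH") {
  if (!is_scalar_num(pct_g) || pct_g < 0 || pct_g > 100)
    stopf("pct_g must lie in [0, 100], got %s", format(pct_g))
  if (!is_scalar_num(tv_ml) || tv_ml < 0) stopf("tv_ml must be non-negative")
  gv <- tv_ml * pct_g / 100
  breast_composition(method, pct_g, gv, tv_ml - gv, tv_ml)
}

#' MATH-pathway composition from a mammogram record
#'
#' @param record a [mammogram_record][read_mammogram].
#' @param tv_ml total breast volume in mL; the linear model predicts only the
#'   percent, so the total must come from elsewhere (typically the HSM total
#'   area x thickness) and is an explicit argument.
#' @param coefficients,clamp passed to [math_pct_g()].
#' @return A [breast_composition] with `method = "MATH"`.
#' @export
math_composition <- function(record, tv_ml,
                             coefficients = math_coefficients(), clamp = TRUE) {
  if (!inherits(record, "mammogram_record")) stopf("record must be a mammogram_record")
  compose_from_pct(math_pct_g(record$params, coefficients, clamp), tv_ml,
                   method = "MATH")
}

#' FFDM-pathway composition from the unit's own density estimate
#'
#' The mammography unit writes its own percent-density estimate ("Raddose")
#' into the image header; this passthrough combines it with a known total
#' volume.
#'
#' @param record a [mammogram_record][read_mammogram]; must carry
#'   `raddose_pct_g`.
#' @param tv_ml total breast volume, mL (see [math_composition()] for why this
#'   is explicit).
#' @return A [breast_composition] with `method = "FFDM"`.
#' @export
ffdm_composition <- function(record, tv_ml) {
  if (!inherits(record, "mammogram_record")) stopf("record must be a mammogram_record")
  if (is.null(record$raddose_pct_g))
    stopf("record carries no Raddose percent-density estimate")
  compose_from_pct(record$raddose_pct_g, tv_ml, method = "FFDM")
}
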