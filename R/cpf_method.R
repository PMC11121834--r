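#' Cone-pyramid formula (CPF) volume
#'
#' The simplified volume estimate from two four-chamber linear measurements:
#' `V = k * diameter^2 * length`, with the established constant `k = 1.21`.
#' Applied to end-diastolic measurements (Dd, Ld) it gives EDV, to
#' end-systolic measurements (Ds, Ls) ESV.  Vectorized.
#'
#' @param diameter basal diameter at the tricuspid-valve level, cm.
#' @param length baso-apical length (tricuspid-valve center to apex), cm.
#' @param k formula coefficient; kept as an argument so sensitivity analyses
#'   against geometrically calibrated coefficients are possible.
#' @return Volume in mL.
#' @export
#' @examples
#' cpf_volume(4.2, 7.7)  # 164.35 mL
#' cpf_volume(3.5, 6.5)  # 96.35 mL
cpf_volume <- function(diameter, length, k = 1.21) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("'diameter' must be positive")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("'length' must be positive")
  if (k <= 0) stop("'k' must be positive")
  k * diameter^2 * length
}

#' Ejection fraction
#'
#' `EF = (EDV - ESV) * 100 / EDV`, in percent.  Values outside [0, 100] can
#' arise from noisy inputs; they are returned unclamped (with a warning when
#' negative) so downstream agreement statistics are not distorted.
#'
#' @param edv end-diastolic volume, mL (> 0).
#' @param esv end-systolic volume, mL.
#' @return EF in percent; vectorized.
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(!is.finite(edv)) || any(edv <= 0))
    stop("'edv' must be positive: EF undefined")
  ef <- (edv - esv) * 100 / edv
  if (any(ef < 0))
    warning("negative ejection fraction (ESV > EDV); returned unclamped",
            call. = FALSE)
  ef
}

#' Index a volume to body surface area
#'
#' @param volume volume, mL.
#' @param bsa body surface area, m^2 (> 0).
#' @return Indexed volume, mL/m^2; vectorized.
#' @export
#' @examples
#' index_to_bsa(162.6, 1.99)  # ~81.7 mL/m^2
index_to_bsa <- function(volume, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) stop("'bsa' must be positive")
  volume / bsa
}

#' Sex-specific CMR reference thresholds
#'
#' Published reference limits: the RV is enlarged if the EDV index exceeds
#' 123 mL/m^2 in men or 104 mL/m^2 in women, or the ESV index exceeds
#' 59 / 48 mL/m^2; RV function is reduced if EF is below 42% in men or 46%
#' in women.  All comparisons are strict, exactly as published.
#'
#' @param edvi_male,edvi_female EDV index limits, mL/m^2.
#' @param esvi_male,esvi_female ESV index limits, mL/m^2.
#' @param ef_male,ef_female EF limits, %.
#' @return An object of class `rv_thresholds`.
#' @export
reference_thresholds <- function(edvi_male = 123, edvi_female = 104,
                                 esvi_male = 59, esvi_female = 48,
                                 ef_male = 42, ef_female = 46) {
  vals <- c(edvi_male, edvi_female, esvi_male, esvi_female, ef_male, ef_female)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds must be positive")
  structure(list(edvi_male = edvi_male, edvi_female = edvi_female,
                 esvi_male = esvi_male, esvi_female = esvi_female,
                 ef_male = ef_male, ef_female = ef_female),
            class = "rv_thresholds")
}

#' Classify RV size and function against reference thresholds
#'
#' @param sex character vector, `"male"` or `"female"`.
#' @param edvi EDV index, mL/m^2.
#' @param esvi ESV index, mL/m^2.
#' @param ef ejection fraction, %.
#' @param thresholds an [reference_thresholds()] object.
#' @return A data.frame with logical columns `enlarged_edv` (EDV index
#'   strictly above the sex-specific limit), `enlarged_esv`, and `reduced_ef`
#'   (EF strictly below the limit).
#' @export
classify_rv <- function(sex, edvi, esvi, ef,
                        thresholds = reference_thresholds()) {
  if (!inherits(thresholds, "rv_thresholds"))
    stop("'thresholds' must be an rv_thresholds object")
  if (!all(sex %in% c("male", "female")))
    stop("'sex' must be \"male\" or \"female\"")
  male <- sex == "male"
  data.frame(
    enlarged_edv = edvi > ifelse(male, thresholds$edvi_male,
                                 thresholds$edvi_female),
    enlarged_esv = esvi > ifelse(male, thresholds$esvi_male,
                                 thresholds$esvi_female),
    reduced_ef = ef < ifelse(male, thresholds$ef_male, thresholds$ef_female))
}

#' Assemble per-subject method results
#'
#' Derives EF and BSA-indexed volumes from raw volumes for one method and
#' returns the standard results-table rows.
#'
#' @param id subject identifiers.
#' @param method `"standard"` (disk summation) or `"cpf"`.
#' @param edv_ml,esv_ml volumes in mL.
#' @param bsa_m2 body surface area in m^2.
#' @return A data.frame with columns `id`, `method`, `edv_ml`, `esv_ml`,
#'   `ef_pct`, `edvi`, `esvi`.
#' @export
method_results <- function(id, method, edv_ml, esv_ml, bsa_m2) {
  method <- match.arg(method, c("standard", "cpf"))
  data.frame(id = id, method = method,
             edv_ml = edv_ml, esv_ml = esv_ml,
             ef_pct = ejection_fraction(edv_ml, esv_ml),
             edvi = index_to_bsa(edv_ml, bsa_m2),
             esvi = index_to_bsa(esv_ml, bsa_m2),
             stringsAsFactors = FALSE)
}
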