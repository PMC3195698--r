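# Per-nucleus feature extraction: morphometry + co-occurrence texture +
# fractal dimension, one row per nucleus.

#' All nuclear features of one nucleus
#'
#' Runs the full feature set on one segmented nucleus: geometric
#' morphometry, the seven co-occurrence texture features and the
#' Minkowski-Bouligand fractal dimension with its goodness of fit. Only
#' pixels inside the mask are ever read.
#'
#' @param nucleus A [nucleus_image()].
#' @param glcm_distance,glcm_directions,glcm_levels Passed to
#'   [build_glcm()].
#' @param eps_max,connectivity,fit_range Passed to the fractal routines.
#' @param form_factor_method Passed to [form_factor()].
#' @return One-row data.frame: metadata (`patient_id`, `cell_class`,
#'   `cell_index`) plus all feature columns.
#' @export
nucleus_features <- function(nucleus, glcm_distance = 1L,
                             glcm_directions = c("0", "45", "90", "135"),
                             glcm_levels = 256L,
                             eps_max = 10L, connectivity = 8L,
                             fit_range = NULL,
                             form_factor_method = "circularity") {
  stopifnot(inherits(nucleus, "nucleus_image"))
  morph <- morphometry(nucleus, form_factor_method)
  tex <- glcm_features(build_glcm(nucleus, glcm_distance, glcm_directions,
                                  glcm_levels))
  tex$mu_x <- NULL; tex$mu_y <- NULL
  frac <- fractal_features(nucleus, eps_max, connectivity, fit_range)
  cbind(
    data.frame(patient_id = nucleus$patient_id,
               cell_class = nucleus$cell_class,
               cell_index = nucleus$cell_index,
               stringsAsFactors = FALSE),
    morph, tex, frac
  )
}

#' Per-nucleus feature table for a set of nuclei
#'
#' @param nuclei List of [nucleus_image()] objects (e.g. from
#'   [load_manifest()] or [generate_nucleus()]).
#' @param ... Passed to [nucleus_features()].
#' @return Data frame with one row per nucleus.
#' @export
analyze_nuclei <- function(nuclei, ...) {
  do.call(rbind, lapply(nuclei, nucleus_features, ...))
}
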