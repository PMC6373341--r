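STATISTICAL_NAMES <- c("min", "max", "range", "mean", "median", "sd",
                       "variance", "mad", "skewness", "kurtosis", "energy",
                       "entropy", "uniformity", "rms", "iqr", "p10", "p90")
MORPHOLOGICAL_NAMES <- c("volume", "surface", "areavolume", "eqsph_radius",
                         "L_major", "L_minor", "L_least", "elongation",
                         "flatness", "compactness1", "compactness2",
                         "sphdispr", "sphericity", "asphericity")
FRACTAL_NAMES <- c("meanFD", "medianFD", "sdFD", "minFD", "maxFD", "rangeFD")
TEXTURAL_NAMES <- RLM_FEATURE_NAMES

#' The canonical 53-feature panel
#'
#' An ordered data.frame of the panel: 17 statistical, 14 morphological,
#' 6 fractal and 16 run-length textural features (53 in total). The exact
#' membership of the original institutional panel is unpublished; this
#' reconstruction keeps the printed family count and every feature name
#' reported as significant in the source study, completed with standard
#' first-order, shape and run-length definitions.
#'
#' @return data.frame with columns `feature` and `family`
#'   (`statistical`, `morphological`, `fractal`, `textural`).
#' @export
feature_panel <- function() {
  data.frame(
    feature = c(STATISTICAL_NAMES, MORPHOLOGICAL_NAMES,
                FRACTAL_NAMES, TEXTURAL_NAMES),
    family = rep(c("statistical", "morphological", "fractal", "textural"),
                 times = c(length(STATISTICAL_NAMES),
                           length(MORPHOLOGICAL_NAMES),
                           length(FRACTAL_NAMES),
                           length(TEXTURAL_NAMES))),
    stringsAsFactors = FALSE)
}

#' Extraction settings
#'
#' @param n_levels grey levels for run-length quantization (default 32).
#' @param n_bins histogram bins for entropy/uniformity (default 64).
#' @param surface_method `"mesh"` or `"voxel_face"` (see [surface_area]).
#' @param smooth_sigma mesh pre-smoothing sigma in voxels.
#' @return a list of class `extraction_config`.
#' @export
extraction_config <- function(n_levels = 32L, n_bins = 64L,
                              surface_method = "mesh", smooth_sigma = 0.8) {
  structure(list(n_levels = as.integer(n_levels),
                 n_bins = as.integer(n_bins),
                 surface_method = match.arg(surface_method,
                                            c("mesh", "voxel_face")),
                 smooth_sigma = smooth_sigma),
            class = "extraction_config")
}

#' Extract the full 53-feature panel from one observation
#'
#' Runs all four family extractors on the raw image intensities inside
#' the mask — no image filtering is applied beforehand — and returns the
#' features in canonical panel order. Extraction is deterministic and
#' invariant to the enumeration order of ROI voxels.
#'
#' @param obs a [lesion_observation].
#' @param config an [extraction_config].
#' @return named numeric vector of length 53 with attributes `patient_id`
#'   and `timepoint`.
#' @export
extract_all <- function(obs, config = extraction_config()) {
  stopifnot(inherits(obs, "lesion_obs"))
  if (!any(obs$mask$values)) stop("empty ROI: mask contains no occupied voxel")
  intens <- obs$image$values[obs$mask$values]
  out <- c(statistical_features(intens, n_bins = config$n_bins),
           shape_features(obs$mask, surface_method = config$surface_method,
                          smooth_sigma = config$smooth_sigma),
           fd_summaries(obs$mask)[FRACTAL_NAMES],
           texture_features(obs$image, obs$mask, n_levels = config$n_levels))
  out <- out[feature_panel()$feature]
  attr(out, "patient_id") <- obs$patient_id
  attr(out, "timepoint") <- obs$timepoint
  out
}
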