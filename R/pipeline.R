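#' Extract the feature panel for a whole cohort
#'
#' Reads every manifest row (image + mask pair), validates geometry, and
#' extracts the 53-feature panel. A failing observation is logged and
#' skipped — one bad scan must not abort a cohort run — unless every
#' observation fails.
#'
#' @param manifest data.frame with columns `patient_id`, `timepoint`,
#'   `image_path`, `mask_path` (and optionally `outcome`), or the path of
#'   such a CSV.
#' @param config an [extraction_config].
#' @param quiet suppress per-failure messages.
#' @return long feature table as from [longitudinal_table]; attribute
#'   `failures` is a data.frame of skipped observations and reasons.
#' @export
run_extract <- function(manifest, config = extraction_config(),
                        quiet = FALSE) {
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  need <- c("patient_id", "timepoint", "image_path", "mask_path")
  if (nrow(manifest) == 0L) stop("empty manifest: nothing to extract")
  stopifnot(all(need %in% names(manifest)))
  vectors <- list()
  failures <- list()
  for (r in seq_len(nrow(manifest))) {
    row <- manifest[r, ]
    res <- tryCatch({
      img <- read_volume(row$image_path)
      msk <- binary_mask(read_volume(row$mask_path))
      obs <- lesion_observation(row$patient_id, row$timepoint, img, msk)
      extract_all(obs, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!quiet) {
        message(sprintf("skipping %s/%s: %s", row$patient_id,
                        row$timepoint, conditionMessage(res)))
      }
      failures[[length(failures) + 1L]] <-
        data.frame(patient_id = row$patient_id, timepoint = row$timepoint,
                   reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      vectors[[length(vectors) + 1L]] <- res
    }
  }
  if (length(vectors) == 0L) {
    stop("run error: no observation could be processed")
  }
  out <- longitudinal_table(vectors)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
                           else NULL
  out
}

#' Extract directly from in-memory observations
#'
#' @param observations list of [lesion_observation] objects (for example
#'   `generate_cohort(...)$observations`).
#' @inheritParams run_extract
#' @return long feature table.
#' @export
extract_cohort <- function(observations, config = extraction_config()) {
  longitudinal_table(lapply(observations, extract_all, config = config))
}

#' Delta table, screening grid and rendered report in one call
#'
#' @param features long feature table ([run_extract]/[extract_cohort]) or
#'   the path of such a CSV.
#' @param outcomes data.frame `patient_id`, `outcome`, or a CSV path.
#' @param alpha,exact_limit,p_adjust passed to [screen_features].
#' @param out_dir optional directory; when given, writes `features.csv`,
#'   `delta.csv`, `screening.csv` and `report.txt` there.
#' @return list `delta` (delta table), `screening`
#'   (`screening_result`), `report` (rendered significance grid).
#' @export
run_screen <- function(features, outcomes, alpha = 0.05,
                       exact_limit = 30L, p_adjust = "none",
                       out_dir = NULL) {
  if (is.character(features)) features <- read.csv(features,
                                                   stringsAsFactors = FALSE)
  if (is.character(outcomes)) outcomes <- read.csv(outcomes,
                                                   stringsAsFactors = FALSE)
  if (!any(features$timepoint == "t0")) {
    stop("feature table has no t0 rows: deltas are undefined")
  }
  delta <- delta_table(features)
  sc <- screen_features(features, delta, outcomes, alpha = alpha,
                        exact_limit = exact_limit, p_adjust = p_adjust)
  report <- render_screening(sc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    write.csv(delta, file.path(out_dir, "delta.csv"), row.names = FALSE)
    write.csv(sc, file.path(out_dir, "screening.csv"), row.names = FALSE)
    writeLines(c(sprintf("Significance grid (p < %g, exact WMW, no multiplicity correction unless noted; p_adjust = %s)",
                         alpha, p_adjust),
                 "Caveat: univariate screening without multiple-testing correction inflates the family-wise error rate.",
                 "",
                 utils::capture.output(print(report, row.names = FALSE))),
               file.path(out_dir, "report.txt"))
  }
  list(delta = delta, screening = sc, report = report)
}
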