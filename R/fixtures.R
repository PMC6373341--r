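#' Packaged study reference tables
#'
#' The source study's patient-characteristics table and its grid of
#' significant feature/timepoint cells, transcribed cell-by-cell into
#' versioned CSVs shipped with the package, so tallies over them never
#' depend on document parsing at run time.
#'
#' `study_patients()` returns one row per patient: `age` (years), `sex`
#' (1 male, 2 female), `site` (1 high, 2 medium, 3 low rectum), `chemo`
#' (0 none, 1 capecitabine, 2 capecitabine + oxaliplatin), `stage` (cTNM),
#' `restaging` (ycTNM), `watch_and_wait` (0/1). `study_significance()`
#' returns the significant cells in long form: `feature` (panel name),
#' `family`, `column` (`t0` = absolute baseline, `t11`..`t55` = delta),
#' `p_value` (all < 0.05 — only significant cells were printed).
#'
#' @return a data.frame (see details).
#' @export
study_patients <- function() {
  read.csv(system.file("extdata", "table1_patients.csv",
                       package = "deltarad"),
           stringsAsFactors = FALSE)
}

#' @rdname study_patients
#' @export
study_significance <- function() {
  read.csv(system.file("extdata", "table2_significance.csv",
                       package = "deltarad"),
           stringsAsFactors = FALSE)
}

#' Count clinical complete responders
#'
#' A patient is a clinical complete responder (cCR) iff restaging is
#' exactly `ycT0 ycN0 ycM0`.
#'
#' @param records data.frame with a `restaging` column
#'   (default: the shipped patient table).
#' @return list `count` and `percentage` (rounded to integer percent).
#' @export
count_ccr <- function(records = study_patients()) {
  if (nrow(records) == 0L) {
    stop("empty record set: percentage undefined")
  }
  ok <- grepl("^ycT[0-9x/ab]+ ycN[0-9x/]+ ycM[0-9x]+$", records$restaging)
  if (any(!ok)) {
    stop(sprintf("malformed restaging string in record(s) %s",
                 paste(which(!ok), collapse = ", ")))
  }
  n <- sum(records$restaging == "ycT0 ycN0 ycM0")
  list(count = n, percentage = round(100 * n / nrow(records)))
}

#' Tally significant cells over selected columns
#'
#' @param table significance table ([study_significance]).
#' @param columns subset of `TIMEPOINTS` to restrict to.
#' @return number of significant cells in those columns.
#' @export
tally_significant <- function(table = study_significance(),
                              columns = TIMEPOINTS) {
  bad <- setdiff(columns, TIMEPOINTS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown column label(s): %s", paste(bad, collapse = ", ")))
  }
  sum(table$column %in% columns)
}

#' Features significant at every delta timepoint
#'
#' @param table significance table ([study_significance]).
#' @return character vector of features with a significant cell in all
#'   five delta columns (t11..t55).
#' @export
features_significant_at_all_deltas <- function(table = study_significance()) {
  if (nrow(table) == 0L) return(character(0))
  deltas <- TIMEPOINTS[-1]
  tab <- table[table$column %in% deltas, ]
  cnt <- tapply(tab$column, tab$feature, function(x) length(unique(x)))
  sort(names(cnt)[cnt == length(deltas)])
}
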