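#' Assemble a longitudinal feature table
#'
#' @param vectors list of feature vectors from [extract_all].
#' @return long data.frame `patient_id`, `timepoint`, `feature`, `value`,
#'   one row per (patient, timepoint, feature).
#' @export
longitudinal_table <- function(vectors) {
  rows <- lapply(vectors, function(v) {
    data.frame(patient_id = attr(v, "patient_id"),
               timepoint = attr(v, "timepoint"),
               feature = names(v),
               value = as.numeric(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dup <- duplicated(out[, c("patient_id", "timepoint", "feature")])
  if (any(dup)) stop("duplicate (patient, timepoint, feature) entries")
  rownames(out) <- NULL
  out
}

#' Baseline-normalised delta features
#'
#' The delta feature at an on-treatment timepoint is the ratio of the
#' feature value there to its value on the simulation scan (`t0`). A cell
#' is undefined (NA, never 0 or infinity) when the `t0` value is missing
#' or zero; patients without a `t0` row yield a structured warning and
#' all-undefined deltas.
#'
#' @param long long table from [longitudinal_table].
#' @return long data.frame `patient_id`, `timepoint` (t11..t55),
#'   `feature`, `ratio`; attribute `n_defined` counts defined cells.
#' @export
delta_table <- function(long) {
  stopifnot(all(c("patient_id", "timepoint", "feature", "value") %in%
                  names(long)))
  on_tx <- TIMEPOINTS[-1]
  base <- long[long$timepoint == "t0", c("patient_id", "feature", "value")]
  names(base)[3] <- "t0_value"
  no_base <- setdiff(unique(long$patient_id), unique(base$patient_id))
  if (length(no_base) > 0L) {
    warning(sprintf("no t0 scan for patient(s) %s: their delta features are undefined",
                    paste(no_base, collapse = ", ")))
  }
  lt <- long[long$timepoint %in% on_tx, ]
  m <- merge(lt, base, by = c("patient_id", "feature"), all.x = TRUE)
  m$ratio <- ifelse(!is.na(m$t0_value) & m$t0_value != 0,
                    m$value / m$t0_value, NA_real_)
  out <- m[order(m$patient_id, match(m$timepoint, TIMEPOINTS), m$feature),
           c("patient_id", "timepoint", "feature", "ratio")]
  rownames(out) <- NULL
  attr(out, "n_defined") <- sum(!is.na(out$ratio))
  out
}

# cache of exact rank-sum null distributions keyed by the pooled midrank
# multiset and group size (the null law does not depend on the labelling)
.wmw_cache <- new.env(parent = emptyenv())

# Exact distribution of the size-n1 subset rank sum over all C(n, n1)
# equally likely label assignments, by the shift (dynamic-programming)
# algorithm on doubled midranks. Returns support (doubled sums) and counts.
wmw_null_distribution <- function(r2, n1) {
  key <- paste(n1, paste(r2, collapse = ","), sep = "|")
  hit <- .wmw_cache[[key]]
  if (!is.null(hit)) return(hit)
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  dp <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  dp[1L, 1L] <- 1  # empty subset, sum 0
  kmax <- 0L
  for (v in r2) {
    top <- min(kmax, n1 - 1L)
    for (k in top:0L) {
      nz <- which(dp[k + 1L, ] > 0)
      dp[k + 2L, nz + v] <- dp[k + 2L, nz + v] + dp[k + 1L, nz]
    }
    kmax <- min(kmax + 1L, n1)
  }
  counts <- dp[n1 + 1L, ]
  support <- which(counts > 0) - 1L
  out <- list(support = support, counts = counts[support + 1L])
  .wmw_cache[[key]] <- out
  out
}

#' Exact two-sided Wilcoxon-Mann-Whitney test
#'
#' Rank-sum test with mid-ranks for ties. On the exact path (combined
#' n at most `exact_limit`) the two-sided p-value is the probability,
#' over all equally likely assignments of the pooled values to the two
#' group sizes, that the group-A rank sum deviates from its null mean at
#' least as far as observed (mean-symmetric tail rule); the full
#' assignment distribution is computed by a shift algorithm, which
#' enumerates exactly. Above the bound the tie-corrected normal
#' approximation is used (no continuity correction).
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @param exact_limit largest combined sample size for the exact path.
#' @return two-sided p-value in (0, 1]; attribute `method` records the
#'   path taken (`"exact"` or `"normal"`).
#' @export
wmw_exact <- function(group_a, group_b, exact_limit = 30L) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  x <- c(group_a, group_b)
  if (any(!is.finite(x))) stop("non-finite value in a group")
  n1 <- length(group_a)
  n <- length(x)
  r <- rank(x)
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  if (n <= exact_limit) {
    r2 <- sort(as.integer(round(2 * r)))  # doubled midranks are integers;
    d <- wmw_null_distribution(r2, n1)    # null law ignores the ordering
    dev_obs <- abs(2 * w - 2 * e)
    p <- sum(d$counts[abs(d$support - 2 * e) >= dev_obs - 1e-9]) /
      sum(d$counts)
    return(structure(p, method = "exact"))
  }
  n2 <- n - n1
  ties <- table(r)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(structure(1, method = "normal"))
  p <- min(1, 2 * pnorm(-abs(w - e) / sqrt(v)))
  structure(p, method = "normal")
}

#' Screen absolute and delta features against the outcome
#'
#' One two-sided WMW test per feature for the absolute baseline (`t0`)
#' column and per (feature, dose level) for the five delta columns — up
#' to 53 + 265 = 318 tests for the full panel. Undefined delta cells are
#' excluded pairwise; a cell left with fewer than two patients per class
#' is reported untested. No multiplicity correction is applied by
#' default (each cell is judged against `alpha` alone); set
#' `p_adjust = "BH"` for Benjamini-Hochberg across tested cells.
#'
#' @param long longitudinal table ([longitudinal_table]).
#' @param delta delta table ([delta_table]); computed from `long` if NULL.
#' @param outcomes data.frame `patient_id`, `outcome` (1 = cCR, 0 = not)
#'   or a named 0/1 vector.
#' @param alpha significance level (default 0.05).
#' @param exact_limit passed to [wmw_exact].
#' @param p_adjust `"none"` (default) or a [stats::p.adjust] method.
#' @return data.frame of class `screening_result`: `feature`, `family`,
#'   `column` (t0 = absolute, t11..t55 = delta), `p_value`,
#'   `significant`, `n_ccr`, `n_other`, `tested`.
#' @export
screen_features <- function(long, delta = NULL, outcomes, alpha = 0.05,
                            exact_limit = 30L, p_adjust = "none") {
  if (is.null(delta)) delta <- delta_table(long)
  if (!is.data.frame(outcomes)) {
    outcomes <- data.frame(patient_id = names(outcomes),
                           outcome = as.numeric(outcomes),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("patient_id", "outcome") %in% names(outcomes)))
  patients <- unique(long$patient_id)
  missing_lab <- setdiff(patients, outcomes$patient_id)
  if (length(missing_lab) > 0L) {
    stop(sprintf("missing outcome label for patient(s): %s",
                 paste(missing_lab, collapse = ", ")))
  }
  lab <- setNames(outcomes$outcome, outcomes$patient_id)[patients]
  if (length(unique(lab)) < 2L) {
    stop("screening needs both outcome classes in the cohort")
  }
  if (min(table(lab)) < 2L) {
    stop("screening needs at least 2 patients per outcome class")
  }
  panel <- feature_panel()
  feats <- unique(long$feature)
  fam <- setNames(panel$family, panel$feature)
  cell_test <- function(vals, pats) {
    keep <- !is.na(vals)
    g <- lab[pats[keep]]
    v <- vals[keep]
    if (sum(g == 1) < 2L || sum(g == 0) < 2L) {
      return(list(p = NA_real_, n1 = sum(g == 1), n0 = sum(g == 0),
                  tested = FALSE))
    }
    p <- wmw_exact(v[g == 1], v[g == 0], exact_limit = exact_limit)
    list(p = as.numeric(p), n1 = sum(g == 1), n0 = sum(g == 0),
         tested = TRUE)
  }
  rows <- list()
  base <- long[long$timepoint == "t0", ]
  for (f in feats) {
    bf <- base[base$feature == f, ]
    res <- cell_test(bf$value, bf$patient_id)
    rows[[length(rows) + 1L]] <-
      data.frame(feature = f, column = "t0", p_value = res$p,
                 n_ccr = res$n1, n_other = res$n0, tested = res$tested,
                 stringsAsFactors = FALSE)
    for (tp in TIMEPOINTS[-1]) {
      df <- delta[delta$feature == f & delta$timepoint == tp, ]
      res <- cell_test(df$ratio, df$patient_id)
      rows[[length(rows) + 1L]] <-
        data.frame(feature = f, column = tp, p_value = res$p,
                   n_ccr = res$n1, n_other = res$n0, tested = res$tested,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$family <- unname(fam[out$feature])
  if (p_adjust != "none") {
    out$p_value[out$tested] <- p.adjust(out$p_value[out$tested],
                                        method = p_adjust)
  }
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out <- out[, c("feature", "family", "column", "p_value", "significant",
                 "n_ccr", "n_other", "tested")]
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Render a screening result as a significance grid
#'
#' Wide feature-by-column table in the style of a published significance
#' table: cells show the p-value when `p < alpha`, blank otherwise; rows
#' without any significant cell are dropped unless `all_rows = TRUE`.
#'
#' @param result a `screening_result` from [screen_features].
#' @param all_rows keep non-significant rows too.
#' @param digits p-value digits.
#' @return character data.frame, one row per feature.
#' @export
render_screening <- function(result, all_rows = FALSE, digits = 3) {
  alpha <- attr(result, "alpha")
  cols <- TIMEPOINTS
  feats <- unique(result$feature)
  grid <- matrix("", nrow = length(feats), ncol = length(cols),
                 dimnames = list(feats, cols))
  sig <- result[result$significant %in% TRUE, ]
  for (i in seq_len(nrow(sig))) {
    grid[sig$feature[i], sig$column[i]] <-
      formatC(sig$p_value[i], digits = digits, format = "f")
  }
  keep <- if (all_rows) seq_along(feats) else which(rowSums(grid != "") > 0)
  out <- data.frame(feature = feats[keep],
                    family = result$family[match(feats[keep], result$feature)],
                    grid[keep, , drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
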