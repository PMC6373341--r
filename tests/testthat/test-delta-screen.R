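test_that("cumulative dose bookkeeping matches the fractionation", {
  expect_equal(dose_at_fraction(10), 22)
  expect_equal(dose_at_fraction(5), 11)
  expect_equal(dose_at_fraction(0), 0)
  expect_equal(dose_at_fraction(25), 55)
  expect_error(dose_at_fraction(-1), "non-negative")
})

test_that("delta ratios are value(t)/value(t0) with a strict zero policy", {
  long <- toy_long(list(
    A = c(t0 = 7, t11 = 7, t22 = 3.5),
    B = c(t0 = 50, t11 = 25),
    C = c(t0 = 0, t11 = 4)))
  d <- delta_table(long)
  get <- function(p, tp) d$ratio[d$patient_id == p & d$timepoint == tp]
  expect_equal(get("A", "t11"), 1)
  expect_equal(get("A", "t22"), 0.5)
  expect_equal(get("B", "t11"), 0.5)
  expect_true(is.na(get("C", "t11")))  # zero baseline: undefined, not Inf
  expect_equal(attr(d, "n_defined"), 3)
})

test_that("a missing baseline row warns and leaves deltas undefined", {
  long <- toy_long(list(A = c(t0 = 2, t11 = 4), B = c(t11 = 6)))
  expect_warning(d <- delta_table(long), "no t0 scan.*B")
  expect_true(is.na(d$ratio[d$patient_id == "B"]))
})

test_that("exact WMW p-values match brute-force enumeration", {
  expect_equal(as.numeric(wmw_exact(c(1, 2, 3), c(4, 5))), 0.2,
               tolerance = 1e-12)
  expect_equal(as.numeric(wmw_exact(c(5), c(5))), 1)
  set.seed(13)
  for (rep in 1:25) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    # mix continuous values and ties
    pool <- c(rnorm(6), sample(1:3, 6, replace = TRUE))
    a <- sample(pool, n1, replace = TRUE)
    b <- sample(pool, n2, replace = TRUE)
    expect_equal(as.numeric(wmw_exact(a, b)), brute_wmw(a, b),
                 tolerance = 1e-12)
  }
  # larger balanced case still on the exact path
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(as.numeric(wmw_exact(a, b)), brute_wmw(a, b),
               tolerance = 1e-12)
})

test_that("WMW is symmetric in its groups and rank invariant", {
  set.seed(29)
  a <- rnorm(5); b <- rnorm(8)
  expect_equal(as.numeric(wmw_exact(a, b)), as.numeric(wmw_exact(b, a)),
               tolerance = 1e-12)
  # strictly increasing transform preserves ranks hence the p-value
  tr <- function(x) exp(x) + x^3
  expect_equal(as.numeric(wmw_exact(a, b)),
               as.numeric(wmw_exact(tr(a), tr(b))), tolerance = 1e-12)
  expect_error(wmw_exact(numeric(0), 1), "non-empty")
})

test_that("the normal fallback engages above the exact bound", {
  set.seed(41)
  a <- rnorm(20); b <- rnorm(20, 1)
  p <- wmw_exact(a, b)
  expect_identical(attr(p, "method"), "normal")
  # sanity: close to the asymptotic wilcox.test p (no continuity corr.)
  ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
  expect_equal(as.numeric(p), ref, tolerance = 1e-9)
  p2 <- wmw_exact(a, b, exact_limit = 40L)
  expect_identical(attr(p2, "method"), "exact")
})

test_that("screening flags perfectly separated deltas at the minimal p", {
  # 4 responders' volume deltas uniformly below 6 non-responders'
  vals <- c(seq(0.2, 0.35, length.out = 4), seq(0.8, 1.0, length.out = 6))
  pats <- sprintf("P%02d", 1:10)
  long <- do.call(rbind, lapply(seq_along(pats), function(i)
    toy_long(setNames(list(c(t0 = 10, t55 = 10 * vals[i])), pats[i]),
             feature = "volume")))
  outcomes <- data.frame(patient_id = pats, outcome = rep(c(1, 0), c(4, 6)))
  sc <- screen_features(long, outcomes = outcomes)
  p55 <- sc$p_value[sc$feature == "volume" & sc$column == "t55"]
  expect_equal(p55, 2 / choose(10, 4), tolerance = 1e-12)
  expect_true(sc$significant[sc$feature == "volume" & sc$column == "t55"])
})

test_that("constant features and untestable cells are handled", {
  pats <- sprintf("P%02d", 1:8)
  long <- do.call(rbind, lapply(pats, function(p)
    toy_long(setNames(list(c(t0 = 5, t11 = 5)), p), feature = "flat")))
  outcomes <- data.frame(patient_id = pats, outcome = rep(c(1, 0), 4))
  sc <- screen_features(long, outcomes = outcomes)
  expect_equal(sc$p_value[sc$column == "t0"], 1)
  expect_false(any(sc$significant[sc$tested]))
  # untested: all deltas NA for one class
  long2 <- long
  long2$value[long2$timepoint == "t0" & long2$patient_id %in%
                pats[c(1, 3, 5, 7)]] <- 0  # responders' baselines zero
  sc2 <- screen_features(long2, outcomes = outcomes)
  t11 <- sc2[sc2$column == "t11", ]
  expect_false(t11$tested)
  expect_true(is.na(t11$p_value))
})

test_that("screening rejects degenerate cohorts and missing labels", {
  pats <- c("A", "B", "C", "D")
  long <- do.call(rbind, lapply(pats, function(p)
    toy_long(setNames(list(c(t0 = rnorm(1), t11 = rnorm(1))), p))))
  expect_error(
    screen_features(long, outcomes = data.frame(patient_id = pats,
                                                outcome = c(1, 1, 1, 1))),
    "both outcome classes")
  expect_error(
    screen_features(long, outcomes = data.frame(patient_id = pats[1:2],
                                                outcome = c(1, 0))),
    "missing outcome label")
  expect_error(
    screen_features(long, outcomes = data.frame(patient_id = pats,
                                                outcome = c(1, 0, 0, 0))),
    "2 patients per outcome class")
})

test_that("monotone feature transforms leave screening p-values unchanged", {
  set.seed(61)
  pats <- sprintf("P%02d", 1:10)
  vals <- rnorm(10, 1, 0.2)
  mk <- function(v) do.call(rbind, lapply(seq_along(pats), function(i)
    toy_long(setNames(list(c(t0 = 1, t22 = v[i])), pats[i]))))
  outcomes <- data.frame(patient_id = pats, outcome = rep(c(1, 0), 5))
  p1 <- screen_features(mk(vals), outcomes = outcomes)
  p2 <- screen_features(mk(vals^3 + vals), outcomes = outcomes)
  cell <- function(sc) sc$p_value[sc$column == "t22"]
  expect_equal(cell(p1), cell(p2), tolerance = 1e-12)
})

test_that("Benjamini-Hochberg adjustment is available but off by default", {
  pats <- sprintf("P%02d", 1:10)
  set.seed(8)
  long <- do.call(rbind, lapply(pats, function(p)
    toy_long(setNames(list(c(t0 = rnorm(1, 10), t11 = rnorm(1, 10))), p))))
  outcomes <- data.frame(patient_id = pats, outcome = rep(c(1, 0), 5))
  raw <- screen_features(long, outcomes = outcomes)
  adj <- screen_features(long, outcomes = outcomes, p_adjust = "BH")
  expect_true(all(adj$p_value[adj$tested] >= raw$p_value[raw$tested] - 1e-12))
})
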