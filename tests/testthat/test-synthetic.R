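test_that("lesion generation is deterministic per seed", {
  a <- generate_lesion(c(12, 10, 9), seed = 123)
  b <- generate_lesion(c(12, 10, 9), seed = 123)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$mask$values, b$mask$values)
  c <- generate_lesion(c(12, 10, 9), seed = 124)
  expect_false(identical(a$image$values, c$image$values))
})

test_that("a noiseless sphere phantom passes through the full stack", {
  obs <- generate_lesion(c(15, 15, 15), noise_sigma = 0, texture_sd = 0,
                         seed = 1)
  v <- extract_all(obs)
  expect_lt(abs(v[["sphericity"]] - 1), 0.03)
  expect_lt(abs(v[["volume"]] / (4 / 3 * pi * 15^3) - 1), 0.03)
  expect_equal(v[["sd"]], 0)  # constant interior
})

test_that("degenerate lesion requests are rejected", {
  expect_error(generate_lesion(c(1, 10, 10)), "degenerate lesion")
  expect_error(generate_lesion(c(-5, 10, 10)), "positive")
})

test_that("the default cohort has the study's shape", {
  coh <- generate_cohort(cohort_config(seed = 7))
  expect_length(coh$observations, 96)   # 16 patients x 6 scans
  expect_equal(nrow(coh$outcomes), 16)
  expect_equal(sum(coh$outcomes$outcome), 5)  # round(16 * 0.31)
  tps <- table(vapply(coh$observations, `[[`, "", "timepoint"))
  expect_true(all(tps == 16))
  expect_equal(sort(unique(names(tps))), sort(TIMEPOINTS))
  # per-patient grids are shared across timepoints
  p1 <- Filter(function(o) o$patient_id == "P01", coh$observations)
  dims <- unique(lapply(p1, function(o) dim(o$image$values)))
  expect_length(dims, 1)
  # truth record carries the seed and trajectories
  expect_true(all(coh$truth$seed == 7))
  expect_true(all(coh$truth$volume_ratio > 0))
})

test_that("fractional cohorts round the responder count", {
  coh <- generate_cohort(cohort_config(n_patients = 4, ccr_fraction = 0.5,
                                       seed = 3))
  expect_equal(sum(coh$outcomes$outcome), 2)
  expect_error(generate_cohort(cohort_config(n_patients = 4,
                                             ccr_fraction = 0.05)),
               "strictly between")
  expect_error(generate_cohort(cohort_config(n_patients = 4,
                                             ccr_fraction = 1)),
               "strictly between|\\[0, 1\\]")
})

test_that("noise-free responder volumes shrink monotonically with dose", {
  cfg <- cohort_config(n_patients = 6, ccr_fraction = 0.5, noise_sigma = 0,
                       traj_sd = 0, texture_sd = 0, seed = 5)
  coh <- generate_cohort(cfg)
  resp <- coh$outcomes$patient_id[coh$outcomes$outcome == 1]
  for (pid in resp) {
    obs <- Filter(function(o) o$patient_id == pid, coh$observations)
    ord <- order(vapply(obs, `[[`, 0, "dose_gy"))
    vols <- vapply(obs[ord], function(o) sum(o$mask$values), 0)
    expect_true(all(diff(vols) < 0))
  }
})

test_that("longer texture correlation lengthens runs on average", {
  # simulation-oracle property: over replicates, mean extracted lre is
  # larger when the intensity field is coherent over twice the length
  lre_at <- function(cl, seeds) {
    vapply(seeds, function(s) {
      o <- generate_lesion(c(10, 10, 10), corr_length = cl, seed = s,
                           noise_sigma = 2)
      f <- rlm_features(lapply(seq_len(13), function(d)
        build_glrlm(quantize(o$image, o$mask, 16),
                    glrlm_directions()[d, ], 16)))
      f[["lre"]]
    }, 0)
  }
  seeds <- 1:20
  expect_gt(mean(lre_at(9, seeds)), mean(lre_at(4.5, seeds)))
})

test_that("written cohorts are re-readable through the manifest", {
  dir <- file.path(tempdir(), "minicohort")
  coh <- generate_cohort(cohort_config(n_patients = 4, ccr_fraction = 0.5,
                                       n_timepoints = 2, seed = 9,
                                       semi_axes_range = c(8, 10)))
  manifest <- write_cohort(coh, dir)
  expect_equal(nrow(manifest), 8)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_volume(manifest$image_path[1])
  expect_equal(back$values, coh$observations[[1]]$image$values,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
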