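#' Configuration of the synthetic longitudinal cohort
#'
#' The generator emulates the study conditions: ~16 patients with ~31%
#' clinical complete responders, six scans each (simulation plus every
#' five fractions), 1.5 mm isotropic voxels, an ellipsoidal lesion whose
#' volume shrinks to `responder_ratio_t55` (default 0.3) of baseline by
#' 55 Gy in responders while staying near-stable
#' (`nonresponder_ratio_t55`, default 0.9) otherwise, an interior texture
#' field whose variance decays in responders (homogenisation), and
#' Rician (magnitude-MR) noise motivated by the low-field acquisition.
#'
#' @param n_patients cohort size (default 16).
#' @param ccr_fraction responder prevalence (default 0.31; responder
#'   count is `round(n_patients * ccr_fraction)`).
#' @param n_timepoints scans per patient (default 6: t0..t55).
#' @param spacing voxel spacing in mm (default 1.5 isotropic).
#' @param semi_axes_range bounds (mm) for the uniform draw of each
#'   baseline lesion semi-axis (default 10-18 mm).
#' @param responder_ratio_t55,nonresponder_ratio_t55 lesion volume ratio
#'   at 55 Gy relative to baseline; intermediate doses follow the
#'   geometric trajectory `ratio^(dose/55)`.
#' @param traj_sd log-normal sd of per-(patient, timepoint) jitter on the
#'   volume ratio (default 0.05; inter-patient response variability).
#' @param homogenization_factor per-timepoint multiplier on the
#'   responder texture-field sd (default 0.85; 1 = no homogenisation).
#' @param base_intensity,texture_sd lesion mean intensity and the sd of
#'   the spatially correlated interior field (arbitrary MR units).
#' @param corr_length correlation length of the texture field in mm.
#' @param noise_sigma Rician noise sigma (same units as intensity).
#' @param background mean background intensity outside the lesion.
#' @param seed integer RNG seed, recorded in every output.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 16L, ccr_fraction = 0.31,
                          n_timepoints = 6L, spacing = c(1.5, 1.5, 1.5),
                          semi_axes_range = c(10, 18),
                          responder_ratio_t55 = 0.3,
                          nonresponder_ratio_t55 = 0.9,
                          traj_sd = 0.05,
                          homogenization_factor = 0.85,
                          base_intensity = 100, texture_sd = 15,
                          corr_length = 4.5, noise_sigma = 5,
                          background = 20, seed = 1L) {
  if (ccr_fraction < 0 || ccr_fraction > 1) stop("`ccr_fraction` must be in [0, 1]")
  if (responder_ratio_t55 <= 0 || nonresponder_ratio_t55 <= 0) {
    stop("volume-ratio trajectories must be positive")
  }
  if (n_timepoints < 2L || n_timepoints > length(TIMEPOINTS)) {
    stop(sprintf("`n_timepoints` must be between 2 and %d", length(TIMEPOINTS)))
  }
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate one synthetic lesion observation
#'
#' An ellipsoidal mask (semi-axes in mm, axis-aligned) on an isotropic
#' grid, with interior intensity = base level + spatially correlated
#' Gaussian field (white noise smoothed to `corr_length`, rescaled to
#' `texture_sd`) and Rician magnitude noise; the background sits at a
#' lower mean with the same noise. Deterministic for a given seed.
#'
#' @param semi_axes numeric length-3, mm (each at least one voxel).
#' @param spacing voxel spacing mm.
#' @param grid_dim optional grid size; computed from the semi-axes when
#'   NULL (lesion plus a margin).
#' @param base_intensity,texture_sd,corr_length,noise_sigma,background
#'   see [cohort_config].
#' @param seed optional integer; when supplied the RNG is seeded.
#' @param patient_id,timepoint provenance labels for the observation.
#' @return a [lesion_observation].
#' @export
generate_lesion <- function(semi_axes, spacing = c(1.5, 1.5, 1.5),
                            grid_dim = NULL,
                            base_intensity = 100, texture_sd = 15,
                            corr_length = 4.5, noise_sigma = 5,
                            background = 20, seed = NULL,
                            patient_id = "synthetic", timepoint = "t0") {
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("`semi_axes` must be three positive lengths (mm)")
  }
  if (any(semi_axes < spacing)) {
    stop("degenerate lesion: semi-axis smaller than one voxel")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid_dim)) {
    grid_dim <- 2L * ceiling(semi_axes / spacing) + 8L
  }
  ax <- lapply(1:3, function(d)
    (seq_len(grid_dim[d]) - (grid_dim[d] + 1) / 2) * spacing[d])
  u2 <- lapply(1:3, function(d) (ax[[d]] / semi_axes[d])^2)
  dist2 <- outer(outer(u2[[1]], u2[[2]], `+`), u2[[3]], `+`)
  occ <- dist2 <= 1
  if (!any(occ)) stop("degenerate lesion: no voxel centre falls inside")
  signal <- array(background, grid_dim)
  if (texture_sd > 0) {
    field <- gaussian_smooth_3d(array(rnorm(prod(grid_dim)), grid_dim),
                                corr_length / mean(spacing))
    field <- field / sd(field) * texture_sd
  } else {
    field <- array(0, grid_dim)
  }
  signal[occ] <- base_intensity + field[occ]
  if (noise_sigma > 0) {  # Rician magnitude noise
    e1 <- array(rnorm(prod(grid_dim), sd = noise_sigma), grid_dim)
    e2 <- array(rnorm(prod(grid_dim), sd = noise_sigma), grid_dim)
    signal <- sqrt((signal + e1)^2 + e2^2)
  }
  origin <- -(grid_dim - 1) / 2 * spacing
  lesion_observation(patient_id, timepoint,
                     voxel_grid(signal, spacing, origin),
                     voxel_grid(occ, spacing, origin))
}

#' Generate a full longitudinal phantom cohort
#'
#' Draws baseline semi-axes per patient, assigns
#' `round(n_patients * ccr_fraction)` responders at random, and produces
#' one observation per (patient, timepoint): responders follow the
#' shrinking/homogenising trajectory, non-responders the near-stable one.
#' All timepoints of a patient share one grid (sized for the baseline
#' lesion), so no registration is needed.
#'
#' @param config a [cohort_config].
#' @return list with `observations` (list of [lesion_observation]),
#'   `outcomes` (data.frame `patient_id`, `outcome`), and `truth`
#'   (per-observation record of semi-axes and target volume ratios).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  n_ccr <- round(n * config$ccr_fraction)
  if (n_ccr == 0L || n_ccr == n) {
    stop("responder count must be strictly between 0 and n_patients")
  }
  set.seed(config$seed)
  ids <- sprintf("P%02d", seq_len(n))
  responder <- setNames(rep(0, n), ids)
  responder[sample(ids, n_ccr)] <- 1
  tps <- TIMEPOINTS[seq_len(config$n_timepoints)]
  doses <- TIMEPOINT_DOSES[tps]
  obs <- vector("list", n * length(tps))
  truth <- vector("list", n * length(tps))
  k <- 0L
  for (pid in ids) {
    base_axes <- sort(runif(3, config$semi_axes_range[1],
                            config$semi_axes_range[2]), decreasing = TRUE)
    grid_dim <- 2L * ceiling(base_axes / config$spacing) + 8L
    r55 <- if (responder[pid] == 1) config$responder_ratio_t55
           else config$nonresponder_ratio_t55
    h <- if (responder[pid] == 1) config$homogenization_factor else 1
    for (ti in seq_along(tps)) {
      d <- doses[ti]
      ratio <- r55^(d / max(TIMEPOINT_DOSES))
      if (config$traj_sd > 0 && d > 0) {
        ratio <- ratio * exp(rnorm(1, sd = config$traj_sd))
      }
      k <- k + 1L
      obs[[k]] <- generate_lesion(
        semi_axes = base_axes * ratio^(1 / 3),
        spacing = config$spacing, grid_dim = grid_dim,
        base_intensity = config$base_intensity,
        texture_sd = config$texture_sd * h^(ti - 1),
        corr_length = config$corr_length,
        noise_sigma = config$noise_sigma,
        background = config$background,
        patient_id = pid, timepoint = tps[ti])
      truth[[k]] <- data.frame(
        patient_id = pid, timepoint = tps[ti], dose_gy = unname(d),
        responder = unname(responder[pid]),
        a1 = base_axes[1], a2 = base_axes[2], a3 = base_axes[3],
        volume_ratio = ratio,
        texture_sd = config$texture_sd * h^(ti - 1),
        seed = config$seed, stringsAsFactors = FALSE)
    }
  }
  list(observations = obs,
       outcomes = data.frame(patient_id = ids,
                             outcome = unname(responder),
                             stringsAsFactors = FALSE),
       truth = do.call(rbind, truth))
}

#' Write a cohort to disk in the standard layout
#'
#' One NIfTI (or NRRD) image/mask pair per observation plus
#' `manifest.csv` (patient_id, timepoint, image_path, mask_path, outcome)
#' consumable by [run_extract] unchanged.
#'
#' @param cohort result of [generate_cohort].
#' @param dir output directory (created if needed).
#' @param format `"nifti"` or `"nrrd"`.
#' @return invisibly the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir, format = c("nifti", "nrrd")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".nrrd"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- setNames(cohort$outcomes$outcome, cohort$outcomes$patient_id)
  rows <- lapply(cohort$observations, function(o) {
    stem <- sprintf("%s_%s", o$patient_id, o$timepoint)
    img <- file.path(dir, paste0(stem, "_image", ext))
    msk <- file.path(dir, paste0(stem, "_mask", ext))
    write_volume(o$image, img, format)
    write_volume(o$mask, msk, format)
    data.frame(patient_id = o$patient_id, timepoint = o$timepoint,
               image_path = img, mask_path = msk,
               outcome = unname(lab[o$patient_id]),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
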