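#' The 13 unique 3D run directions
#'
#' One representative per axis-neighbour direction pair (26-connectivity
#' modulo sign), as an integer matrix with columns dx, dy, dz.
#' @return 13 x 3 integer matrix.
#' @export
glrlm_directions <- function() {
  m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
             c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  colnames(m) <- c("dx", "dy", "dz")
  storage.mode(m) <- "integer"
  m
}

#' Equal-width grey-level quantization of the ROI
#'
#' Bins the ROI intensity range `[min, max]` into `n_levels` equal-width
#' levels; the ROI maximum maps to level `n_levels`, and a constant ROI
#' maps wholly to level 1. Voxels outside the ROI are coded 0.
#'
#' @param image [voxel_grid] of intensities.
#' @param mask logical [voxel_grid], same geometry.
#' @param n_levels number of grey levels (>= 2; default 32).
#' @return integer 3D array: levels `1..n_levels` inside the ROI, 0 outside.
#' @export
quantize <- function(image, mask, n_levels = 32L) {
  if (n_levels < 2L) stop("`n_levels` must be at least 2")
  validate_geometry(image, mask)
  occ <- mask$values
  if (!any(occ)) stop("empty ROI: mask contains no occupied voxel")
  x <- image$values[occ]
  lo <- min(x); hi <- max(x)
  q <- array(0L, dim(occ))
  if (hi == lo) {
    q[occ] <- 1L
  } else {
    lev <- floor((x - lo) / (hi - lo) * n_levels) + 1L
    q[occ] <- as.integer(pmin(lev, n_levels))
  }
  q
}

#' Grey-level run-length matrix for one direction
#'
#' Counts maximal runs of equal quantized level along `direction`,
#' restricted to ROI voxels (a run breaks at any non-ROI voxel). The
#' result satisfies the voxel-conservation identity
#' `sum_ij r(i,j) * j = Np` (ROI voxel count).
#'
#' @param quantized integer 3D array as returned by [quantize].
#' @param direction integer length-3 offset, e.g. `c(1, 0, 0)`.
#' @param n_levels number of grey levels (rows of the matrix).
#' @return integer matrix `r[i, j]` (level x run length), trailing all-zero
#'   run-length columns trimmed; attributes `Np` (ROI voxels) and `Nr`
#'   (total runs).
#' @export
build_glrlm <- function(quantized, direction, n_levels = max(quantized)) {
  direction <- as.integer(direction)
  if (length(direction) != 3L || all(direction == 0L)) {
    stop("`direction` must be a non-zero integer offset triplet")
  }
  counts <- cpp_glrlm(quantized, as.integer(n_levels),
                      direction[1], direction[2], direction[3])
  jmax <- max(which(colSums(counts) > 0L), 1L)
  counts <- counts[, seq_len(jmax), drop = FALSE]
  structure(counts,
            Np = sum(quantized > 0L),
            Nr = sum(counts))
}

RLM_FEATURE_NAMES <- c("sre", "lre", "glnu", "glnu_norm", "rlnu", "rlnu_norm",
                       "rperc", "lgre", "hgre", "srlge", "srhge", "lrlge",
                       "lrhge", "glvar", "rlvar", "run_entropy")

rlm_features_one <- function(m) {
  nr <- attr(m, "Nr")
  np <- attr(m, "Np")
  if (is.null(nr)) nr <- sum(m)
  if (nr < 1) stop("degenerate ROI: run-length matrix holds no run")
  i <- row(m)
  j <- col(m)
  p <- m / nr
  pg <- rowSums(m)  # runs per grey level
  pr <- colSums(m)  # runs per run length
  mu_i <- sum(p * i)
  mu_j <- sum(p * j)
  pnz <- p[p > 0]
  c(sre = sum(m / j^2) / nr,
    lre = sum(m * j^2) / nr,
    glnu = sum(pg^2) / nr,
    glnu_norm = sum(pg^2) / nr^2,
    rlnu = sum(pr^2) / nr,
    rlnu_norm = sum(pr^2) / nr^2,
    rperc = nr / np,
    lgre = sum(m / i^2) / nr,
    hgre = sum(m * i^2) / nr,
    srlge = sum(m / (i^2 * j^2)) / nr,
    srhge = sum(m * i^2 / j^2) / nr,
    lrlge = sum(m * j^2 / i^2) / nr,
    lrhge = sum(m * i^2 * j^2) / nr,
    glvar = sum(p * (i - mu_i)^2),
    rlvar = sum(p * (j - mu_j)^2),
    run_entropy = -sum(pnz * log2(pnz)))
}

#' Run-length texture features aggregated over directions
#'
#' Computes the 16 textural panel members for each supplied run-length
#' matrix and returns their unweighted mean across directions (the
#' classical Galloway treatment; matrices are not merged).
#'
#' @param matrices a single matrix from [build_glrlm] or a list of them
#'   (one per direction).
#' @return named numeric vector of the 16 textural features.
#' @export
rlm_features <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (length(matrices) == 0L) stop("degenerate ROI: no run-length matrix supplied")
  per_dir <- vapply(matrices, rlm_features_one,
                    numeric(length(RLM_FEATURE_NAMES)))
  rowMeans(per_dir)
}

#' All run-length texture features of an observation
#' @noRd
texture_features <- function(image, mask, n_levels = 32L) {
  q <- quantize(image, mask, n_levels)
  dirs <- glrlm_directions()
  mats <- lapply(seq_len(nrow(dirs)), function(d)
    build_glrlm(q, dirs[d, ], n_levels = n_levels))
  rlm_features(mats)
}
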