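#' Box-counting fractal dimension of a binary slice
#'
#' Counts boxes of side `s` pixels (dyadic: 1, 2, 4, ... up to half the
#' larger slice dimension, grids anchored at the slice origin) that
#' intersect the occupied set, and returns the least-squares slope of
#' `log N(s)` against `log(1/s)`. A filled plane approaches 2, a straight
#' line 1, an isolated point 0.
#'
#' @param slice logical matrix with at least one occupied pixel.
#' @return the fitted dimension (a real, typically in `[0, 2]`).
#' @export
boxcount_fd <- function(slice) {
  if (!is.matrix(slice)) stop("`slice` must be a 2D matrix")
  occ <- which(slice, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("empty slice: no occupied pixel")
  smax <- max(dim(slice)) / 2
  sizes <- 1L
  while (2L * sizes[length(sizes)] <= smax) {
    sizes <- c(sizes, 2L * sizes[length(sizes)])
  }
  if (length(sizes) < 3L) {
    stop(sprintf("insufficient scales: only %d dyadic box size(s) fit a %dx%d slice (need >= 3)",
                 length(sizes), nrow(slice), ncol(slice)))
  }
  counts <- vapply(sizes, function(s) {
    bi <- (occ[, 1] - 1L) %/% s
    bj <- (occ[, 2] - 1L) %/% s
    length(unique(bi * (ncol(slice) %/% s + 2L) + bj))
  }, integer(1))
  lx <- log(1 / sizes)
  ly <- log(counts)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Per-slice fractal-dimension profile and its summaries
#'
#' Computes [boxcount_fd] on every axial (z) slice of the mask that
#' contains at least one ROI voxel, then summarises the per-slice values.
#' Slices failing the three-scale requirement are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param mask logical [voxel_grid] with at least one occupied voxel.
#' @return named numeric vector `meanFD`, `medianFD`, `sdFD`, `minFD`,
#'   `maxFD`, `rangeFD`; attributes `per_slice` (the raw profile) and
#'   `n_skipped`.
#' @export
fd_summaries <- function(mask) {
  occ <- mask$values
  if (!any(occ)) stop("empty ROI: mask contains no occupied voxel")
  ks <- which(apply(occ, 3, any))
  fds <- numeric(0)
  skipped <- 0L
  for (k in ks) {
    fd <- tryCatch(boxcount_fd(occ[, , k]), error = function(e) NA_real_)
    if (is.na(fd)) skipped <- skipped + 1L else fds <- c(fds, fd)
  }
  if (length(fds) == 0L) {
    stop("insufficient scales: every ROI slice is too small for a 3-scale box-count fit")
  }
  out <- c(meanFD = mean(fds),
           medianFD = median(fds),
           sdFD = if (length(fds) > 1L) sd(fds) else 0,
           minFD = min(fds),
           maxFD = max(fds),
           rangeFD = max(fds) - min(fds))
  attr(out, "per_slice") <- fds
  attr(out, "n_skipped") <- skipped
  out
}
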