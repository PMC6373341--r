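# Independent oracles and small phantom builders used across the suite.
# These deliberately avoid the package's own computational paths.

# Digital ball mask on an isotropic grid (analytic shape phantom).
ball_mask <- function(radius_mm, spacing = 1.5, margin = 4L) {
  n <- 2L * ceiling(radius_mm / spacing) + 2L * margin
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  d2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  binary_mask(array(d2 <= radius_mm^2, c(n, n, n)),
              spacing = rep(spacing, 3))
}

# Axis-aligned digital ellipsoid mask.
ellipsoid_mask <- function(semi_axes, spacing = 1.5, margin = 4L) {
  n <- 2L * ceiling(semi_axes / spacing) + 2L * margin
  ax <- lapply(1:3, function(d)
    ((seq_len(n[d]) - (n[d] + 1) / 2) * spacing / semi_axes[d])^2)
  d2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  binary_mask(array(d2 <= 1, n), spacing = rep(spacing, 3))
}

# Constant-intensity image covering a mask's grid.
flat_image <- function(mask, value = 100) {
  voxel_grid(array(value, dim(mask$values)), mask$spacing, mask$origin)
}

# Brute-force grey-level run enumerator: scans every line of the grid in
# the given direction voxel by voxel, independent of the C++ path.
brute_glrlm <- function(q, dir, n_levels) {
  d <- dim(q)
  counts <- matrix(0L, n_levels, sum(d))
  inb <- function(p) all(p >= 1L) && all(p <= d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    p <- c(x, y, z)
    if (inb(p - dir)) next  # not a line start
    lev <- integer(0)
    while (inb(p)) {
      lev <- c(lev, q[p[1], p[2], p[3]])
      p <- p + dir
    }
    r <- rle(lev)
    keep <- r$values > 0L
    for (ii in which(keep)) {
      counts[r$values[ii], r$lengths[ii]] <- counts[r$values[ii], r$lengths[ii]] + 1L
    }
  }
  jmax <- max(which(colSums(counts) > 0L), 1L)
  counts[, seq_len(jmax), drop = FALSE]
}

# Brute-force exact two-sided WMW p-value by explicit subset enumeration
# (mean-symmetric tail rule on midranks).
brute_wmw <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  e <- n1 * (length(x) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - e)
  subs <- utils::combn(length(x), n1)
  ws <- apply(subs, 2, function(ix) sum(r[ix]))
  mean(abs(ws - e) >= obs - 1e-9)
}

# Tiny longitudinal table built by hand for screening contract tests.
toy_long <- function(values_by_patient, feature = "f1") {
  rows <- do.call(rbind, lapply(names(values_by_patient), function(pid) {
    v <- values_by_patient[[pid]]
    data.frame(patient_id = pid, timepoint = names(v), feature = feature,
               value = as.numeric(v), stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}
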