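# Truncated, unit-sum 1D Gaussian kernel in voxel units (SD in voxels),
# cut at 4 SD.
gaussian_axis_kernel <- function(sd_vox) {
  r <- ceiling(4 * sd_vox)
  x <- (-r):r
  k <- exp(-0.5 * (x / sd_vox)^2)
  k / sum(k)
}

# Banded convolution matrix applying a symmetric 1D kernel along an axis of
# length n with zero padding; renormalization is handled by the caller.
axis_convolution_matrix <- function(kernel, n) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in (-r):r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[o + r + 1L]
  }
  K
}

# Axis kernel matrices and in-grid normalizer for a fixed grid; shared by
# the R smoother and the compiled permutation engine. The normalizer is
# the all-ones image pushed through the axis kernels, so dividing by it
# renormalizes the kernel over in-grid support.
smoother_parts <- function(grid_shape, sd_mm, voxel_size_mm) {
  if (sd_mm < 0) stop_bad("`sd_mm` must be non-negative")
  if (any(voxel_size_mm <= 0)) stop_bad("voxel sizes must be positive")
  if (sd_mm == 0)
    return(list(K = lapply(grid_shape, diag), W = array(1, grid_shape)))
  Ks <- lapply(1:3, function(a)
    axis_convolution_matrix(gaussian_axis_kernel(sd_mm / voxel_size_mm[a]),
                            grid_shape[a]))
  W <- apply_axis_kernels(array(1, grid_shape), Ks, grid_shape)
  list(K = Ks, W = W)
}

apply_axis_kernels <- function(m, Ks, d) {
  m <- Ks[[1L]] %*% matrix(m, d[1L])                       # x axis
  m <- array(m, d)
  m <- aperm(array(Ks[[2L]] %*% matrix(aperm(m, c(2L, 1L, 3L)), d[2L]),
                   d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))       # y axis
  aperm(array(Ks[[3L]] %*% matrix(aperm(m, c(3L, 1L, 2L)), d[3L]),
              d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))            # z axis
}

# Precompiled separable 3D Gaussian smoother for a fixed grid. Zero-pads at
# the boundary and renormalizes over in-grid support (dividing by the
# smoothed all-ones image) so constant images pass through unchanged and
# edges are not attenuated. Returns a function(map) -> map.
make_smoother <- function(grid_shape, sd_mm, voxel_size_mm) {
  if (sd_mm == 0) return(identity)
  parts <- smoother_parts(grid_shape, sd_mm, voxel_size_mm)
  function(map) apply_axis_kernels(map, parts$K, grid_shape) / parts$W
}

#' Smooth a 3D map with an isotropic Gaussian kernel
#'
#' Separable Gaussian convolution with per-axis SD `sd_mm /
#' voxel_size_mm[axis]` voxels (so the kernel is isotropic in millimetres
#' on anisotropic grids), truncated at 4 SD. The grid boundary is
#' zero-padded and the kernel renormalized over in-grid support, which
#' preserves constants and avoids spurious edge attenuation. `sd_mm = 0`
#' returns the input unchanged.
#'
#' @param map 3D numeric array.
#' @param sd_mm Kernel standard deviation in millimetres (default 3).
#' @param voxel_size_mm Numeric 3-vector of voxel edge lengths, mm.
#' @return Smoothed 3D array of the same shape.
#' @export
smooth_map <- function(map, sd_mm = 3, voxel_size_mm = c(2.5, 2.5, 3.5)) {
  d <- dim(map)
  stopifnot(length(d) == 3L)
  make_smoother(d, sd_mm, voxel_size_mm)(map)
}

# Per-row medians of a V x n matrix (one column per subject) via an
# odd-even transposition sorting network over the columns: O(n^2)
# vectorized compare-exchanges on contiguous columns, exact for any n and
# fast for the small per-voxel sample sizes used here.
row_medians <- function(M) {
  n <- ncol(M)
  if (n == 1L) return(M[, 1L])
  for (pass in seq_len(n)) {
    i <- seq.int(if (pass %% 2L == 1L) 1L else 2L, n - 1L, by = 2L)
    if (length(i) == 0L) next
    a <- M[, i, drop = FALSE]
    b <- M[, i + 1L, drop = FALSE]
    M[, i] <- pmin(a, b)
    M[, i + 1L] <- pmax(a, b)
  }
  k <- (n + 1L) %/% 2L
  if (n %% 2L == 1L) M[, k] else (M[, k] + M[, k + 1L]) / 2
}

#' Voxelwise median image across subjects
#'
#' The group-level BOLD response map: the sample median at every voxel
#' across the (smoothed, spatially aligned) subject maps. The median is
#' used in place of the mean to resist outlying subjects; with an even
#' number of subjects the midpoint of the two central order statistics is
#' taken.
#'
#' @param maps List of 3D arrays (or `subject_bold_map` objects) sharing
#'   one shape.
#' @param smoothing_sd_mm Optional metadata: the smoothing SD already
#'   applied to the inputs.
#' @return Object of class `group_bold_map`: `median_map` (3D array),
#'   `n_subjects`, `smoothing_sd_mm`.
#' @export
median_map <- function(maps, smoothing_sd_mm = NA_real_) {
  if (length(maps) == 0L) stop_bad("`maps` must be a non-empty list")
  maps <- lapply(maps, function(m) if (inherits(m, "subject_bold_map"))
    m$tmap else m)
  d <- dim(maps[[1L]])
  stopifnot(length(d) == 3L)
  for (m in maps) if (!identical(dim(m), d))
    stop_bad("all maps must share the same shape")
  M <- vapply(maps, as.vector, numeric(prod(d)))
  structure(list(median_map = array(row_medians(M), d),
                 n_subjects = length(maps),
                 smoothing_sd_mm = smoothing_sd_mm),
            class = "group_bold_map")
}
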