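#' Randomly permute the rows of a performance matrix
#'
#' Row shuffling preserves the column sums (the subject's realized
#' performance level) while destroying the correspondence between trial
#' outcomes and acquisition times -- the exchangeability device behind the
#' permutation null.
#'
#' @param Z Performance matrix.
#' @param perm Optional explicit permutation of `seq_len(nrow(Z))`; by
#'   default a uniform random permutation is drawn from the current RNG
#'   stream.
#' @return Row-permuted performance matrix.
#' @export
permute_performance <- function(Z, perm = NULL) {
  Z <- as_performance_matrix(Z)
  n <- nrow(Z)
  if (is.null(perm)) perm <- sample.int(n)
  if (!identical(sort(perm), seq_len(n)))
    stop_bad("`perm` must be a permutation of 1..n")
  out <- Z[perm, , drop = FALSE]
  class(out) <- class(Z)
  out
}

# Per-subject precomputation for the permutation engine: everything that
# does not depend on the permuted Z. Mirrors subject_map() exactly (same
# mask, nuisance component, centering and pseudo-inverse conventions) so a
# forced identity permutation reproduces the true subject map. Because the
# response is centered, the event-regressor block of X'y reduces to
# Zp' (H'Yc), and Zp being one-hot makes that a rowsum of the precomputed
# H'Yc over permuted outcome labels -- no per-permutation matrix product
# touches the voxel dimension.
precompute_subject_fit <- function(dataset, hrf, mask_fraction) {
  d <- dim(dataset$bold)
  n <- d[4L]
  V <- prod(d[1:3])
  mean_vol <- array(rowMeans(matrix(dataset$bold, V, n)), d[1:3])
  mask <- compute_brain_mask(mean_vol, mask_fraction)
  pc1 <- first_pc_timecourse(dataset$bold, mask)
  N <- cbind(pc1, dataset$motion)
  Nc <- N - rep(colMeans(N), each = n)
  Yc <- t(matrix(dataset$bold, V, n))
  Yc <- Yc - rep(colMeans(Yc), each = n)
  H <- hrf_toeplitz(hrf$samples, n)
  HtY <- crossprod(H, Yc)
  outcome <- max.col(dataset$Z, "first")
  counts <- tabulate(outcome, 4L)
  list(n = n, V = V, grid = d[1:3], mask = as.vector(mask),
       Z = unclass(dataset$Z), outcome = outcome,
       major = which.max(counts),
       Nc = Nc, NtY = crossprod(Nc, Yc), HtYT = t(HtY),
       HtY_total = colSums(HtY), yty = colSums(Yc^2), H = H)
}

# Contrast t-map for one subject under a given row permutation of Z,
# using the precomputed pieces. Returns a length-V vector (0 outside the
# subject mask). The event block of X'y is assembled by summing columns of
# t(H'Yc) over the permuted outcome groups; the most frequent outcome
# (correct Go in practice) is obtained by subtraction from the fixed
# column total, so only the minority outcomes are ever summed explicitly.
permuted_tmap <- function(pre, perm, C) {
  n <- pre$n
  V <- pre$V
  E <- pre$H %*% pre$Z[perm, , drop = FALSE]
  Ec <- E - rep(colMeans(E), each = n)
  G <- pinv(crossprod(cbind(pre$Nc, Ec)))
  df <- n - 1L - attr(G, "rank")
  oc <- pre$outcome[perm]
  EtY <- matrix(0, 4L, V)
  rest <- pre$HtY_total
  for (j in seq_len(4L)) {
    if (j == pre$major) next
    idx <- which(oc == j)
    if (length(idx) == 0L) next
    row_j <- if (length(idx) == 1L) pre$HtYT[, idx] else
      .rowSums(pre$HtYT[, idx, drop = FALSE], V, length(idx))
    EtY[j, ] <- row_j
    rest <- rest - row_j
  }
  EtY[pre$major, ] <- rest
  XtY <- rbind(pre$NtY, EtY)
  B <- G %*% XtY
  num <- drop(crossprod(C, B))
  rss <- pmax(pre$yty - colSums(XtY * B), 0)
  sigma2 <- rss / df
  ctgc <- drop(crossprod(C, G %*% C))
  t <- numeric(pre$V)
  ok <- sigma2 > 1e-12 * pmax(pre$yty, 1) / df
  if (ctgc > 0) {
    t[ok] <- num[ok] / sqrt(sigma2[ok] * ctgc)
    bad <- !ok & abs(num) > 1e-12 * sqrt(pmax(pre$yty, 1))
    t[bad] <- sign(num[bad]) * Inf
  }
  t[!pre$mask] <- 0
  t
}

#' Permutation null distribution of group-map extrema
#'
#' Repeats the full subject-to-group pipeline `B` times with each
#' subject's performance matrix independently row-permuted: subject GLM
#' contrast maps, isotropic Gaussian smoothing, voxelwise median, and the
#' global maximum and minimum of the resulting group map within the
#' intersection brain mask. Each run draws a fresh independent permutation
#' per subject; the whole procedure is deterministic for a fixed
#' `master_seed`.
#'
#' @param cohort A [generate_cohort()] cohort (or list of subject
#'   datasets).
#' @param B Number of permutation runs (default 1000).
#' @param master_seed Integer seed driving every permutation draw.
#' @param hrf HRF kernel; default [gamma_hrf()] at the cohort's TR.
#' @param smoothing_sd_mm Gaussian smoothing SD in mm (default 3).
#' @param mask_fraction Brain-mask threshold fraction.
#' @param contrast Contrast vector (default NoGo-minus-Go).
#' @param .identity If TRUE, force the identity permutation in every run
#'   (diagnostic: run 1 then reproduces the true group map's extrema).
#' @return Object of class `null_distribution`: `maxima`, `minima`
#'   (length-B vectors), `B`, `master_seed`, `true_max`/`true_min` (the
#'   unpermuted group map's extrema, computed from the same inputs), and
#'   `group_mask` (3D logical intersection mask).
#' @export
null_distribution <- function(cohort, B = 1000L, master_seed = 1L,
                              hrf = NULL, smoothing_sd_mm = 3,
                              mask_fraction = 0.5,
                              contrast = nogo_vs_go_contrast(),
                              .identity = FALSE) {
  if (length(cohort) == 0L) stop_bad("`cohort` must be non-empty")
  check_number(B, "B", min = 1)
  B <- as.integer(B)
  spec <- attr(cohort, "spec")
  vox <- if (!is.null(spec)) spec$voxel_size_mm else
    cohort[[1L]]$voxel_size_mm
  if (is.null(hrf))
    hrf <- gamma_hrf(tr_seconds = cohort[[1L]]$tr_seconds)
  pre <- lapply(cohort, precompute_subject_fit, hrf = hrf,
                mask_fraction = mask_fraction)
  grid <- pre[[1L]]$grid
  n <- pre[[1L]]$n
  mask_vec <- Reduce(`&`, lapply(pre, `[[`, "mask"))
  parts <- smoother_parts(grid, smoothing_sd_mm, vox)
  n_sub <- length(pre)
  # All permutations are drawn up front, subject-major, from one stream
  # seeded by master_seed: subject s gets columns s of every run in order.
  perms <- with_seed(master_seed, {
    lapply(seq_len(n_sub), function(s) {
      if (.identity) matrix(rep(seq_len(n), B), n, B) else
        vapply(seq_len(B), function(b) sample.int(n), integer(n))
    })
  })
  mask0 <- which(mask_vec) - 1L
  maps <- lapply(seq_len(n_sub), function(s) {
    p <- pre[[s]]
    cpp_subject_perm_maps(p$Nc, p$NtY, p$HtYT, p$HtY_total, p$yty, p$H,
                          perms[[s]], p$outcome, p$major, contrast,
                          which(p$mask) - 1L, parts$K[[1L]], parts$K[[2L]],
                          parts$K[[3L]], as.vector(parts$W), grid[1L],
                          grid[2L], grid[3L], 1e-10)
  })
  ext <- cpp_median_extrema(maps, mask0)
  # the true (unpermuted) group map's extrema, from the same precompute
  id <- matrix(seq_len(n), n, 1L)
  true_maps <- lapply(seq_len(n_sub), function(s) {
    p <- pre[[s]]
    cpp_subject_perm_maps(p$Nc, p$NtY, p$HtYT, p$HtY_total, p$yty, p$H,
                          id, p$outcome, p$major, contrast,
                          which(p$mask) - 1L, parts$K[[1L]], parts$K[[2L]],
                          parts$K[[3L]], as.vector(parts$W), grid[1L],
                          grid[2L], grid[3L], 1e-10)
  })
  text <- cpp_median_extrema(true_maps, mask0)
  structure(list(maxima = ext[, 1L], minima = ext[, 2L], B = B,
                 master_seed = master_seed,
                 true_max = text[1L, 1L], true_min = text[1L, 2L],
                 group_mask = array(mask_vec, grid)),
            class = "null_distribution")
}

#' Empirical FWER thresholds from permutation extrema
#'
#' For each alpha, the upper threshold is the order statistic of the
#' permutation maxima guaranteeing that the empirical probability of any
#' voxel anywhere in a null group map exceeding it is strictly less than
#' alpha (position `B - ceiling(alpha * B) + 1` of the sorted maxima);
#' lower thresholds are the mirror image on the minima. The defaults give
#' the six familywise thresholds at alpha 0.001, 0.01 and 0.05 per tail.
#'
#' @param null A [null_distribution()].
#' @param alphas Per-tail FWER levels (default `c(0.001, 0.01, 0.05)`).
#' @return Object of class `threshold_set`: `upper` and `lower` named
#'   numeric vectors (lower entries are the applied cutoffs, typically
#'   negative), `alphas`, `B`.
#' @export
compute_thresholds <- function(null, alphas = c(0.001, 0.01, 0.05)) {
  stopifnot(inherits(null, "null_distribution"))
  if (length(null$maxima) == 0L) stop_bad("empty null distribution")
  alphas <- sort(unique(alphas))
  if (any(alphas <= 0 | alphas >= 1)) stop_bad("alphas must lie in (0, 1)")
  B <- null$B
  if (B < 1 / min(alphas))
    warning(sprintf(paste0("B = %d permutations cannot resolve alpha = %g ",
                           "(need B >= %d); thresholds at that level are ",
                           "the sample extreme"),
                    B, min(alphas), ceiling(1 / min(alphas))))
  k <- B - ceiling(alphas * B) + 1L
  smax <- sort(null$maxima)
  smin <- sort(null$minima)
  upper <- smax[k]
  lower <- smin[B - k + 1L]
  names(upper) <- names(lower) <- as.character(alphas)
  structure(list(upper = upper, lower = lower, alphas = alphas, B = B),
            class = "threshold_set")
}

#' Threshold a group map into signed significance tiers
#'
#' Labels each voxel with the most stringent FWER tier its value passes:
#' `+m` when the value exceeds the upper threshold of the m-th most
#' lenient alpha (so with the default alphas, +1/+2/+3 mean above the
#' 0.05/0.01/0.001 upper thresholds), `-m` for the mirrored lower
#' thresholds, and 0 otherwise.
#'
#' @param group_map A [median_map()] result or a 3D array.
#' @param thresholds A [compute_thresholds()] result.
#' @return Integer 3D array of class `significance_map` with an `alphas`
#'   attribute.
#' @export
threshold_map <- function(group_map, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  m <- if (inherits(group_map, "group_bold_map")) group_map$median_map else
    group_map
  stopifnot(length(dim(m)) == 3L)
  alphas_desc <- sort(thresholds$alphas, decreasing = TRUE)
  lab <- array(0L, dim(m))
  for (i in seq_along(alphas_desc)) {
    a <- as.character(alphas_desc[i])
    lab[m > thresholds$upper[[a]]] <- i
    lab[m < thresholds$lower[[a]]] <- -i
  }
  structure(lab, class = c("significance_map", "array"),
            alphas = alphas_desc)
}

neighbor_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_bad("`connectivity` must be 6, 18 or 26")
  ds <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d1 <- rowSums(abs(ds))
  keep <- d1 > 0 & d1 <= switch(as.character(connectivity),
                                "6" = 1L, "18" = 2L, "26" = 3L)
  ds[keep, , drop = FALSE]
}

# Connected components of a logical 3D array by depth-first search over a
# preallocated stack of linear indices. Returns an integer array of
# component ids (0 = background).
label_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  noff <- nrow(offs)
  comp <- array(0L, d)
  nextid <- 0L
  idx <- which(mask)
  if (length(idx) == 0L) return(comp)
  coords <- arrayInd(seq_len(prod(d)), d)
  stack <- integer(length(idx))
  for (start in idx) {
    if (comp[start] > 0L) next
    nextid <- nextid + 1L
    comp[start] <- nextid
    stack[1L] <- start
    top <- 1L
    while (top > 0L) {
      v <- stack[top]
      top <- top - 1L
      vc <- coords[v, ]
      for (o in seq_len(noff)) {
        w <- vc + offs[o, ]
        if (w[1L] < 1L || w[1L] > d[1L] || w[2L] < 1L || w[2L] > d[2L] ||
            w[3L] < 1L || w[3L] > d[3L]) next
        li <- w[1L] + d[1L] * ((w[2L] - 1L) + d[2L] * (w[3L] - 1L))
        if (mask[li] && comp[li] == 0L) {
          comp[li] <- nextid
          top <- top + 1L
          stack[top] <- li
        }
      }
    }
  }
  comp
}

#' Extract significant clusters above a minimum volume
#'
#' Connected components are computed separately for positively and
#' negatively labeled voxels (any significance tier) -- clusters of
#' opposite sign never merge -- and only components strictly larger than
#' `min_size_mm3` are kept. Each cluster reports its peak (the voxel of
#' maximum absolute statistic) and is sorted by size, largest first.
#'
#' @param sig_image A [threshold_map()] result (or integer 3D array of
#'   signed tier labels).
#' @param voxel_size_mm Numeric 3-vector, mm.
#' @param connectivity Neighborhood: 6 (faces), 18 (+edges, default) or
#'   26 (+corners).
#' @param min_size_mm3 Strict minimum cluster volume in mm^3 (default
#'   100).
#' @param values Optional 3D array of the underlying statistic for peak
#'   localization; defaults to the tier labels.
#' @return `data.frame` of class `cluster_table` with columns `sign`,
#'   `size_voxels`, `size_mm3`, `peak_x`, `peak_y`, `peak_z`,
#'   `peak_value`, `label` (free text, empty).
#' @export
extract_clusters <- function(sig_image, voxel_size_mm = c(2.5, 2.5, 3.5),
                             connectivity = 18L, min_size_mm3 = 100,
                             values = NULL) {
  stopifnot(length(dim(sig_image)) == 3L)
  if (is.null(values)) values <- sig_image
  stopifnot(identical(dim(values), dim(sig_image)))
  vvol <- prod(voxel_size_mm)
  rows <- list()
  for (sgn in c(1, -1)) {
    comp <- label_components(sign(sig_image) == sgn, connectivity)
    if (max(comp) == 0L) next
    for (id in seq_len(max(comp))) {
      vox <- which(comp == id)
      size_mm3 <- length(vox) * vvol
      if (size_mm3 <= min_size_mm3) next
      peak <- vox[which.max(abs(values[vox]))]
      pc <- arrayInd(peak, dim(sig_image))
      rows[[length(rows) + 1L]] <-
        data.frame(sign = if (sgn > 0) "positive" else "negative",
                   size_voxels = length(vox), size_mm3 = size_mm3,
                   peak_x = pc[1L], peak_y = pc[2L], peak_z = pc[3L],
                   peak_value = values[peak], label = "",
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(), size_voxels = integer(),
               size_mm3 = numeric(), peak_x = integer(), peak_y = integer(),
               peak_z = integer(), peak_value = numeric(),
               label = character(), stringsAsFactors = FALSE)
  out <- out[order(-out$size_mm3), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_table", "data.frame")
  out
}
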