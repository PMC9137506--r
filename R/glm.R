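#' Brain mask from a mean-volume intensity threshold
#'
#' Thresholds the temporal mean volume at a fraction of its robust maximum
#' (the 99th intensity percentile), the usual quick mask for EPI data.
#'
#' @param mean_volume 3D numeric array (temporal mean of the run).
#' @param threshold_fraction Fraction of the robust maximum, in (0, 1\].
#' @return Logical 3D array; errors if the mask would be empty.
#' @export
compute_brain_mask <- function(mean_volume, threshold_fraction = 0.5) {
  if (!all(is.finite(mean_volume))) stop_bad("`mean_volume` must be finite")
  check_number(threshold_fraction, "threshold_fraction",
               min = .Machine$double.eps, max = 1)
  ref <- stats::quantile(mean_volume, 0.99, names = FALSE)
  mask <- mean_volume >= threshold_fraction * ref
  if (!any(mask))
    stop_bad("empty brain mask: no voxel reaches ",
             format(threshold_fraction), " x robust maximum (",
             format(ref), "); lower `threshold_fraction`")
  mask
}

#' First principal-component time course of a 4D run
#'
#' The unit-norm time course capturing the greatest variance across brain
#' voxels, used as the leading nuisance regressor. Each voxel's temporal
#' mean is removed, the leading eigenvector of the n x n temporal
#' covariance is taken, and the sign is fixed so the component correlates
#' positively with the global mean time course (falling back to a positive
#' leading coefficient when that correlation is zero).
#'
#' @param bold 4D array (x, y, z, t).
#' @param mask Logical 3D array selecting brain voxels (>= 2 voxels).
#' @return Unit-norm numeric vector of length `n`.
#' @export
first_pc_timecourse <- function(bold, mask) {
  d <- dim(bold)
  stopifnot(length(d) == 4L, all(dim(mask) == d[1:3]))
  if (sum(mask) < 2L) stop_bad("mask must contain at least 2 voxels")
  n <- d[4L]
  M <- matrix(bold, prod(d[1:3]), n)[as.vector(mask), , drop = FALSE]
  M <- M - rowMeans(M)
  S <- crossprod(M)                    # n x n temporal covariance (scaled)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[1L] <= 1e-12 * max(1, abs(S[1L, 1L])) ||
      e$values[1L] <= 0)
    stop_bad("no temporal variance inside the mask; ",
             "cannot extract a principal component")
  pc <- e$vectors[, 1L]
  gm <- colMeans(M)
  s <- sum(pc * gm)
  if (abs(s) < 1e-12) s <- pc[which.max(abs(pc))]
  if (s < 0) pc <- -pc
  pc
}

#' Assemble the subject-level GLM design matrix
#'
#' Columns in fixed order: the first-PC nuisance time course, the six
#' rigid-body motion series, and the four HRF-convolved event regressors
#' `h * z_j`. With the standard inputs this gives p = 11 columns.
#'
#' @param pc1 Length-n nuisance time course ([first_pc_timecourse()]).
#' @param motion `n x 6` motion parameter matrix.
#' @param Z `n x 4` performance matrix.
#' @param h HRF kernel ([gamma_hrf()]).
#' @return `n x p` matrix of class `design_matrix` with a `roles`
#'   attribute naming each column.
#' @export
build_design_matrix <- function(pc1, motion, Z, h) {
  if (is.null(pc1) || is.null(motion) || is.null(Z) || is.null(h))
    stop_bad("all of pc1, motion, Z, h are required")
  motion <- as.matrix(motion)
  Z <- as.matrix(Z)
  n <- length(pc1)
  if (nrow(motion) != n || nrow(Z) != n)
    stop_bad("pc1 (", n, "), motion (", nrow(motion), ") and Z (", nrow(Z),
             ") must all have the same number of time points")
  if (ncol(motion) != 6L) stop_bad("`motion` must have 6 columns")
  E <- convolve_events(Z, h)
  X <- cbind(pc1, motion, E)
  roles <- c("pc1_nuisance", paste0("motion_", 1:6),
             paste0("hrf_", colnames(Z)))
  dimnames(X) <- list(NULL, roles)
  structure(X, roles = roles, class = c("design_matrix", "matrix", "array"))
}

#' Default NoGo-versus-Go contrast vector
#'
#' Zero everywhere except -1 at the correct-Go regressor (column 8) and
#' +1 at the correct-NoGo regressor (column 9); the two error regressors
#' get 0.
#'
#' @param p Number of design-matrix columns (default 11).
#' @return Numeric contrast vector of length `p`.
#' @export
nogo_vs_go_contrast <- function(p = 11L) {
  if (p < 9L) stop_bad("contrast needs at least 9 columns")
  C <- numeric(p)
  C[8L] <- -1
  C[9L] <- 1
  C
}

# Shared vectorized GLM contrast engine. Y: n x V matrix of time series
# (one column per voxel). Mean-centers y and every design column, solves the
# normal equations through the Moore-Penrose pseudo-inverse of X'X, and
# returns the contrast t statistic per voxel:
#   t_v = C'beta / sqrt(sigma2 * C'GC),  sigma2 = (y'y - y'XGX'y) / df,
#   df = n - 1 - rank(X'X).
# Voxels where sigma2 and the numerator both vanish are undefined (flag);
# zero-residual voxels with a nonzero numerator get a signed Inf.
fit_glm_contrast_engine <- function(Y, X, C) {
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  Yc <- Y - rep(colMeans(Y), each = n)
  G <- pinv(crossprod(Xc))
  rank <- attr(G, "rank")
  df <- n - 1L - rank
  if (df <= 0L) stop_bad("non-positive residual degrees of freedom (df = ",
                         df, ")")
  XtY <- crossprod(Xc, Yc)
  B <- G %*% XtY
  yty <- colSums(Yc^2)
  rss <- pmax(yty - colSums(XtY * B), 0)
  sigma2 <- rss / df
  ctgc <- drop(crossprod(C, G %*% C))
  num <- drop(crossprod(C, B))
  scale <- pmax(yty, 1)
  zero_var <- sigma2 <= 1e-12 * scale / df
  zero_num <- abs(num) <= 1e-12 * sqrt(scale)
  t <- numeric(ncol(Y))
  if (ctgc <= 0) {
    # Contrast lies outside the estimable space (or is zero): t = 0 where
    # the numerator vanishes and the residual variance is positive.
    undefined <- !(zero_num & !zero_var)
    t[] <- 0
  } else {
    ok <- !zero_var
    t[ok] <- num[ok] / sqrt(sigma2[ok] * ctgc)
    t[!ok & !zero_num] <- sign(num[!ok & !zero_num]) * Inf
    undefined <- !ok & zero_num
  }
  list(t = t, beta = B, sigma2 = sigma2, df = df, G = G, ctgc = ctgc,
       undefined = undefined)
}

#' Fit the voxel GLM and compute the contrast t statistic
#'
#' Ordinary least squares on a mean-centered response and design (the
#' centering plays the role of an implicit intercept, consistent with the
#' residual degrees of freedom `df = n - 1 - rank(X'X)`), with parameters
#' estimated through the Moore-Penrose pseudo-inverse `G` of `X'X`:
#' `beta = G X' y`, `sigma2 = (y'y - y'XGX'y)/df`, and
#' `t = C'beta / sqrt(sigma2 C'GC)`.
#'
#' @param y Length-n response time series.
#' @param X Design matrix ([build_design_matrix()] or any `n x p` matrix).
#' @param C Contrast vector of length p ([nogo_vs_go_contrast()] by
#'   default).
#' @return List of class `glm_contrast_fit`: `t`, `beta`, `sigma2`, `df`,
#'   `G`, `defined` (FALSE when both the numerator and the residual
#'   variance vanish, a 0/0 statistic).
#' @export
fit_glm_contrast <- function(y, X, C = nogo_vs_go_contrast(ncol(X))) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop_bad("`y` must have one value per row of X")
  if (length(C) != ncol(X)) stop_bad("`C` must have one entry per column of X")
  f <- fit_glm_contrast_engine(matrix(as.numeric(y), ncol = 1L), X, C)
  structure(list(t = f$t[1L], beta = drop(f$beta), sigma2 = f$sigma2[1L],
                 df = f$df, G = f$G, defined = !f$undefined[1L]),
            class = "glm_contrast_fit")
}

#' Subject-level BOLD response map
#'
#' Runs the full subject pipeline: brain mask from the mean volume, first
#' principal-component nuisance time course, p = 11 design matrix, and the
#' voxelwise contrast t statistic inside the mask. Voxels whose statistic
#' is undefined (zero residual variance and zero contrast estimate) are
#' set to 0 and counted.
#'
#' @param dataset A [simulate_subject()] dataset, or any list with `bold`
#'   (4D array), `Z`, `motion`, and optional `group_name`/`tr_seconds`.
#' @param hrf HRF kernel; default [gamma_hrf()] at the dataset's TR.
#' @param mask_fraction Threshold fraction for [compute_brain_mask()].
#' @param contrast Contrast vector; default NoGo-minus-Go.
#' @return Object of class `subject_bold_map`: `tmap` (3D array, 0 outside
#'   the mask), `mask`, `meta` (group, seed), `n_undefined`, `df`.
#' @export
subject_map <- function(dataset, hrf = NULL, mask_fraction = 0.5,
                        contrast = nogo_vs_go_contrast()) {
  d <- dim(dataset$bold)
  stopifnot(length(d) == 4L)
  n <- d[4L]
  if (is.null(hrf))
    hrf <- gamma_hrf(tr_seconds = if (!is.null(dataset$tr_seconds))
      dataset$tr_seconds else 2)
  mean_vol <- array(rowMeans(matrix(dataset$bold, prod(d[1:3]), n)), d[1:3])
  mask <- compute_brain_mask(mean_vol, mask_fraction)
  pc1 <- first_pc_timecourse(dataset$bold, mask)
  X <- build_design_matrix(pc1, dataset$motion, dataset$Z, hrf)
  Y <- matrix(dataset$bold, prod(d[1:3]), n)   # V x n
  idx <- which(as.vector(mask))
  f <- fit_glm_contrast_engine(t(Y[idx, , drop = FALSE]), X, contrast)
  tmap <- array(0, d[1:3])
  tmap[idx] <- f$t
  structure(list(tmap = tmap, mask = mask,
                 meta = list(group = dataset$group_name,
                             seed = dataset$seed),
                 n_undefined = sum(f$undefined), df = f$df),
            class = "subject_bold_map")
}
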