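#' Assemble the subjects x significant-voxels response matrix
#'
#' Gathers, for every subject, the map value at each voxel carrying a
#' nonzero significance label (the 0.05 tier or stricter), giving the
#' n x p matrix whose principal components summarize between-subject
#' variation in BOLD response.
#'
#' @param subject_maps List of 3D arrays (typically the smoothed,
#'   spatially aligned subject maps that entered the group median) or
#'   `subject_bold_map` objects.
#' @param sig_image A [threshold_map()] significance image.
#' @param group_labels Optional per-subject labels (taken from
#'   `subject_bold_map` metadata when present).
#' @return Object of class `response_matrix`: `R` (n x p), `voxel_index`
#'   (p x 3 integer matrix of coordinates), `group_labels`.
#' @export
build_response_matrix <- function(subject_maps, sig_image,
                                  group_labels = NULL) {
  if (is.null(group_labels))
    group_labels <- vapply(subject_maps, function(m)
      if (inherits(m, "subject_bold_map") && !is.null(m$meta$group))
        m$meta$group else NA_character_, "")
  maps <- lapply(subject_maps, function(m)
    if (inherits(m, "subject_bold_map")) m$tmap else m)
  d <- dim(sig_image)
  for (m in maps) if (!identical(dim(m), d))
    stop_bad("subject maps and significance image must share one shape")
  sel <- which(sig_image != 0L)
  if (length(sel) == 0L)
    stop_bad("no significant voxels: the significance image is all zero, ",
             "so there is no response matrix to build")
  R <- do.call(rbind, lapply(maps, function(m) m[sel]))
  structure(list(R = R, voxel_index = arrayInd(sel, d),
                 group_labels = group_labels, grid = d),
            class = "response_matrix")
}

#' Rank-K SVD of the response matrix with normalized PC scores
#'
#' Columns (voxels) are mean-centered, then the singular value
#' decomposition `R = U D V'` is taken. Loadings `v_k` (unit norm) are the
#' eigenimages; scores `u_k` are rescaled to mean 0 and variance 1. The
#' sign of each component is fixed so the largest-magnitude loading
#' element is positive. Explained-variance fractions are `d_k^2 / sum
#' d^2` over all singular values.
#'
#' @param R A [build_response_matrix()] result or a plain n x p matrix.
#' @param K Rank of the decomposition, `K <= min(n - 1, p)`.
#' @return Object of class `pc_decomposition`: `U` (n x K standardized
#'   scores), `D` (K singular values, descending), `V` (p x K unit-norm
#'   loadings), `K`, `explained` (length-K fractions), `group_labels`.
#' @export
pca_scores <- function(R, K = 10L) {
  labels <- NULL
  if (inherits(R, "response_matrix")) {
    labels <- R$group_labels
    R <- R$R
  }
  R <- as.matrix(R)
  n <- nrow(R)
  K <- as.integer(K)
  if (K < 1L || K > min(n - 1L, ncol(R)))
    stop_bad("`K` must lie in [1, min(n - 1, p)] = [1, ",
             min(n - 1L, ncol(R)), "]")
  Rc <- R - rep(colMeans(R), each = n)
  s <- svd(Rc)
  total <- sum(s$d^2)
  U <- s$u[, seq_len(K), drop = FALSE]
  V <- s$v[, seq_len(K), drop = FALSE]
  D <- s$d[seq_len(K)]
  for (k in seq_len(K)) {
    if (V[which.max(abs(V[, k])), k] < 0) {
      V[, k] <- -V[, k]
      U[, k] <- -U[, k]
    }
  }
  U <- U * sqrt(n - 1)   # unit-norm columns -> sample variance 1
  structure(list(U = U, D = D, V = V, K = K,
                 explained = D^2 / total, group_labels = labels),
            class = "pc_decomposition")
}

#' Mann-Whitney U test between two groups of scores
#'
#' The U statistic counts pairs in which the group-1 value is below the
#' group-2 value, plus half of the tied pairs. The two-sided p-value comes
#' from the exact distribution when `n1 * n2 <= 400` and there are no
#' ties, and otherwise from the normal approximation with tie and
#' continuity correction.
#'
#' @param scores Numeric vector.
#' @param group_labels Vector with exactly two distinct values; the first
#'   value encountered defines group 1.
#' @return List of class `mw_test`: `U`, `p`, `n1`, `n2`, `groups`.
#' @export
mw_u_test <- function(scores, group_labels) {
  if (length(scores) != length(group_labels))
    stop_bad("`scores` and `group_labels` must have equal length")
  gl <- unique(group_labels)
  if (length(gl) != 2L) stop_bad("exactly two groups are required")
  g1 <- scores[group_labels == gl[1L]]
  g2 <- scores[group_labels == gl[2L]]
  if (length(g1) == 0L || length(g2) == 0L)
    stop_bad("both groups must be non-empty")
  n1 <- length(g1)
  n2 <- length(g2)
  r <- rank(c(g1, g2))
  U_gt <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs g1 > g2 (+ties/2)
  U <- n1 * n2 - U_gt                              # pairs g1 < g2 (+ties/2)
  ties <- anyDuplicated(c(g1, g2)) > 0L
  exact <- (n1 * n2 <= 400) && !ties
  p <- suppressWarnings(
    stats::wilcox.test(g1, g2, exact = exact, correct = TRUE)$p.value)
  structure(list(U = U, p = p, n1 = n1, n2 = n2, groups = gl),
            class = "mw_test")
}

#' Group tests on the leading PC scores
#'
#' Applies the Mann-Whitney U test to each of the first `K_test` PC score
#' vectors and reports the raw two-sided p-values (no multiplicity
#' adjustment; the components are screened individually) with a flag at
#' `alpha`.
#'
#' @param pcs A [pca_scores()] decomposition with `K >= K_test`.
#' @param group_labels Per-subject group labels (default: those stored in
#'   the decomposition).
#' @param K_test Number of leading components to test (default 10).
#' @param alpha Flagging level (default 0.05).
#' @return `data.frame` with one row per component: `component`, `U`,
#'   `p`, `significant`.
#' @export
test_top_components <- function(pcs, group_labels = NULL, K_test = 10L,
                                alpha = 0.05) {
  stopifnot(inherits(pcs, "pc_decomposition"))
  if (is.null(group_labels)) group_labels <- pcs$group_labels
  if (is.null(group_labels)) stop_bad("group labels are required")
  if (pcs$K < K_test)
    stop_bad("decomposition has only K = ", pcs$K, " components; ",
             "K_test = ", K_test, " requested")
  rows <- lapply(seq_len(K_test), function(k) {
    m <- mw_u_test(pcs$U[, k], group_labels)
    data.frame(component = k, U = m$U, p = m$p,
               significant = m$p < alpha)
  })
  do.call(rbind, rows)
}

# Soft threshold, and the l1 norm of the l2-normalized soft-thresholded
# vector (decreasing in lambda) used to pin the sparsity constraint.
soft <- function(a, lambda) sign(a) * pmax(abs(a) - lambda, 0)

l1_after_threshold <- function(a, lambda) {
  v <- soft(a, lambda)
  nv <- sqrt(sum(v^2))
  if (nv == 0) 0 else sum(abs(v)) / nv
}

# Choose the smallest soft-threshold level making ||v||_1 <= c after l2
# normalization, by bisection (the standard feasibility step of rank-1
# penalized matrix decomposition).
solve_threshold <- function(a, c) {
  if (l1_after_threshold(a, 0) <= c) return(0)
  lo <- 0
  hi <- max(abs(a))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (l1_after_threshold(a, mid) > c) lo <- mid else hi <- mid
  }
  hi
}

#' Sparse first principal component via penalized matrix decomposition
#'
#' Rank-1 sparse PCA: maximize `u' R v` subject to `||u||_2 <= 1`,
#' `||v||_2 <= 1` and `||v||_1 <= c`, by alternating updates with soft
#' thresholding of the loading vector, initialized at the dense first
#' component. The l1 bound zeroes weak loadings and thereby localizes the
#' component. `c >= sqrt(p)` leaves the constraint inactive (dense PC);
#' `c = 1` forces a single nonzero loading. Alternatively a target
#' fraction of nonzero loadings may be given, and `c` is found by
#' bisection.
#'
#' @param R A [build_response_matrix()] result or n x p matrix; columns
#'   are mean-centered internally.
#' @param c Sparsity bound on `||v||_1`, in `[1, sqrt(p)]`.
#' @param target_nnz_fraction Alternative to `c`: desired fraction of
#'   nonzero loadings in (0, 1].
#' @param max_iter,tol Alternation stops when the relative change of the
#'   objective falls below `tol` (default 1e-6) or after `max_iter`
#'   (default 200) iterations.
#' @return Object of class `sparse_pc`: `v1_sparse` (p-vector, unit l2
#'   norm), `u1_sparse` (standardized scores along it), `c`, `nnz`,
#'   `objective` (the attained `u' R v`, i.e. the sparse singular value),
#'   `iterations`.
#' @export
sparse_pc <- function(R, c = NULL, target_nnz_fraction = NULL,
                      max_iter = 200L, tol = 1e-6) {
  labels <- NULL
  if (inherits(R, "response_matrix")) {
    labels <- R$group_labels
    R <- R$R
  }
  R <- as.matrix(R)
  n <- nrow(R)
  p <- ncol(R)
  Rc <- R - rep(colMeans(R), each = n)
  if (is.null(c) && is.null(target_nnz_fraction))
    stop_bad("supply either `c` or `target_nnz_fraction`")
  if (!is.null(target_nnz_fraction)) {
    check_number(target_nnz_fraction, "target_nnz_fraction",
                 min = 1e-12, max = 1)
    target <- max(1L, round(target_nnz_fraction * p))
    lo <- 1
    hi <- sqrt(p)
    fit <- NULL
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      fit <- sparse_pc_fixed(Rc, mid, max_iter, tol)
      if (fit$nnz > target) hi <- mid else if (fit$nnz < target)
        lo <- mid else break
    }
    out <- fit
  } else {
    check_number(c, "c", min = 1)
    out <- sparse_pc_fixed(Rc, c, max_iter, tol)
  }
  scores <- drop(Rc %*% out$v)
  sdv <- stats::sd(scores)
  u1 <- if (sdv > 0) (scores - mean(scores)) / sdv else scores * 0
  structure(list(v1_sparse = out$v, u1_sparse = u1, c = out$c,
                 nnz = out$nnz, objective = out$objective,
                 iterations = out$iterations, group_labels = labels),
            class = "sparse_pc")
}

sparse_pc_fixed <- function(Rc, c, max_iter, tol) {
  s <- svd(Rc, nu = 1L, nv = 1L)
  v <- drop(s$v)
  if (v[which.max(abs(v))] < 0) v <- -v
  obj_old <- -Inf
  iter <- 0L
  u <- numeric(nrow(Rc))
  repeat {
    iter <- iter + 1L
    Rv <- drop(Rc %*% v)
    nu <- sqrt(sum(Rv^2))
    if (nu == 0) break
    u <- Rv / nu
    a <- drop(crossprod(Rc, u))
    lam <- solve_threshold(a, c)
    vs <- soft(a, lam)
    nv <- sqrt(sum(vs^2))
    if (nv == 0) break
    v <- vs / nv
    obj <- drop(crossprod(u, Rc %*% v))
    if (iter >= max_iter ||
        (is.finite(obj_old) && abs(obj - obj_old) <= tol * max(1, abs(obj))))
      break
    obj_old <- obj
  }
  if (v[which.max(abs(v))] < 0) v <- -v
  # with u = Rv/||Rv||, the attained objective u'Rv equals ||Rv||_2
  list(v = v, c = c, nnz = sum(v != 0),
       objective = sqrt(sum((Rc %*% v)^2)), iterations = iter)
}

#' Scatter a loading vector back into image space
#'
#' Renders an eigenimage: loadings are placed at their voxel coordinates
#' and the background is 0.
#'
#' @param v Loading vector (length p).
#' @param voxel_index p x 3 integer matrix of voxel coordinates.
#' @param grid Integer 3-vector of grid dimensions.
#' @return 3D numeric array.
#' @export
eigenimage_to_volume <- function(v, voxel_index, grid) {
  voxel_index <- as.matrix(voxel_index)
  if (length(v) != nrow(voxel_index))
    stop_bad("`v` and `voxel_index` must have matching lengths")
  if (any(voxel_index < 1L) ||
      any(voxel_index > rep(grid, each = nrow(voxel_index))))
    stop_bad("voxel indices fall outside the grid")
  img <- array(0, grid)
  img[voxel_index] <- v
  img
}
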