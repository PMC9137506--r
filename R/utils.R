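# Internal helpers shared across modules.

#' @keywords internal
#' @useDynLib permbold, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Seeds are reduced mod 2^31 - 1 so callers may pass
# derived seeds (master + offset) without overflow.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as.integer(abs(seed) %% 2147483647L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derived per-unit seed: master seed plus an offset, kept inside 32-bit range.
derive_seed <- function(master_seed, offset) {
  as.integer((as.numeric(master_seed) + as.numeric(offset)) %% 2147483647L)
}

# Moore-Penrose pseudo-inverse of a symmetric (or general) matrix via SVD.
# Singular values below rtol * largest are treated as zero. Also returns the
# numerical rank, which downstream code uses for residual degrees of freedom.
pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  tol <- rtol * max(s$d, 0)
  pos <- s$d > tol
  rank <- sum(pos)
  dinv <- ifelse(pos, 1 / s$d, 0)
  G <- s$v %*% (dinv * t(s$u))
  attr(G, "rank") <- rank
  G
}

stop_bad <- function(...) stop(..., call. = FALSE)

# Write a 3D/4D array as NIfTI with the given voxel (and optional time)
# spacing.
write_nifti_map <- function(arr, pixdims, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdims
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop_bad(sprintf("`%s` must be a single finite number in [%s, %s]",
                     name, format(min), format(max)))
  invisible(x)
}
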