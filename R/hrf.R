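#' Canonical gamma hemodynamic response function kernel
#'
#' Samples a single-gamma HRF at TR resolution and scales it to unit peak.
#' The gamma density is parameterized by the time-to-peak (its mode) and a
#' dispersion (the gamma scale parameter, seconds): shape =
#' `1 + peak_seconds / dispersion`, scale = `dispersion`. The defaults
#' (peak 6 s, dispersion 0.7 s) give a kernel with FWHM of about 5 s,
#' sampled over 16 TRs (32 s at TR 2 s).
#'
#' A `kernel_length` of 1 degenerates to a unit impulse (the gamma density
#' is 0 at t = 0, so the single sample is defined as the kernel's own
#' peak, 1).
#'
#' @param peak_seconds Time-to-peak of the response, seconds (> 0).
#' @param dispersion Gamma scale parameter, seconds (> 0); larger values
#'   widen the response.
#' @param tr_seconds Sampling interval (repetition time), seconds.
#' @param kernel_length Number of TR samples in the kernel.
#' @return Object of class `hrf_kernel`: list with `samples` (unit-peak,
#'   non-negative), `peak_seconds`, `dispersion`, `tr_seconds`,
#'   `kernel_length`.
#' @export
gamma_hrf <- function(peak_seconds = 6, dispersion = 0.7,
                      tr_seconds = 2, kernel_length = 16L) {
  check_number(peak_seconds, "peak_seconds", min = .Machine$double.eps)
  check_number(dispersion, "dispersion", min = .Machine$double.eps)
  check_number(tr_seconds, "tr_seconds", min = .Machine$double.eps)
  check_number(kernel_length, "kernel_length", min = 1)
  kernel_length <- as.integer(kernel_length)
  t <- (seq_len(kernel_length) - 1) * tr_seconds
  shape <- 1 + peak_seconds / dispersion
  h <- stats::dgamma(t, shape = shape, scale = dispersion)
  m <- max(h)
  samples <- if (m > 0) h / m else c(1, rep(0, kernel_length - 1L))
  structure(list(samples = samples, peak_seconds = peak_seconds,
                 dispersion = dispersion, tr_seconds = tr_seconds,
                 kernel_length = kernel_length),
            class = "hrf_kernel")
}

#' Convolve event indicator columns with an HRF kernel
#'
#' Discrete causal convolution of each column of the performance matrix Z
#' with the kernel, truncated to the run length, producing the four
#' hemodynamic event regressors (columns 8-11 of the design matrix).
#'
#' @param Z `n x 4` performance matrix (or any `n x k` indicator matrix).
#' @param h An [gamma_hrf()] kernel.
#' @return `n x k` numeric matrix of regressors, one per event type.
#' @export
convolve_events <- function(Z, h) {
  stopifnot(inherits(h, "hrf_kernel"))
  Z <- as.matrix(Z)
  n <- nrow(Z)
  H <- hrf_toeplitz(h$samples, n)
  R <- H %*% Z
  dimnames(R) <- list(NULL, colnames(Z))
  R
}

# Lower-triangular Toeplitz convolution matrix: (H %*% z)[i] =
# sum_k h[k+1] z[i-k], i.e. causal convolution truncated to n samples.
# Precomputed once and reused heavily by the permutation engine.
hrf_toeplitz <- function(samples, n) {
  L <- length(samples)
  H <- matrix(0, n, n)
  for (k in seq_len(min(L, n))) {
    idx <- seq_len(n - k + 1L)
    H[cbind(idx + k - 1L, idx)] <- samples[k]
  }
  H
}
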