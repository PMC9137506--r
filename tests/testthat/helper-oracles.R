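# Independent oracles and small fixture builders used across tests.

# Recursive flood fill: a deliberately naive connected-components labeling
# used as the oracle for extract_clusters().
flood_fill_components <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- permbold:::neighbor_offsets(connectivity)
  comp <- array(0L, d)
  id <- 0L
  fill <- function(v) {
    stack <- list(v)
    while (length(stack)) {
      w <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in seq_len(nrow(offs))) {
        u <- w + offs[o, ]
        if (any(u < 1L) || any(u > d)) next
        li <- u[1L] + d[1L] * (u[2L] - 1L) + d[1L] * d[2L] * (u[3L] - 1L)
        if (mask[li] && comp[li] == 0L) {
          comp[li] <<- id
          stack[[length(stack) + 1L]] <- u
        }
      }
    }
  }
  for (start in which(mask)) {
    if (comp[start] > 0L) next
    id <- id + 1L
    comp[start] <- id
    fill(arrayInd(start, d)[1, ])
  }
  comp
}

# Textbook OLS contrast t computed through an explicit normal-equations
# solve (distinct numeric path from the package's SVD pseudo-inverse),
# rescaled to the df = n - 1 - rank convention.
ols_contrast_oracle <- function(y, X, C) {
  n <- length(y)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  b <- solve(XtX, crossprod(Xc, yc))
  res <- yc - Xc %*% b
  df <- n - 1 - qr(Xc)$rank
  s2 <- sum(res^2) / df
  Vinv <- solve(XtX)
  drop(crossprod(C, b)) / sqrt(s2 * drop(t(C) %*% Vinv %*% C))
}

# A tiny subject dataset with configurable noise for fast unit tests.
tiny_subject <- function(noise_sd = 1, drift = 1, regions = NULL,
                         seed = 1, n_trials = 60, grid = c(6L, 6L, 4L)) {
  cfg <- task_config(n_trials = n_trials, seed = seed)
  spec <- cohort_spec(n_per_group = 1L, grid_shape = grid,
                      active_regions = if (is.null(regions)) list() else
                        regions,
                      noise_sd = noise_sd, drift_amplitude = drift,
                      seed = seed)
  sq <- generate_task_sequence(cfg)
  Z <- simulate_performance(sq, 0.9, 0.85, seed = seed + 1)
  simulate_subject(cfg, spec, Z, group = 1L, seed = seed + 2)
}

# A small cohort wrapper with sensible unit-test defaults.
tiny_cohort <- function(n_per_group = 2L, seed = 1, active = list(),
                        grid = c(8L, 8L, 6L), n_trials = 60) {
  spec <- cohort_spec(n_per_group = n_per_group, grid_shape = grid,
                      active_regions = active, seed = seed)
  generate_cohort(spec, task_config(n_trials = n_trials))
}
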