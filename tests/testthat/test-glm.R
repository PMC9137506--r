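test_that("brain masks threshold on the robust maximum", {
  vol <- array(5, c(4, 4, 3))
  expect_true(all(compute_brain_mask(vol, 0.5)))

  # blob occupying >1% of voxels separates cleanly at fraction 0.4
  vol2 <- array(1, c(10, 10, 5))
  vol2[3:6, 3:6, 2:3] <- 100
  mask <- compute_brain_mask(vol2, 0.4)
  expect_identical(mask, vol2 == 100)

  expect_error(compute_brain_mask(array(NaN, c(2, 2, 2))), "finite")
})

test_that("the first PC time course recovers rank-1 structure", {
  n <- 40L
  s <- sin(seq_len(n) / 3)
  grid <- c(4L, 4L, 2L)
  V <- prod(grid)
  weights <- seq(0.5, 2, length.out = V)
  bold <- array(NA_real_, c(grid, n))
  for (v in seq_len(V)) {
    idx <- arrayInd(v, grid)
    bold[idx[1], idx[2], idx[3], ] <- 100 + v + weights[v] * s
  }
  mask <- array(TRUE, grid)
  pc <- first_pc_timecourse(bold, mask)
  expect_equal(sum(pc^2), 1)
  sc <- s - mean(s)
  expect_gt(cor(pc, sc), 1 - 1e-10)  # sign fixed toward global mean

  expect_error(first_pc_timecourse(array(1, c(grid, n)), mask),
               "variance")
})

test_that("the first PC matches an SVD oracle on random data", {
  set.seed(21)
  n <- 30L
  grid <- c(5L, 5L, 2L)
  V <- prod(grid)
  bold <- array(rnorm(V * n), c(grid, n))
  mask <- array(TRUE, grid)
  pc <- first_pc_timecourse(bold, mask)
  M <- matrix(bold, V, n)
  Mc <- M - rowMeans(M)
  sv <- svd(Mc)
  expect_equal(abs(sum(pc * sv$v[, 1L])), 1, tolerance = 1e-8)
  attained <- drop(t(pc) %*% crossprod(Mc) %*% pc)
  expect_equal(attained, sv$d[1L]^2, tolerance = 1e-8)
})

test_that("the design matrix has the fixed 11-column layout", {
  d <- tiny_subject(seed = 2)
  h <- gamma_hrf(tr_seconds = 2)
  mask <- compute_brain_mask(
    array(rowMeans(matrix(d$bold, prod(dim(d$bold)[1:3]),
                          dim(d$bold)[4])), dim(d$bold)[1:3]))
  pc1 <- first_pc_timecourse(d$bold, mask)
  X <- build_design_matrix(pc1, d$motion, d$Z, h)
  expect_equal(ncol(X), 11L)
  expect_equal(attr(X, "roles")[1L], "pc1_nuisance")
  expect_equal(X[, 8L], unname(convolve_events(d$Z, h)[, 1L]))
  expect_equal(X[, 2:7], unclass(d$motion), ignore_attr = TRUE)
  expect_error(build_design_matrix(pc1, NULL, d$Z, h), "required")
  expect_error(build_design_matrix(pc1[-1], d$motion, d$Z, h),
               "same number")
  expect_error(build_design_matrix(pc1, d$motion[, 1:5], d$Z, h),
               "6 columns")
})

test_that("the default contrast picks NoGo minus Go", {
  C <- nogo_vs_go_contrast()
  expect_length(C, 11L)
  expect_equal(C[8L], -1)
  expect_equal(C[9L], 1)
  expect_equal(sum(C != 0), 2L)
})

test_that("degenerate contrasts and rank-deficient designs are handled", {
  set.seed(5)
  n <- 30L
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  y <- rnorm(n)
  f0 <- fit_glm_contrast(y, X, c(0, 0, 0))
  expect_equal(f0$t, 0)
  expect_true(f0$defined)

  # duplicated column: pseudo-inverse path succeeds; the contrast estimate
  # on an unaffected column is unchanged
  Xd <- cbind(X, X[, 3L])
  f1 <- fit_glm_contrast(y, X, c(1, 0, 0))
  f2 <- fit_glm_contrast(y, Xd, c(1, 0, 0, 0))
  expect_equal(sum(c(1, 0, 0, 0) * f2$beta), sum(c(1, 0, 0) * f1$beta),
               tolerance = 1e-8)
  expect_equal(attr(f2$G, "rank"), 3L)
})

test_that("the contrast t matches an independent OLS oracle", {
  for (s in 1:25) {
    set.seed(s)
    n <- 40L
    p <- 5L
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- X %*% beta + rnorm(n)
    C <- rnorm(p)
    expect_equal(fit_glm_contrast(y, X, C)$t,
                 ols_contrast_oracle(y, X, C), tolerance = 1e-8)
  }
})

test_that("the t statistic is scale-equivariant and shift-consistent", {
  set.seed(9)
  n <- 50L
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rnorm(n)
  C <- c(0, -1, 1, 0)
  t0 <- fit_glm_contrast(y, X, C)$t
  for (k in c(0.1, 3, 250)) {
    expect_equal(fit_glm_contrast(k * y, X, C)$t, t0, tolerance = 1e-10)
  }
  # adding X a to y shifts the contrast estimate by C'a exactly
  a <- c(2, -1, 0.5, 3)
  f0 <- fit_glm_contrast(y, X, C)
  f1 <- fit_glm_contrast(y + X %*% a, X, C)
  expect_equal(sum(C * f1$beta) - sum(C * f0$beta), sum(C * a),
               tolerance = 1e-8)
})

test_that("the standard 200 x 11 design has df = 188", {
  cfg <- task_config(seed = 31)
  spec <- cohort_spec(n_per_group = 1L, seed = 31)
  Z <- simulate_performance(generate_task_sequence(cfg), 0.9, 0.85,
                            seed = 32)
  d <- simulate_subject(cfg, spec, Z, group = 1L, seed = 33)
  m <- subject_map(d)
  expect_equal(m$df, 188L)
})

test_that("subject maps localize a noiseless single active voxel", {
  region <- cuboid_region(c(3L, 3L, 2L), c(3L, 3L, 2L),
                          nogo_amplitude = c(5, 5))
  cfg <- task_config(n_trials = 60L, seed = 41)
  # noise, drift and motion coupling all off: the event response is the
  # only source of variance, so the statistic localizes it exactly
  spec <- cohort_spec(n_per_group = 1L, grid_shape = c(6L, 6L, 4L),
                      active_regions = list(region), noise_sd = 0,
                      drift_amplitude = 0, motion_sd = c(0, 0),
                      nuisance_weight_sd = 0, seed = 41)
  Z <- simulate_performance(generate_task_sequence(cfg), 0.9, 0.85,
                            seed = 42)
  d <- simulate_subject(cfg, spec, Z, group = 1L, seed = 43)
  m <- subject_map(d)
  expect_equal(which.max(abs(m$tmap)),
               which(as.vector(d$truth) != 0))
  expect_true(is.infinite(m$tmap[3, 3, 2]))  # exact fit, zero residual
})

test_that("pure-noise t-maps are centered at zero", {
  d <- tiny_subject(noise_sd = 1, seed = 51, n_trials = 100,
                    grid = c(8L, 8L, 6L))
  m <- subject_map(d)
  tv <- m$tmap[m$mask]
  expect_lt(abs(mean(tv)), 3 * sd(tv) / sqrt(length(tv)))
  expect_equal(m$n_undefined, 0L)
})

test_that("the permutation engine reproduces subject_map under relabeling", {
  d <- tiny_subject(noise_sd = 1, seed = 61, n_trials = 80,
                    grid = c(6L, 6L, 4L))
  h <- gamma_hrf(tr_seconds = 2)
  pre <- permbold:::precompute_subject_fit(d, h, 0.5)
  set.seed(62)
  perm <- sample.int(80L)
  t_fast <- permbold:::permuted_tmap(pre, perm, nogo_vs_go_contrast())
  d_perm <- d
  d_perm$Z <- permute_performance(d$Z, perm)
  m <- subject_map(d_perm, hrf = h)
  expect_equal(array(t_fast, dim(m$tmap)), m$tmap, tolerance = 1e-8)
})
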