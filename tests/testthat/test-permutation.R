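test_that("row permutation preserves performance margins", {
  Z <- simulate_performance(
    generate_task_sequence(task_config(n_trials = 50L, seed = 1)),
    0.9, 0.85, seed = 2)
  expect_identical(permute_performance(Z, perm = seq_len(50L)), Z)
  set.seed(3)
  for (i in 1:10) {
    Zp <- permute_performance(Z)
    expect_equal(colSums(Zp), colSums(Z))
    expect_true(all(rowSums(Zp) == 1))
  }
  expect_error(permute_performance(Z, perm = c(1L, 1L, 3:50)),
               "permutation")
})

test_that("permutations of distinct rows are uniform over orderings", {
  Z <- matrix(0L, 3L, 4L)
  Z[1L, 1L] <- 1L
  Z[2L, 2L] <- 1L
  Z[3L, 3L] <- 1L
  Z <- as_performance_matrix(Z)
  keys <- character(60000L)
  set.seed(4)
  for (i in seq_along(keys)) {
    keys[i] <- paste(max.col(permute_performance(Z)), collapse = "")
  }
  counts <- table(keys)
  expect_length(counts, 6L)
  chisq <- sum((counts - 10000)^2 / 10000)
  expect_lt(chisq, qchisq(0.99, df = 5))
})

test_that("thresholds follow the strict-exceedance order statistic", {
  fake <- structure(list(maxima = as.numeric(1:1000),
                         minima = -as.numeric(1:1000), B = 1000L),
                    class = "null_distribution")
  thr <- compute_thresholds(fake)
  expect_length(thr$upper, 3L)
  expect_length(thr$lower, 3L)

  # brute-force oracle: smallest threshold with exceedance strictly < alpha
  for (a in c(0.001, 0.01, 0.05)) {
    t_pkg <- thr$upper[[as.character(a)]]
    exceed <- function(t) sum(fake$maxima > t) / fake$B
    expect_lt(exceed(t_pkg), a)
    candidates <- sort(fake$maxima)
    smallest <- candidates[which(vapply(candidates, exceed, 0) < a)[1L]]
    expect_equal(t_pkg, smallest)
    # mirror image on the minima
    t_lo <- thr$lower[[as.character(a)]]
    expect_lt(sum(fake$minima < t_lo) / fake$B, a)
    expect_equal(t_lo, -smallest)
  }

  # nested thresholds on random distributions
  set.seed(5)
  for (i in 1:10) {
    nd <- structure(list(maxima = rnorm(500, 2), minima = rnorm(500, -2),
                         B = 500L), class = "null_distribution")
    th <- compute_thresholds(nd, c(0.01, 0.05))
    expect_gte(th$upper[["0.01"]], th$upper[["0.05"]])
    expect_lte(th$lower[["0.01"]], th$lower[["0.05"]])
  }

  degenerate <- structure(list(maxima = rep(3, 100), minima = rep(-2, 100),
                               B = 100L), class = "null_distribution")
  thd <- suppressWarnings(compute_thresholds(degenerate))
  expect_true(all(thd$upper == 3))
  expect_true(all(thd$lower == -2))

  expect_warning(compute_thresholds(fake, alphas = c(0.0001)),
                 "cannot resolve")
})

test_that("significance tiers encode the most stringent level passed", {
  thr <- structure(list(upper = c("0.001" = 3, "0.01" = 2, "0.05" = 1),
                        lower = c("0.001" = -3, "0.01" = -2, "0.05" = -1),
                        alphas = c(0.001, 0.01, 0.05), B = 1000L),
                   class = "threshold_set")
  m <- array(0, c(2, 2, 2))
  expect_true(all(threshold_map(m, thr) == 0L))

  m[1, 1, 1] <- 3.5   # above the 0.001 threshold -> +3, not +1
  m[2, 1, 1] <- 1.5   # above 0.05 only -> +1
  m[1, 2, 1] <- -2.5  # below the 0.01 cutoff -> -2
  lab <- threshold_map(m, thr)
  expect_equal(lab[1, 1, 1], 3L)
  expect_equal(lab[2, 1, 1], 1L)
  expect_equal(lab[1, 2, 1], -2L)

  # label counts match direct per-tier comparisons
  set.seed(6)
  r <- array(rnorm(1000, sd = 2), c(10, 10, 10))
  lab_r <- threshold_map(r, thr)
  expect_equal(sum(lab_r == 3L), sum(r > 3))
  expect_equal(sum(lab_r == 2L), sum(r > 2 & r <= 3))
  expect_equal(sum(lab_r == 1L), sum(r > 1 & r <= 2))
  expect_equal(sum(lab_r == -3L), sum(r < -3))
  expect_equal(sum(lab_r == 0L), sum(r >= -1 & r <= 1))
})

test_that("cluster extraction filters on strict volume and keeps signs apart", {
  vox <- c(2.5, 2.5, 3.5)  # 21.875 mm^3 per voxel
  img <- array(0L, c(10, 10, 6))
  img[2:8, 2, 2] <- 1L              # 7 voxels = 153.1 mm^3 -> kept
  img[2:5, 5, 2] <- 1L              # 4 voxels = 87.5 mm^3  -> dropped
  cl <- extract_clusters(img, vox, connectivity = 18L, min_size_mm3 = 100)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size_voxels, 7L)
  expect_equal(cl$size_mm3, 7 * prod(vox))

  # adjacent clusters of opposite sign never merge
  img2 <- array(0L, c(10, 10, 6))
  img2[2:8, 2, 2] <- 1L
  img2[2:8, 3, 2] <- -1L
  cl2 <- extract_clusters(img2, vox, 18L, 100)
  expect_equal(nrow(cl2), 2L)
  expect_setequal(cl2$sign, c("positive", "negative"))

  expect_equal(nrow(extract_clusters(array(0L, c(4, 4, 4)), vox)), 0L)
  expect_error(extract_clusters(img, vox, connectivity = 10L), "6, 18 or 26")

  # cluster count is non-increasing in the volume filter
  set.seed(7)
  ri <- array(sample(c(0L, 1L), 12 * 12 * 8, TRUE, c(0.7, 0.3)),
              c(12, 12, 8))
  sizes <- c(0, 50, 100, 200, 400)
  counts <- vapply(sizes, function(ms)
    nrow(extract_clusters(ri, vox, 6L, ms)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("connected components agree with a flood-fill oracle", {
  set.seed(8)
  for (i in 1:5) {
    img <- array(sample(c(0L, 1L, -1L), 10 * 8 * 6, TRUE,
                        c(0.6, 0.25, 0.15)), c(10, 8, 6))
    for (conn in c(6L, 18L, 26L)) {
      for (sgn in c(1L, -1L)) {
        ours <- permbold:::label_components(img == sgn, conn)
        oracle <- flood_fill_components(img == sgn, conn)
        expect_equal(max(ours), max(oracle))
        # identical partitions: co-membership must agree
        idx <- which(img == sgn)
        expect_true(all(outer(ours[idx], ours[idx], "==") ==
                          outer(oracle[idx], oracle[idx], "==")))
      }
    }
  }
})

test_that("the permutation null is deterministic and internally consistent", {
  co <- tiny_cohort(n_per_group = 2L, seed = 11)
  nd1 <- null_distribution(co, B = 15L, master_seed = 5)
  nd2 <- null_distribution(co, B = 15L, master_seed = 5)
  expect_identical(nd1$maxima, nd2$maxima)
  expect_identical(nd1$minima, nd2$minima)
  expect_true(all(nd1$maxima >= nd1$minima))

  nd3 <- null_distribution(co, B = 15L, master_seed = 6)
  expect_false(identical(nd1$maxima, nd3$maxima))
})

test_that("forced identity runs reproduce the true group map extrema", {
  co <- tiny_cohort(n_per_group = 2L, seed = 12)
  nd <- null_distribution(co, B = 2L, master_seed = 1, .identity = TRUE)
  gm <- group_map_from_cohort(co)
  truth <- gm$group_map$median_map[gm$group_mask]
  expect_equal(nd$maxima, rep(max(truth), 2L), tolerance = 1e-10)
  expect_equal(nd$minima, rep(min(truth), 2L), tolerance = 1e-10)
  expect_equal(nd$true_max, max(truth), tolerance = 1e-10)
  expect_equal(nd$true_min, min(truth), tolerance = 1e-10)
})

test_that("the compiled engine matches the R reference path run by run", {
  co <- tiny_cohort(n_per_group = 2L, seed = 13, n_trials = 50)
  B <- 4L
  seed <- 21
  nd <- null_distribution(co, B = B, master_seed = seed)
  # replay the documented draw procedure (subject-major) in plain R
  h <- gamma_hrf(tr_seconds = 2)
  pre <- lapply(co, permbold:::precompute_subject_fit, hrf = h,
                mask_fraction = 0.5)
  perms <- permbold:::with_seed(seed, lapply(seq_along(co), function(s)
    vapply(seq_len(B), function(b) sample.int(50L), integer(50L))))
  grid <- dim(co[[1]]$truth)
  smoother <- permbold:::make_smoother(grid, 3, c(2.5, 2.5, 3.5))
  gmask <- Reduce(`&`, lapply(pre, `[[`, "mask"))
  for (b in seq_len(B)) {
    maps <- lapply(seq_along(co), function(s)
      smoother(array(permbold:::permuted_tmap(pre[[s]], perms[[s]][, b],
                                              nogo_vs_go_contrast()),
                     grid)))
    med <- permbold:::row_medians(sapply(maps, as.vector))[gmask]
    expect_equal(nd$maxima[b], max(med), tolerance = 1e-10)
    expect_equal(nd$minima[b], min(med), tolerance = 1e-10)
  }
})
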