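test_that("the response matrix gathers exactly the significant voxels", {
  grid <- c(4L, 4L, 2L)
  sig <- array(0L, grid)
  sig[1, 1, 1] <- 1L
  sig[2, 3, 1] <- -2L
  sig[4, 4, 2] <- 3L
  set.seed(1)
  maps <- lapply(1:4, function(i) array(rnorm(prod(grid)), grid))
  R <- build_response_matrix(maps, sig, group_labels = rep(c("a", "b"), 2))
  expect_equal(dim(R$R), c(4L, 3L))
  expect_equal(ncol(R$R), sum(sig != 0L))
  for (i in 1:4) {
    for (j in seq_len(nrow(R$voxel_index))) {
      v <- R$voxel_index[j, ]
      expect_equal(R$R[i, j], maps[[i]][v[1], v[2], v[3]])
    }
  }
  expect_error(build_response_matrix(maps, array(0L, grid)),
               "no significant voxels")
})

test_that("PC scores are standardized and recover rank-1 structure", {
  set.seed(2)
  u_true <- rnorm(12)
  v_true <- rnorm(30)
  v_true <- v_true / sqrt(sum(v_true^2))
  R <- outer(u_true, v_true)
  pcs <- pca_scores(R, K = 1L)
  expect_equal(abs(sum(pcs$V[, 1] * v_true)), 1, tolerance = 1e-8)
  expect_equal(pcs$explained[1L], 1, tolerance = 1e-10)
  expect_equal(mean(pcs$U[, 1]), 0, tolerance = 1e-10)
  expect_equal(var(pcs$U[, 1]), 1, tolerance = 1e-10)
  # sign convention: the largest-magnitude loading is positive
  expect_gt(pcs$V[which.max(abs(pcs$V[, 1])), 1], 0)

  expect_error(pca_scores(R, K = 12L), "K")
})

test_that("the SVD matches a covariance eigendecomposition oracle", {
  set.seed(3)
  R <- matrix(rnorm(10 * 20), 10, 20)
  K <- 5L
  pcs <- pca_scores(R, K = K)
  Rc <- scale(R, center = TRUE, scale = FALSE)
  eg <- eigen(crossprod(Rc), symmetric = TRUE)
  expect_equal(pcs$D^2, eg$values[seq_len(K)], tolerance = 1e-8)
  for (k in seq_len(K)) {
    expect_equal(abs(sum(pcs$V[, k] * eg$vectors[, k])), 1,
                 tolerance = 1e-8)
    expect_equal(mean(pcs$U[, k]), 0, tolerance = 1e-10)
    expect_equal(var(pcs$U[, k]), 1, tolerance = 1e-8)
  }
  expect_equal(pcs$explained,
               eg$values[seq_len(K)] / sum(eg$values), tolerance = 1e-8)
})

test_that("rank-K truncation beats random factorizations (Eckart-Young)", {
  set.seed(4)
  R <- matrix(rnorm(12 * 30), 12, 30)
  Rc <- scale(R, center = TRUE, scale = FALSE)
  K <- 3L
  pcs <- pca_scores(R, K = K)
  recon <- (pcs$U / sqrt(nrow(R) - 1)) %*% diag(pcs$D) %*% t(pcs$V)
  err_svd <- sum((Rc - recon)^2)
  for (i in 1:50) {
    A <- matrix(rnorm(12 * K), 12, K)
    Bm <- matrix(rnorm(30 * K), 30, K)
    fit <- A %*% solve(crossprod(A), crossprod(A, Rc))  # best given A
    expect_gte(sum((Rc - fit)^2) + 1e-10, err_svd)
    expect_gte(sum((Rc - A %*% t(Bm))^2), err_svd)
  }
})

test_that("the U statistic counts cross-group pairs", {
  # identical multisets in both groups
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  m <- mw_u_test(x, g)
  expect_equal(m$U, 4.5)  # n1 n2 / 2 with ties halved

  # complete separation
  m2 <- mw_u_test(c(1, 2, 3, 10, 11, 12), g)
  expect_equal(m2$U, 9)
  m3 <- mw_u_test(c(10, 11, 12, 1, 2, 3), g)
  expect_equal(m3$U, 0)

  expect_error(mw_u_test(x, rep("a", 6)), "two groups")
})

test_that("U and its exact p match exhaustive enumeration at n = 8 + 8", {
  set.seed(5)
  scores <- rnorm(16)
  g <- rep(c("a", "b"), each = 8)
  m <- mw_u_test(scores, g)

  # brute force: all C(16, 8) assignments of the same scores
  r <- rank(scores)
  combos <- utils::combn(16L, 8L)
  u_all <- colSums(matrix(r[combos], 8L)) - 8 * 9 / 2
  u_all <- 64 - u_all  # convert to "group1 below group2" orientation
  u_obs <- m$U
  mu <- 64 / 2
  p_oracle <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(m$p, p_oracle, tolerance = 1e-12)
  # the observed U is the one computed from the true labeling
  expect_equal(u_obs, u_all[1L])
  expect_equal(mean(u_all), mu)
})

test_that("component screening has the right shape and finds real shifts", {
  set.seed(6)
  n <- 24L
  g <- rep(c("ctl", "cas"), each = 12)
  v <- rnorm(40)
  v <- v / sqrt(sum(v^2))
  shift <- ifelse(g == "ctl", 2, -2)
  R <- outer(shift, v) + matrix(rnorm(n * 40, sd = 0.5), n, 40)
  pcs <- pca_scores(R, K = 10L)
  tab <- test_top_components(pcs, g, K_test = 10L)
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$component, 1:10)
  expect_true(tab$significant[1L])
  expect_lt(tab$p[1L], 0.05)
})

test_that("sparse PCA obeys its constraints across the sparsity path", {
  set.seed(7)
  R <- matrix(rnorm(15 * 40), 15, 40) +
    outer(rnorm(15, sd = 2), c(rep(1, 8), rep(0, 32)))
  p <- ncol(R)

  # inactive constraint reproduces the dense first component
  dense <- pca_scores(R, K = 1L)
  s_dense <- sparse_pc(R, c = sqrt(p))
  expect_equal(s_dense$v1_sparse, dense$V[, 1L], tolerance = 1e-6)

  # maximal sparsity keeps exactly one loading
  s1 <- sparse_pc(R, c = 1)
  expect_equal(s1$nnz, 1L)
  expect_equal(sum(abs(s1$v1_sparse)), 1, tolerance = 1e-8)

  # the l1 bound holds everywhere and nnz shrinks with c
  cs <- seq(sqrt(p), 1, length.out = 8)
  nnzs <- integer(length(cs))
  for (i in seq_along(cs)) {
    s <- sparse_pc(R, c = cs[i])
    expect_lte(sum(abs(s$v1_sparse)), cs[i] + 1e-8)
    expect_lte(sqrt(sum(s$v1_sparse^2)), 1 + 1e-8)
    nnzs[i] <- s$nnz
  }
  expect_true(all(diff(nnzs) <= 0))

  # target fraction lands near the requested support size
  st <- sparse_pc(R, target_nnz_fraction = 0.5)
  expect_lte(abs(st$nnz - 20L), 3L)

  expect_error(sparse_pc(R, c = 0.5), "c")
  expect_error(sparse_pc(R), "supply either")
})

test_that("eigenimages scatter and gather without loss", {
  grid <- c(5L, 4L, 3L)
  set.seed(8)
  idx <- arrayInd(sample(prod(grid), 10L), grid)
  v <- rnorm(10)
  img <- eigenimage_to_volume(v, idx, grid)
  expect_equal(img[idx], v)
  expect_equal(sum(img != 0), sum(v != 0))
  expect_equal(sum(img == 0), prod(grid) - 10L)
  expect_error(eigenimage_to_volume(v, idx + 10L, grid), "outside")
  expect_error(eigenimage_to_volume(v[-1], idx, grid), "matching")
})
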