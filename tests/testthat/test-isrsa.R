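test_that("similarity matrix reproduces hand-computed values", {
  s <- similarity_matrix(c(-10, -8, 0))
  expect_equal(unname(s[1, 2]), 1 / 3)
  expect_equal(unname(s[1, 3]), 1 / 11)
  expect_equal(unname(s[2, 3]), 1 / 9)
  expect_equal(diag(s), c(`1` = 1, `2` = 1, `3` = 1))
  expect_true(isSymmetric(unclass(s)))
  # identical values -> similarity 1; d = 1 -> 0.5; d = 3 -> 0.25
  s2 <- similarity_matrix(c(2, 2, 3, 5))
  expect_equal(unname(s2[1, 2]), 1)
  expect_equal(unname(s2[2, 3]), 0.5)
  expect_equal(unname(s2[2, 4]), 0.25)
  expect_true(all(s2 > 0 & s2 <= 1))
  # vector-valued observations use the Euclidean distance
  m <- rbind(c(0, 0), c(3, 4))
  expect_equal(unname(similarity_matrix(m)[1, 2]), 1 / 6)
  expect_error(similarity_matrix(c(1, NA)), "non-finite")
  expect_error(similarity_matrix(5), "at least 2")
})

test_that("BH-FDR thresholding reproduces hand-worked cases", {
  # max i with p(i) <= 0.05 i / 4 is 4 -> all survive
  r1 <- fdr_threshold(c(0.01, 0.02, 0.03, 0.04))
  expect_true(all(r1$survivors))
  # 0.04 > 0.0125 and nothing else helps -> none survive
  r2 <- fdr_threshold(c(0.04, 0.5, 0.9, 1.0))
  expect_false(any(r2$survivors))
  expect_true(all(fdr_threshold(rep(0, 5))$survivors))
  expect_equal(fdr_threshold(c(0.02, 0.8))$adjusted, c(0.04, 0.8))
  p <- with_seed_test(3, runif(50))
  expect_true(all(fdr_threshold(p)$adjusted >= p))   # q >= p voxelwise
  expect_error(fdr_threshold(numeric(0)), "empty")
  expect_error(fdr_threshold(c(0.5, 1.2)), "lie in")
})

test_that("cluster extraction respects contiguity and the size threshold", {
  dims <- c(10, 10, 10)
  mask <- array(FALSE, dims)
  mask[2:7, 5, 5] <- TRUE                   # line of 6: one cluster
  mask[9, 1:4, 1] <- TRUE                   # block of 4: discarded
  mask[1:2, 9:10, 8:9] <- TRUE              # 2x2x2 block: kept (size 8)
  cl <- extract_clusters(mask, min_size = 5)
  expect_equal(nrow(cl$clusters), 2)
  expect_setequal(cl$clusters$size, c(6, 8))
  expect_equal(sum(cl$labels > 0), 14)
  expect_equal(cl$labels[9, 2, 1], 0L)       # small block removed
  # two blocks separated by a gap are distinct clusters
  mask2 <- array(FALSE, dims)
  mask2[1:5, 1, 1] <- TRUE
  mask2[7:10, 1, 1] <- TRUE
  cl2 <- extract_clusters(mask2, min_size = 4)
  expect_equal(nrow(cl2$clusters), 2)
  # diagonal voxels connect under 26- but not 6-connectivity
  mask3 <- array(FALSE, c(4, 4, 4))
  mask3[1, 1, 1] <- mask3[2, 2, 2] <- TRUE
  expect_equal(nrow(extract_clusters(mask3, min_size = 2,
                                     connectivity = 6)$clusters), 0)
  expect_equal(nrow(extract_clusters(mask3, min_size = 2,
                                     connectivity = 26)$clusters), 1)
})

test_that("dyadic OLS equals the closed-form regression on dyads", {
  n <- 8
  phi <- with_seed_test(21, rnorm(n, -10, 6))
  alp <- with_seed_test(22, runif(n, 0.7, 1))
  B <- with_seed_test(23,
    matrix(rnorm(n * 3), n, 3) + cbind(phi, 0, 0))
  ps <- similarity_matrix(phi); as_ <- similarity_matrix(alp)
  res <- dyadic_regress_voxelwise(B, ps, as_, method = "ols")
  ij <- harmalloc:::dyad_index(n)
  for (v in 1:3) {
    y <- 1 / (1 + abs(B[ij[, 1], v] - B[ij[, 2], v]))
    fit <- lm(y ~ ps[ij] + as_[ij])
    expect_equal(res$estimate[v], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(res$se[v], unname(sqrt(diag(vcov(fit)))[2]), tolerance = 1e-10)
  }
})

test_that("multi-membership REML matches a dense brute-force oracle", {
  n <- 7
  phi <- with_seed_test(31, rnorm(n, 0, 3))
  alp <- with_seed_test(32, rnorm(n))
  B <- with_seed_test(33, matrix(rnorm(n * 2), n, 2) + cbind(phi, 0))
  ps <- similarity_matrix(phi); as_ <- similarity_matrix(alp)
  res <- dyadic_regress_voxelwise(B, ps, as_, method = "lmm")
  ij <- harmalloc:::dyad_index(n)
  D <- nrow(ij)
  X <- cbind(1, ps[ij], as_[ij])
  Z <- matrix(0, D, n)
  Z[cbind(1:D, ij[, 1])] <- 1
  Z[cbind(1:D, ij[, 2])] <- 1
  # dense REML: grid over the variance ratio, GLS per grid point
  dense_reml <- function(y) {
    crit <- function(lambda) {
      V <- diag(D) + lambda * tcrossprod(Z)
      Vi <- solve(V)
      XtVX <- t(X) %*% Vi %*% X
      b <- solve(XtVX, t(X) %*% Vi %*% y)
      r <- y - X %*% b
      rss <- drop(t(r) %*% Vi %*% r)
      -0.5 * (determinant(V)$modulus + (D - 3) * log(rss) +
                determinant(XtVX)$modulus)
    }
    lam <- exp(seq(-12, 8, length.out = 2000))
    best <- lam[which.max(vapply(lam, crit, numeric(1)))]
    V <- diag(D) + best * tcrossprod(Z)
    Vi <- solve(V)
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / (D - 3)
    list(beta = b[2], se = sqrt(solve(XtVX)[2, 2] * s2))
  }
  for (v in 1:2) {
    y <- 1 / (1 + abs(B[ij[, 1], v] - B[ij[, 2], v]))
    o <- dense_reml(y)
    expect_equal(res$estimate[v], o$beta, tolerance = 1e-3)
    expect_equal(res$se[v], o$se, tolerance = 5e-3)
  }
})

test_that("multi-membership REML agrees with lme4 on a custom Z", {
  skip_if_not_installed("lme4")
  n <- 8
  phi <- with_seed_test(41, rnorm(n, 0, 4))
  alp <- with_seed_test(42, rnorm(n))
  B <- with_seed_test(43, matrix(rnorm(n), n, 1) + 0.8 * phi)
  ps <- similarity_matrix(phi); as_ <- similarity_matrix(alp)
  res <- dyadic_regress_voxelwise(B, ps, as_, method = "lmm")
  ij <- harmalloc:::dyad_index(n)
  D <- nrow(ij)
  # g is a placeholder factor whose only job is to give the random term n
  # levels; its Zt is replaced by the true multi-membership incidence below
  dd <- data.frame(y = 1 / (1 + abs(B[ij[, 1], 1] - B[ij[, 2], 1])),
                   x1 = ps[ij], x2 = as_[ij],
                   g = factor(rep(1:n, length.out = D)))
  lf <- lme4::lFormula(y ~ x1 + x2 + (1 | g), data = dd,
                       control = lme4::lmerControl(
                         check.nobs.vs.nlev = "ignore",
                         check.nobs.vs.nRE = "ignore"))
  Z <- matrix(0, D, n)
  Z[cbind(1:D, ij[, 1])] <- 1
  Z[cbind(1:D, ij[, 2])] <- 1
  lf$reTrms$Zt <- methods::as(Matrix::Matrix(t(Z), sparse = TRUE), "CsparseMatrix")
  devfun <- do.call(lme4::mkLmerDevfun, lf)
  opt <- lme4::optimizeLmer(devfun)
  fit <- lme4::mkMerMod(environment(devfun), opt, lf$reTrms, fr = lf$fr)
  expect_equal(res$estimate[1], unname(lme4::fixef(fit)["x1"]),
               tolerance = 1e-4)
  expect_equal(res$se[1],
               unname(sqrt(diag(as.matrix(vcov(fit))))[2]), tolerance = 1e-3)
})

test_that("planted signal voxel is detected and zero-variance voxels flagged", {
  n <- 12
  phi <- with_seed_test(51, rnorm(n, -10, 8))
  alp <- with_seed_test(52, runif(n, 0.6, 1))
  # voxel 1: neural similarity equals phi similarity exactly (beta = phi);
  # voxel 2: pure noise; voxel 3: identical betas (zero variance)
  B <- cbind(phi, with_seed_test(53, rnorm(n, 0, 5)), rep(2, n))
  res <- dyadic_regress_voxelwise(B, similarity_matrix(phi),
                                  similarity_matrix(alp))
  expect_equal(res$estimate[1], 1, tolerance = 1e-6)
  expect_lt(res$p[1], 1e-10)
  expect_gt(res$p[2], 0.001)
  expect_true(res$undefined[3])
  expect_true(is.na(res$p[3]))
})

test_that("subject-level permutation p agrees with the planted structure", {
  n <- 10
  phi <- with_seed_test(61, rnorm(n, 0, 5))
  alp <- with_seed_test(62, rnorm(n))
  B <- cbind(phi + with_seed_test(63, rnorm(n, 0, 0.3)),
             with_seed_test(64, rnorm(n)))
  res <- dyadic_regress_voxelwise(B, similarity_matrix(phi),
                                  similarity_matrix(alp), n_perm = 99,
                                  seed = 5)
  expect_lt(res$p_perm[1], 0.05)
  expect_gt(res$p_perm[2], 0.05)
})
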