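# Background statistics and covariance conditioning.

cube_from_matrix <- function(x) {
  # wrap an n x 3 matrix as a 1 x n x 1 x 3 hypercube + all-true mask
  v <- array(0, dim = c(1, nrow(x), 1, 3))
  v[1, , 1, ] <- x
  list(cube = hypercube(v), mask = array(TRUE, dim = c(1, nrow(x), 1)))
}

test_that("estimated covariance approaches the truth on Gaussian draws", {
  sigma <- matrix(c(4, 1, 0.5, 1, 2, 0.3, 0.5, 0.3, 1), 3, 3)
  set.seed(41)
  x <- MASS::mvrnorm(10000, mu = c(10, 20, 30), Sigma = sigma)
  cm <- cube_from_matrix(x)
  est <- estimate_stats(cm$cube, cm$mask)
  err <- norm(est$cov$matrix - sigma, "F") / norm(sigma, "F")
  expect_lt(err, 0.05)
  expect_equal(unname(est$stats$mu), colMeans(x), tolerance = 1e-10)
})

test_that("two-voxel covariance matches the outer-product closed form", {
  x <- rbind(c(1, 2, 3), c(5, 0, 7))
  cm <- cube_from_matrix(rbind(x, x, x, x, x, x, x, x, x, x,
                               x, x, x, x, x, x, x, x, x, x,
                               x, x, x, x, x))   # 50 voxels, 2 distinct
  est <- estimate_stats(cm$cube, cm$mask)
  d <- (x[1, ] - x[2, ]) / 2
  # population convention: mean of the two outer products = d d'
  expect_equal(est$cov$matrix, outer(d, d), tolerance = 1e-12)
})

test_that("degenerate channels and tiny masks reject the patient", {
  x <- cbind(rnorm(100), rnorm(100), rep(5, 100))
  cm <- cube_from_matrix(x)
  expect_error(estimate_stats(cm$cube, cm$mask), class = "bpscr_reject")
  small <- cube_from_matrix(matrix(rnorm(30), 10, 3))
  expect_error(estimate_stats(small$cube, small$mask),
               class = "bpscr_reject")
})

test_that("PC filtering discards low-eigenvalue components", {
  cov <- cov_estimate(diag(c(100, 10, 0.1)))
  pf <- pc_filter(cov, 0.01)
  expect_equal(pf$kept_components, c(1L, 2L))   # 0.1 < 0.01 * 100
  inv <- bpscr:::cov_inverse(pf)
  expect_equal(inv, diag(c(0.01, 0.1, 0)), tolerance = 1e-12)

  idf <- pc_filter(cov_estimate(diag(3)), 0.01)
  expect_equal(idf$kept_components, 1:3)
  expect_equal(idf$matrix, diag(3), tolerance = 1e-12)
})

test_that("rank-one matrices keep one component with a true pseudo-inverse", {
  v <- c(1, 2, 3)
  m <- outer(v, v)
  pf <- pc_filter(cov_estimate(m), 0.01)
  expect_length(pf$kept_components, 1L)
  inv <- bpscr:::cov_inverse(pf)
  # Moore-Penrose on the kept subspace: m %*% inv %*% m == m
  expect_equal(m %*% inv %*% m, m, tolerance = 1e-8)
})

test_that("with a tiny keep fraction the filtered inverse is the plain one", {
  for (seed in 1:10) {
    m <- random_spd(seed)
    pf <- pc_filter(cov_estimate(m), 1e-12)
    expect_lt(norm(bpscr:::cov_inverse(pf) - solve(m), "F"), 1e-8)
  }
})

test_that("shrinkage endpoints and midpoint behave exactly", {
  m <- matrix(c(4, 1, 0.5, 1, 2, 0.3, 0.5, 0.3, 1), 3, 3)
  cov <- cov_estimate(m)
  expect_equal(shrink(cov, "IDENTITY", 0)$matrix, m)
  full <- shrink(cov, "IDENTITY", 1)$matrix
  expect_equal(full, diag(rep(sum(diag(m)) / 3, 3)))
  expect_equal(kappa(full, exact = TRUE), 1)
  half <- shrink(cov, "DIAG", 0.5)$matrix
  expect_equal(half, 0.5 * m + 0.5 * diag(diag(m)))
  expect_equal(shrink(cov, "DIAG", 1)$method, "MOD_REG")
  expect_equal(shrink(cov, "IDENTITY", 0.3)$method, "REG")
})

test_that("identity-target shrinkage never worsens the condition number", {
  grid <- seq(0, 1, by = 0.05)
  for (seed in 1:100) {
    m <- random_spd(seed, jitter = 0.01)
    cov <- cov_estimate(m)
    conds <- vapply(grid, function(g)
      kappa(shrink(cov, "IDENTITY", g)$matrix, exact = TRUE), numeric(1))
    expect_true(all(diff(conds) <= 1e-8))
  }
})

test_that("gamma selection prefers no shrinkage for abundant clean data", {
  set.seed(43)
  x <- MASS::mvrnorm(10000, c(0, 0, 0),
                     matrix(c(4, 1, 0.5, 1, 2, 0.3, 0.5, 0.3, 1), 3, 3))
  g <- select_gamma(x, "IDENTITY", seed = 5)
  sc <- attr(g, "scores")
  expect_gt(sc[1], sc[length(sc)])   # gamma = 0 beats gamma = 1
  expect_lte(g, 0.1)
})

test_that("gamma selection shrinks when n barely exceeds the dimension", {
  set.seed(44)
  x <- MASS::mvrnorm(8, c(0, 0, 0), diag(3))
  g <- select_gamma(x, "IDENTITY", folds = 4L, seed = 5)
  expect_gt(g, 0)
})

test_that("gamma selection is deterministic under a fixed seed", {
  set.seed(45)
  x <- MASS::mvrnorm(300, c(0, 0, 0), random_spd(9))
  expect_identical(as.numeric(select_gamma(x, "DIAG", seed = 7)),
                   as.numeric(select_gamma(x, "DIAG", seed = 7)))
})

test_that("EVM shrinks the ellipsoid and resists planted outliers", {
  set.seed(46)
  clean <- MASS::mvrnorm(1000, c(0, 0, 0), diag(3))
  ev <- evm(clean, seed = 3)
  expect_lte(det(ev$cov$matrix), det(bpscr:::pop_cov(clean)))

  # 10% outliers at 10 sigma
  n_out <- 100
  out <- MASS::mvrnorm(n_out, c(10, 10, 10), diag(3))
  x <- rbind(MASS::mvrnorm(900, c(0, 0, 0), diag(3)), out)
  full_mu <- colMeans(x)
  full_cov <- bpscr:::pop_cov(x)
  ev2 <- evm(x, seed = 4)
  # random 10%-deletion removes ~10-20% of the outliers in its best trial,
  # so the volume shrinks but not drastically
  expect_lt(det(ev2$cov$matrix), det(full_cov))
  d_evm <- sqrt(sum(ev2$stats$mu^2))      # inlier mean is the origin
  d_full <- sqrt(sum(full_mu^2))
  expect_lt(d_evm, d_full)
})

test_that("EVM ignores voxel input order and reproduces under a seed", {
  set.seed(47)
  x <- MASS::mvrnorm(300, c(1, 2, 3), random_spd(2))
  a <- evm(x, trials = 50L, seed = 9)
  b <- evm(x[sample(nrow(x)), ], trials = 50L, seed = 9)
  expect_equal(a$cov$matrix, b$cov$matrix)
  expect_equal(a$stats$mu, b$stats$mu)
  c1 <- evm(x, trials = 1L, seed = 10)
  c2 <- evm(x, trials = 1L, seed = 10)
  expect_identical(c1$cov$matrix, c2$cov$matrix)
})

test_that("the z-score covariance is the diagonal of squared sigmas", {
  st <- list(sigma = c(ADC = 2, HBV = 3, T2 = 4))
  zc <- zscore_covariance(st)
  expect_equal(zc$matrix, diag(c(4, 9, 16)))
  expect_equal(zc$method, "ZSCORE_DIAG")
  expect_true(all(zc$matrix[upper.tri(zc$matrix)] == 0))
  expect_equal(zscore_covariance(list(sigma = c(1, 1, 1)))$matrix, diag(3))
})

test_that("all conditioned variants stay symmetric PSD and tagged", {
  set.seed(48)
  x <- MASS::mvrnorm(400, c(1200, 120, 400),
                     diag(c(250, 30, 90)) %*% default_channel_corr() %*%
                       diag(c(250, 30, 90)))
  cm <- cube_from_matrix(x)
  bg <- background_variants(cm$cube, cm$mask, seed = 2, evm_trials = 30L)
  expect_setequal(names(bg$covs),
                  c("UNTRANSFORMED", "ELLIPTIC", "PC_FILTER", "REG",
                    "MOD_REG", "ZSCORE_DIAG"))
  for (nm in names(bg$covs)) {
    m <- bg$covs[[nm]]$matrix
    expect_equal(m, t(m), tolerance = 1e-10)
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) > -1e-10 * max(ev))
    expect_equal(bg$covs[[nm]]$method, nm)
  }
  expect_true(bg$covs$REG$gamma >= 0 && bg$covs$REG$gamma <= 1)
})
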