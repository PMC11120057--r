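# Thresholding, morphology, labeling, size filter, blob and window stats.

as_green <- function(a) structure(a, class = "green_image")

test_that("thresholding includes the boundary and respects the mask", {
  g <- array(0, dim = c(1, 3, 3))
  g[1, 1, 1] <- 0.90; g[1, 1, 2] <- 0.899; g[1, 1, 3] <- 0.95
  mask <- array(TRUE, dim = c(1, 3, 3)); mask[1, 1, 3] <- FALSE
  b <- threshold_green(as_green(g), mask, 0.90)
  expect_true(b[1, 1, 1])        # >= convention at the boundary
  expect_false(b[1, 1, 2])
  expect_false(b[1, 1, 3])       # above threshold but out of mask
  expect_false(any(threshold_green(as_green(array(0, c(1, 3, 3))), mask)))
})

test_that("morphology removes strings, keeps squares, matches the oracle", {
  m <- matrix(FALSE, 20, 20)
  m[3, 3:10] <- TRUE                      # 1-voxel-wide string, length 8
  sq <- matrix(FALSE, 20, 20)
  sq[8:12, 8:12] <- TRUE                  # solid 5x5 square
  for (fix in list(m, sq, m | sq, matrix(FALSE, 20, 20))) {
    vol <- array(fix, dim = c(1, 20, 20))
    got <- morph_clean(vol)[1, , ]
    want <- oracle_dilate33(oracle_erode22(fix))
    expect_identical(got, want)
  }
  expect_false(any(morph_clean(array(m, dim = c(1, 20, 20)))))  # string dies
  sq_clean <- morph_clean(array(sq, dim = c(1, 20, 20)))[1, , ]
  expect_true(sum(sq_clean) > 0)                                # square lives
})

test_that("erosion output is a subset of the input and of the dilation", {
  set.seed(21)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.4, 20, 20)
    er <- oracle_erode22(m)
    expect_true(all(!er | m))                       # erosion subset of input
    di <- bpscr:::dilate33(er)
    expect_true(all(!er | di))                      # erosion subset of dilation
  }
})

test_that("labeling is 8-connected per slice with no through-slice links", {
  b <- array(FALSE, dim = c(2, 4, 4))
  b[1, 1, 1] <- TRUE; b[1, 2, 2] <- TRUE            # diagonal touch
  blobs <- label_blobs(b)
  expect_length(blobs, 1L)
  expect_equal(blobs[[1]]$size, 2L)

  b2 <- array(FALSE, dim = c(2, 4, 4))
  b2[1, 2, 2] <- TRUE; b2[2, 2, 2] <- TRUE          # identical across slices
  expect_length(label_blobs(b2), 2L)
  expect_length(label_blobs(b2, "3d26"), 1L)        # 3D mode links them
})

test_that("labeling agrees with a flood-fill oracle on random slices", {
  set.seed(22)
  for (i in 1:100) {
    m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.6), 32, 32)
    vol <- array(m, dim = c(1, 32, 32))
    blobs <- label_blobs(vol)
    ref <- oracle_label_slice(m)
    expect_equal(length(blobs), max(ref))
    # identical partition: same voxel sets
    got_sets <- lapply(blobs, function(b)
      sort(b$voxels[, 2] * 1000 + b$voxels[, 3]))
    ref_sets <- lapply(seq_len(max(ref)), function(l) {
      w <- which(ref == l, arr.ind = TRUE)
      sort(w[, 1] * 1000 + w[, 2])
    })
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(ref_sets, paste, character(1), collapse = ","))
  }
})

test_that("the size filter keeps only blobs of at least min_size voxels", {
  b <- array(FALSE, dim = c(1, 20, 40))
  b[1, 2:12, 2] <- TRUE                      # 11 voxels
  b[1, 2:13, 10] <- TRUE                     # 12 voxels
  b[1, 2:9, 20:24] <- TRUE                   # 40 voxels
  blobs <- label_blobs(b)
  kept <- filter_small(blobs, 12L)
  expect_equal(sort(vapply(kept, function(x) x$size, integer(1))), c(12L, 40L))
  expect_length(filter_small(list(), 12L), 0L)
  expect_length(filter_small(blobs, 1L), 3L)
  expect_true(sum(vapply(kept, function(x) x$size, integer(1))) <=
              sum(vapply(blobs, function(x) x$size, integer(1))))
})

test_that("blob statistics use the population convention", {
  g <- array(0, dim = c(1, 5, 5))
  g[1, 2, 2] <- 0.8; g[1, 2, 3] <- 1.0
  mask <- array(TRUE, dim = c(1, 5, 5))
  blob <- list(id = 1L, slice = 1L, size = 2L,
               voxels = cbind(c(1L, 1L), c(2L, 2L), c(2L, 3L)))
  st <- blob_statistics(blob, as_green(g), mask, spacing = c(3, 1, 1))
  expect_equal(st$mean_green, 0.9)
  expect_equal(st$std_green, 0.1)            # divide-by-n, not n-1
  expect_equal(st$blob_cov, 9)
  expect_false(st$cov_flagged)
})

test_that("constant blobs flag the epsilon-floored covariance", {
  g <- array(0.7, dim = c(1, 5, 5))
  mask <- array(TRUE, dim = c(1, 5, 5))
  blob <- list(id = 1L, slice = 1L, size = 3L,
               voxels = cbind(rep(1L, 3), 2:4, rep(2L, 3)))
  st <- blob_statistics(blob, as_green(g), mask, c(3, 1, 1))
  expect_true(st$cov_flagged)
  expect_equal(st$blob_cov, 0.7 / 1e-6)
})

test_that("eccentricity separates discs from elongated blobs", {
  mk <- function(vox) list(id = 1L, slice = 1L, size = nrow(vox), voxels = vox)
  g <- as_green(array(0.5, dim = c(1, 30, 30)))
  mask <- array(TRUE, dim = c(1, 30, 30))
  # filled disc radius 6
  rc <- as.matrix(expand.grid(r = 1:30, c = 1:30))
  disc <- rc[(rc[, 1] - 15)^2 + (rc[, 2] - 15)^2 <= 36, ]
  st_disc <- blob_statistics(mk(cbind(1L, disc)), g, mask, c(3, 1, 1))
  expect_lt(st_disc$eccentricity, 0.1)
  line <- cbind(1L, 5:25, 7L)
  st_line <- blob_statistics(mk(line), g, mask, c(3, 1, 1))
  expect_gt(st_line$eccentricity, 0.99)
})

test_that("a 3x3 window reproduces the 9-value hand computation", {
  g <- array(0, dim = c(1, 5, 5))
  g[1, 2:4, 2:4] <- 0.9
  g[1, 3, 3] <- 1.0
  mask <- array(TRUE, dim = c(1, 5, 5))
  vox <- as.matrix(expand.grid(s = 1L, r = 2:4, c = 2:4))
  colnames(vox) <- NULL
  blob <- list(id = 1L, slice = 1L, size = 9L, voxels = vox)
  st <- sliding_window_stats(blob, as_green(g), mask)
  w <- c(rep(0.9, 8), 1.0)
  mu <- mean(w)                              # (8*0.9 + 1)/9 = 0.91111...
  sd9 <- sqrt(mean((w - mu)^2))
  ctr <- st$windows[st$windows$row == 3 & st$windows$col == 3, ]
  expect_equal(ctr$mean, mu, tolerance = 1e-12)
  expect_equal(ctr$std, sd9, tolerance = 1e-12)
  expect_equal(mu, 0.911111, tolerance = 1e-6)
})

test_that("windows need 9 in-mask voxels, with a greenest-voxel fallback", {
  g <- array(0, dim = c(1, 4, 4))
  g[1, 1, 1] <- 0.5; g[1, 1, 2] <- 0.9; g[1, 2, 1] <- 0.7
  mask <- array(FALSE, dim = c(1, 4, 4))
  mask[1, 1:2, 1:2] <- TRUE                  # too thin for any full window
  vox <- cbind(c(1L, 1L, 1L), c(1L, 1L, 2L), c(1L, 2L, 1L))
  blob <- list(id = 1L, slice = 1L, size = 3L, voxels = vox)
  st <- sliding_window_stats(blob, as_green(g), mask)
  expect_true(st$win_fallback)
  expect_equal(st$win_best_center, c(1L, 1L, 2L))  # argmax green
})

test_that("the best window center is always a voxel of its blob", {
  set.seed(23)
  for (i in 1:20) {
    g <- array(runif(6 * 16 * 16), dim = c(6, 16, 16))
    mask <- array(TRUE, dim = c(6, 16, 16))
    bin <- g > 0.6
    blobs <- filter_small(label_blobs(bin), 5L)
    for (b in blobs) {
      st <- sliding_window_stats(b, as_green(g), mask)
      hit <- any(st$voxels[, 1] == st$win_best_center[1] &
                 st$voxels[, 2] == st$win_best_center[2] &
                 st$voxels[, 3] == st$win_best_center[3])
      expect_true(hit)
    }
  }
})

test_that("detect_blobs can compute statistics on a separate green image", {
  set.seed(24)
  det <- array(0, dim = c(1, 12, 12))
  det[1, 3:8, 3:8] <- 0.95                  # detection image: one clear blob
  raw <- array(runif(144, 0.2, 0.4), dim = c(1, 12, 12))
  mask <- array(TRUE, dim = c(1, 12, 12))
  blobs <- detect_blobs(as_green(det), mask, stats_green = as_green(raw))
  expect_length(blobs, 1L)
  expect_lt(blobs[[1]]$mean_green, 0.5)      # stats came from raw, not det
})
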