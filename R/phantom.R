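# Synthetic bi-parametric MRI phantoms: ellipsoidal prostate, correlated
# 3-channel Gaussian background, planted ellipsoidal lesions whose contrast
# scales with grade (hypointense in ADC and T2, hyperintense in HBV).

#' Default inter-channel background correlation
#'
#' Positive couplings dominated by tissue composition: glandular density
#' drives ADC, T2 and (through the unattenuated baseline signal) HBV in the
#' same direction across normal prostate voxels, with the strongest link
#' between ADC and T2. The tumor pattern (ADC down, HBV up, T2 down) runs
#' against this common mode, which is exactly why whitening by the
#' background covariance amplifies it relative to the plain z-score.
#'
#' @return 3x3 correlation matrix (ADC, HBV, T2).
#' @export
default_channel_corr <- function() {
  m <- matrix(c(1, 0.25, 0.65,
                0.25, 1, 0.50,
                0.65, 0.50, 1), 3, 3, byrow = TRUE)
  dimnames(m) <- list(CHANNEL_IDS, CHANNEL_IDS)
  m
}

# ellipsoid indicator on an integer grid
ellipsoid_mask <- function(shape, center, radii) {
  z <- (seq_len(shape[1]) - center[1]) / radii[1]
  y <- (seq_len(shape[2]) - center[2]) / radii[2]
  x <- (seq_len(shape[3]) - center[3]) / radii[3]
  arr <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  arr <= 1
}

# small separable in-plane Gaussian blur (partial-volume effect)
blur_inplane <- function(a, sigma = 0.7) {
  if (sigma <= 0) return(a)
  half <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(a)
  conv1 <- function(m, along) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      off <- j - half - 1L
      if (along == 1) {
        src <- pmin(pmax(seq_len(nrow(m)) + off, 1L), nrow(m))
        out <- out + k[j] * m[src, , drop = FALSE]
      } else {
        src <- pmin(pmax(seq_len(ncol(m)) + off, 1L), ncol(m))
        out <- out + k[j] * m[, src, drop = FALSE]
      }
    }
    out
  }
  for (s in seq_len(d[1]))
    a[s, , ] <- conv1(conv1(a[s, , ], 1), 2)
  a
}

#' Generate one bi-parametric MRI phantom
#'
#' Builds an ellipsoidal prostate mask inside the volume, fills the volume
#' with correlated 3-channel Gaussian background noise at channel means and
#' standard deviations typical in magnitude of (ADC, HBV, T2), and, for
#' grade > 0, plants one ellipsoidal lesion at a random feasible position
#' wholly inside the mask. The lesion shifts each channel mean by
#' `grade * contrast_per_grade * sigma` (negative ADC and T2, positive
#' HBV), and its indicator is blurred in-plane to emulate partial-volume
#' averaging (the interior keeps the full shift). Grade 0 plants no lesion.
#'
#' Two further features emulate real bi-parametric data. First, the noise
#' field is smoothed in-plane by a small point-spread function and rescaled
#' back to nominal variance: MRI noise is spatially correlated after
#' acquisition filtering and grid resampling, and without that coherence no
#' normal gland would ever produce a candidate blob. Second, every patient
#' carries a few benign focal nodules with the same tumor-like channel
#' polarity but sub-clinical amplitude (BPH-like mimics), so the clinically
#' insignificant class is scored rather than silently dropped, and the
#' planted lesion is heterogeneous: its contrast is modulated by a smooth
#' multiplicative field, as in real tumors whose cellularity varies --
#' which is what the sliding-window search is designed for. An optional
#' incoherent HBV-only distractor is available for ranking experiments.
#'
#' @param shape volume shape `(slices, rows, cols)`, default `c(12, 48, 48)`.
#' @param grade integer ISUP grade 0..5.
#' @param contrast_per_grade per-grade channel shift in background-sigma
#'   units, default `c(-0.8, 0.8, -0.6)` for (ADC, HBV, T2).
#' @param corr 3x3 inter-channel correlation (symmetric PSD, unit diagonal).
#' @param seed integer seed; same seed, same phantom.
#' @param spacing `(dz, dy, dx)` mm, default `c(3, 1, 1)`.
#' @param channel_means,channel_sds background means and standard
#'   deviations per channel.
#' @param lesion_radii lesion semi-axes in voxels `(slice, row, col)` at
#'   grade 1; radii grow by `lesion_growth` per further grade step, since
#'   higher-grade tumors are typically larger.
#' @param lesion_growth fractional radius growth per grade above 1
#'   (default 0.08).
#' @param benign_radii benign nodule semi-axes in voxels.
#' @param mask_radii prostate semi-axes in voxels.
#' @param blur_sigma in-plane partial-volume blur of planted indicators.
#' @param benign_nodules number of benign mimic nodules per patient
#'   (default 2).
#' @param benign_amplitude range (in units of the per-grade contrast, i.e.
#'   "grade equivalents") of the benign nodule amplitude; default
#'   `c(0.7, 1.2)`, overlapping grade-1 disease but below grade 2.
#' @param smooth_frac fraction of the background variance carried by a
#'   spatially coherent textural component (default 0.4); the remainder is
#'   voxelwise thermal noise.
#' @param smooth_sigma in-plane correlation length (voxels) of the
#'   coherent component (default 0.8, below the blob size filter scale so
#'   pure-noise structures are mostly removed by morphology and the
#'   12-voxel minimum).
#' @param heterogeneity relative standard deviation of the smooth
#'   multiplicative contrast modulation inside the carcinoma (default
#'   0.4); benign nodules stay homogeneous, as well-circumscribed BPH
#'   nodules are.
#' @param distractor plant an additional HBV-only hyperintense blob (high
#'   green but less coherent) to exercise blob ranking; default `FALSE`.
#' @return list with `cube` (a [hypercube()]), `mask` (logical array) and
#'   `truth` (list: `lesion` logical array, `benign` logical array,
#'   `grade`, `contrast`, `seed`).
#' @export
make_phantom <- function(shape = c(16L, 64L, 64L), grade = 0L,
                         contrast_per_grade = c(-0.8, 0.8, -0.6),
                         corr = default_channel_corr(), seed = 1L,
                         spacing = c(3, 1, 1),
                         channel_means = c(1200, 120, 400),
                         channel_sds = c(250, 30, 90),
                         lesion_radii = c(1.4, 4, 4), lesion_growth = 0.08,
                         mask_radii = NULL, blur_sigma = 0.5,
                         benign_nodules = 3L, benign_radii = c(1.2, 4, 4),
                         benign_amplitude = c(0.7, 1.2),
                         smooth_frac = 0.4, smooth_sigma = 0.8,
                         heterogeneity = 0.4,
                         distractor = FALSE) {
  stopifnot(grade %in% 0:5)
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)) ||
      any(abs(diag(corr) - 1) > 1e-10) ||
      min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("'corr' must be symmetric PSD with unit diagonal")
  if (is.null(mask_radii))
    mask_radii <- c(0.38, 0.36, 0.36) * shape
  center <- (shape + 1) / 2
  mask <- ellipsoid_mask(shape, center, mask_radii)

  sigma_mat <- diag(channel_sds) %*% corr %*% diag(channel_sds)
  nvox <- prod(shape)
  with_seed(seed, {
    noise <- MASS::mvrnorm(nvox, mu = channel_means, Sigma = sigma_mat)
    vals <- array(noise, dim = c(shape, 3L))
    if (smooth_frac > 0) {
      # two-component background: smooth anatomical variation plus
      # voxelwise thermal noise, each channel keeping nominal variance
      smooth <- MASS::mvrnorm(nvox, mu = c(0, 0, 0), Sigma = sigma_mat)
      smooth <- array(smooth, dim = c(shape, 3L))
      half <- max(1L, ceiling(2 * smooth_sigma))
      k <- exp(-((-half):half)^2 / (2 * smooth_sigma^2))
      k <- k / sum(k)
      shrink_sd <- sum(k^2)            # sd shrink factor over the 2 in-plane axes
      for (ch in 1:3)
        smooth[, , , ch] <- blur_inplane(smooth[, , , ch, drop = TRUE],
                                         smooth_sigma) / shrink_sd
      vals <- sweep(vals, 4, channel_means) * sqrt(1 - smooth_frac) +
        smooth * sqrt(smooth_frac)
      vals <- sweep(vals, 4, channel_means, `+`)
    }
    # smooth multiplicative modulation shared by all planted structures
    het <- if (heterogeneity > 0) {
      f <- blur_inplane(array(stats::rnorm(nvox), dim = shape), 1.2)
      f <- f / stats::sd(f)
      pmax(1 + heterogeneity * f, 0.2)
    } else array(1, dim = shape)
    lesion <- array(FALSE, dim = shape)
    if (grade > 0L) {
      lesion_radii <- lesion_radii * (1 + lesion_growth * (grade - 1))
      # feasible centers: lesion ellipsoid must fit inside the mask ellipsoid
      feas <- ellipsoid_mask(shape, center,
                             pmax(mask_radii - lesion_radii - 0.5, 0.5))
      cand <- which(feas, arr.ind = TRUE)
      if (nrow(cand) == 0L)
        stop("lesion does not fit inside the prostate mask")
      ctr <- cand[sample.int(nrow(cand), 1L), ]
      lesion <- ellipsoid_mask(shape, ctr, lesion_radii)
      if (!all(mask[lesion]))
        stop("lesion does not fit inside the prostate mask")
      ind <- blur_inplane(array(as.numeric(lesion), dim = shape),
                          blur_sigma) * het
      for (k in 1:3)
        vals[, , , k] <- vals[, , , k] +
          grade * contrast_per_grade[k] * channel_sds[k] * ind
    }
    benign <- array(FALSE, dim = shape)
    if (benign_nodules > 0L) {
      nod_radii <- benign_radii
      # keep nodules clear of the lesion so blobs stay distinct
      excl <- if (any(lesion)) blur_inplane(array(as.numeric(lesion),
                                                  dim = shape), 1.5) > 0.01
              else array(FALSE, dim = shape)
      for (j in seq_len(benign_nodules)) {
        feas <- ellipsoid_mask(shape, center,
                               pmax(mask_radii - nod_radii - 0.5, 0.5))
        feas <- feas & !excl & !benign
        cand <- which(feas, arr.ind = TRUE)
        if (nrow(cand) == 0L) break
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        nod <- ellipsoid_mask(shape, ctr, nod_radii) & mask & !lesion
        amp <- stats::runif(1, benign_amplitude[1], benign_amplitude[2])
        # benign nodules are homogeneous (well-circumscribed BPH-like),
        # unlike the heterogeneous carcinoma
        ind <- blur_inplane(array(as.numeric(nod), dim = shape), blur_sigma)
        for (k in 1:3)
          vals[, , , k] <- vals[, , , k] +
            amp * contrast_per_grade[k] * channel_sds[k] * ind
        benign <- benign | nod
      }
    }
    if (distractor) {
      feas <- ellipsoid_mask(shape, center,
                             pmax(mask_radii - c(1, 2.5, 2.5) - 0.5, 0.5))
      feas <- feas & !lesion & !benign
      cand <- which(feas, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ctr <- cand[sample.int(nrow(cand), 1L), ]
        db <- ellipsoid_mask(shape, ctr, c(1, 2.5, 2.5)) & !lesion
        # HBV-only lift plus extra voxelwise roughness: green but incoherent
        vals[, , , 2][db] <- vals[, , , 2][db] +
          2.5 * channel_sds[2] + stats::rnorm(sum(db), 0, 1.5 * channel_sds[2])
      }
    }
  })
  cube <- hypercube(vals, spacing = spacing)
  truth <- list(lesion = lesion, benign = benign, grade = as.integer(grade),
                contrast = contrast_per_grade, seed = as.integer(seed))
  list(cube = cube, mask = mask, truth = truth)
}

#' Default cohort grade distribution
#'
#' 42 patients with grade multiset {0: 14, 1: 10, 2: 8, 3: 5, 4: 3, 5: 2},
#' giving a mean grade near the study population's 1.12. For other cohort
#' sizes the counts are scaled proportionally (largest remainders win the
#' leftover patients).
#'
#' @param n cohort size (default 42).
#' @return named integer vector (names are grades "0".."5") summing to `n`.
#' @export
default_grade_distribution <- function(n = 42L) {
  base <- c("0" = 14L, "1" = 10L, "2" = 8L, "3" = 5L, "4" = 3L, "5" = 2L)
  if (n == 42L) return(base)
  exact <- base * n / 42
  cnt <- floor(exact)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(exact - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }
  stats::setNames(as.integer(cnt), names(base))
}

#' Generate a synthetic patient cohort
#'
#' Independent phantoms with per-patient seeds derived from the master seed;
#' the same master seed reproduces the identical cohort.
#'
#' @param n number of patients (default 42).
#' @param grade_distribution named counts over grades "0".."5", summing to
#'   `n`.
#' @param seed master integer seed.
#' @param ... further arguments to [make_phantom()].
#' @return list of `n` phantoms (each as returned by [make_phantom()]),
#'   with a `manifest` attribute (data.frame: patient_id, grade, seed).
#' @export
make_cohort <- function(n = 42L, grade_distribution = default_grade_distribution(),
                        seed = 1L, ...) {
  if (sum(grade_distribution) != n)
    stop("grade distribution must sum to n")
  grades <- rep(as.integer(names(grade_distribution)), grade_distribution)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  cohort <- vector("list", n)
  for (i in seq_len(n))
    cohort[[i]] <- make_phantom(grade = grades[i], seed = seeds[i], ...)
  attr(cohort, "manifest") <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), grade = grades, seed = seeds)
  cohort
}
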