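# Normal-prostate background statistics and the conditioned covariance
# variants feeding the SCR: untransformed, PC-filtered, shrinkage-regularized
# (identity / diagonal targets), elliptical-volume-minimized, and the
# diagonal z-score matrix.

COV_METHODS <- c("UNTRANSFORMED", "ELLIPTIC", "PC_FILTER", "REG", "MOD_REG",
                 "ZSCORE_DIAG")

#' Covariance estimate container
#'
#' @param matrix 3x3 symmetric PSD matrix.
#' @param method one of `"UNTRANSFORMED"`, `"ELLIPTIC"`, `"PC_FILTER"`,
#'   `"REG"`, `"MOD_REG"`, `"ZSCORE_DIAG"`.
#' @param gamma shrinkage mixing parameter (REG/MOD_REG), or `NA`.
#' @param kept_components kept principal components (PC_FILTER), or `NULL`.
#' @return object of class `cov_estimate`.
#' @export
cov_estimate <- function(matrix, method = "UNTRANSFORMED", gamma = NA_real_,
                         kept_components = NULL) {
  method <- match.arg(method, COV_METHODS)
  matrix <- unname(as.matrix(matrix))
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-10)))
    stop("covariance matrix must be symmetric")
  matrix <- (matrix + t(matrix)) / 2
  structure(list(matrix = matrix, method = method, gamma = gamma,
                 kept_components = kept_components),
            class = "cov_estimate")
}

# masked voxels as an n x 3 matrix of (ADC, HBV, T2) values
masked_vectors <- function(cube, mask) {
  idx <- which(mask)
  n <- prod(dim(mask))
  cbind(cube$values[idx], cube$values[idx + n], cube$values[idx + 2 * n])
}

# population (divide-by-n) covariance
pop_cov <- function(x) {
  n <- nrow(x)
  cc <- sweep(x, 2, colMeans(x))
  crossprod(cc) / n
}

#' Estimate background statistics over the prostate
#'
#' Per-channel means and population standard deviations plus the 3x3
#' population covariance over all masked voxels. A patient with fewer than
#' 50 mask voxels or a degenerate (zero-variance) channel is rejected.
#'
#' @param cube a [hypercube()].
#' @param mask logical prostate mask.
#' @return list with `stats` (list `mu`, `sigma`, `n_voxels`) and `cov`
#'   (a [cov_estimate()] tagged `UNTRANSFORMED`).
#' @export
estimate_stats <- function(cube, mask) {
  x <- masked_vectors(cube, mask)
  if (nrow(x) < 50L)
    stop_reject("fewer than 50 prostate voxels: patient rejected")
  mu <- colMeans(x)
  cm <- pop_cov(x)
  sigma <- sqrt(diag(cm))
  if (any(sigma <= 0))
    stop_reject("degenerate (constant) channel in background: patient rejected")
  names(mu) <- names(sigma) <- CHANNEL_IDS
  list(stats = list(mu = mu, sigma = sigma, n_voxels = nrow(x)),
       cov = cov_estimate(cm, "UNTRANSFORMED"))
}

#' Principal-component filtering of the covariance
#'
#' Eigendecomposes the covariance and discards noisy components with
#' eigenvalue below `keep_frac` times the largest eigenvalue. The filtered
#' matrix is the reconstruction over kept components; downstream whitening
#' uses the pseudo-inverse over those components only.
#'
#' @param cov a [cov_estimate()].
#' @param keep_frac fraction `f` of the leading eigenvalue below which a
#'   component is discarded (default 0.01).
#' @return a [cov_estimate()] tagged `PC_FILTER` with `kept_components` and
#'   an `eigen` attribute carrying the kept eigenpairs.
#' @export
pc_filter <- function(cov, keep_frac = 0.01) {
  e <- eigen(cov$matrix, symmetric = TRUE)
  keep <- which(e$values >= keep_frac * e$values[1])
  mat <- matrix(0, 3, 3)
  for (i in keep)
    mat <- mat + e$values[i] * tcrossprod(e$vectors[, i])
  out <- cov_estimate(mat, "PC_FILTER", kept_components = keep)
  attr(out, "eigen") <- list(values = e$values, vectors = e$vectors)
  out
}

# pseudo-inverse over kept components (PC_FILTER) or plain inverse
cov_inverse <- function(cov) {
  if (cov$method == "PC_FILTER") {
    e <- attr(cov, "eigen")
    inv <- matrix(0, 3, 3)
    for (i in cov$kept_components)
      inv <- inv + tcrossprod(e$vectors[, i]) / e$values[i]
    return(inv)
  }
  ev <- eigen(cov$matrix, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop_singular("covariance matrix not invertible: patient flagged")
  solve(cov$matrix)
}

#' Shrinkage regularization of the covariance
#'
#' `CM(gamma) = (1 - gamma) * CM + gamma * D`, where the target `D` is the
#' trace-scaled identity `(tr(CM)/3) * I` for `"IDENTITY"` (regularized,
#' REG; trace-preserving so gamma is unit-free across patients) or the
#' diagonal of CM (variances) for `"DIAG"` (modified regularization,
#' MOD_REG).
#'
#' @param cov a [cov_estimate()].
#' @param target `"IDENTITY"` or `"DIAG"`.
#' @param gamma mixing parameter in `[0, 1]`.
#' @return a [cov_estimate()] tagged `REG` or `MOD_REG`.
#' @export
shrink <- function(cov, target = c("IDENTITY", "DIAG"), gamma) {
  target <- match.arg(target)
  stopifnot(gamma >= 0, gamma <= 1)
  cm <- cov$matrix
  d <- if (target == "IDENTITY") diag(rep(sum(diag(cm)) / 3, 3))
       else diag(diag(cm))
  cov_estimate((1 - gamma) * cm + gamma * d,
               if (target == "IDENTITY") "REG" else "MOD_REG", gamma = gamma)
}

#' Select the shrinkage mixing parameter
#'
#' Grid search over `gamma` in `{0, 0.05, ..., 1}` scored by the K-fold
#' held-out Gaussian discriminant: for each fold, the covariance is
#' estimated and shrunk on the training voxels and the score is the mean of
#' `-[ln det CM(gamma) + d' CM(gamma)^-1 d]` over held-out deviations `d`
#' from the training mean. The gamma maximizing the average held-out score
#' wins; ties go to the smallest gamma.
#'
#' @param voxels n x 3 matrix of masked background vectors (n >= 100).
#' @param target `"IDENTITY"` or `"DIAG"`.
#' @param grid gamma grid.
#' @param folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return selected gamma (scalar); the score curve is the
#'   `"scores"` attribute.
#' @export
select_gamma <- function(voxels, target = c("IDENTITY", "DIAG"),
                         grid = seq(0, 1, by = 0.05), folds = 5L,
                         seed = 1L) {
  target <- match.arg(target)
  n <- nrow(voxels)
  stopifnot(n > 6L)   # the usual operating point is n >= 100
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  score <- numeric(length(grid))
  for (f in seq_len(folds)) {
    tr <- voxels[fold_id != f, , drop = FALSE]
    te <- voxels[fold_id == f, , drop = FALSE]
    if (nrow(tr) < 4L || nrow(te) < 1L) next
    mu <- colMeans(tr)
    base <- cov_estimate(pop_cov(tr), "UNTRANSFORMED")
    d <- sweep(te, 2, mu)
    for (gi in seq_along(grid)) {
      cm <- shrink(base, target, grid[gi])$matrix
      ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 1e-12 * max(ev)) {
        score[gi] <- score[gi] - Inf
        next
      }
      quad <- rowSums(d * t(solve(cm, t(d))))
      score[gi] <- score[gi] - (log(prod(ev)) + mean(quad))
    }
  }
  best <- which.max(score)   # first max: ties go to the smallest gamma
  structure(grid[best], scores = score / folds)
}

#' Elliptical volume minimization (robust background estimate)
#'
#' Repeatedly drops a random `drop_frac` subset of the voxels, estimates
#' mean and covariance of the remaining voxels, and keeps the trial whose
#' covariance ellipsoid has minimal hypervolume (minimal determinant) --
#' suppressing the influence of aberrant voxels. Voxel rows are
#' canonicalized by sorting before subsampling, so the result does not
#' depend on input order.
#'
#' @param voxels n x 3 matrix of masked background vectors (n >= 100).
#' @param drop_frac fraction removed per trial (default 0.10).
#' @param trials number of random subsets (default 200).
#' @param seed integer seed.
#' @return list with `stats` (`mu`, `sigma`, `n_voxels` of the retained
#'   set) and `cov` (a [cov_estimate()] tagged `ELLIPTIC`); the winning
#'   trial index is the `"trial"` attribute.
#' @export
evm <- function(voxels, drop_frac = 0.10, trials = 200L, seed = 1L) {
  n <- nrow(voxels)
  stopifnot(n >= 100L)
  voxels <- voxels[order(voxels[, 1], voxels[, 2], voxels[, 3]), ,
                   drop = FALSE]
  n_drop <- round(drop_frac * n)
  best <- NULL
  best_det <- Inf
  best_trial <- NA_integer_
  with_seed(seed, {
    for (t in seq_len(trials)) {
      drop <- sample.int(n, n_drop)
      keep <- voxels[-drop, , drop = FALSE]
      cm <- pop_cov(keep)
      dt <- det(cm)
      if (dt < best_det) {
        best_det <- dt
        best <- keep
        best_trial <- t
      }
    }
  })
  mu <- colMeans(best)
  cm <- pop_cov(best)
  sigma <- sqrt(diag(cm))
  names(mu) <- names(sigma) <- CHANNEL_IDS
  structure(list(stats = list(mu = mu, sigma = sigma, n_voxels = nrow(best)),
                 cov = cov_estimate(cm, "ELLIPTIC")),
            trial = best_trial)
}

#' Diagonal z-score covariance
#'
#' `diag(sigma^2)`: the covariance implied by per-channel standardization,
#' ignoring inter-sequence correlation.
#'
#' @param stats background stats (list with `sigma`).
#' @return a [cov_estimate()] tagged `ZSCORE_DIAG`.
#' @export
zscore_covariance <- function(stats) {
  stopifnot(all(stats$sigma > 0))
  cov_estimate(diag(stats$sigma^2), "ZSCORE_DIAG")
}

#' All conditioned background variants for one patient
#'
#' Convenience wrapper producing the six covariance treatments from one
#' hypercube + mask: UNTRANSFORMED, ELLIPTIC (robust stats ride along),
#' PC_FILTER, REG and MOD_REG (gamma selected by [select_gamma()]),
#' ZSCORE_DIAG.
#'
#' @param cube a [hypercube()].
#' @param mask logical prostate mask.
#' @param seed integer seed (EVM subsets and gamma folds).
#' @param methods subset of the six method tags.
#' @param evm_trials,evm_drop,pc_keep_frac,gamma_grid,gamma_folds tuning
#'   parameters (defaults as in [default_config()]).
#' @return list with `stats` (baseline background stats), `evm_stats`
#'   (robust stats or NULL), and `covs` (named list of [cov_estimate()]s).
#' @export
background_variants <- function(cube, mask, seed = 1L, methods = COV_METHODS,
                                evm_trials = 200L, evm_drop = 0.10,
                                pc_keep_frac = 0.01,
                                gamma_grid = seq(0, 1, by = 0.05),
                                gamma_folds = 5L) {
  base <- estimate_stats(cube, mask)
  x <- masked_vectors(cube, mask)
  covs <- list()
  evm_stats <- NULL
  for (m in methods) {
    covs[[m]] <- switch(
      m,
      UNTRANSFORMED = base$cov,
      ZSCORE_DIAG = zscore_covariance(base$stats),
      PC_FILTER = pc_filter(base$cov, pc_keep_frac),
      REG = shrink(base$cov, "IDENTITY",
                   select_gamma(x, "IDENTITY", gamma_grid, gamma_folds,
                                seed = seed + 1L)),
      MOD_REG = shrink(base$cov, "DIAG",
                       select_gamma(x, "DIAG", gamma_grid, gamma_folds,
                                    seed = seed + 2L)),
      ELLIPTIC = {
        ev <- evm(x, evm_drop, evm_trials, seed = seed)
        evm_stats <- ev$stats
        ev$cov
      })
  }
  list(stats = base$stats, evm_stats = evm_stats, covs = covs)
}

# run code with a temporary, restored RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
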