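# Whitened-Euclidean SCR and z-score for a signature against the
# normal-prostate background.

#' Signal-to-clutter ratio (whitened Euclidean distance)
#'
#' `SCR = sqrt( (s - mu)' CM^-1 (s - mu) )`: the Mahalanobis-type distance
#' of the tumor signature from the normal-prostate mean under the
#' (conditioned) background covariance. Whitening by the covariance
#' decorrelates the MRI sequences so each contributes its true share. For a
#' PC-filtered covariance the pseudo-inverse over the kept components is
#' used; any other non-invertible matrix flags the patient (error of class
#' `bpscr_singular`).
#'
#' @param signature a `signature` (see [extract_signature()]) or a plain
#'   3-vector.
#' @param stats background stats (list with `mu`).
#' @param cov a [cov_estimate()].
#' @return non-negative scalar.
#' @export
scr <- function(signature, stats, cov) {
  s <- if (inherits(signature, "signature")) signature$s else signature
  d <- as.numeric(s - stats$mu)
  inv <- cov_inverse(cov)
  sqrt(max(0, as.numeric(d %*% inv %*% d)))
}

#' Per-channel z-score distance
#'
#' `sqrt( sum_k ((s_k - mu_k) / sigma_k)^2 )`: the same distance as [scr()]
#' with the diagonal `ZSCORE_DIAG` covariance -- sequence correlations are
#' ignored.
#'
#' @param signature a `signature` or a plain 3-vector.
#' @param stats background stats (list with `mu`, `sigma`).
#' @return non-negative scalar.
#' @export
zscore <- function(signature, stats) {
  stopifnot(all(stats$sigma > 0))
  s <- if (inherits(signature, "signature")) signature$s else signature
  sqrt(sum(((s - stats$mu) / stats$sigma)^2))
}
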