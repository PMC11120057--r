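# Weighted rank-sum blob selection and tumor-signature extraction.

#' Blob selection weights
#'
#' Relative weights of the eight selection criteria. The defaults are the
#' trial-and-error weights used throughout the pipeline: Size = 1,
#' Green = 2, Sliding Window Maximum = 3, Sliding Window Covariance = 3,
#' Standard Deviation = 1, Blob Eccentricity = 0, Blob Position = 1,
#' Blob Covariance = 2. Eccentricity is computed but carries zero weight.
#'
#' @param size,green,win_max,win_cov,std,eccentricity,position,blob_cov
#'   non-negative criterion weights.
#' @return named numeric vector of class `selection_weights`.
#' @export
selection_weights <- function(size = 1, green = 2, win_max = 3, win_cov = 3,
                              std = 1, eccentricity = 0, position = 1,
                              blob_cov = 2) {
  w <- c(size = size, green = green, win_max = win_max, win_cov = win_cov,
         std = std, eccentricity = eccentricity, position = position,
         blob_cov = blob_cov)
  if (any(w < 0)) stop("selection weights must be >= 0")
  structure(w, class = "selection_weights")
}

# criterion direction: +1 larger-is-better, -1 smaller-is-better
SELECTION_CRITERIA <- c(size = 1, green = 1, win_max = 1, win_cov = 1,
                        std = -1, eccentricity = -1, position = -1,
                        blob_cov = 1)

blob_criterion_value <- function(blob, criterion) {
  switch(criterion,
         size = blob$size,
         green = blob$mean_green,
         win_max = blob$win_max_mean,
         win_cov = blob$win_max_cov,
         std = blob$std_green,
         eccentricity = blob$eccentricity,
         position = blob$position_score,
         blob_cov = blob$blob_cov)
}

#' Rank blobs and select the best candidate
#'
#' For each criterion all blobs are rated relative to one another: rank 1 is
#' best (larger is better for size, mean green, window maximum, window
#' covariance and blob covariance; smaller is better for standard deviation,
#' eccentricity and position). Tied values share the best (minimum) rank.
#' The total score is the weight-weighted rank sum; the blob with the
#' minimal score wins. Score ties go to the larger size, then the larger
#' mean green, then the lowest blob id.
#'
#' @param blobs list of filled blobs (see [detect_blobs()]).
#' @param weights a [selection_weights()].
#' @return list with `selected` (the winning blob), `scores` (data.frame of
#'   per-blob criterion ranks and total scores).
#' @export
rank_blobs <- function(blobs, weights = selection_weights()) {
  if (length(blobs) == 0L)
    stop_no_candidate("no candidate blobs: patient flagged, no signature")
  crit <- names(SELECTION_CRITERIA)
  vals <- sapply(crit, function(cr)
    vapply(blobs, blob_criterion_value, numeric(1), criterion = cr))
  vals <- matrix(vals, nrow = length(blobs),
                 dimnames = list(NULL, crit))
  ranks <- vals
  for (cr in crit) {
    v <- vals[, cr] * SELECTION_CRITERIA[cr]
    # rank 1 = best; ties share the minimal (competition) rank
    ranks[, cr] <- rank(-v, ties.method = "min")
  }
  total <- as.numeric(ranks %*% unclass(weights)[crit])
  size <- vals[, "size"]; mg <- vals[, "green"]
  ids <- vapply(blobs, function(b) b$id, numeric(1))
  sel <- order(total, -size, -mg, ids)[1]
  scores <- data.frame(blob_id = ids, ranks, score = total)
  list(selected = blobs[[sel]], scores = scores)
}

#' Center-of-mass voxel of a blob
#'
#' The blob voxel nearest (in voxel units) to the continuous centroid; when
#' the rounded centroid itself belongs to the blob it is that voxel. Ties go
#' to the smaller (slice, row, col).
#'
#' @param blob a blob.
#' @return integer `(slice, row, col)`.
#' @export
center_of_mass_voxel <- function(blob) {
  stopifnot(blob$size >= 1L)
  ctr <- colMeans(blob$voxels)
  d2 <- rowSums(sweep(blob$voxels, 2, ctr)^2)
  o <- order(d2, blob$voxels[, 1], blob$voxels[, 2], blob$voxels[, 3])
  as.integer(blob$voxels[o[1], ])
}

#' Extract the raw tumor signature at a voxel
#'
#' The signature is the 3-vector of raw (un-stretched) channel values at the
#' chosen voxel, in (ADC, HBV, T2) order and native channel units.
#'
#' @param cube a [hypercube()].
#' @param voxel integer `(slice, row, col)`.
#' @param mask logical prostate mask; an out-of-mask voxel is an error.
#' @param mode `"CM"` or `"GREEN"` provenance tag.
#' @return object of class `signature`: list with `s`, `source_voxel`,
#'   `mode`, `provenance`.
#' @export
extract_signature <- function(cube, voxel, mask, mode = c("CM", "GREEN")) {
  mode <- match.arg(mode)
  voxel <- as.integer(voxel)
  if (!mask[voxel[1], voxel[2], voxel[3]])
    stop("signature voxel lies outside the prostate mask")
  s <- cube$values[voxel[1], voxel[2], voxel[3], ]
  names(s) <- cube$channels
  structure(list(s = s, source_voxel = voxel, mode = mode,
                 provenance = "selected_blob"),
            class = "signature")
}

#' Average signature over all blobs
#'
#' Arithmetic mean of the per-blob signatures taken at each blob's
#' center-of-mass voxel (`mode = "CM"`) or best sliding-window center
#' (`mode = "GREEN"`).
#'
#' @param cube a [hypercube()].
#' @param blobs list of filled blobs.
#' @param mask logical prostate mask.
#' @param mode `"CM"` or `"GREEN"`.
#' @return a `signature` with provenance `"average_all_blobs"`.
#' @export
average_signature <- function(cube, blobs, mask, mode = c("CM", "GREEN")) {
  mode <- match.arg(mode)
  if (length(blobs) == 0L)
    stop_no_candidate("no candidate blobs: patient flagged, no signature")
  sig <- vapply(blobs, function(b) {
    vox <- if (mode == "CM") center_of_mass_voxel(b) else b$win_best_center
    extract_signature(cube, vox, mask, mode)$s
  }, numeric(3))
  s <- rowMeans(matrix(sig, nrow = 3))
  names(s) <- cube$channels
  structure(list(s = s, source_voxel = c(NA_integer_, NA_integer_, NA_integer_),
                 mode = mode, provenance = "average_all_blobs"),
            class = "signature")
}

#' All four per-patient signature variants
#'
#' Runs [rank_blobs()] once and returns the four signature modes reported by
#' the pipeline: the selected blob's center-of-mass voxel (`Signature CM`),
#' its greenest sliding-window voxel (`Signature Green`), and the averages
#' over all blobs (`Ave Blob CM`, `Ave Blob Green`).
#'
#' @param cube a [hypercube()].
#' @param blobs list of filled blobs.
#' @param mask logical prostate mask.
#' @param weights a [selection_weights()].
#' @return named list of four `signature`s, plus attribute `selected_id`.
#' @export
signature_variants <- function(cube, blobs, mask,
                               weights = selection_weights()) {
  sel <- rank_blobs(blobs, weights)$selected
  out <- list(
    "Signature CM" = extract_signature(cube, center_of_mass_voxel(sel),
                                       mask, "CM"),
    "Signature Green" = extract_signature(cube, sel$win_best_center,
                                          mask, "GREEN"),
    "Ave Blob CM" = average_signature(cube, blobs, mask, "CM"),
    "Ave Blob Green" = average_signature(cube, blobs, mask, "GREEN"))
  attr(out, "selected_id") <- sel$id
  out
}
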