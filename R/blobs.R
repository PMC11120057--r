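# Blob detection on the green image: threshold, binary morphology,
# 8-connected labeling, size filter, per-blob and 3x3 sliding-window
# statistics.

BLOB_EPS <- 1e-6   # std floor used in mean/std ("covariance") ratios

#' Threshold the green image
#'
#' @param green a `green_image` (see [green_ratio()]).
#' @param mask logical prostate mask.
#' @param thr threshold in (0, 1); a voxel is kept iff `green >= thr`
#'   (boundary included) and in-mask.
#' @return logical 3D array.
#' @export
threshold_green <- function(green, mask, thr = 0.90) {
  stopifnot(thr > 0, thr < 1)
  unclass(green) >= thr & mask
}

# erosion with an all-ones 2x2 element anchored at its top-left corner:
# out[r, c] is TRUE iff the 2x2 square with corner (r, c) is all TRUE
erode22 <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  out <- matrix(FALSE, nr, nc)
  if (nr < 2L || nc < 2L) return(out)
  out[-nr, -nc] <- b[-nr, -nc] & b[-1, -nc] & b[-nr, -1] & b[-1, -1]
  out
}

# dilation with a centred all-ones 3x3 element
dilate33 <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- b
  out <- matrix(FALSE, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out | pad[(1:nr) + dr, (1:nc) + dc]
  out
}

#' Morphological cleaning of the thresholded image
#'
#' Per-slice 2D erosion with a 2x2 all-ones structure element followed by
#' dilation with a 3x3 all-ones element; removes 1-voxel-wide strings and
#' isolated voxels while restoring the bulk of compact blobs.
#'
#' @param binary logical 3D array `[slice, row, col]`.
#' @return logical 3D array.
#' @export
morph_clean <- function(binary) {
  out <- binary
  for (k in seq_len(dim(binary)[1]))
    out[k, , ] <- dilate33(erode22(binary[k, , ]))
  out
}

# union-find labeling over an ordered voxel list; offs = prior-neighbour
# index offsets (rows of (ds, dr, dc))
label_voxels <- function(coords, dims, offs) {
  lab <- array(0L, dim = dims)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  nv <- nrow(coords)
  for (k in seq_len(nv)) {
    v <- coords[k, ]
    nb <- integer(0)
    for (j in seq_len(nrow(offs))) {
      p <- v + offs[j, ]
      if (p[1] >= 1L && p[1] <= dims[1] && p[2] >= 1L && p[2] <= dims[2] &&
          p[3] >= 1L && p[3] <= dims[3]) {
        l <- lab[p[1], p[2], p[3]]
        if (l > 0L) nb <- c(nb, l)
      }
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[v[1], v[2], v[3]] <- nxt
    } else {
      roots <- unique(vapply(unique(nb), find, integer(1)))
      m <- min(roots)
      lab[v[1], v[2], v[3]] <- m
      for (rt in roots) parent[rt] <- m
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    pos <- which(lab > 0L)
    lab[pos] <- roots[lab[pos]]
  }
  lab
}

#' Label connected blobs
#'
#' Default connectivity is 8-connected within each 2D slice (horizontal,
#' vertical and diagonal neighbours), with no linking across slices;
#' `"3d26"` enables full 3D 26-connectivity for experimentation. Blobs are
#' returned in deterministic order: by slice, then by first voxel in
#' row-major raster order (top-left first).
#'
#' @param binary logical 3D array.
#' @param connectivity `"2d8"` (default) or `"3d26"`.
#' @return list of blobs; each blob is a list with `id`, `slice` (of its
#'   first voxel), `voxels` (n x 3 matrix of (slice, row, col)) and `size`.
#' @export
label_blobs <- function(binary, connectivity = c("2d8", "3d26")) {
  connectivity <- match.arg(connectivity)
  dims <- dim(binary)
  coords <- which(binary, arr.ind = TRUE)
  if (nrow(coords) == 0L) return(list())
  colnames(coords) <- NULL
  # raster order: slice, then row, then col
  coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), , drop = FALSE]
  offs <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
  colnames(offs) <- NULL
  if (connectivity == "2d8") {
    keep <- offs[, 1] == 0 & !(offs[, 2] == 0 & offs[, 3] == 0) &
      (offs[, 2] < 0 | (offs[, 2] == 0 & offs[, 3] < 0))
  } else {
    keep <- offs[, 1] < 0 |
      (offs[, 1] == 0 & (offs[, 2] < 0 | (offs[, 2] == 0 & offs[, 3] < 0)))
  }
  lab <- label_voxels(coords, dims, offs[keep, , drop = FALSE])
  labs_in_order <- lab[coords]         # matrix-subscript lookup, raster order
  first <- !duplicated(labs_in_order)
  ids <- labs_in_order[first]          # labels ordered by first appearance
  blobs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    vox <- coords[labs_in_order == ids[i], , drop = FALSE]
    blobs[[i]] <- list(id = i, slice = vox[1, 1], voxels = vox,
                       size = nrow(vox))
  }
  blobs
}

#' Remove small blobs
#'
#' @param blobs list of blobs from [label_blobs()].
#' @param min_size minimum voxel count; blobs with `size < min_size` are
#'   dropped (12 voxels by default).
#' @return filtered list (ids renumbered in order).
#' @export
filter_small <- function(blobs, min_size = 12L) {
  stopifnot(min_size >= 1L)
  out <- Filter(function(b) b$size >= min_size, blobs)
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' Fill per-blob statistics
#'
#' Mean and (population) standard deviation of green over the blob, the
#' blob "covariance" mean/std (std floored at 1e-6, flagged), the
#' eccentricity of the in-plane second-moment ellipse, the continuous
#' centroid, and the position score: Euclidean mm distance from the blob
#' centroid to the whole-mask centroid.
#'
#' @param blob one blob from [label_blobs()].
#' @param green `green_image`.
#' @param mask logical prostate mask.
#' @param spacing `(dz, dy, dx)` mm, for the position score.
#' @return the blob with fields `mean_green`, `std_green`, `blob_cov`,
#'   `cov_flagged`, `eccentricity`, `centroid`, `position_score` added.
#' @export
blob_statistics <- function(blob, green, mask, spacing = c(3, 1, 1)) {
  stopifnot(blob$size >= 1L)
  g <- unclass(green)[blob$voxels]
  m <- mean(g)
  s <- sqrt(mean((g - m)^2))
  blob$mean_green <- m
  blob$std_green <- s
  blob$cov_flagged <- s < BLOB_EPS
  blob$blob_cov <- m / max(s, BLOB_EPS)
  rc <- blob$voxels[, 2:3, drop = FALSE]
  mu <- colMeans(rc)
  cc <- sweep(rc, 2, mu)
  mom <- crossprod(cc) / nrow(rc)
  ev <- sort(eigen(mom, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  blob$eccentricity <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))
  blob$centroid <- colMeans(blob$voxels)
  mc <- colMeans(which(mask, arr.ind = TRUE))
  blob$position_score <- sqrt(sum(((blob$centroid - mc) * spacing)^2))
  blob
}

#' Sliding 3x3 window statistics within a blob
#'
#' A 9-voxel window is evaluated at every blob voxel as center; the window
#' is the in-plane 3x3 neighbourhood and is skipped unless all 9 voxels are
#' inside the prostate mask (window values are green values regardless of
#' blob membership). The best window maximizes cov = mean/std (std floored
#' at 1e-6); ties go to the larger mean, then the smaller row, then the
#' smaller column. If every window is skipped the blob's greenest voxel is
#' the fallback center.
#'
#' @inheritParams blob_statistics
#' @return the blob with `windows` (data.frame of per-window stats),
#'   `win_max_mean`, `win_max_cov`, `win_best_center`, `win_fallback` added.
#' @export
sliding_window_stats <- function(blob, green, mask) {
  g <- unclass(green)
  dims <- dim(g)
  vox <- blob$voxels
  n <- nrow(vox)
  wmean <- wsd <- wcov <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    s <- vox[i, 1]; r <- vox[i, 2]; cl <- vox[i, 3]
    if (r < 2L || r > dims[2] - 1L || cl < 2L || cl > dims[3] - 1L) next
    mwin <- mask[s, (r - 1L):(r + 1L), (cl - 1L):(cl + 1L)]
    if (!all(mwin)) next
    w <- g[s, (r - 1L):(r + 1L), (cl - 1L):(cl + 1L)]
    mu <- mean(w)
    sd9 <- sqrt(mean((w - mu)^2))
    wmean[i] <- mu
    wsd[i] <- sd9
    wcov[i] <- mu / max(sd9, BLOB_EPS)
    ok[i] <- TRUE
  }
  if (any(ok)) {
    cand <- which(ok)
    o <- cand[order(-wcov[cand], -wmean[cand], vox[cand, 2], vox[cand, 3])]
    best <- o[1]
    blob$windows <- data.frame(slice = vox[ok, 1], row = vox[ok, 2],
                               col = vox[ok, 3], mean = wmean[ok],
                               std = wsd[ok], cov = wcov[ok])
    blob$win_max_mean <- max(wmean[ok])
    blob$win_max_cov <- max(wcov[ok])
    blob$win_best_center <- vox[best, ]
    blob$win_fallback <- FALSE
  } else {
    gb <- g[vox]
    best <- which.max(gb)              # raster order breaks ties (first wins)
    blob$windows <- data.frame(slice = integer(0), row = integer(0),
                               col = integer(0), mean = numeric(0),
                               std = numeric(0), cov = numeric(0))
    blob$win_max_mean <- gb[best]
    blob$win_max_cov <- gb[best] / BLOB_EPS
    blob$win_best_center <- vox[best, ]
    blob$win_fallback <- TRUE
  }
  blob
}

#' Full blob detection for one patient
#'
#' Threshold, morphology, labeling, size filter, then per-blob and
#' sliding-window statistics.
#'
#' @param green `green_image` used for thresholding (typically the
#'   per-patient re-stretched green, see [rescale_green()]).
#' @param mask logical prostate mask.
#' @param thr green threshold (default 0.90).
#' @param min_size minimum blob size (default 12 voxels).
#' @param spacing `(dz, dy, dx)` mm.
#' @param connectivity see [label_blobs()].
#' @param stats_green `green_image` used for blob and window statistics;
#'   defaults to `green`. Passing the un-re-stretched quantitative ratio
#'   here keeps the within-blob ordering that the re-stretch clipping
#'   (everything beyond the 98th percentile becomes exactly 1) destroys.
#' @return list of fully filled blobs (possibly empty).
#' @export
detect_blobs <- function(green, mask, thr = 0.90, min_size = 12L,
                         spacing = c(3, 1, 1),
                         connectivity = c("2d8", "3d26"),
                         stats_green = green) {
  bin <- morph_clean(threshold_green(green, mask, thr)) & mask
  blobs <- filter_small(label_blobs(bin, connectivity), min_size)
  lapply(blobs, function(b)
    sliding_window_stats(blob_statistics(b, stats_green, mask, spacing),
                         stats_green, mask))
}

#' Tabulate blob statistics
#'
#' @param blobs list of filled blobs.
#' @param patient_id identifier column value.
#' @return data.frame, one row per blob (the CSV export contract).
#' @export
blob_table <- function(blobs, patient_id = NA_character_) {
  if (length(blobs) == 0L)
    return(data.frame(patient_id = character(0), blob_id = integer(0),
                      slice = integer(0), size = integer(0),
                      mean_green = numeric(0), std_green = numeric(0),
                      blob_cov = numeric(0), eccentricity = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      win_max_mean = numeric(0), win_max_cov = numeric(0),
                      best_center = character(0), position_score = numeric(0)))
  do.call(rbind, lapply(blobs, function(b) data.frame(
    patient_id = patient_id, blob_id = b$id, slice = b$slice, size = b$size,
    mean_green = b$mean_green, std_green = b$std_green,
    blob_cov = b$blob_cov, eccentricity = b$eccentricity,
    centroid_row = b$centroid[2], centroid_col = b$centroid[3],
    win_max_mean = b$win_max_mean, win_max_cov = b$win_max_cov,
    best_center = paste(b$win_best_center, collapse = ";"),
    position_score = b$position_score)))
}
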