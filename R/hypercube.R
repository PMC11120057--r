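# Registered-hypercube assembly: channel containers, NIfTI/DICOM input,
# in-plane resampling, integer-voxel translation, channel stacking.
#
# Conventions (used throughout the package):
#   * arrays are indexed [slice, row, col], 0-based indices in the API
#     docs but ordinary 1-based R subscripts in code;
#   * spacing is (dz, dy, dx) in mm; origin offsets are (z, y, x) in mm;
#   * the axial slice index increases with scanner z.

CHANNEL_IDS <- c("ADC", "HBV", "T2")

#' Construct a single-sequence MRI volume
#'
#' A `volume_channel` holds one MRI sequence on its native grid together
#' with the geometry needed for registration: voxel spacing and the scanner
#' position of the first voxel.
#'
#' @param values 3D numeric array, `[slice, row, col]`.
#' @param spacing numeric length-3, voxel pitch `(dz, dy, dx)` in mm.
#' @param origin numeric length-3, position `(z, y, x)` of voxel
#'   `[1, 1, 1]` in mm.
#' @param channel one of `"ADC"`, `"HBV"`, `"T2"`.
#' @return An object of class `volume_channel`.
#' @export
volume_channel <- function(values, spacing, origin = c(0, 0, 0),
                           channel = c("ADC", "HBV", "T2")) {
  channel <- match.arg(channel)
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array [slice, row, col]")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three positive finite numbers (dz, dy, dx)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite numbers (z, y, x)")
  if (any(!is.finite(values)))
    stop("channel values must be finite")
  structure(
    list(values = values, spacing = as.numeric(spacing),
         origin = as.numeric(origin), channel = channel),
    class = "volume_channel")
}

#' @export
print.volume_channel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_channel %s> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$channel, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Load one MRI channel from disk
#'
#' Reads a NIfTI file or a DICOM series directory and returns the volume
#' on its native grid, slices ordered by ascending axial position.
#'
#' NIfTI files are expected in conventional `(x, y, z)` axis order; they are
#' permuted to the package's `[slice, row, col]` layout. The translation part
#' of the sform/qform supplies the origin offset.
#'
#' @param path file path (NIfTI) or directory (DICOM series).
#' @param channel channel tag, one of `"ADC"`, `"HBV"`, `"T2"`.
#' @param kind `"auto"` (directory implies DICOM), `"nifti"` or `"dicom"`.
#' @return A [volume_channel()].
#' @export
load_channel <- function(path, channel = c("ADC", "HBV", "T2"),
                         kind = c("auto", "nifti", "dicom")) {
  channel <- match.arg(channel)
  kind <- match.arg(kind)
  if (!file.exists(path))
    stop("input does not exist: ", path)
  if (kind == "auto")
    kind <- if (dir.exists(path)) "dicom" else "nifti"
  if (kind == "dicom") {
    ser <- read_dicom_series(path)
    return(volume_channel(ser$values, ser$spacing, ser$origin, channel))
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume: ", path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("NIfTI header is missing valid pixel spacing (pixdim): ", path)
  xf <- try(RNifti::xform(img), silent = TRUE)
  off <- if (inherits(xf, "try-error")) c(0, 0, 0) else unname(xf[1:3, 4])
  # (x, y, z) -> (slice, row, col)
  vals <- aperm(arr, c(3L, 2L, 1L))
  volume_channel(vals, spacing = rev(pd[1:3]), origin = rev(off),
                 channel = channel)
}

#' Write one channel (or any 3D grid) as NIfTI
#'
#' Inverse of [load_channel()]: the `[slice, row, col]` array is permuted to
#' `(x, y, z)` order and spacing/origin go into pixdim and the sform.
#'
#' @param channel a [volume_channel()], or a 3D array when `spacing`/`origin`
#'   are given explicitly.
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing,origin geometry overrides for plain arrays.
#' @return `path`, invisibly.
#' @export
write_channel_nifti <- function(channel, path, spacing = NULL, origin = NULL) {
  if (inherits(channel, "volume_channel")) {
    vals <- channel$values
    spacing <- channel$spacing
    origin <- channel$origin
  } else {
    vals <- as.array(channel)
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    if (is.null(origin)) origin <- c(0, 0, 0)
  }
  arr <- aperm(vals, c(3L, 2L, 1L))      # -> (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing)
  aff <- diag(c(rev(spacing), 1))
  aff[1:3, 4] <- rev(origin)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load a binary prostate mask from NIfTI
#'
#' @param path NIfTI file with 0/1 voxels.
#' @param min_voxels minimum number of in-mask voxels; fewer rejects the
#'   patient (hard error).
#' @return logical 3D array `[slice, row, col]`.
#' @export
load_mask <- function(path, min_voxels = 50L) {
  ch <- load_channel(path, channel = "T2", kind = "nifti")
  m <- ch$values != 0
  if (sum(m) < min_voxels)
    stop_reject(sprintf("prostate mask has %d voxels (< %d): patient rejected",
                        sum(m), min_voxels))
  m
}

#' Resample a channel onto a reference grid
#'
#' Bilinear interpolation in-plane, nearest-neighbour across slices (slice
#' alignment is integer by construction; no through-plane interpolation).
#' Reference grid point `(i, j, k)` (0-based) is taken at
#' `i * ref_spacing` mm from the channel's own origin, and likewise in-plane;
#' points outside the source extent become 0.
#'
#' @param channel a [volume_channel()].
#' @param ref_spacing target `(dz, dy, dx)` in mm.
#' @param ref_shape target `(slices, rows, cols)`.
#' @return A [volume_channel()] on the reference grid.
#' @export
resample_to_reference <- function(channel, ref_spacing, ref_shape) {
  stopifnot(length(ref_spacing) == 3L, all(ref_spacing > 0),
            length(ref_shape) == 3L, all(ref_shape >= 1))
  src <- channel$values
  d <- dim(src)
  same_grid <- all(abs(ref_spacing - channel$spacing) < 1e-12) &&
    all(ref_shape == d)
  if (same_grid) return(channel)

  out <- array(0, dim = ref_shape)
  # source in-plane coordinates of the reference columns/rows (1-based)
  yp <- ((seq_len(ref_shape[2]) - 1) * ref_spacing[2]) / channel$spacing[2] + 1
  xp <- ((seq_len(ref_shape[3]) - 1) * ref_spacing[3]) / channel$spacing[3] + 1
  grid <- pracma::meshgrid(xp, yp)   # $X cols, $Y rows; dims rows x cols
  in_y <- yp >= 1 & yp <= d[2]
  in_x <- xp >= 1 & xp <= d[3]
  ypc <- pmin(pmax(grid$Y, 1), d[2])
  xpc <- pmin(pmax(grid$X, 1), d[3])
  for (k in seq_len(ref_shape[1])) {
    zsrc <- round(((k - 1) * ref_spacing[1]) / channel$spacing[1]) + 1
    if (zsrc < 1 || zsrc > d[1]) next
    plane <- src[zsrc, , ]
    interp <- pracma::interp2(x = seq_len(d[3]), y = seq_len(d[2]),
                              Z = plane, xp = as.vector(xpc),
                              yp = as.vector(ypc), method = "linear")
    res <- matrix(interp, nrow = ref_shape[2], ncol = ref_shape[3])
    res[!in_y, ] <- 0
    res[, !in_x] <- 0
    out[k, , ] <- res
  }
  volume_channel(out, spacing = ref_spacing, origin = channel$origin,
                 channel = channel$channel)
}

#' Translate a channel onto a reference channel's grid
#'
#' Integer-voxel shift computed from the origin-offset difference, rounded to
#' the nearest voxel; out-of-range voxels are 0-filled. Both inputs must share
#' one spacing.
#'
#' @param channel,ref [volume_channel()]s on a common spacing.
#' @param extra_shift optional additional integer in-plane `(dy, dx)` shift in
#'   voxels (manual adjustment hook), default `c(0, 0)`.
#' @return `channel` resampled onto `ref`'s grid.
#' @export
align_translate <- function(channel, ref, extra_shift = c(0L, 0L)) {
  if (any(abs(channel$spacing - ref$spacing) > 1e-9))
    stop("align_translate requires a common spacing; resample first")
  shift <- round((ref$origin - channel$origin) / channel$spacing)
  shift <- shift + c(0, extra_shift[1], extra_shift[2])
  out <- shift_array(channel$values, shift, dim(ref$values))
  volume_channel(out, spacing = ref$spacing, origin = ref$origin,
                 channel = channel$channel)
}

# value at ref index v comes from source index v + shift; 0 outside.
shift_array <- function(a, shift, out_dim) {
  d <- dim(a)
  out <- array(0, dim = out_dim)
  idx <- vector("list", 3L)
  src <- vector("list", 3L)
  for (ax in 1:3) {
    v <- seq_len(out_dim[ax])
    s <- v + shift[ax]
    ok <- s >= 1 & s <= d[ax]
    idx[[ax]] <- v[ok]
    src[[ax]] <- s[ok]
    if (!any(ok)) return(out)
  }
  out[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Assemble the registered 3-channel hypercube
#'
#' The reference grid is the channel with the coarsest in-plane resolution
#' (largest voxel area, i.e. the ADC/HBV grid in practice); the remaining
#' channels are resampled to that spacing and shifted by the rounded
#' origin-offset difference. Channel order is fixed (ADC, HBV, T2).
#'
#' @param adc,hbv,t2 [volume_channel()]s with distinct channel tags.
#' @param t2_shift optional manual in-plane `(dy, dx)` voxel shift applied to
#'   T2 after automatic alignment, default `c(0, 0)`.
#' @return An object of class `hypercube`: list with `values`
#'   (`[slice, row, col, channel]`), `spacing`, `channels`.
#' @export
assemble_hypercube <- function(adc, hbv, t2, t2_shift = c(0L, 0L)) {
  chans <- list(adc, hbv, t2)
  ids <- vapply(chans, function(ch) ch$channel, character(1))
  if (anyDuplicated(ids))
    stop("duplicate channel_id among inputs: ", paste(ids, collapse = ", "))
  names(chans) <- ids
  chans <- chans[CHANNEL_IDS]
  if (any(vapply(chans, is.null, logical(1))))
    stop("need exactly one ADC, one HBV and one T2 channel")
  area <- vapply(chans, function(ch) ch$spacing[2] * ch$spacing[3], numeric(1))
  ref <- chans[[which.max(area)]]
  ref_dim <- dim(ref$values)
  aligned <- lapply(chans, function(ch) {
    shift <- if (ch$channel == "T2") t2_shift else c(0L, 0L)
    rs <- resample_to_reference(ch, ref$spacing, ref_dim)
    align_translate(rs, ref, extra_shift = shift)
  })
  vals <- array(0, dim = c(ref_dim, 3L))
  for (i in 1:3) vals[, , , i] <- aligned[[i]]$values
  structure(list(values = vals, spacing = ref$spacing,
                 origin = ref$origin, channels = CHANNEL_IDS),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d x %d voxels x (%s), spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Build a hypercube from three congruent arrays
#'
#' Convenience constructor used when the channels are already registered
#' (e.g. by the phantom generator).
#'
#' @param values 4D array `[slice, row, col, 3]` in (ADC, HBV, T2) order.
#' @param spacing `(dz, dy, dx)` mm.
#' @param origin `(z, y, x)` mm.
#' @return A `hypercube`.
#' @export
hypercube <- function(values, spacing = c(3, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 4L || dim(values)[4] != 3L)
    stop("'values' must be [slice, row, col, 3]")
  if (any(!is.finite(values))) stop("hypercube values must be finite")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), channels = CHANNEL_IDS),
            class = "hypercube")
}

# split a hypercube back into its three volume_channels
hypercube_channels <- function(cube) {
  lapply(seq_along(cube$channels), function(i)
    volume_channel(cube$values[, , , i, drop = TRUE], cube$spacing,
                   cube$origin, cube$channels[i]))
}

#' Write / read a hypercube as 4D NIfTI plus JSON sidecar
#'
#' The 4th NIfTI dimension is the channel (ADC, HBV, T2); the sidecar records
#' channel order, spacing and the patient id.
#'
#' @param cube a `hypercube`.
#' @param path output `.nii`/`.nii.gz`; the sidecar is `<path>.json`.
#' @param patient_id identifier stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_hypercube <- function(cube, path, patient_id = NA_character_) {
  arr <- aperm(cube$values, c(3L, 2L, 1L, 4L))   # (x, y, z, channel)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rev(cube$spacing), 1)
  aff <- diag(c(rev(cube$spacing), 1))
  aff[1:3, 4] <- rev(cube$origin)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  sidecar <- list(channel_order = cube$channels,
                  spacing_mm = cube$spacing,
                  patient_id = patient_id)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_hypercube
#' @export
read_hypercube <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("expected a 4D NIfTI with 3 channels: ", path)
  pd <- RNifti::pixdim(img)
  xf <- try(RNifti::xform(img), silent = TRUE)
  off <- if (inherits(xf, "try-error")) c(0, 0, 0) else unname(xf[1:3, 4])
  hypercube(aperm(arr, c(3L, 2L, 1L, 4L)), spacing = rev(pd[1:3]),
            origin = rev(off))
}

# --- condition helpers used across modules ---------------------------------

stop_reject <- function(msg) {
  stop(errorCondition(msg, class = c("bpscr_reject", "error")))
}

stop_no_candidate <- function(msg) {
  stop(errorCondition(msg, class = c("bpscr_no_candidate", "error")))
}

stop_singular <- function(msg) {
  stop(errorCondition(msg, class = c("bpscr_singular", "error")))
}
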