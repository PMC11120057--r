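# Normalized "green" ratio image: per-channel percentile stretch over
# prostate voxels, then HBV' / (ADC' + HBV' + T2').

#' Percentile-stretch a channel over the prostate mask
#'
#' Masked voxels are mapped linearly so that the `p_low` percentile goes to 0
#' and the `p_high` percentile to 1; values beyond those percentiles are
#' clipped to 0 and 1 (aberrant voxels do not distort the normalization).
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7). Voxels outside the mask are set to 0.
#'
#' @param values 3D numeric array.
#' @param mask logical array, same shape; at least 50 voxels.
#' @param p_low,p_high percentile bounds (defaults 1 and 98).
#' @return array of the same shape with masked values in `[0, 1]`.
#' @export
percentile_stretch <- function(values, mask, p_low = 1, p_high = 98) {
  stopifnot(identical(dim(values), dim(mask)), p_low < p_high)
  if (sum(mask) < 50L)
    stop_reject("mask has fewer than 50 voxels: patient rejected")
  v <- values[mask]
  q <- stats::quantile(v, probs = c(p_low, p_high) / 100,
                       names = FALSE, type = 7)
  out <- array(0, dim = dim(values))
  if (q[2] <= q[1]) {
    warning("degenerate (constant) channel under mask; stretched values set to 0.5")
    out[mask] <- 0.5
    return(out)
  }
  out[mask] <- pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
  out
}

#' Stretch all three hypercube channels
#'
#' @param cube a [hypercube()].
#' @param mask logical prostate mask.
#' @inheritParams percentile_stretch
#' @return a `hypercube` whose channels are stretched to `[0, 1]` in-mask.
#' @export
stretch_hypercube <- function(cube, mask, p_low = 1, p_high = 98) {
  vals <- cube$values
  d3 <- dim(vals)[1:3]
  for (i in seq_along(cube$channels))
    vals[, , , i] <- percentile_stretch(array(cube$values[, , , i], dim = d3),
                                        mask, p_low, p_high)
  out <- cube
  out$values <- vals
  out
}

#' Form the normalized "green" ratio image
#'
#' `g = HBV' / (ADC' + HBV' + T2')` per masked voxel, the multispectral
#' analogue of the green fraction in an RGB composite with (R, G, B) =
#' (ADC, HBV, T2). Tumors (low ADC, high HBV, low T2) maximize g. A zero
#' denominator yields g = 0.
#'
#' @param stretched_cube a [hypercube()] with channels already stretched to
#'   `[0, 1]` (see [stretch_hypercube()]).
#' @param mask logical prostate mask.
#' @return object of class `green_image`: 3D array in `[0, 1]`, 0 outside
#'   the mask, with attributes `p_low`/`p_high` of the stretch.
#' @export
green_ratio <- function(stretched_cube, mask) {
  v <- stretched_cube$values
  d3 <- dim(v)[1:3]
  chan <- function(i) array(v[, , , i], dim = d3)
  denom <- chan(1) + chan(2) + chan(3)
  g <- array(0, dim = d3)
  ok <- mask & denom > 0
  g[ok] <- chan(2)[ok] / denom[ok]
  structure(g, p_low = 1, p_high = 98, class = "green_image")
}

#' Re-stretch the green image per patient
#'
#' Applies the same 1/98 percentile stretch to the green ratio itself, so a
#' fixed detection threshold (0.90 by default downstream) has a stable
#' meaning across patients. On by default in the pipeline; the raw-ratio
#' alternative is available by skipping this step.
#'
#' @param green a `green_image` (or 3D array).
#' @param mask logical prostate mask.
#' @inheritParams percentile_stretch
#' @return a `green_image`.
#' @export
rescale_green <- function(green, mask, p_low = 1, p_high = 98) {
  out <- percentile_stretch(unclass(green), mask, p_low, p_high)
  structure(out, p_low = p_low, p_high = p_high, class = "green_image")
}
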