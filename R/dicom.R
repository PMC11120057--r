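# Minimal DICOM series reader: uncompressed explicit/implicit VR
# little-endian, single-frame grayscale slices. Only the geometry and pixel
# tags the registration pipeline needs are decoded; anything fancier
# (compressed syntaxes, undefined-length sequences) is a hard error rather
# than a silent misread.

DCM_TAGS <- list(
  transfer_syntax     = c(0x0002L, 0x0010L),
  slice_thickness     = c(0x0018L, 0x0050L),
  spacing_between     = c(0x0018L, 0x0088L),
  image_position      = c(0x0020L, 0x0032L),
  image_orientation   = c(0x0020L, 0x0037L),
  rows                = c(0x0028L, 0x0010L),
  cols                = c(0x0028L, 0x0011L),
  pixel_spacing       = c(0x0028L, 0x0030L),
  bits_allocated      = c(0x0028L, 0x0100L),
  pixel_representation= c(0x0028L, 0x0103L),
  rescale_intercept   = c(0x0028L, 0x1052L),
  rescale_slope       = c(0x0028L, 0x1053L),
  pixel_data          = c(0x7FE0L, 0x0010L)
)

EXPLICIT_LE <- "1.2.840.10008.1.2.1"
IMPLICIT_LE <- "1.2.840.10008.1.2"

u16 <- function(raw, at) {
  as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
}
u32 <- function(raw, at) {
  as.integer(raw[at]) + 256 * as.integer(raw[at + 1L]) +
    65536 * as.integer(raw[at + 2L]) + 16777216 * as.integer(raw[at + 3L])
}

# parse one DICOM file, returning the decoded tags we care about
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file (missing DICM magic): ", path)
  pos <- 133L
  n <- length(raw)
  found <- list()
  syntax <- EXPLICIT_LE   # file meta group is always explicit LE
  in_meta <- TRUE
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

  while (pos + 7L <= n) {
    group <- u16(raw, pos); elem <- u16(raw, pos + 2L)
    if (in_meta && group != 0x0002L) {
      in_meta <- FALSE   # meta group ended; switch to dataset syntax
    }
    explicit <- in_meta || syntax == EXPLICIT_LE
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- u16(raw, pos + 6L)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(raw, pos + 4L)
      hdr <- 8L
    }
    if (len == 4294967295)  # 0xFFFFFFFF undefined length
      stop("undefined-length element (sequence?) unsupported at tag (",
           sprintf("%04X,%04X", group, elem), ") in ", path)
    val_at <- pos + hdr
    if (val_at + len - 1L > n)
      stop("truncated DICOM element in ", path)
    for (nm in names(DCM_TAGS)) {
      tg <- DCM_TAGS[[nm]]
      if (group == tg[1] && elem == tg[2])
        found[[nm]] <- list(vr = vr, bytes = raw[seq.int(val_at, length.out = len)])
    }
    if (group == 0x0002L && elem == 0x0010L) {
      ts <- sub("\\s+$", "", rawToChar(found$transfer_syntax$bytes))
      ts <- gsub("\\x00", "", ts, useBytes = TRUE)
      if (!ts %in% c(EXPLICIT_LE, IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax ", ts, " in ", path)
      syntax <- ts
    }
    pos <- val_at + len
    if (group == 0x7FE0L && elem == 0x0010L) break
  }
  found
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el$bytes)
  s <- gsub("\\x00", "", s, useBytes = TRUE)
  trimws(s)
}
dcm_numeric <- function(el) {
  s <- dcm_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dcm_us <- function(el) {
  if (is.null(el)) return(NULL)
  u16(el$bytes, 1L)
}

# decode the pixel matrix of one slice (rows x cols, row-major on disk)
dcm_pixels <- function(found, path) {
  rows <- dcm_us(found$rows); cols <- dcm_us(found$cols)
  bits <- dcm_us(found$bits_allocated)
  if (is.null(rows) || is.null(cols))
    stop("DICOM file missing Rows/Columns: ", path)
  if (is.null(bits) || !bits %in% c(8L, 16L))
    stop("unsupported BitsAllocated (need 8 or 16): ", path)
  signed <- identical(dcm_us(found$pixel_representation), 1L)
  px <- found$pixel_data
  if (is.null(px)) stop("DICOM file missing PixelData: ", path)
  vals <- readBin(px$bytes, "integer", n = rows * cols,
                  size = bits %/% 8L, signed = if (bits == 8L) FALSE else signed,
                  endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  slope <- dcm_numeric(found$rescale_slope)
  inter <- dcm_numeric(found$rescale_intercept)
  m <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  if (!is.null(slope)) m <- m * slope[1]
  if (!is.null(inter)) m <- m + inter[1]
  m
}

#' Read an axial DICOM series as one volume
#'
#' Parses every file in `dir`, checks geometric consistency, and stacks the
#' slices in ascending axial position (projection of ImagePositionPatient on
#' the slice normal), regardless of file order on disk.
#'
#' @param dir directory containing one single-channel DICOM series.
#' @return list with `values` (`[slice, row, col]`), `spacing` `(dz, dy, dx)`
#'   mm and `origin` `(z, y, x)` mm of the first (lowest) slice.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM series directory: ", dir)
  slices <- lapply(files, read_dicom_file)

  ps <- lapply(slices, function(s) dcm_numeric(s$pixel_spacing))
  if (any(vapply(ps, is.null, logical(1))))
    stop("DICOM series is missing pixel spacing (PixelSpacing tag) in ", dir)
  ipp <- lapply(slices, function(s) dcm_numeric(s$image_position))
  if (any(vapply(ipp, is.null, logical(1))))
    stop("DICOM series is missing image position (ImagePositionPatient) in ", dir)
  iop <- lapply(slices, function(s) dcm_numeric(s$image_orientation))
  iop <- iop[!vapply(iop, is.null, logical(1))]
  if (length(iop) > 1L) {
    ref <- iop[[1]]
    if (any(vapply(iop, function(o) max(abs(o - ref)) > 1e-4, logical(1))))
      stop("mixed orientations within DICOM series in ", dir)
  }
  normal <- if (length(iop) >= 1L) {
    o <- iop[[1]]
    c(o[2] * o[6] - o[3] * o[5],
      o[3] * o[4] - o[1] * o[6],
      o[1] * o[5] - o[2] * o[4])
  } else c(0, 0, 1)
  zpos <- vapply(ipp, function(p) sum(p * normal), numeric(1))
  ord <- order(zpos)
  mats <- lapply(slices[ord], function(s) dcm_pixels(s, dir))
  rows <- unique(vapply(mats, nrow, integer(1)))
  cols <- unique(vapply(mats, ncol, integer(1)))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("inconsistent slice dimensions within DICOM series in ", dir)
  vals <- array(0, dim = c(length(mats), rows, cols))
  for (k in seq_along(mats)) vals[k, , ] <- mats[[k]]
  dz <- if (length(mats) > 1L) {
    stats::median(diff(sort(zpos)))
  } else {
    st <- dcm_numeric(slices[[1]]$slice_thickness)
    sb <- dcm_numeric(slices[[1]]$spacing_between)
    if (!is.null(sb)) sb[1] else if (!is.null(st)) st[1] else 1
  }
  if (!is.finite(dz) || dz <= 0) dz <- 1
  sp <- ps[[1]]                        # PixelSpacing = (row pitch, col pitch)
  first <- ipp[[ord[1]]]
  list(values = vals, spacing = c(dz, sp[1], sp[2]),
       origin = c(zpos[ord[1]], first[2], first[1]))
}
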