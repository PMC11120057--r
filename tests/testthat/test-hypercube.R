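# Hypercube assembly: containers, NIfTI round-trips, resampling,
# translation, channel stacking.

test_that("volume_channel validates its geometry", {
  a <- array(1, dim = c(2, 3, 4))
  expect_s3_class(volume_channel(a, c(3, 1, 1), channel = "ADC"),
                  "volume_channel")
  expect_error(volume_channel(a, c(0, 1, 1), channel = "ADC"), "positive")
  expect_error(volume_channel(array(NA_real_, c(2, 3, 4)), c(3, 1, 1),
                              channel = "ADC"), "finite")
  expect_error(volume_channel(matrix(1, 2, 2), c(3, 1, 1), channel = "ADC"),
               "3D")
})

test_that("NIfTI write/read round-trips values, spacing and origin", {
  set.seed(42)
  ch <- volume_channel(array(rnorm(60), dim = c(3, 4, 5)),
                       spacing = c(3, 1, 0.5), origin = c(7, -2, 10.5),
                       channel = "HBV")
  f <- tempfile(fileext = ".nii.gz")
  write_channel_nifti(ch, f)
  back <- load_channel(f, channel = "HBV")
  expect_identical(back$values, ch$values)
  expect_equal(back$spacing, ch$spacing)
  expect_equal(back$origin, ch$origin)
})

test_that("4D hypercube NIfTI round-trip is bitwise exact with sidecar", {
  set.seed(7)
  cube <- hypercube(array(rnorm(2 * 3 * 4 * 3), dim = c(2, 3, 4, 3)),
                    spacing = c(3, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_hypercube(cube, f, patient_id = "P001")
  back <- read_hypercube(f)
  expect_identical(back$values, cube$values)
  expect_equal(back$spacing, cube$spacing)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(unlist(side$channel_order), c("ADC", "HBV", "T2"))
  expect_equal(side$patient_id, "P001")
})

test_that("resampling is identity on the same grid and exact for bilinear", {
  set.seed(1)
  ch <- volume_channel(array(rnorm(32), dim = c(2, 4, 4)), c(3, 1, 1),
                       channel = "ADC")
  same <- resample_to_reference(ch, c(3, 1, 1), c(2, 4, 4))
  expect_identical(same$values, ch$values)

  # 2x2 plane upsampled 2x: value at the cell midpoint is the 4-cell mean
  plane <- array(0, dim = c(1, 2, 2))
  plane[1, , ] <- matrix(c(0, 2, 2, 4), 2, 2, byrow = TRUE)
  ch2 <- volume_channel(plane, c(1, 2, 2), channel = "ADC")
  up <- resample_to_reference(ch2, c(1, 1, 1), c(1, 3, 3))
  expect_equal(up$values[1, 2, 2], 2.0)   # midpoint of [[0,2],[2,4]]

  # constants survive interpolation inside the source extent
  con <- volume_channel(array(5, dim = c(2, 8, 8)), c(3, 2, 2),
                        channel = "T2")
  re <- resample_to_reference(con, c(3, 1, 1), c(2, 15, 15))
  expect_true(all(abs(re$values - 5) < 1e-12))
})

test_that("translation rounds the offset difference to whole voxels", {
  set.seed(2)
  a <- array(rnorm(3 * 5 * 5), dim = c(3, 5, 5))
  ref <- volume_channel(a, c(3, 1, 1), origin = c(0, 0, 0), channel = "ADC")
  same <- volume_channel(a, c(3, 1, 1), origin = c(0, 0, 0), channel = "T2")
  expect_identical(align_translate(same, ref)$values, a)

  # exactly one voxel pitch in x: content shifts one column (a channel whose
  # origin sits one pitch to the left contributes its second column at the
  # reference origin)
  off <- volume_channel(a, c(3, 1, 1), origin = c(0, 0, -1), channel = "T2")
  sh <- align_translate(off, ref)
  expect_equal(sh$values[, , 1:4], a[, , 2:5])
  expect_true(all(sh$values[, , 5] == 0))

  # 0.4 voxel pitch rounds to zero shift
  off2 <- volume_channel(a, c(3, 1, 1), origin = c(0, 0, 0.4), channel = "T2")
  expect_identical(align_translate(off2, ref)$values, a)
})

test_that("assembly stacks identical grids unchanged in ADC, HBV, T2 order", {
  set.seed(3)
  mk <- function(ch) volume_channel(array(rnorm(36), dim = c(2, 3, 6)),
                                    c(3, 1, 1), channel = ch)
  adc <- mk("ADC"); hbv <- mk("HBV"); t2 <- mk("T2")
  cube <- assemble_hypercube(adc, hbv, t2)
  expect_equal(cube$values[, , , 1], adc$values)
  expect_equal(cube$values[, , , 2], hbv$values)
  expect_equal(cube$values[, , , 3], t2$values)
  expect_error(assemble_hypercube(adc, mk("ADC"), t2), "duplicate")
})

test_that("the coarsest in-plane grid is the assembly reference", {
  set.seed(4)
  adc <- volume_channel(array(rnorm(2 * 8 * 8), dim = c(2, 8, 8)),
                        c(3, 2, 2), channel = "ADC")
  hbv <- volume_channel(array(rnorm(2 * 8 * 8), dim = c(2, 8, 8)),
                        c(3, 2, 2), channel = "HBV")
  t2 <- volume_channel(array(rnorm(2 * 32 * 32), dim = c(2, 32, 32)),
                       c(3, 0.5, 0.5), channel = "T2")
  cube <- assemble_hypercube(adc, hbv, t2)
  expect_equal(dim(cube$values)[1:3], c(2L, 8L, 8L))
  expect_equal(cube$spacing, c(3, 2, 2))
  expect_equal(cube$values[, , , 1], adc$values)
})

test_that("re-assembling a hypercube from its own channels changes nothing", {
  set.seed(5)
  cube <- hypercube(array(rnorm(2 * 4 * 4 * 3), dim = c(2, 4, 4, 3)))
  chans <- bpscr:::hypercube_channels(cube)
  again <- assemble_hypercube(chans[[1]], chans[[2]], chans[[3]])
  expect_equal(again$values, cube$values)
})

test_that("a too-small mask rejects the patient", {
  f <- tempfile(fileext = ".nii.gz")
  m <- array(0, dim = c(3, 6, 6)); m[2, 3, 3] <- 1
  write_channel_nifti(m, f, spacing = c(3, 1, 1))
  expect_error(load_mask(f), class = "bpscr_reject")
})
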