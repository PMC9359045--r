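test_that("downscaling a constant volume returns the constant at the reduced size", {
  v <- array(5, c(8, 8, 4))
  out <- downscale_volume(v, 2)
  expect_identical(dim(out), c(4L, 4L, 4L))
  expect_true(all(abs(out - 5) < 1e-12))
  expect_identical(dim(downscale_volume(array(0, c(12, 12, 3)), 4)), c(3L, 3L, 3L))
  # non-divisible shapes resample to ceiling(n / factor)
  expect_identical(dim(downscale_volume(array(1, c(9, 7, 2)), 2)), c(5L, 4L, 2L))
  expect_error(downscale_volume(v, 0), "positive integer")
  expect_error(downscale_volume(v, -2), "positive integer")
})

test_that("mask downscaling stays binary and roughly conserves in-plane area", {
  # sphere of radius 10 voxels in a 64^3 grid
  co <- (1:64) - 32.5
  r2 <- outer(outer(co^2, co^2, "+"), co^2, "+")
  sphere <- (r2 <= 100) * 1
  small <- downscale_volume(sphere, 2, mask = TRUE)
  expect_true(all(small %in% c(0, 1)))
  # in-plane downscale by 2 quarters the per-slice area; z is untouched
  expect_lt(abs(sum(small) - sum(sphere) / 4) / (sum(sphere) / 4), 0.15)
})

test_that("min-max normalization is exact, invertible, and rejects constants", {
  r <- minmax_normalize(array(c(0, 35, 70), c(3, 1, 1)))
  expect_equal(as.vector(r$values), c(0, 0.5, 1))
  expect_equal(c(r$min, r$max), c(0, 70))

  v01 <- array(seq(0, 1, length.out = 8), c(2, 2, 2))
  r01 <- minmax_normalize(v01)
  expect_equal(r01$values, v01)
  expect_equal(c(r01$min, r01$max), c(0, 1))

  set.seed(4)
  v <- array(rnorm(64, 50, 20), c(4, 4, 4))
  r2 <- minmax_normalize(v)
  expect_identical(min(r2$values), 0)
  expect_identical(max(r2$values), 1)
  back <- minmax_denormalize(r2$values, r2$min, r2$max)
  expect_lt(max(abs(back - v)) / max(abs(v)), 1e-12)

  expect_error(minmax_normalize(array(3, c(2, 2, 2))), "degenerate")
})

test_that("channel assembly stacks normalized CT plus masks and is invertible", {
  case <- toy_case()
  x <- assemble_channels(case, c("PTV", "spinal_cord"))
  expect_identical(dim(x), c(dim(case$ct), 3L))
  expect_equal(x[, , , 1], minmax_normalize(case$ct)$values)
  # extracting a mask channel recovers the mask exactly
  expect_identical(x[, , , 2], case$structures$masks$PTV)
  expect_identical(x[, , , 3], case$structures$masks$spinal_cord)

  x0 <- assemble_channels(case, character())
  expect_identical(dim(x0), c(dim(case$ct), 1L))

  # an absent structure becomes an all-zero channel; others are untouched
  x2 <- assemble_channels(case, c("PTV", "larynx", "spinal_cord"))
  expect_true(all(x2[, , , 3] == 0))
  expect_identical(x2[, , , 4], case$structures$masks$spinal_cord)

  expect_error(assemble_channels(case, c("PTV", "PTV")), "duplicate")
})

test_that("NIfTI case round trip is lossless for values, masks and spacing", {
  case <- toy_case(seed = 9)
  dir <- withr::local_tempdir()
  write_nifti_case(case, dir)
  back <- read_nifti_case(dir)
  expect_equal(back$ct, case$ct)
  expect_equal(back$reference_dose$values, case$reference_dose$values)
  expect_identical(back$structures$masks$PTV, case$structures$masks$PTV)
  expect_true(all(back$structures$masks$spinal_cord %in% c(0, 1)))
  expect_equal(back$spacing, case$spacing)
  expect_equal(back$prescription, case$prescription)
  expect_identical(unname(back$structures$roles["spinal_cord"]), "oar")
})

test_that("OpenKBP sparse CSV cases round-trip and carry the 70 Gy prescription", {
  g <- c(128L, 128L, 128L)
  ct <- array(0, g); dose <- array(0, g)
  ptv <- array(0, g); cord <- array(0, g)
  set.seed(2)
  vox <- cbind(sample(60, 40), sample(60, 40), sample(60, 40))
  ct[vox] <- round(runif(40, 10, 100), 3)
  dose[vox] <- round(runif(40, 0, 70), 3)
  ptv[vox[1:15, ]] <- 1
  cord[vox[30:40, ]] <- 1
  case <- plan_case(ct, structure_set(list(PTV = ptv, SpinalCord = cord)),
                    dose_volume(dose), prescription = 70, case_id = "pt_001")
  dir <- withr::local_tempdir()
  write_openkbp_case(case, dir)
  back <- read_openkbp_case(dir)
  expect_equal(back$ct, case$ct)
  expect_equal(back$reference_dose$values, case$reference_dose$values)
  expect_identical(back$structures$masks$PTV, ptv)
  expect_equal(back$prescription, 70)
  expect_identical(unname(back$structures$roles["PTV"]), "target")
  expect_identical(unname(back$structures$roles["SpinalCord"]), "oar")

  # writing the reloaded case reproduces the sparse listings up to row order
  dir2 <- withr::local_tempdir()
  write_openkbp_case(back, dir2)
  for (f in list.files(dir)) {
    a <- read.csv(file.path(dir, f)); b <- read.csv(file.path(dir2, f))
    expect_equal(a[order(a[[1]]), , drop = FALSE], b[order(b[[1]]), , drop = FALSE],
                 ignore_attr = TRUE)
  }

  # a single listed voxel produces exactly one nonzero voxel
  dir3 <- withr::local_tempdir()
  writeLines(c("index,value", "0,1"), file.path(dir3, "ct.csv"))
  writeLines(c("index,value", "0,2"), file.path(dir3, "dose.csv"))
  writeLines(c("index", "0"), file.path(dir3, "m.csv"))
  one <- read_openkbp_case(dir3)
  expect_equal(sum(one$structures$masks$m != 0), 1)
  expect_equal(one$structures$masks$m[1, 1, 1], 1)

  writeLines(c("index", "99999999"), file.path(dir3, "m.csv"))
  expect_error(read_openkbp_case(dir3), "out of range")
})

test_that("volume and case constructors enforce their invariants", {
  expect_error(dose_volume(array(-1, c(2, 2, 2))), "non-negative")
  expect_error(dose_volume(array(0.5, c(2, 2, 2)), normalized = TRUE), "range")
  expect_error(structure_set(list(a = array(2, c(2, 2, 2)))), "outside")
  case <- toy_case()
  expect_error(plan_case(case$ct, case$structures, case$reference_dose, -1),
               "prescription")
  bad <- dose_volume(array(1, c(3, 3, 3)))
  expect_error(plan_case(case$ct, case$structures, bad, 70), "share one grid")
})
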