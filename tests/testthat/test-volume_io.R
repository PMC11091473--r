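# Volume containers, TIFF and raw binary round trips, displacement CSVs.

test_that("oct_volume validates its invariants", {
  expect_error(oct_volume(array(1, c(4, 16, 16))), ">= 8")
  bad <- array(1, c(8, 16, 16)); bad[2, 3, 4] <- NaN
  expect_error(oct_volume(bad), "non-finite")
  v <- oct_volume(array(runif(8 * 16 * 16), c(8, 16, 16)), pitch_depth = 3.2)
  expect_identical(dim(v$data), c(8L, 16L, 16L))
  expect_identical(dim(get_frame(v, 3)), c(16L, 16L))
  expect_identical(dim(enface_projection(v)), c(8L, 16L))
})

test_that("volume_set requires identical member shapes", {
  a <- oct_volume(array(runif(8 * 8 * 8), c(8, 8, 8)))
  b <- oct_volume(array(runif(8 * 8 * 16), c(8, 8, 16)))
  expect_error(volume_set(list(a, b)), "identical")
  vs <- volume_set(list(a, a), reference_index = 1L)
  expect_identical(length(vs), 2L)
})

test_that("TIFF round trip preserves data and sidecar metadata", {
  dir <- withr::local_tempdir()
  arr <- array(sample(0:4095, 16 * 32 * 32, replace = TRUE), c(16, 32, 32))
  v <- oct_volume(arr, pitch_slow = 6, pitch_depth = 3.2, pitch_fast = 9.7,
                  modality = "OCTA", id = "rt")
  path <- file.path(dir, "vol.tif")
  save_volume(v, path)
  w <- load_volume(path)
  expect_identical(w$data, v$data)  # bit-exact for integer-valued data
  expect_identical(c(w$pitch_slow, w$pitch_depth, w$pitch_fast), c(6, 3.2, 9.7))
  expect_identical(w$modality, "OCTA")

  vf <- oct_volume(array(rnorm(8 * 16 * 16), c(8, 16, 16)))
  pf <- file.path(dir, "volf.tif")
  save_volume(vf, pf)
  wf <- load_volume(pf)
  expect_equal(wf$data, vf$data, tolerance = 1e-6)  # float32 precision
})

test_that("raw round trip restores canonical order from any on-disk axis order", {
  dir <- withr::local_tempdir()
  arr <- array(runif(12 * 16 * 20), c(12, 16, 20))
  v <- oct_volume(arr, pitch_slow = 1, pitch_depth = 2, pitch_fast = 3)
  path <- file.path(dir, "vol.bin")
  save_volume(v, path, dtype = "float64")
  expect_identical(load_volume(path)$data, arr)

  # hand-write the same volume in (fast, depth, slow) order, C layout
  perm <- aperm(arr, c(3, 2, 1))
  p2 <- file.path(dir, "perm.bin")
  writeBin(as.numeric(aperm(perm, 3:1)), p2, size = 8, endian = "little")
  jsonlite::write_json(
    list(dtype = "float64", shape = dim(perm),
         axis_order = c("fast", "depth", "slow"), pitch_um = c(3, 2, 1)),
    file.path(dir, "perm.json"), auto_unbox = TRUE, digits = NA)
  w <- load_volume(p2)
  expect_identical(w$data, arr)          # voxel (i,j,k) preserved
  expect_identical(w$pitch_depth, 2)
})

test_that("loader errors name the failure mode", {
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "orphan.bin")
  writeBin(rnorm(10), raw)
  expect_error(load_volume(raw), "sidecar")

  nan <- file.path(dir, "nan.bin")
  writeBin(c(1, NaN, rep(1, 8 * 8 * 8 - 2)), nan, size = 4, endian = "little")
  jsonlite::write_json(list(dtype = "float32", shape = c(8, 8, 8),
                            axis_order = c("slow", "depth", "fast")),
                       file.path(dir, "nan.json"), auto_unbox = TRUE)
  expect_error(load_volume(nan), "NaN")

  v <- oct_volume(array(runif(8^3), c(8, 8, 8)))
  expect_error(save_volume(v, "/nonexistent-dir-xyz/out.tif"), "not writable")
})

test_that("displacement field CSV round trips", {
  f <- displacement_field(dx = c(1, -2, 0), dy = c(0, 1, -1), dz = c(3, 0, 0),
                          valid = c(TRUE, FALSE, TRUE),
                          source = c("matched", "interpolated", "matched"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_field_csv(f, path)
  g <- read_field_csv(path)
  expect_identical(as.data.frame(g), as.data.frame(f))
})
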