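# Stage-2 coarse-to-fine B-scan registration and field application.

make_pair <- function(trace_fn, seed = 20, shape = c(48L, 64L, 64L), speckle = 0) {
  tpl <- generate_phantom(phantom_params(shape = shape, speckle_variance = 0,
                                         seed = seed))
  tr <- trace_fn(shape[1])
  tgt <- corrupt(tpl, tr, seed = seed + 1, speckle_variance = speckle)$volume
  list(ref = tpl, tgt = tgt, tr = tr)
}

test_that("coarse_register reports a uniform displacement on every subvolume", {
  p <- make_pair(function(n) {
    tr <- zero_trace_n(n); tr$dx <- rep(6L, n); tr$dy <- rep(2L, n); tr
  })
  co <- coarse_register(p$ref, p$tgt, size = 8L)
  expect_true(all(abs(round(co$matches$dx) - 6) <= 1))
  expect_true(all(abs(round(co$matches$dy) - 2) <= 1))

  co0 <- coarse_register(p$ref, p$ref, size = 8L)
  expect_true(all(round(co0$matches$dx) == 0))
  expect_true(all(round(co0$matches$dy) == 0))
})

test_that("coarse_register interpolates degenerate subvolumes linearly", {
  p <- make_pair(function(n) {
    tr <- zero_trace_n(n)
    tr$dx <- c(rep(4L, n / 2), rep(6L, n / 2))  # piecewise lateral offset
    tr
  })
  # blank the middle subvolume (frames 17..24 of 48 at size 8 -> block 3)
  p$tgt$data[17:24, , ] <- 0
  co <- coarse_register(p$ref, p$tgt, size = 8L)
  expect_false(co$matches$valid[3])
  expect_equal(co$matches$dx[3], 5, tolerance = 1)  # between 4 and 6
})

test_that("fine_register matches a smooth drift without exclusions", {
  p <- make_pair(function(n) drift_trace(n, seed = 77, amp_dx = 2, amp_dy = 1),
                 speckle = 0.05)
  co <- coarse_register(p$ref, p$tgt)
  f <- fine_register(p$ref, p$tgt, co, tolerance_px = 4L)
  expect_true(mean(f$source == "matched") > 0.9)
  exp <- trace_expected_corrections(p$tr)
  ok <- f$valid & !is.na(exp$dx)
  expect_lte(rms(f$dx[ok], exp$dx[ok]), 1)
})

test_that("fine_register excludes a spurious jump and reconstructs it by interpolation", {
  p <- make_pair(function(n) zero_trace_n(n), speckle = 0.05)
  # one frame given a spurious +9 px lateral shift
  p$tgt$data[25, , ] <- octreg3d:::shift_matrix(p$tgt$data[25, , ], dc = 9)
  co <- coarse_register(p$ref, p$tgt)
  f <- fine_register(p$ref, p$tgt, co, tolerance_px = 4L)
  expect_false(f$valid[25])
  expect_identical(f$source[25], "interpolated")
  expect_lte(abs(f$dx[25]), 1)  # reconstructed from zero-shift neighbors
  # the exclusion rule itself: no matched frame's shift deviates from both
  # neighbors by more than the tolerance
  midx <- which(f$source == "matched")
  for (k in seq_along(midx)) {
    i <- midx[k]
    devs <- c()
    if (k > 1) devs <- c(devs, max(abs(f$dx[i] - f$dx[midx[k - 1]]),
                                   abs(f$dy[i] - f$dy[midx[k - 1]])))
    if (k < length(midx)) devs <- c(devs, max(abs(f$dx[i] - f$dx[midx[k + 1]]),
                                              abs(f$dy[i] - f$dy[midx[k + 1]])))
    expect_true(min(devs) <= 4)
  }
})

test_that("fine_register on identical volumes yields the zero field", {
  tpl <- generate_phantom(phantom_params(shape = c(48L, 64L, 64L),
                                         speckle_variance = 0, seed = 21))
  co <- coarse_register(tpl, tpl)
  f <- fine_register(tpl, tpl, co)
  expect_true(all(f$dx == 0L))
  expect_true(all(f$dy == 0L))
  expect_true(all(f$source == "matched"))
})

test_that("apply_field implements shifts, reassignment, collisions and gaps", {
  v <- generate_phantom(phantom_params(shape = c(16L, 24L, 24L),
                                       speckle_variance = 0, seed = 22))
  n <- 16L
  zero <- displacement_field(dx = integer(n), dy = integer(n))
  expect_identical(apply_field(v, zero)$data, v$data)

  uni <- displacement_field(dx = rep(6L, n), dy = rep(2L, n), dz = rep(0L, n))
  out <- suppressWarnings(apply_field(v, uni))
  # interior equals a rigid translation of the input (the last slow position
  # collects the clamped out-of-bounds frames and is excluded)
  for (i in 3:13)
    expect_equal(out$data[i + 2, , ], octreg3d:::shift_matrix(v$data[i, , ], dc = 6))

  # frames 4 and 5 both map to slow position 5: contributors averaged
  dy <- integer(n); dy[4] <- 1L
  col <- apply_field(v, displacement_field(dx = integer(n), dy = dy))
  expect_equal(col$data[5, , ], (v$data[4, , ] + v$data[5, , ]) / 2)
  # vacated position 4 interpolated between frames 3 and 5
  expect_equal(col$data[4, , ], (col$data[3, , ] + col$data[5, , ]) / 2)
})

test_that("coarse-to-fine recovers a combined drift+saccade trace end to end", {
  p <- phantom_params(shape = c(64L, 96L, 96L), speckle_variance = 0.05, seed = 33)
  ens <- make_ensemble(p, n = 2, motion_model = "combined")
  cfg <- default_config()
  cfg$stages$affine <- FALSE
  cfg$stages$axial_motion <- FALSE
  res <- suppressWarnings(register_volume(ens$volumes$volumes[[1]],
                                          ens$volumes$volumes[[2]], cfg))
  exp <- trace_expected_corrections(ens$traces[[2]])
  ok <- res$totals$valid & !is.na(exp$dx)
  expect_gt(sum(ok), 20)
  pooled <- sqrt(mean(c(res$totals$dx[ok] - exp$dx[ok],
                        res$totals$dy[ok] - exp$dy[ok],
                        res$totals$dz[ok] - exp$dz[ok])^2))
  # smoke-level bound for a single ensemble; the rigorous aggregate bound
  # over ten ensembles lives in the acceptance tests
  expect_lte(pooled, 1.5)
})
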