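# Phantom generator, motion traces, corruption operator, ensembles.

test_that("generate_phantom is deterministic and honors its parameters", {
  p <- small_params(seed = 80)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$data, b$data)

  clean <- generate_phantom(phantom_params(shape = c(48L, 64L, 64L),
                                           speckle_variance = 0, seed = 80))
  expect_identical(clean$data, attr(clean, "template"))

  expect_error(phantom_params(vessel_density = 0.7), "vessel_density")
  expect_error(phantom_params(shape = c(4, 64, 64)), ">= 8")
})

test_that("vessel pattern reaches the requested en-face density", {
  for (seed in 1:3) {
    v <- generate_phantom(phantom_params(shape = c(64L, 96L, 96L),
                                         vessel_density = 0.1,
                                         speckle_variance = 0, seed = seed))
    expect_lte(abs(mean(attr(v, "vessel_mask")) - 0.1), 0.02)
  }
})

test_that("the vitreous band is dark and structureless", {
  v <- generate_phantom(phantom_params(shape = c(32L, 64L, 64L),
                                       speckle_variance = 0, seed = 81))
  band <- attr(v, "vitreous_band")
  slab <- v$data[, band[1]:band[2], ]
  expect_true(all(slab == slab[1]))
  expect_lt(slab[1], 0.1)
})

test_that("corrupt applies the sampling model exactly and validates traces", {
  tpl <- generate_phantom(phantom_params(shape = c(24L, 48L, 48L),
                                         speckle_variance = 0, seed = 82))
  expect_identical(corrupt(tpl, zero_trace_n(24))$volume$data, tpl$data)

  tr <- zero_trace_n(24)
  tr$dx <- rep(3L, 24); tr$dy <- rep(-2L, 24); tr$dz <- rep(4L, 24)
  out <- corrupt(tpl, tr)$volume
  for (p in 3:22)
    expect_identical(out$data[p, , ],
                     octreg3d:::shift_matrix(tpl$data[p + 2, , ], dr = 4, dc = 3))

  bad <- zero_trace_n(24); bad$dx <- rep(40L, 24)
  expect_error(corrupt(tpl, bad), "exceed")
  expect_error(corrupt(tpl, zero_trace_n(10)), "length")
})

test_that("corrupt and apply_field with the negated trace are mutually inverse", {
  tpl <- generate_phantom(phantom_params(shape = c(24L, 48L, 48L),
                                         speckle_variance = 0, seed = 83))
  tr <- drift_trace(24, seed = 84, amp_dx = 3, amp_dy = 0, amp_dz = 3)
  out <- corrupt(tpl, tr)$volume
  field <- displacement_field(dx = -tr$dx, dy = -tr$dy, dz = -tr$dz)
  rec <- apply_field(out, field)
  # exact recovery away from the zero-filled borders
  interior_d <- 8:40; interior_f <- 8:40
  expect_identical(rec$data[, interior_d, interior_f],
                   tpl$data[, interior_d, interior_f])
})

test_that("motion_trace presets carry their advertised structure", {
  tr <- motion_trace(64, "saccades", seed = 85)
  expect_gte(length(tr$saccade_frames), 1)
  expect_lte(length(tr$saccade_frames), 3)
  jumps <- abs(tr$dx[tr$saccade_frames] -
               tr$dx[pmax(1, tr$saccade_frames - 1)])
  expect_true(all(jumps >= 3 & jumps <= 10))

  dr <- motion_trace(64, "drift_only", seed = 86)
  expect_length(dr$saccade_frames, 0)
  expect_true(all(abs(dr$dx) <= 4) && all(abs(dr$dy) <= 2))
  expect_true(all(dr$dz == 0))

  rot <- motion_trace(64, "rotation", seed = 87)
  expect_true(abs(rot$global_rotation_deg) >= 0.2 &&
              abs(rot$global_rotation_deg) <= 0.8)

  cw <- motion_trace(64, "tracked_warp", seed = 88)
  expect_false(is.null(cw$warp))

  cb <- motion_trace(64, "combined", seed = 89)
  expect_true(max(abs(cb$dz)) <= 6)
  expect_error(motion_trace(64, "nope", seed = 1), "unknown motion preset")
})

test_that("make_ensemble is reproducible with independent speckle per member", {
  p <- small_params(seed = 90)
  a <- make_ensemble(p, n = 3, motion_model = "drift_only")
  b <- make_ensemble(p, n = 3, motion_model = "drift_only")
  expect_identical(a$volumes$volumes[[2]]$data, b$volumes$volumes[[2]]$data)
  expect_false(identical(a$volumes$volumes[[2]]$data, a$volumes$volumes[[3]]$data))
  expect_length(a$traces, 3)
  expect_true(all(a$traces[[1]]$dx == 0L))  # member 1 is the clean acquisition
  expect_error(make_ensemble(p, n = 1), "n >= 2")
  expect_error(make_ensemble(p, n = 2, motion_model = "bogus"), "unknown")
})
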