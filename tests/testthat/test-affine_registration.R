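# Stage-3 strip-wise rotation estimation and application.

test_that("apply_strip_rotations with a zero plan is the identity", {
  v <- generate_phantom(phantom_params(shape = c(32L, 48L, 48L),
                                       speckle_variance = 0, seed = 40))
  plan <- structure(list(n_strips = 4L, strips = split(1:32, rep(1:4, each = 8)),
                         angles = rep(0, 4), cc_at_optimum = rep(1, 4),
                         upsample_factor = 1L, max_deg = 1),
                    class = "strip_rotation_plan")
  expect_identical(apply_strip_rotations(v, plan)$data, v$data)
})

test_that("the same 2D transform is applied at every depth index", {
  v <- generate_phantom(phantom_params(shape = c(32L, 48L, 48L),
                                       speckle_variance = 0, seed = 41))
  # make two depth layers identical, then rotate; outputs must stay identical
  v$data[, 48, ] <- v$data[, 1, ]
  plan <- structure(list(n_strips = 4L, strips = split(1:32, rep(1:4, each = 8)),
                         angles = rep(0.6, 4), cc_at_optimum = rep(1, 4),
                         upsample_factor = 1L, max_deg = 1),
                    class = "strip_rotation_plan")
  out <- apply_strip_rotations(v, plan)
  expect_equal(out$data[, 48, ], out$data[, 1, ], tolerance = 1e-12)
})

test_that("estimated rotations recover injected global angles", {
  tpl <- generate_phantom(phantom_params(shape = c(64L, 96L, 96L),
                                         speckle_variance = 0, seed = 42))
  for (ang in c(-0.5, 0.2)) {
    tr <- zero_trace_n(64)
    tr$global_rotation_deg <- ang
    tgt <- corrupt(tpl, tr)$volume
    plan <- suppressWarnings(
      estimate_strip_rotations(tpl, tgt, n_strips = 8L, upsample_factor = 2L))
    expect_lte(abs(mean(plan$angles) + ang), 0.05)
  }
})

test_that("identical volumes give near-zero angles; saturation is flagged", {
  tpl <- generate_phantom(phantom_params(shape = c(32L, 48L, 48L),
                                         speckle_variance = 0, seed = 43))
  plan <- estimate_strip_rotations(tpl, tpl, n_strips = 4L)
  expect_true(all(abs(plan$angles) <= 0.03))

  tr <- zero_trace_n(32)
  tr$global_rotation_deg <- 2  # outside the +/-1 degree bracket
  tgt <- corrupt(tpl, tr)$volume
  warns <- capture_warnings(
    plan2 <- estimate_strip_rotations(tpl, tgt, n_strips = 4L))
  expect_true(any(grepl("bracket edge", warns)))
  expect_true(any(abs(plan2$angles) >= 0.9))
})

test_that("rotate then inverse-rotate recovers the volume within bilinear tolerance", {
  v <- generate_phantom(phantom_params(shape = c(32L, 48L, 48L),
                                       speckle_variance = 0, seed = 44))
  strips <- split(1:32, rep(1:4, each = 8))
  mkplan <- function(a) structure(
    list(n_strips = 4L, strips = strips, angles = rep(a, 4),
         cc_at_optimum = rep(1, 4), upsample_factor = 1L, max_deg = 1),
    class = "strip_rotation_plan")
  fwd <- apply_strip_rotations(v, mkplan(0.8))
  back <- apply_strip_rotations(fwd, mkplan(-0.8))
  interior <- back$data[3:30, , 5:44]
  ref <- v$data[3:30, , 5:44]
  expect_lte(mean(abs(interior - ref)), 0.02 * diff(range(v$data)))
})

test_that("bracketed search matches an exhaustive fine scan of the same objective", {
  tpl <- generate_phantom(phantom_params(shape = c(64L, 96L, 96L),
                                         speckle_variance = 0, seed = 45))
  tr <- zero_trace_n(64)
  tr$global_rotation_deg <- 0.4
  tgt <- corrupt(tpl, tr)$volume
  plan <- suppressWarnings(
    estimate_strip_rotations(tpl, tgt, n_strips = 8L, upsample_factor = 1L))
  # exhaustive 0.01-degree scan of the identical masked symmetric objective
  ref_ef <- enface_projection(tpl); ref_ef <- ref_ef - mean(ref_ef)
  tgt_ef <- enface_projection(tgt); tgt_ef <- tgt_ef - mean(tgt_ef)
  interior <- matrix(FALSE, 64, 96); interior[3:62, 3:94] <- TRUE
  for (s in c(2L, 5L)) {
    rows <- plan$strips[[s]]
    grid <- seq(-1, 1, by = 0.01)
    vals <- vapply(grid, function(a) {
      rr <- octreg3d:::rotate_strip(ref_ef, rows, -a / 2, 1L)
      rt <- octreg3d:::rotate_strip(tgt_ef, rows, a / 2, 1L)
      ok <- interior[rows, ] & attr(rr, "support") > 0.999 &
        attr(rt, "support") > 0.999
      octreg3d:::ncc(rr[ok], rt[ok])
    }, numeric(1))
    expect_lte(abs(plan$angles[s] - grid[which.max(vals)]), 0.02)
  }
})

test_that("affine registration never worsens en-face agreement with the reference", {
  p <- phantom_params(shape = c(64L, 96L, 96L), speckle_variance = 0.05, seed = 46)
  ens <- make_ensemble(p, n = 2, motion_model = "rotation")
  cfg <- default_config()
  cfg$stages$affine <- FALSE
  cfg$stages$axial_motion <- FALSE
  ref <- ens$volumes$volumes[[1]]
  res <- suppressWarnings(register_volume(ref, ens$volumes$volumes[[2]], cfg))
  before <- res$volume
  plan <- suppressWarnings(
    estimate_strip_rotations(ref, before, n_strips = 8L, upsample_factor = 2L))
  after <- apply_strip_rotations(before, plan)
  cc <- function(v) octreg3d:::ncc(enface_projection(ref), enface_projection(v))
  expect_gte(cc(after), cc(before) - 1e-6)
})
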