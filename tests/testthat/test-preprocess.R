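# Stage-1 preprocessing: intra-volume axial correction, quality ranking,
# transverse/nonrigid/axial alignment, motion detection and removal.

test_that("axial_motion_correct recovers an injected per-frame depth shift and is idempotent", {
  tpl <- generate_phantom(phantom_params(shape = c(32L, 64L, 48L),
                                         speckle_variance = 0, seed = 4))
  v <- oct_volume(tpl$data)
  amc_clean <- axial_motion_correct(v)
  base <- attr(amc_clean, "axial_shifts")$pass1

  corr <- v
  corr$data[10, , ] <- octreg3d:::shift_matrix(corr$data[10, , ], dr = 3)
  amc <- axial_motion_correct(corr)
  got <- attr(amc, "axial_shifts")$pass1
  # the injected +3 px shift is undone on top of the volume's own curvature
  expect_equal(got[10] - base[10], -3)

  again <- axial_motion_correct(amc)
  expect_true(all(attr(again, "axial_shifts")$pass1 == 0))
})

test_that("axial_motion_correct gives degenerate frames a zero shift and warns", {
  v <- generate_phantom(phantom_params(shape = c(16L, 32L, 32L),
                                       speckle_variance = 0, seed = 5))
  v$data[3, , ] <- 0.5
  expect_warning(out <- axial_motion_correct(v), "degenerate")
  # the frame pass assigns the constant frame no shift of its own (the
  # slow-section pass may still move its columns with their sections)
  expect_identical(attr(out, "axial_shifts")$pass1[3], 0L)
})

test_that("rank_volumes orders by corruption level and keeps stable ties", {
  tpl <- generate_phantom(phantom_params(shape = c(48L, 64L, 64L),
                                         speckle_variance = 0, seed = 3))
  saccade_copy <- function(n_sac, seed) {
    tr <- zero_trace_n(48)
    if (n_sac > 0) {
      octreg3d:::with_seed(seed, {
        starts <- sort(sample(5:40, n_sac))
        for (s in starts) {
          jump <- sample(c(-6L, 6L), 1)
          tr$dx[s:min(48, s + 2)] <- tr$dx[s:min(48, s + 2)] + jump
        }
      })
    }
    corrupt(tpl, tr, seed = seed, speckle_variance = 0.05)$volume
  }
  for (seed in c(210, 220, 230)) {
    vs <- volume_set(list(saccade_copy(0, seed + 1), saccade_copy(2, seed + 2),
                          saccade_copy(6, seed + 3)))
    r <- rank_volumes(vs)
    expect_identical(r$order[1], 1L)
    expect_identical(r$reference_index, 1L)
  }
  # lower speckle ranks first at zero motion
  noisy <- corrupt(tpl, zero_trace_n(48), seed = 9, speckle_variance = 0.1)$volume
  clean <- corrupt(tpl, zero_trace_n(48), seed = 10, speckle_variance = 0.01)$volume
  expect_identical(rank_volumes(volume_set(list(noisy, clean)))$order[1], 2L)
  # identical volumes keep input order
  same <- corrupt(tpl, zero_trace_n(48), seed = 5, speckle_variance = 0.05)$volume
  expect_identical(rank_volumes(volume_set(list(same, same)))$order, c(1L, 2L))
  expect_error(rank_volumes(volume_set(list(same))), "at least 2")
})

test_that("transverse_align undoes a rigid translation", {
  tpl <- generate_phantom(phantom_params(shape = c(32L, 48L, 48L),
                                         speckle_variance = 0, seed = 6))
  tr <- zero_trace_n(32)
  tr$dx <- rep(4L, 32)   # fast +4
  tr$dy <- rep(-3L, 32)  # slow -3
  tgt <- corrupt(tpl, tr)$volume
  out <- transverse_align(tpl, tgt)
  expect_identical(attr(out, "applied_shift"), c(fast = -4L, slow = 3L))
  res <- windowed_poc_shift(enface_projection(tpl), enface_projection(out))
  expect_identical(c(res$dx, res$dy), c(0L, 0L))

  idn <- transverse_align(tpl, tpl)
  expect_identical(attr(idn, "applied_shift"), c(fast = 0L, slow = 0L))
  flat <- oct_volume(array(1, c(8, 8, 8)) + 0)
  flat$data[] <- 1
  expect_warning(transverse_align(flat, flat), "degenerate")
})

test_that("nonrigid_enface_align recovers a smooth quadratic warp", {
  tpl <- generate_phantom(phantom_params(shape = c(48L, 64L, 64L),
                                         speckle_variance = 0, seed = 7))
  tr <- motion_trace(48, "tracked_warp", seed = 12)
  tr$dx[] <- 0L; tr$dy[] <- 0L  # isolate the warp
  tgt <- corrupt(tpl, tr)$volume
  out <- nonrigid_enface_align(tpl, tgt, grid = 16L)
  warp <- attr(out, "warp")
  expect_false(warp$fallback)
  # residual block displacements after alignment
  pr <- enface_projection(tpl); po <- enface_projection(out)
  resid <- c()
  for (r in seq(1, 33, by = 16)) for (cc in seq(1, 49, by = 16)) {
    br <- r:(r + 15); bc <- cc:(cc + 15)
    s <- windowed_poc_shift(pr[br, bc], po[br, bc], window = "hann")
    resid <- c(resid, abs(s$dx), abs(s$dy))
  }
  expect_lte(mean(resid), 1)
  # featureless target falls back to the rigid path
  flat <- oct_volume(array(0.5, c(48, 64, 64)))
  expect_warning(nonrigid_enface_align(tpl, flat, grid = 16L), "falling back")
})

test_that("axial_align estimates per-tile depth shifts against subvolume centers", {
  tpl <- generate_phantom(phantom_params(shape = c(40L, 64L, 64L),
                                         speckle_variance = 0, seed = 8))
  tgt <- tpl
  # +4 px axial shift on the left half of every frame
  for (i in 1:40) {
    half <- tgt$data[i, , 1:32]
    tgt$data[i, , 1:32] <- octreg3d:::shift_matrix(half, dr = 4)
  }
  res <- axial_align(tpl, tgt, subvolume_size = 10L, sub_bscan_width = 32L)
  expect_true(mean(res$plan$dz_map[, 1] == -4L) > 0.9)
  expect_true(mean(res$plan$dz_map[, 2] == 0L) > 0.9)

  res0 <- axial_align(tpl, tpl, subvolume_size = 10L, sub_bscan_width = 32L)
  expect_true(all(res0$plan$dz_map == 0L))
  # the center of a 10-frame block is its 6th member (0-based index 5)
  expect_identical(octreg3d:::center_index(10L), 6L)
})

test_that("detect_motion flags saccade boundaries with the +/-3 dilation", {
  tpl <- generate_phantom(phantom_params(shape = c(64L, 64L, 64L),
                                         speckle_variance = 0, seed = 9))
  clean <- corrupt(tpl, zero_trace_n(64), seed = 2, speckle_variance = 0.05)$volume
  m0 <- detect_motion(clean, threshold_px = 2L)
  expect_length(m0$flagged, 0)
  expect_length(m0$removed, 0)

  tr <- zero_trace_n(64)
  tr$dx[50:52] <- 5L  # jump enters at 50, reverts after 52
  tgt <- corrupt(tpl, tr, seed = 3, speckle_variance = 0.05)$volume
  m <- detect_motion(tgt, threshold_px = 2L)
  expect_true(any(m$flagged %in% 49:54))
  expect_true(all(unlist(lapply(m$flagged, function(i)
    max(1, i - 3):min(64, i + 3))) %in% m$removed))
  # threshold above the jump size flags nothing
  m2 <- detect_motion(tgt, threshold_px = 8L)
  expect_length(m2$flagged, 0)
})

test_that("remove_motion deletes flagged frames and preserves the rest bit-exactly", {
  v <- generate_phantom(small_params(seed = 10))
  mask <- structure(list(flagged = c(20L), removed = 17:23,
                         offsets = integer(48), kept_index_map = setdiff(1:48, 17:23),
                         threshold_px = 2L), class = "motion_mask")
  res <- remove_motion(v, mask)
  expect_identical(dim(res$volume$data)[1], 41L)
  expect_identical(res$kept_index_map, setdiff(1:48, 17:23))
  for (j in seq_along(res$kept_index_map))
    expect_identical(res$volume$data[j, , ], v$data[res$kept_index_map[j], , ])

  empty <- structure(list(flagged = integer(0), removed = integer(0),
                          offsets = integer(48), kept_index_map = 1:48,
                          threshold_px = 2L), class = "motion_mask")
  expect_identical(remove_motion(v, empty)$volume$data, v$data)

  big <- structure(list(flagged = 1L, removed = 1:34, offsets = integer(48),
                        kept_index_map = 35:48, threshold_px = 2L),
                   class = "motion_mask")
  expect_error(remove_motion(v, big), "> 50%")
})
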