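# Stage 1: intra-volume axial motion correction, quality-based reference
# ranking, inter-volume transverse alignment, optional nonrigid en-face
# alignment for motion-tracked systems, subvolume/sub-B-scan axial alignment,
# and automatic motion-artifact detection/removal.

#' Shift a volume's array by integer offsets along each axis, zero fill
#' @noRd
shift_volume_array <- function(arr, d_slow = 0L, d_depth = 0L, d_fast = 0L) {
  d <- dim(arr)
  out <- array(0, d)
  src <- function(n, dlt) {
    dst <- seq_len(n)
    s <- dst - as.integer(round(dlt))
    ok <- s >= 1L & s <= n
    list(dst = dst[ok], src = s[ok])
  }
  i1 <- src(d[1], d_slow); i2 <- src(d[2], d_depth); i3 <- src(d[3], d_fast)
  if (length(i1$dst) && length(i2$dst) && length(i3$dst))
    out[i1$dst, i2$dst, i3$dst] <- arr[i1$src, i2$src, i3$src]
  out
}

#' Cross-correlation row shift between two equally shaped matrices
#'
#' Plain (not phase-normalized) circular cross-correlation restricted to
#' shifts along rows; returns the target's displacement. Columnwise 1D FFTs
#' accumulated in double precision.
#' @noRd
row_shift_xcorr <- function(reference, target, max_shift = NULL) {
  r0 <- reference - mean(reference)
  t0 <- target - mean(target)
  cross <- rowSums(Conj(mvfft(r0)) * mvfft(t0))
  cc <- Re(fft(cross, inverse = TRUE)) / length(cross)
  dz_all <- wrap_shift(seq_along(cc) - 1L, nrow(reference))
  if (!is.null(max_shift)) cc[abs(dz_all) > max_shift] <- -Inf
  peak <- max(cc)
  cand <- which(cc >= peak - 1e-9 * max(1, abs(peak)))
  dz <- dz_all[cand]
  dz[order(abs(dz), dz)][1]
}

#' Depth displacement of `target` relative to `reference` by overlap-only
#' correlation: candidate integer row shifts are scored by the Pearson
#' correlation over the rows the two images share under that shift, so
#' zero-filled borders never bias the estimate. Ties break toward the
#' smallest |shift|.
#' @noRd
row_shift_overlap <- function(reference, target, max_shift) {
  nr <- nrow(reference)
  best_s <- 0L; best_cc <- -Inf
  for (s in 0:max_shift) for (sgn in if (s == 0L) 1L else c(1L, -1L)) {
    ss <- s * sgn
    rr <- max(1L, 1L + ss):min(nr, nr + ss)
    if (length(rr) < 8L) next
    cc <- ncc(reference[rr - ss, , drop = FALSE], target[rr, , drop = FALSE])
    if (cc > best_cc + 1e-12) { best_cc <- cc; best_s <- ss }
  }
  best_s
}

#' Intra-volume axial motion correction
#'
#' Two passes against the volume's own center frames. Pass 1: every fast
#' B-scan is shifted along depth (integer pixels, zero fill) to maximize
#' cross-correlation with the center fast B-scan. Pass 2: the same along the
#' slow direction, shifting each slow cross-section (fixed fast index) along
#' depth against the center slow cross-section. Center references are left
#' unshifted; constant (degenerate) frames get a zero shift and a warning.
#' The applied corrections are attached as attribute `axial_shifts`
#' (`pass1`: per slow index, `pass2`: per fast index).
#'
#' @param volume an [oct_volume].
#' @param logger optional logger from the pipeline; internal.
#' @return The corrected [oct_volume].
#' @export
axial_motion_correct <- function(volume, logger = NULL) {
  arr <- volume$data
  ns <- dim(arr)[1]; nf <- dim(arr)[3]
  # pass 1: fast B-scans (frames) against the center frame
  c1 <- center_index(ns)
  ref <- arr[c1, , ]
  pass1 <- integer(ns)
  for (i in seq_len(ns)) {
    if (i == c1) next
    frame <- arr[i, , ]
    if (sd(as.numeric(frame)) == 0 || sd(as.numeric(ref)) == 0) {
      warnf("axial_motion_correct: degenerate frame at slow index %d left unshifted", i)
      next
    }
    dz <- row_shift_xcorr(ref, frame, max_shift = dim(arr)[2] %/% 3L)
    if (dz != 0L) {
      pass1[i] <- -dz
      arr[i, , ] <- shift_matrix(frame, dr = -dz)
    }
  }
  # pass 2: slow cross-sections (fixed fast index) against the center one
  c2 <- center_index(nf)
  ref2 <- arr[, , c2]   # (slow, depth): depth along columns
  pass2 <- integer(nf)
  for (k in seq_len(nf)) {
    if (k == c2) next
    sec <- arr[, , k]
    if (sd(as.numeric(sec)) == 0 || sd(as.numeric(ref2)) == 0) {
      warnf("axial_motion_correct: degenerate slow section at fast index %d left unshifted", k)
      next
    }
    dz <- row_shift_xcorr(t(ref2), t(sec), max_shift = dim(arr)[2] %/% 3L)  # rows = depth after transpose
    if (dz != 0L) {
      pass2[k] <- -dz
      arr[, , k] <- t(shift_matrix(t(sec), dr = -dz))
    }
  }
  if (!is.null(logger))
    logger$log("axial_motion_correct[%s]: pass1 shifts %s; pass2 nonzero %d/%d",
               volume$id, paste(pass1, collapse = ","), sum(pass2 != 0), nf)
  out <- with_data(volume, arr)
  attr(out, "axial_shifts") <- list(pass1 = pass1, pass2 = pass2)
  out
}

# --- quality ranking --------------------------------------------------------

#' @noRd
quality_terms <- function(volume) {
  arr <- volume$data
  ns <- dim(arr)[1]
  # adjacent-frame correlation on layer-stripped frames (see prep_frame):
  # the laterally uniform layer pattern keeps raw B-scan pairs correlated
  # straight through a saccade, so it must not enter the motion metric
  prepped <- lapply(seq_len(ns), function(i) prep_frame(arr[i, , ]))
  adj <- vapply(seq_len(ns - 1L), function(i) ncc(prepped[[i]], prepped[[i + 1L]]),
                numeric(1))
  # lower decile of the adjacent-frame correlations: a handful of motion
  # breaks drags it down, while re-scanned (duplicated) lines — which
  # inflate the mean — leave it untouched
  motion <- as.numeric(quantile(adj, 0.1))
  v <- as.numeric(arr)
  # inverse coefficient of variation over the bright half: multiplicative
  # speckle widens a homogeneous region's spread in proportion to its mean,
  # so mu/sigma falls as noise grows regardless of overall gain
  bright <- v[v >= median(v)]
  snr <- if (sd(bright) > 0) mean(bright) / sd(bright) else mean(bright) / .Machine$double.eps
  ef <- enface_projection(volume)
  # clarity = typical fast-axis gradient energy of the projection: the
  # median is insensitive to the few strong artificial edges that motion
  # artifacts and shifted-border fill produce, which a mean would reward
  gy <- t(diff(t(ef)))
  sharp <- median(gy^2)
  c(motion_term = motion, snr_term = snr, sharpness_term = sharp)
}

#' Min-max normalize within the set; a term whose relative spread is below
#' 5% carries no real information and would only amplify noise to full
#' scale, so it is neutralized at 0.5 for every member.
#' @noRd
minmax_norm <- function(x) {
  rng <- range(x)
  scale_ref <- max(abs(median(x)), .Machine$double.eps)
  if (diff(rng) == 0 || diff(rng) / scale_ref < 0.05)
    return(rep(0.5, length(x)))
  (x - rng[1]) / diff(rng)
}

#' Rank volumes by quality and pick the reference
#'
#' Scores every member of the set on three ingredients: level of motion
#' (mean adjacent-frame normalized cross-correlation — saccades break
#' frame-to-frame similarity), an SNR proxy (mean of the top-decile voxel
#' intensities over the standard deviation of the bottom decile), and image
#' clarity (mean squared gradient of the en-face projection). Each term is
#' min-max normalized within the set and combined as
#' `0.5 * motion + 0.3 * snr + 0.2 * sharpness`; volumes are ranked from
#' highest to lowest total and the top-ranked volume becomes the reference.
#' Ties preserve the original list order.
#'
#' @param volumes a [volume_set] with at least 2 members.
#' @return A list with `order` (indices sorted best first),
#'   `reference_index` (= `order[1]`), and `scores` (per-volume data frame of
#'   raw terms, normalized terms and totals, in input order).
#' @export
rank_volumes <- function(volumes) {
  if (length(volumes) < 2L)
    stopf("rank_volumes needs at least 2 volumes (nothing to register)")
  terms <- t(vapply(volumes$volumes, quality_terms, numeric(3)))
  norm <- apply(terms, 2, minmax_norm)
  total <- 0.5 * norm[, 1] + 0.3 * norm[, 2] + 0.2 * norm[, 3]
  ord <- order(-total)  # stable: ties keep original order
  scores <- data.frame(
    volume = vapply(volumes$volumes, function(v) v$id, character(1)),
    motion_term = terms[, 1], snr_term = terms[, 2], sharpness_term = terms[, 3],
    motion_norm = norm[, 1], snr_norm = norm[, 2], sharpness_norm = norm[, 3],
    total = total)
  list(order = ord, reference_index = ord[1], scores = scores)
}

# --- inter-volume alignment -------------------------------------------------

#' Rigid transverse alignment of a target volume to a reference
#'
#' Estimates the `(dx, dy)` displacement between the two en-face mean
#' projections with Hann-windowed POC and rigidly shifts the target by the
#' negated estimate in the (fast, slow) plane, zero-filling vacated borders.
#' The applied shift is attached as attribute `applied_shift`
#' (`c(fast = ..., slow = ...)`). Degenerate (constant) projections pass the
#' volume through unchanged with a warning.
#'
#' @param reference,target [oct_volume]s of equal shape.
#' @param logger optional pipeline logger.
#' @return The aligned target [oct_volume].
#' @export
transverse_align <- function(reference, target, logger = NULL) {
  if (!identical(dim(reference$data), dim(target$data)))
    stopf("transverse_align requires equally shaped volumes")
  pr <- enface_projection(reference)
  pt <- enface_projection(target)
  if (sd(as.numeric(pr)) == 0 || sd(as.numeric(pt)) == 0) {
    warnf("transverse_align: degenerate en-face projection, passing through")
    out <- target
    attr(out, "applied_shift") <- c(fast = 0L, slow = 0L)
    return(out)
  }
  # candidate shifts from POC (precise) and plain cross-correlation (robust
  # when saccade-corrupted frames contaminate the projection); the winner is
  # whichever aligns the overlapping region best
  s_poc <- windowed_poc_shift(pr, pt, window = "hann")
  s_cc <- xcorr_shift(box3(pr), box3(pt),
                      dx_range = c(-ncol(pr) %/% 3L, ncol(pr) %/% 3L),
                      dy_range = c(-nrow(pr) %/% 3L, nrow(pr) %/% 3L))
  score <- function(s) overlap_ncc(pr, pt, s$dy, s$dx)
  s <- if (score(s_cc) > score(s_poc)) s_cc else s_poc
  applied <- c(fast = -s$dx, slow = -s$dy)
  arr <- shift_volume_array(target$data, d_slow = applied["slow"],
                            d_fast = applied["fast"])
  if (!is.null(logger))
    logger$log("transverse_align[%s]: applied shift fast %d, slow %d (peak %.3f)",
               target$id, applied["fast"], applied["slow"], s$peak)
  out <- with_data(target, arr)
  attr(out, "applied_shift") <- applied
  out
}

#' Nonrigid en-face alignment for motion-tracked acquisitions
#'
#' Commercial systems with active motion tracking rescan saccade-corrupted
#' locations, leaving smooth residual distortions rather than rigid offsets.
#' This stage estimates a smooth 2D warp between the en-face projections by
#' Hann-windowed POC on a regular grid of blocks, fits quadratic displacement
#' surfaces `d(slow, fast)` to the per-block shifts by least squares, and
#' resamples every depth layer of the target with the identical warp
#' (bilinear, zero fill). Degenerate or low-confidence blocks are dropped
#' from the fit; if more than half the blocks are unusable the warp falls
#' back to the global rigid shift with a warning.
#'
#' @param reference,target [oct_volume]s of equal shape (target already
#'   rigidly aligned).
#' @param grid block size in pixels (square blocks on the en-face grid).
#' @param logger optional pipeline logger.
#' @return The warped target [oct_volume] with attribute `warp` (list with
#'   per-pixel displacement matrices `d_slow`, `d_fast`, and `fallback`).
#' @export
nonrigid_enface_align <- function(reference, target, grid = 16L, logger = NULL) {
  if (!identical(dim(reference$data), dim(target$data)))
    stopf("nonrigid_enface_align requires equally shaped volumes")
  pr <- enface_projection(reference)
  pt <- enface_projection(target)
  ns <- nrow(pr); nf <- ncol(pr)
  rs <- seq(1L, ns - grid + 1L, by = grid)
  cs <- seq(1L, nf - grid + 1L, by = grid)
  obs <- list(); n_blocks <- 0L; n_bad <- 0L
  for (r in rs) for (c in cs) {
    n_blocks <- n_blocks + 1L
    br <- r:min(r + grid - 1L, ns); bc <- c:min(c + grid - 1L, nf)
    rb <- pr[br, bc]; tb <- pt[br, bc]
    if (sd(as.numeric(rb)) == 0 || sd(as.numeric(tb)) == 0) {
      n_bad <- n_bad + 1L; next
    }
    s <- windowed_poc_shift(rb, tb, window = "hann")
    if (s$peak < 0.05 || abs(s$dx) > grid / 2 || abs(s$dy) > grid / 2) {
      n_bad <- n_bad + 1L; next
    }
    obs[[length(obs) + 1L]] <- c(row = mean(br), col = mean(bc), dy = s$dy, dx = s$dx)
  }
  fallback <- n_bad > n_blocks / 2
  grid_r <- matrix(seq_len(ns), ns, nf)
  grid_c <- matrix(seq_len(nf), ns, nf, byrow = TRUE)
  if (fallback) {
    warnf("nonrigid_enface_align: %d/%d blocks degenerate, falling back to rigid shift",
          n_bad, n_blocks)
    rigid <- if (sd(as.numeric(pr)) > 0 && sd(as.numeric(pt)) > 0)
      windowed_poc_shift(pr, pt, window = "hann") else list(dx = 0L, dy = 0L)
    d_slow <- matrix(rigid$dy, ns, nf)
    d_fast <- matrix(rigid$dx, ns, nf)
  } else {
    ob <- do.call(rbind, obs)
    df <- data.frame(row = ob[, "row"], col = ob[, "col"],
                     dy = ob[, "dy"], dx = ob[, "dx"])
    fit_dy <- lm(dy ~ row + col + I(row^2) + I(col^2) + I(row * col), data = df)
    fit_dx <- lm(dx ~ row + col + I(row^2) + I(col^2) + I(row * col), data = df)
    newd <- data.frame(row = as.numeric(grid_r), col = as.numeric(grid_c))
    d_slow <- matrix(predict(fit_dy, newd), ns, nf)
    d_fast <- matrix(predict(fit_dx, newd), ns, nf)
  }
  # pull resampling: aligned(x) = target(x + d(x)), identical at every depth
  src_r <- grid_r + d_slow
  src_c <- grid_c + d_fast
  arr <- target$data
  out_arr <- array(0, dim(arr))
  for (z in seq_len(dim(arr)[2])) {
    layer <- arr[, z, ]  # (slow, fast)
    out_arr[, z, ] <- matrix(bilinear_sample(layer, src_r, src_c), ns, nf)
  }
  if (!is.null(logger))
    logger$log("nonrigid_enface_align[%s]: %d/%d blocks used%s, max |d| = %.2f px",
               target$id, n_blocks - n_bad, n_blocks,
               if (fallback) " (rigid fallback)" else "",
               max(abs(c(d_slow, d_fast))))
  out <- with_data(target, out_arr)
  attr(out, "warp") <- list(d_slow = d_slow, d_fast = d_fast, fallback = fallback)
  out
}

# --- axial alignment --------------------------------------------------------

#' Partition 1..n into blocks of `size`, merging a short tail
#'
#' A trailing block shorter than half the nominal size is merged into its
#' neighbor. Returns a list of index vectors.
#' @noRd
partition_indices <- function(n, size) {
  starts <- seq(1L, n, by = size)
  blocks <- lapply(starts, function(s) s:min(s + size - 1L, n))
  k <- length(blocks)
  if (k > 1L && length(blocks[[k]]) < size / 2) {
    blocks[[k - 1L]] <- c(blocks[[k - 1L]], blocks[[k]])
    blocks[[k]] <- NULL
  }
  blocks
}

#' Inter-volume axial alignment via subvolumes and sub-B-scans
#'
#' Both volumes are partitioned into subvolumes of `subvolume_size` fast
#' B-scans; the center frame of each reference subvolume serves as the local
#' reference (for a 10-frame subvolume, the frame at 0-based index 5). Every
#' target frame in the corresponding subvolume is split into sub-B-scans of
#' `sub_bscan_width` A-lines, and normalized cross-correlation on each
#' (depth x width) tile against the same tile of the local reference yields
#' the axial displacement; the
#' negated displacement is applied as an integer depth shift with zero fill.
#' Trailing partial subvolumes/sub-B-scans shorter than half the nominal
#' size are merged into their neighbor.
#'
#' @param reference,target [oct_volume]s of equal shape, already
#'   transversely aligned.
#' @param subvolume_size frames per subvolume (>= 3).
#' @param sub_bscan_width A-lines per sub-B-scan (>= 16).
#' @param logger optional pipeline logger.
#' @return A list with `volume` (the axially aligned target) and `plan` (an
#'   `axial_alignment_plan`: `dz_map` matrix of applied shifts per
#'   (frame, tile), the tile column ranges, and the parameters).
#' @export
axial_align <- function(reference, target, subvolume_size = 10L,
                        sub_bscan_width = 64L, logger = NULL) {
  if (!identical(dim(reference$data), dim(target$data)))
    stopf("axial_align requires equally shaped volumes")
  if (subvolume_size < 3L) stopf("subvolume_size must be >= 3")
  if (sub_bscan_width < 16L) stopf("sub_bscan_width must be >= 16")
  ns <- n_slow(target); nd <- n_depth(target); nf <- n_fast(target)
  blocks <- partition_indices(ns, as.integer(subvolume_size))
  tiles <- partition_indices(nf, as.integer(sub_bscan_width))
  dz_map <- matrix(0L, ns, length(tiles))
  arr <- target$data
  max_dz <- min(nd %/% 3L, 16L)
  tile_disp <- function(ref_tile, tile) {
    # depth displacement by overlap-only correlation: circular FFT
    # correlation lets the zero-filled border penalty outweigh a small
    # misalignment of the smooth axial profile, so each candidate shift is
    # scored on the rows both tiles actually share
    if (sd(as.numeric(ref_tile)) == 0 || sd(as.numeric(tile)) == 0) return(NA_integer_)
    row_shift_overlap(box3(ref_tile), box3(tile), max_dz)
  }
  for (blk in blocks) {
    ref_frame <- reference$data[blk[center_index(length(blk))], , ]
    for (i in blk) {
      frame <- arr[i, , ]
      for (t in seq_along(tiles)) {
        tc <- tiles[[t]]
        rt <- ref_frame[, tc]
        raw <- tile_disp(rt, frame[, tc])
        if (is.na(raw)) next
        # curvature compensation: the reference's own frame i is displaced
        # from the subvolume's center frame by the retina's geometry, not by
        # motion; that component must not enter the correction
        bias <- tile_disp(rt, reference$data[i, , tc])
        if (is.na(bias)) bias <- 0L
        dz <- -(raw - bias)
        if (abs(dz) > nd / 2) next
        if (dz != 0L) {
          frame[, tc] <- shift_matrix(frame[, tc], dr = dz)
          dz_map[i, t] <- dz
        }
      }
      arr[i, , ] <- frame
    }
  }
  if (!is.null(logger))
    logger$log("axial_align[%s]: %d subvolumes x %d tiles, mean |dz| = %.2f px",
               target$id, length(blocks), length(tiles), mean(abs(dz_map)))
  plan <- structure(list(subvolume_size = as.integer(subvolume_size),
                         sub_bscan_width = as.integer(sub_bscan_width),
                         dz_map = dz_map, tiles = tiles, blocks = blocks),
                    class = "axial_alignment_plan")
  list(volume = with_data(target, arr), plan = plan)
}

# --- motion detection / removal --------------------------------------------

#' Detect motion-corrupted frames by adjacent-frame offsets
#'
#' Starting at the center slow index and walking outward in both directions,
#' the fast-axis offset between each pair of adjacent fast B-scans is
#' located by normalized cross-correlation ([xcorr_shift()]; robust to the
#' independent speckle of neighboring B-scans); the outer frame of a pair
#' whose absolute offset reaches `threshold_px` is flagged as motion-corrupted
#' (microsaccades produce abrupt vessel displacement between consecutive
#' B-scans). The removal set dilates the flagged indices by 3 frames on
#' either side, clipped to the volume.
#'
#' @param volume an [oct_volume].
#' @param threshold_px integer offset threshold in pixels (default 2;
#'   1-pixel offsets are within POC quantization noise).
#' @param logger optional pipeline logger.
#' @return A `motion_mask`: list with `flagged`, `removed` (both sorted
#'   integer vectors of slow indices), `offsets` (per slow index, the
#'   adjacent-pair fast offset attributed to it), `kept_index_map` (original
#'   indices that survive removal) and `threshold_px`.
#' @export
detect_motion <- function(volume, threshold_px = 2L, logger = NULL) {
  arr <- volume$data
  ns <- dim(arr)[1]
  ctr <- center_index(ns)
  offsets <- integer(ns)
  nf <- dim(arr)[3]
  prep_det <- function(i) {
    f <- arr[min(max(i, 1L), ns), , ]
    if (sd(as.numeric(f)) == 0) return(NULL)
    m <- prep_frame(f)
    # clamp outliers: a saccade moves every pixel, so the broad texture must
    # outvote the few high-amplitude pixels of an individual vessel
    lim <- 1.5 * sd(as.numeric(m))
    pmin(pmax(m, -lim), lim)
  }
  # microsaccade amplitudes are bounded (~10 px at this field size); wider
  # windows only admit aliases of quasi-periodic vessel patterns
  rng <- c(-min(12L, nf %/% 4L), min(12L, nf %/% 4L))
  # candidate offset with a significance margin: the best off-zero peak must
  # beat the best near-zero correlation decisively, else weak-texture
  # near-ties trigger spurious offsets
  candidate <- function(a, b, margin) {
    if (is.null(a) || is.null(b)) return(NA_integer_)
    s <- xcorr_shift(a, b, dx_range = rng, dy_range = c(-5L, 5L))
    if (s$dx == 0L) return(0L)
    near <- xcorr_shift(a, b, dx_range = c(-1L, 1L), dy_range = c(-5L, 5L))
    if (s$peak - near$peak < margin) 0L else s$dx
  }
  est <- function(inner, outer) {
    step <- outer - inner
    stack2 <- function(i, j) {
      a <- prep_det(i); b <- prep_det(j)
      if (is.null(a) || is.null(b)) NULL else rbind(a, b)
    }
    # single-frame estimate first; if the local texture is too weak to
    # decide, fall back to 2-frame stacks on each side of the boundary
    # (double evidence, stricter margin)
    dx <- candidate(prep_det(inner), prep_det(outer), 0.04)
    if (is.na(dx)) return(0L)
    used_stack <- FALSE
    if (dx == 0L) {
      dx <- candidate(stack2(inner - step, inner), stack2(outer, outer + step),
                      0.06)
      if (is.na(dx) || dx == 0L) return(0L)
      used_stack <- TRUE
    }
    # separation-invariance guard: a rigid jump persists unchanged one frame
    # further across the boundary; a steep vessel whose crossing point
    # marches grows with separation, and single-frame vessel wobble decays
    a2 <- if (used_stack) stack2(inner - step, inner) else prep_det(inner)
    b2 <- if (used_stack) stack2(outer + step, outer + 2L * step)
          else prep_det(outer + step)
    if (!is.null(a2) && !is.null(b2)) {
      s2 <- xcorr_shift(a2, b2, dx_range = rng, dy_range = c(-5L, 5L))
      if (abs(s2$dx - dx) > 2L || abs(s2$dx) < threshold_px) return(0L)
    }
    dx
  }
  if (ctr < ns) for (i in (ctr + 1L):ns) offsets[i] <- est(i - 1L, i)
  if (ctr > 1L) for (i in (ctr - 1L):1L) offsets[i] <- est(i + 1L, i)
  # the outermost frames have no second neighbor on the far side, so their
  # offsets cannot be confirmed by the separation-invariance test
  offsets[c(1:3, (ns - 2L):ns)] <- 0L
  flagged <- which(abs(offsets) >= threshold_px)
  removed <- integer(0)
  if (length(flagged))
    removed <- sort(unique(unlist(lapply(flagged, function(i)
      max(1L, i - 3L):min(ns, i + 3L)))))
  if (!is.null(logger))
    logger$log("detect_motion[%s]: flagged %s; removed %d frames",
               volume$id,
               if (length(flagged)) paste(flagged, collapse = ",") else "none",
               length(removed))
  structure(list(flagged = flagged, removed = removed, offsets = offsets,
                 kept_index_map = setdiff(seq_len(ns), removed),
                 threshold_px = as.integer(threshold_px)),
            class = "motion_mask")
}

#' Remove motion-corrupted frames from a volume
#'
#' Deletes the frames in `mask$removed`; the returned `kept_index_map`
#' records each retained frame's original slow index so registration can
#' interpolate displacements across the gaps. Refuses to remove more than
#' half the volume.
#'
#' @param volume an [oct_volume].
#' @param mask a `motion_mask` from [detect_motion()].
#' @return A list with `volume` (frames deleted, retained frames bit
#'   identical to their source) and `kept_index_map`.
#' @export
remove_motion <- function(volume, mask) {
  ns <- n_slow(volume)
  removed <- mask$removed
  if (length(removed) && (any(removed < 1L) || any(removed > ns)))
    stopf("motion mask indices out of range for volume '%s'", volume$id)
  if (length(removed) > ns / 2)
    stopf("motion mask removes %d of %d frames (> 50%%); volume '%s' unusable",
          length(removed), ns, volume$id)
  keep <- setdiff(seq_len(ns), removed)
  out <- with_data(volume, volume$data[keep, , , drop = FALSE])
  list(volume = out, kept_index_map = keep)
}
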