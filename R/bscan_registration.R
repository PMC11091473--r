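# Stage 2: coarse subvolume matching on en-face projections, fine per-B-scan
# matching with tolerance-based outlier rejection, and application of the
# resulting displacement field.

#' Construct a displacement field
#'
#' Per slow index: `dx` (fast-axis correction), `dy` (slow reassignment:
#' frame `i` moves to reference position `i + dy[i]`), `dz` (depth
#' correction, carried from axial alignment for audit), a `valid` flag and
#' the provenance `source` (`matched`, `interpolated`, `extrapolated`).
#'
#' @param dx,dy,dz integer vectors of equal length.
#' @param valid logical vector; invalid matches never contribute raw values.
#' @param source character vector of provenance labels.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(dx, dy, dz = rep(0L, length(dx)),
                               valid = rep(TRUE, length(dx)),
                               source = rep("matched", length(dx))) {
  n <- length(dx)
  if (length(dy) != n || length(dz) != n || length(valid) != n || length(source) != n)
    stopf("displacement_field components must have equal length")
  if (!all(is.finite(dx)) || !all(is.finite(dy)))
    stopf("displacement_field requires finite (dx, dy) at every index")
  structure(list(dx = as.integer(round(dx)), dy = as.integer(round(dy)),
                 dz = as.integer(round(dz)), valid = as.logical(valid),
                 source = as.character(source)),
            class = "displacement_field")
}

#' @export
as.data.frame.displacement_field <- function(x, ...) {
  data.frame(slow_index = seq_along(x$dx), dx = x$dx, dy = x$dy, dz = x$dz,
             valid = x$valid, source = x$source)
}

#' @export
length.displacement_field <- function(x) length(x$dx)

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field over %d frames: %d matched, %d interpolated, %d extrapolated>\n",
              length(x$dx), sum(x$source == "matched"),
              sum(x$source == "interpolated"), sum(x$source == "extrapolated")))
  invisible(x)
}

# --- coarse stage -----------------------------------------------------------

#' Coarse subvolume registration on en-face projections
#'
#' The target volume is divided into evenly spaced subvolumes of `size`
#' sequential fast B-scans — small enough that motion within a subvolume is
#' negligible. Each subvolume's en-face strip is phase-correlated
#' (Hann-windowed POC) against the same rows of the reference volume's
#' en-face projection, yielding the per-subvolume displacement `(dx, dy)`;
#' `dy` identifies the best-matching reference subvolume (the one containing
#' the strip center minus `dy`). Displacements are bounded by half the strip
#' height along slow, which suffices after rigid transverse alignment. Depth
#' displacement is treated as negligible at this stage (the volumes are
#' axially aligned beforehand).
#' Subvolumes with degenerate projections are marked invalid and their
#' displacement is linearly interpolated from their neighbors, as are all
#' per-frame displacements between subvolume centers. If more than 20% of
#' subvolumes are invalid the matching is re-run at half the subvolume size.
#'
#' @param reference,target [oct_volume]s of equal shape, preprocessed.
#' @param size frames per subvolume (default 8, capped at 16).
#' @param logger optional pipeline logger.
#' @return A `subvolume_partition`: list with `size`, `starts`, `matches`
#'   (per-subvolume data frame: `start`, `center`, `dx`, `dy`, `peak`,
#'   `valid`, `ref_block`), `frame_dx`/`frame_dy` (per-frame linear
#'   interpolation of the subvolume displacements) and `ref_blocks` (the
#'   reference subvolume index per frame).
#' @export
coarse_register <- function(reference, target, size = 8L, logger = NULL) {
  if (!identical(dim(reference$data), dim(target$data)))
    stopf("coarse_register requires equally shaped volumes")
  size <- min(as.integer(size), 16L)
  ns <- n_slow(target)
  ref_ef <- enface_projection(reference)
  tgt_ef <- enface_projection(target)
  blocks <- partition_indices(ns, size)
  centers <- vapply(blocks, function(b) mean(b), numeric(1))
  m <- data.frame(start = vapply(blocks, min, numeric(1)), center = centers,
                  dx = NA_real_, dy = NA_real_, peak = NA_real_, valid = FALSE)
  # score a candidate strip displacement by the overlap correlation of the
  # target strip against the reference projection shifted accordingly
  strip_score <- function(rows, dy, dx) {
    src <- rows - dy
    ok <- src >= 1L & src <= ns
    if (sum(ok) < 3L) return(-1)
    overlap_ncc(ref_ef[src[ok], , drop = FALSE],
                tgt_ef[rows[ok], , drop = FALSE], 0L, dx)
  }
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]
    rs <- ref_ef[rows, , drop = FALSE]
    ts <- tgt_ef[rows, , drop = FALSE]
    if (sd(as.numeric(rs)) == 0 || sd(as.numeric(ts)) == 0) next
    # POC (precise) arbitrated against plain cross-correlation (robust to
    # speckle-dominated strips) by the overlap score
    s_poc <- windowed_poc_shift(rs, ts, window = "hann")
    half <- length(rows) %/% 2L
    s_cc <- xcorr_shift(box3(rs), box3(ts),
                        dx_range = c(-(ncol(rs) %/% 3L), ncol(rs) %/% 3L),
                        dy_range = c(-half, half))
    sc_cc <- strip_score(rows, s_cc$dy, s_cc$dx)
    sc_poc <- strip_score(rows, s_poc$dy, s_poc$dx)
    s <- if (sc_cc > sc_poc) s_cc else s_poc
    m$dx[b] <- s$dx; m$dy[b] <- s$dy
    m$peak[b] <- max(sc_cc, sc_poc)  # overlap score: comparable across strips
    m$valid[b] <- TRUE
  }
  if (sum(!m$valid) > length(blocks) / 5 && size > 4L) {
    if (!is.null(logger))
      logger$log("coarse_register[%s]: %d/%d subvolumes invalid, retrying at size %d",
                 target$id, sum(!m$valid), length(blocks), size %/% 2L)
    return(coarse_register(reference, target, size = size %/% 2L, logger = logger))
  }
  if (!any(m$valid))
    stopf("coarse_register: every subvolume degenerate for volume '%s'", target$id)
  # a strip whose POC peak falls far below its peers matched on corrupted or
  # blanked content; treat it as unmatched and interpolate instead
  if (sum(m$valid) > 2L) {
    weak <- m$valid & m$peak < 0.5 * median(m$peak[m$valid])
    if (any(weak) && sum(m$valid & !weak) >= 2L) {
      if (!is.null(logger))
        logger$log("coarse_register[%s]: %d weak subvolume(s) interpolated",
                   target$id, sum(weak))
      m$valid[weak] <- FALSE
    }
  }
  # fill invalid subvolumes and per-frame values by linear interpolation
  interp <- function(vals) {
    ok <- m$valid & !is.na(vals)
    approx(centers[ok], vals[ok], xout = seq_len(ns), rule = 2)$y
  }
  frame_dx <- interp(m$dx)
  frame_dy <- interp(m$dy)
  m$dx[!m$valid] <- approx(centers[m$valid], m$dx[m$valid], xout = centers[!m$valid], rule = 2)$y
  m$dy[!m$valid] <- approx(centers[m$valid], m$dy[m$valid], xout = centers[!m$valid], rule = 2)$y
  # reference subvolume matched to each target frame: content displaced by
  # dy sits at target position i, so it matches reference position i - dy
  ref_pos <- pmin(pmax(seq_len(ns) - round(frame_dy), 1L), ns)
  block_of <- integer(ns)
  for (b in seq_along(blocks)) block_of[blocks[[b]]] <- b
  ref_blocks <- block_of[ref_pos]
  m$ref_block <- block_of[pmin(pmax(round(centers - m$dy), 1L), ns)]
  if (!is.null(logger))
    logger$log("coarse_register[%s]: %d subvolumes of %d frames, dy range [%d, %d]",
               target$id, length(blocks), size, min(round(m$dy)), max(round(m$dy)))
  structure(list(size = size, starts = m$start, matches = m, blocks = blocks,
                 frame_dx = frame_dx, frame_dy = frame_dy,
                 ref_blocks = ref_blocks),
            class = "subvolume_partition")
}

# --- fine stage -------------------------------------------------------------

#' Preprocessed 3-frame stack around slow index i for fine matching
#'
#' Each frame gets 3x3 box smoothing (speckle suppression) and per-depth
#' row-mean removal (strips the laterally uniform layer pattern so vessels
#' and texture — the genuine lateral landmarks — drive the correlation);
#' the frame and its two slow neighbors are stacked row-wise so that a match
#' must be consistent over a 3-frame neighborhood, which stabilizes
#' weak-texture regions. Frames outside the volume contribute zeros.
#' @noRd
stack3 <- function(arr, i, ns) {
  zero <- matrix(0, dim(arr)[2], dim(arr)[3])
  one <- function(k) if (k >= 1L && k <= ns) prep_frame(arr[k, , ]) else zero
  rbind(one(i - 1L), one(i), one(i + 1L))
}

#' Fine per-B-scan registration with outlier rejection
#'
#' For every target fast B-scan the best-matching reference frame and
#' fast-axis shift are found at pixel precision by normalized
#' cross-correlation ([xcorr_shift()]) against each frame of the
#' coarse-matched reference subvolume (best frame = highest correlation
#' peak; the search space never widens to the full volume). Each frame's shift is
#' then compared with its adjacent frames': a frame whose `(dx, dy)` differs
#' from both neighbors by more than `tolerance_px` (Chebyshev distance;
#' boundary frames compare to their single neighbor) is presumed an improper
#' match, excluded, and reconstructed by linear interpolation (interior) or
#' extrapolation (ends); `source` labels record the provenance.
#'
#' @param reference,target [oct_volume]s of equal shape.
#' @param coarse a `subvolume_partition` from [coarse_register()].
#' @param tolerance_px adjacent-shift tolerance in pixels, in 3..5
#'   (default 4).
#' @param logger optional pipeline logger.
#' @return A `displacement_field` storing corrections: shifting frame `i` by
#'   `dx[i]` along fast and reassigning it to slow position `i + dy[i]`
#'   aligns it to the reference.
#' @export
fine_register <- function(reference, target, coarse, tolerance_px = 4L,
                          logger = NULL) {
  if (!identical(dim(reference$data), dim(target$data)))
    stopf("fine_register requires equally shaped volumes")
  if (tolerance_px < 3L || tolerance_px > 5L)
    warnf("tolerance_px %d outside the empirical 3..5 band", tolerance_px)
  ns <- n_slow(target)
  dx <- rep(NA_real_, ns); dy <- rep(NA_real_, ns); peak <- rep(NA_real_, ns)
  for (i in seq_len(ns)) {
    blk <- coarse$blocks[[coarse$ref_blocks[i]]]
    # a 2-frame margin around the matched subvolume keeps a frame whose true
    # counterpart sits just across the block boundary matchable
    cand <- max(1L, min(blk) - 2L):min(ns, max(blk) + 2L)
    frame <- target$data[i, , ]
    if (sd(as.numeric(frame)) == 0) next
    # refine around the coarse estimate: fast-axis search window centered on
    # the interpolated coarse displacement, depth window tight (volumes are
    # axially aligned)
    dx0 <- round(coarse$frame_dx[i])
    frame_s <- stack3(target$data, i, ns)
    if (sd(as.numeric(frame_s)) == 0) next
    best <- NULL
    for (j in cand) {
      rf <- stack3(reference$data, j, ns)
      if (sd(as.numeric(rf)) == 0) next
      s <- xcorr_shift(rf, frame_s, dx_range = c(dx0 - 12L, dx0 + 12L),
                       dy_range = c(-3L, 3L))
      if (is.null(best) || s$peak > best$peak) best <- list(j = j, s = s, peak = s$peak)
    }
    if (is.null(best)) next
    # the stack chooses the reference frame (slow matching benefits from
    # 3-frame coherence), but the lateral shift is re-estimated from the
    # single center frame so that one corrupted B-scan keeps its own
    # (excludable) shift instead of inheriting its neighbors' consensus
    fs <- prep_frame(frame)
    rf <- prep_frame(reference$data[best$j, , ])
    dx_i <- if (sd(as.numeric(fs)) > 0 && sd(as.numeric(rf)) > 0)
      xcorr_shift(rf, fs, dx_range = c(dx0 - 12L, dx0 + 12L),
                  dy_range = c(-3L, 3L))$dx
    else best$s$dx
    dx[i] <- -dx_i               # correction along fast
    dy[i] <- best$j - i          # reassignment to the matched reference frame
    peak[i] <- best$peak
  }
  matched <- !is.na(dx)
  # tolerance-based outlier rejection on the (dx, dy) pair
  excl <- logical(ns)
  dev <- function(i, j) max(abs(dx[i] - dx[j]), abs(dy[i] - dy[j]))
  midx <- which(matched)
  for (k in seq_along(midx)) {
    i <- midx[k]
    devs <- c(if (k > 1L) dev(i, midx[k - 1L]),
              if (k < length(midx)) dev(i, midx[k + 1L]))
    if (length(devs) && min(devs) > tolerance_px) excl[i] <- TRUE
  }
  # second pass: the adjacent-neighbor rule cannot see a short run of
  # consistently wrong matches, so shifts deviating from the running median
  # of the matched shifts by more than the tolerance are also excluded
  midx2 <- which(matched & !excl)
  if (length(midx2) >= 7L) {
    run_med <- function(v) {
      vapply(seq_along(v), function(k) {
        w <- max(1L, k - 3L):min(length(v), k + 3L)
        median(v[w])
      }, numeric(1))
    }
    med_dx <- run_med(dx[midx2]); med_dy <- run_med(dy[midx2])
    off <- pmax(abs(dx[midx2] - med_dx), abs(dy[midx2] - med_dy)) > tolerance_px
    excl[midx2[off]] <- TRUE
  }
  good <- matched & !excl
  n_bad <- sum(!good)
  if (n_bad > 0.6 * ns)
    stopf("fine_register: %d of %d frames excluded (> 60%%); registration failed for '%s'",
          n_bad, ns, target$id)
  if (n_bad > 0.3 * ns)
    warnf("fine_register: %d of %d frames excluded (> 30%%)", n_bad, ns)
  if (!any(good))
    stopf("fine_register: no valid matches for volume '%s'", target$id)
  source <- rep("matched", ns)
  gi <- which(good)
  bad <- which(!good)
  if (length(bad)) {
    source[bad] <- ifelse(bad < min(gi) | bad > max(gi), "extrapolated", "interpolated")
    dx[bad] <- approx(gi, dx[gi], xout = bad, rule = 2)$y
    dy[bad] <- approx(gi, dy[gi], xout = bad, rule = 2)$y
    if (!is.null(logger))
      logger$log("fine_register[%s]: excluded frames %s (tolerance %d px)",
                 target$id, paste(bad, collapse = ","), tolerance_px)
  }
  if (!is.null(logger))
    logger$log("fine_register[%s]: dx range [%d, %d], dy range [%d, %d], %d/%d matched",
               target$id, min(round(dx)), max(round(dx)),
               min(round(dy)), max(round(dy)), sum(good), ns)
  displacement_field(dx = round(dx), dy = round(dy),
                     valid = good, source = source)
}

# --- application ------------------------------------------------------------

#' Apply per-frame displacements to a volume array
#'
#' Shared by [apply_field()] (corrections) and the synthetic corruption
#' operator (ground-truth traces): frame `i` is shifted by (`dz[i]` along
#' depth, `dx[i]` along fast) with zero fill and reassigned to slow position
#' `i + dy[i]`. Out-of-bounds reassignments are clamped to the volume with a
#' warning; collisions are averaged; unfilled slow positions are linearly
#' interpolated between the nearest filled frames.
#' @noRd
apply_displacement_array <- function(arr, dx, dy, dz, warn_oob = TRUE) {
  d <- dim(arr); ns <- d[1]
  acc <- array(0, d)
  cnt <- numeric(ns)
  oob <- FALSE
  for (i in seq_len(ns)) {
    j <- i + as.integer(round(dy[i]))
    if (j < 1L || j > ns) { oob <- TRUE; j <- min(max(j, 1L), ns) }
    acc[j, , ] <- acc[j, , ] + shift_matrix(arr[i, , ], dr = dz[i], dc = dx[i])
    cnt[j] <- cnt[j] + 1
  }
  if (oob && warn_oob) warnf("apply_field: out-of-bounds slow reassignment clamped")
  filled <- which(cnt > 0)
  for (j in filled) if (cnt[j] > 1) acc[j, , ] <- acc[j, , ] / cnt[j]
  holes <- which(cnt == 0)
  for (j in holes) {
    lo <- filled[filled < j]; hi <- filled[filled > j]
    if (length(lo) && length(hi)) {
      a <- max(lo); b <- min(hi)
      w <- (j - a) / (b - a)
      acc[j, , ] <- (1 - w) * acc[a, , ] + w * acc[b, , ]
    } else if (length(lo)) {
      acc[j, , ] <- acc[max(lo), , ]
    } else if (length(hi)) {
      acc[j, , ] <- acc[min(hi), , ]
    }
  }
  acc
}

#' Apply a displacement field to a volume
#'
#' Each frame is shifted by its integer `(dx, dz)` inside the frame (zero
#' fill at vacated pixels) and reassigned to slow position `i + dy[i]`.
#' Frames colliding at one slow position are averaged; slow positions left
#' unfilled are linearly interpolated between the nearest filled frames;
#' out-of-bounds reassignments are clamped with a warning.
#'
#' @param target an [oct_volume].
#' @param field a [displacement_field()] covering every slow index.
#' @return The registered [oct_volume].
#' @export
apply_field <- function(target, field) {
  if (length(field) != n_slow(target))
    stopf("field covers %d frames but volume '%s' has %d",
          length(field), target$id, n_slow(target))
  arr <- apply_displacement_array(target$data, field$dx, field$dy, field$dz)
  with_data(target, arr)
}
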