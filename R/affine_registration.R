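# Stage 3: residual in-plane rotation correction. The en-face projections of
# the B-scan-registered target and the reference are divided into equally
# spaced slow-axis strips; each target strip is rotated by a bracketed search
# over a +/- 1 degree range until its normalized cross-correlation with the
# reference strip is maximal, and the per-strip angle is then applied at
# every depth index.

# strips are rotated with a margin of neighboring rows so boundary pixels
# sample real content instead of zero fill, then cropped back
STRIP_PAD <- 3L

#' @noRd
padded_rows <- function(rows, ns) max(1L, min(rows) - STRIP_PAD):min(ns, max(rows) + STRIP_PAD)

#' Rotate the strip `rows` of full-image `img` about the image centroid,
#' using STRIP_PAD rows of context, and return only the strip rows.
#' Attribute `support` carries the in-support sampling fraction per pixel.
#' @noRd
rotate_strip <- function(img, rows, deg, upsample) {
  ns <- nrow(img)
  prow <- padded_rows(rows, ns)
  ctr <- c((ns + 1) / 2 - min(prow) + 1, (ncol(img) + 1) / 2)
  rot <- rotate_enface(img[prow, , drop = FALSE], deg, upsample, ctr)
  supp <- attr(rot, "support")
  keep <- match(rows, prow)
  out <- rot[keep, , drop = FALSE]
  attr(out, "support") <- if (is.null(supp)) matrix(1, length(rows), ncol(img))
                          else supp[keep, , drop = FALSE]
  out
}

#' Estimate per-strip rotation angles
#'
#' En-face mean projections of both volumes are divided into `n_strips`
#' equally spaced slow-axis strips. For each strip, the rotation angle
#' maximizing the normalized cross-correlation between the rotated target
#' strip and the reference strip is found inside the bracket [-1, +1]
#' degrees (retinal inter-volume rotations are small): a coarse 0.1-degree
#' scan localizes the peak, then golden-section bracketing refines it to a
#' 0.02-degree terminal bracket. The search presumes the correlation is
#' unimodal near its peak, which the coarse scan protects in practice.
#' Strips are optionally upsampled by `upsample_factor` before rotation and
#' box-downsampled after, which reduces quantization of small angles (useful
#' for high-lateral-resolution data). If the best rotated correlation does
#' not exceed the unrotated correlation the strip keeps angle 0; degenerate
#' strips get angle 0 with a warning; an optimum pinned at the bracket edge
#' logs a warning (the true rotation likely exceeds 1 degree).
#'
#' @param reference,target [oct_volume]s of equal shape, target already
#'   B-scan registered.
#' @param n_strips number of strips (default 8); each strip must span at
#'   least 8 frames.
#' @param upsample_factor integer >= 1 (default 1; 2 mirrors the
#'   high-resolution refinement).
#' @param max_deg half-width of the search bracket in degrees (default 1).
#' @param logger optional pipeline logger.
#' @return A `strip_rotation_plan`: list with `n_strips`, `strips` (index
#'   vectors), `angles` (degrees, one per strip), `cc_at_optimum`,
#'   `upsample_factor`, `max_deg`.
#' @export
estimate_strip_rotations <- function(reference, target, n_strips = 8L,
                                     upsample_factor = 1L, max_deg = 1.0,
                                     logger = NULL) {
  if (!identical(dim(reference$data), dim(target$data)))
    stopf("estimate_strip_rotations requires equally shaped volumes")
  ns <- n_slow(target)
  n_strips <- as.integer(n_strips)
  if (ns %/% n_strips < 8L)
    stopf("n_strips = %d gives strips of %d frames; need >= 8", n_strips, ns %/% n_strips)
  # mean-centered projections: out-of-support pixels are filled at the mean
  # level instead of zero, so fill never masquerades as structure
  ref_ef <- enface_projection(reference)
  tgt_ef <- enface_projection(target)
  ref_ef <- ref_ef - mean(ref_ef)
  tgt_ef <- tgt_ef - mean(tgt_ef)
  nf <- ncol(ref_ef)
  # a 2-px frame around the full projection is excluded from the objective:
  # it holds the zero-fill of whatever resampling the volumes have already
  # been through, and a handful of fill pixels otherwise dominates the
  # correlation
  interior <- matrix(FALSE, ns, nf)
  interior[3:(ns - 2), 3:(nf - 2)] <- TRUE
  strips <- partition_indices(ns, ns %/% n_strips)
  angles <- numeric(length(strips))
  ccs <- numeric(length(strips))
  for (s in seq_along(strips)) {
    rows <- strips[[s]]
    rs <- ref_ef[rows, , drop = FALSE]
    ts <- tgt_ef[rows, , drop = FALSE]
    if (sd(as.numeric(rs)) == 0 || sd(as.numeric(ts)) == 0) {
      warnf("estimate_strip_rotations: degenerate strip %d, angle set to 0", s)
      angles[s] <- 0; ccs[s] <- 0
      next
    }
    strip_ok <- interior[rows, , drop = FALSE]
    # rotation about the full en-face centroid, so each strip's transform is
    # the exact restriction of a global in-plane rotation of the volume.
    # The candidate rotation is split half onto each side (reference by
    # -a/2, target by +a/2): both sides then carry identical resampling
    # blur at every candidate angle, which removes the blur-induced
    # shrinkage of the estimate toward zero. Correlation is evaluated only
    # over pixels sampled inside both supports.
    obj <- function(a) {
      rot_r <- rotate_strip(ref_ef, rows, -a / 2, upsample_factor)
      rot_t <- rotate_strip(tgt_ef, rows, a / 2, upsample_factor)
      ok <- strip_ok & attr(rot_r, "support") > 0.999 &
        attr(rot_t, "support") > 0.999
      if (sum(ok) < 64L) return(-1)
      ncc(rot_r[ok], rot_t[ok])
    }
    cc0 <- obj(0)  # baseline at angle 0 under the same masking
    # coarse 0.1-deg scan brackets the peak before golden-section refinement
    grid_a <- seq(-max_deg, max_deg, by = 0.1)
    vals <- vapply(grid_a, obj, numeric(1))
    k <- which.max(vals)
    lo <- grid_a[max(1L, k - 1L)]
    hi <- grid_a[min(length(grid_a), k + 1L)]
    gr <- (sqrt(5) - 1) / 2
    x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
    f1 <- obj(x1); f2 <- obj(x2)
    while (hi - lo > 0.02) {
      if (f1 < f2) {
        lo <- x1; x1 <- x2; f1 <- f2
        x2 <- lo + gr * (hi - lo); f2 <- obj(x2)
      } else {
        hi <- x2; x2 <- x1; f2 <- f1
        x1 <- hi - gr * (hi - lo); f1 <- obj(x1)
      }
    }
    a_best <- (lo + hi) / 2
    cc_best <- obj(a_best)
    if (cc_best <= cc0) { a_best <- 0; cc_best <- cc0 }
    if (abs(a_best) >= max_deg - 0.011)
      warnf("estimate_strip_rotations: strip %d optimum pinned at bracket edge (%.2f deg)",
            s, a_best)
    angles[s] <- a_best
    ccs[s] <- cc_best
  }
  if (!is.null(logger))
    logger$log("estimate_strip_rotations[%s]: angles [%s] deg",
               target$id, paste(sprintf("%.3f", angles), collapse = ", "))
  structure(list(n_strips = length(strips), strips = strips, angles = angles,
                 cc_at_optimum = ccs,
                 upsample_factor = as.integer(upsample_factor),
                 max_deg = max_deg),
            class = "strip_rotation_plan")
}

#' Apply a strip rotation plan to a volume
#'
#' Each strip's en-face rotation (about the full en-face centroid — so the
#' strip transforms are restrictions of one global in-plane rotation —
#' bilinear resampling, upsample/downsample per the plan) is applied
#' identically at every depth index; out-of-support pixels are zero-filled.
#' A zero angle leaves the strip bit-exact.
#'
#' @param target an [oct_volume].
#' @param plan a `strip_rotation_plan` from [estimate_strip_rotations()].
#' @return The rotated [oct_volume].
#' @export
apply_strip_rotations <- function(target, plan) {
  ns <- n_slow(target)
  if (!setequal(unlist(plan$strips), seq_len(ns)))
    stopf("rotation plan strips do not cover the volume's slow axis")
  arr <- target$data
  nd <- dim(arr)[2]
  for (s in seq_along(plan$strips)) {
    a <- plan$angles[s]
    if (a == 0) next
    rows <- plan$strips[[s]]
    prow <- padded_rows(rows, ns)
    ctr <- c((ns + 1) / 2 - min(prow) + 1, (dim(arr)[3] + 1) / 2)
    rotator <- make_rotator(length(prow), dim(arr)[3], a, plan$upsample_factor,
                            center = ctr)
    keep <- match(rows, prow)
    for (z in seq_len(nd)) {
      arr[rows, z, ] <- rotator(target$data[prow, z, , drop = TRUE])[keep, , drop = FALSE]
    }
  }
  with_data(target, arr)
}

#' @export
print.strip_rotation_plan <- function(x, ...) {
  cat(sprintf("<strip_rotation_plan: %d strips, angles [%s] deg, upsample x%d>\n",
              x$n_strips, paste(sprintf("%.3f", x$angles), collapse = ", "),
              x$upsample_factor))
  invisible(x)
}

#' Export a strip rotation plan to CSV
#'
#' Columns: `strip`, `start`, `end` (slow indices), `angle_deg`,
#' `cc_at_optimum`, `upsample_factor`.
#'
#' @param plan a `strip_rotation_plan`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_rotation_csv <- function(plan, path) {
  df <- data.frame(strip = seq_along(plan$strips),
                   start = vapply(plan$strips, min, numeric(1)),
                   end = vapply(plan$strips, max, numeric(1)),
                   angle_deg = plan$angles,
                   cc_at_optimum = plan$cc_at_optimum,
                   upsample_factor = plan$upsample_factor)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
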