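# Internal numeric helpers shared across modules: integer array shifts,
# circular shifts, normalized cross-correlation, bilinear resampling, and a
# minimal run logger.

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Shift a matrix by integer offsets with zero fill
#'
#' Positive `dr` moves content toward larger row indices, positive `dc`
#' toward larger column indices; vacated pixels are zero-filled (retinal
#' volumes are not periodic, so no wrap).
#' @noRd
shift_matrix <- function(m, dr = 0L, dc = 0L, fill = 0) {
  dr <- as.integer(round(dr)); dc <- as.integer(round(dc))
  nr <- nrow(m); nc <- ncol(m)
  if (abs(dr) >= nr || abs(dc) >= nc) return(matrix(fill, nr, nc))
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr
  ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Circular shift of a matrix (used by tests/oracles and FFT conventions)
#' @noRd
circshift_matrix <- function(m, dr = 0L, dc = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- ((as.integer(dr)) %% nr + nr) %% nr
  dc <- ((as.integer(dc)) %% nc + nc) %% nc
  idx_r <- ((seq_len(nr) - 1L - dr) %% nr) + 1L
  idx_c <- ((seq_len(nc) - 1L - dc) %% nc) + 1L
  m[idx_r, idx_c, drop = FALSE]
}

#' Pearson correlation of two matrices, guarded against zero variance
#' @noRd
ncc <- function(a, b) {
  av <- as.numeric(a); bv <- as.numeric(b)
  if (sd(av) == 0 || sd(bv) == 0) return(0)
  cor(av, bv)
}

#' Map raw FFT-correlation argmax coordinates to signed shifts
#'
#' Peaks beyond half the dimension are interpreted as negative shifts.
#' @noRd
wrap_shift <- function(idx0, n) {
  ifelse(idx0 > n / 2, idx0 - n, idx0)
}

#' Bilinear sample of matrix `m` at (fractional) row/col coordinate matrices
#'
#' Out-of-support coordinates return `fill`; `mask` additionally reports the
#' fraction of in-support weight per sample.
#' @noRd
bilinear_sample <- function(m, rows, cols, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- numeric(length(rows))
  wt  <- numeric(length(rows))
  for (dr in 0:1) {
    for (dc in 0:1) {
      rr <- r0 + dr; cc <- c0 + dc
      w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc & w > 0
      if (any(ok)) {
        val[ok] <- val[ok] + w[ok] * m[cbind(rr[ok], cc[ok])]
        wt[ok] <- wt[ok] + w[ok]
      }
    }
  }
  out <- ifelse(wt > 0.999, val, fill)
  attr(out, "support") <- wt
  out
}

#' Bilinear resize of a matrix to (nr, nc)
#' @noRd
bilinear_resize <- function(m, nr, nc) {
  sr <- nrow(m) / nr; sc <- ncol(m) / nc
  rows <- (seq_len(nr) - 0.5) * sr + 0.5
  cols <- (seq_len(nc) - 0.5) * sc + 0.5
  grid_r <- matrix(rows, nr, nc)
  grid_c <- matrix(cols, nr, nc, byrow = TRUE)
  rows_cl <- pmin(pmax(grid_r, 1), nrow(m))
  cols_cl <- pmin(pmax(grid_c, 1), ncol(m))
  matrix(bilinear_sample(m, rows_cl, cols_cl), nr, nc)
}

#' Box-average downsample by an integer factor
#' @noRd
box_downsample <- function(m, factor) {
  if (factor == 1L) return(m)
  nr <- nrow(m) %/% factor; nc <- ncol(m) %/% factor
  m <- m[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  rsum <- rowsum(m, rep(seq_len(nr), each = factor))
  csum <- t(rowsum(t(rsum), rep(seq_len(nc), each = factor)))
  csum / (factor * factor)
}

#' Precompute a rotation resampler for a fixed image size / angle
#'
#' Rotation about `center` (row, col in source-pixel coordinates; defaults
#' to the image centroid), bilinear interpolation, zero fill. When
#' `upsample > 1` the image is bilinearly upsampled, rotated on the fine
#' grid, and box-averaged back down, which reduces quantization of small
#' angles. The returned closure applies the identical 2D transform to any
#' matrix of the given size, so a volume can be rotated layer by layer with
#' one set of sampling weights.
#' @noRd
make_rotator <- function(nr, nc, deg, upsample = 1L,
                         center = c((nr + 1) / 2, (nc + 1) / 2)) {
  if (deg == 0 && upsample == 1L) return(identity)
  up <- as.integer(upsample)
  fnr <- nr * up; fnc <- nc * up
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # source-coordinate center mapped onto the fine grid
  cy <- (center[1] - 0.5) * up + 0.5
  cx <- (center[2] - 0.5) * up + 0.5
  gr <- matrix(seq_len(fnr), fnr, fnc) - cy
  gc <- matrix(seq_len(fnc), fnr, fnc, byrow = TRUE) - cx
  # inverse mapping: output pixel pulls from source rotated by -deg
  src_r <- ct * gr - st * gc + cy
  src_c <- st * gr + ct * gc + cx
  function(m) {
    fine <- if (up > 1L) bilinear_resize(m, fnr, fnc) else m
    val <- bilinear_sample(fine, src_r, src_c)
    rot <- matrix(val, fnr, fnc)
    supp <- matrix(attr(val, "support"), fnr, fnc)
    if (up > 1L) {
      rot <- box_downsample(rot, up)
      supp <- box_downsample(supp, up)
    }
    attr(rot, "support") <- supp
    rot
  }
}

#' Rotate an en-face image by `deg` degrees (about `center`, default its
#' centroid)
#' @noRd
rotate_enface <- function(m, deg, upsample = 1L,
                          center = c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2)) {
  make_rotator(nrow(m), ncol(m), deg, upsample, center)(m)
}

#' Pearson correlation of the overlap of two images under an integer shift
#'
#' `b` carries `a`'s content displaced by (dr, dc): b[r + dr, c + dc] ~
#' a[r, c]. Correlates over the in-bounds overlap only, so fill pixels at
#' the displaced borders never enter. Used to arbitrate between candidate
#' shift estimates.
#' @noRd
overlap_ncc <- function(a, b, dr, dc) {
  nr <- nrow(a); nc <- ncol(a)
  ra <- max(1, 1 - dr):min(nr, nr - dr)
  ca <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(ra) < 4 || length(ca) < 4) return(-1)
  ncc(a[ra, ca], b[ra + dr, ca + dc])
}

#' Standard preprocessing for lateral frame-to-frame matching: 3x3 box
#' smoothing (speckle suppression) followed by double centering — per-depth
#' row means strip the laterally uniform layer pattern, per-A-line column
#' means strip the axial speckle streaks each A-line carries — so vessels
#' and texture, the genuine lateral landmarks, drive the correlation.
#' @noRd
prep_frame <- function(m) {
  m <- box3(m)
  m <- m - rowMeans(m)
  sweep(m, 2, colMeans(m))
}

#' 3x3 box smoothing (replicated edges) — cheap speckle suppression applied
#' before frame-level correlation
#' @noRd
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc)]
  out / 9
}

# --- run logger -------------------------------------------------------------

#' Create a line-oriented logger
#'
#' Returns a list with `log(fmt, ...)` appending a timestamped line and
#' `lines()` retrieving everything logged so far. Used by the pipeline to
#' record every applied shift and excluded frame.
#' @noRd
make_logger <- function(verbose = FALSE) {
  env <- new.env(parent = emptyenv())
  env$lines <- character(0)
  list(
    log = function(fmt, ...) {
      line <- sprintf(fmt, ...)
      env$lines <- c(env$lines, line)
      if (verbose) message(line)
      invisible(line)
    },
    lines = function() env$lines
  )
}

#' @noRd
null_logger <- function() make_logger(verbose = FALSE)
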