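# Phase-only correlation (POC): the translation-estimation primitive used by
# transverse alignment, axial alignment and coarse/fine B-scan registration.

#' Phase-only correlation shift between two images
#'
#' Computes the normalized cross-power spectrum of the two images,
#' `R = (Gr o Gt*) / |Gr o Gt*|` (`o` elementwise product, `*` complex
#' conjugate), and takes the argmax of its inverse Fourier transform. The
#' returned `(dx, dy)` is the displacement of `target` relative to
#' `reference`: if the target content sits `s` pixels to the right of the
#' reference's, `dx = +s`, and shifting the target by `(-dx, -dy)` aligns it
#' to the reference. `dx` is along image columns (the fast axis for en-face
#' and B-scan inputs), `dy` along rows (slow or depth depending on the
#' caller).
#'
#' Shifts are pixel-precision by design (no subpixel peak interpolation).
#' Raw argmax coordinates beyond half the image size are wrapped to negative
#' shifts. Exact ties at the peak are broken toward the smallest
#' `(|dy|, |dx|)` lexicographically, preferring the null shift under
#' ambiguity. Spectrum bins whose cross-power magnitude falls below 1e-12 of
#' the maximum are zeroed rather than normalized.
#'
#' @param reference,target numeric matrices of identical shape with nonzero
#'   variance.
#' @return A list of class `shift_estimate` with elements `dx`, `dy`
#'   (integers), `peak` (POC peak height, ~1 for identical images) and
#'   `peak_location_wrapped` (raw 0-based argmax before centering).
#' @examples
#' img <- matrix(runif(32 * 32), 32, 32)
#' poc_shift(img, img)$dx
#' @export
poc_shift <- function(reference, target) {
  check_poc_inputs(reference, target)
  poc_shift_core(reference, target)
}

#' @noRd
check_poc_inputs <- function(reference, target) {
  if (!is.matrix(reference) || !is.matrix(target))
    stopf("POC inputs must be 2D matrices")
  if (!identical(dim(reference), dim(target)))
    stopf("POC inputs must have identical shapes, got (%s) vs (%s)",
          paste(dim(reference), collapse = "x"), paste(dim(target), collapse = "x"))
  if (sd(as.numeric(reference)) == 0 || sd(as.numeric(target)) == 0)
    stopf("POC is undefined for zero-variance (constant) images")
  invisible(TRUE)
}

#' @noRd
poc_shift_core <- function(reference, target) {
  nr <- nrow(reference); nc <- ncol(reference)
  # zero-mean before the transform so the DC bin does not dominate;
  # accumulate in double precision
  gr <- fft(reference - mean(reference))
  gt <- fft(target - mean(target))
  # Conj(Gr) * Gt puts the correlation peak at the target's displacement
  cross <- Conj(gr) * gt
  mag <- Mod(cross)
  eps <- 1e-12 * max(mag)
  ratio <- cross / mag
  ratio[mag < eps] <- 0 + 0i
  r <- Re(fft(ratio, inverse = TRUE)) / length(ratio)
  peak <- max(r)
  # candidate peaks within numeric tolerance of the max; tie-break toward
  # the smallest (|dy|, |dx|)
  tol <- 1e-9 * max(1, abs(peak))
  cand <- which(r >= peak - tol, arr.ind = TRUE)
  row0 <- cand[, 1] - 1L
  col0 <- cand[, 2] - 1L
  dy <- wrap_shift(row0, nr)
  dx <- wrap_shift(col0, nc)
  ord <- order(abs(dy), abs(dx), dy, dx)
  pick <- ord[1]
  structure(list(dx = as.integer(dx[pick]), dy = as.integer(dy[pick]),
                 peak = peak,
                 peak_location_wrapped = c(row = row0[pick], col = col0[pick])),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate dx=%d dy=%d peak=%.4f>\n", x$dx, x$dy, x$peak))
  invisible(x)
}

#' POC shift with optional apodization window
#'
#' Identical to [poc_shift()] but multiplies both (zero-meaned) images by a
#' 2D Hann window before the transforms, suppressing the spectral leakage of
#' non-periodic retinal content at the image borders. `window = "none"`
#' reduces exactly to [poc_shift()]. Hann is the default for en-face inputs;
#' small sub-B-scan tiles in axial alignment use `"none"`.
#'
#' @inheritParams poc_shift
#' @param window `"none"` or `"hann"`.
#' @return A `shift_estimate`; see [poc_shift()].
#' @export
windowed_poc_shift <- function(reference, target, window = c("hann", "none")) {
  window <- match.arg(window)
  check_poc_inputs(reference, target)
  if (window == "none") return(poc_shift_core(reference, target))
  w <- hann2d(nrow(reference), ncol(reference))
  ref_w <- (reference - mean(reference)) * w
  tgt_w <- (target - mean(target)) * w
  if (sd(as.numeric(ref_w)) == 0 || sd(as.numeric(tgt_w)) == 0)
    stopf("POC is undefined for zero-variance (constant) images")
  poc_shift_core(ref_w, tgt_w)
}

#' Normalized cross-correlation shift between two images
#'
#' FFT-based circular cross-correlation of the zero-meaned images, scaled so
#' the value at each shift is the Pearson correlation of the overlapped
#' (circularly wrapped) pair. Unlike POC this keeps the images' spectral
#' weighting, which makes it robust when independent speckle dominates the
#' high frequencies — the regime of adjacent-B-scan motion detection and
#' frame-to-frame matching. Same shift conventions, tie-breaking and wrap
#' centering as [poc_shift()].
#'
#' @inheritParams poc_shift
#' @param dx_range,dy_range optional inclusive bounds `c(lo, hi)` on the
#'   admissible displacement along columns/rows. Restricting the search
#'   window is how a coarse-to-fine caller avoids the circular-wrap aliases
#'   that smooth, quasi-periodic content (layered B-scans) produces at large
#'   shifts.
#' @return A `shift_estimate`; `peak` is the maximal correlation
#'   coefficient inside the admissible window.
#' @export
xcorr_shift <- function(reference, target, dx_range = NULL, dy_range = NULL) {
  check_poc_inputs(reference, target)
  nr <- nrow(reference); nc <- ncol(reference)
  n <- nr * nc
  r0 <- reference - mean(reference)
  t0 <- target - mean(target)
  num <- Re(fft(Conj(fft(r0)) * fft(t0), inverse = TRUE)) / n
  cc <- num / sqrt(sum(r0^2) * sum(t0^2))
  dy_all <- wrap_shift(seq_len(nr) - 1L, nr)
  dx_all <- wrap_shift(seq_len(nc) - 1L, nc)
  if (!is.null(dy_range))
    cc[dy_all < dy_range[1] | dy_all > dy_range[2], ] <- -Inf
  if (!is.null(dx_range))
    cc[, dx_all < dx_range[1] | dx_all > dx_range[2]] <- -Inf
  peak <- max(cc)
  if (!is.finite(peak)) stopf("xcorr_shift: empty admissible shift window")
  tol <- 1e-9 * max(1, abs(peak))
  cand <- which(cc >= peak - tol, arr.ind = TRUE)
  dy <- dy_all[cand[, 1]]
  dx <- dx_all[cand[, 2]]
  pick <- order(abs(dy), abs(dx), dy, dx)[1]
  structure(list(dx = as.integer(dx[pick]), dy = as.integer(dy[pick]),
                 peak = peak,
                 peak_location_wrapped = c(row = cand[pick, 1] - 1L,
                                           col = cand[pick, 2] - 1L)),
            class = "shift_estimate")
}

#' @noRd
hann1d <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' @noRd
hann2d <- function(nr, nc) outer(hann1d(nr), hann1d(nc))
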