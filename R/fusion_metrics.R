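# Multi-volume averaging and quantitative evaluation: MSE, SSIM, multi-scale
# SSIM, CNR, and the metric-versus-number-of-averages curve.

#' Average a set of registered volumes
#'
#' Voxelwise mean across the set, excluding zero-filled (vacated) voxels
#' from the denominator so that shifted borders are not darkened: a voxel's
#' denominator counts only the volumes with a nonzero value there. Voxels
#' zero in every member stay zero.
#'
#' @param registered a [volume_set] of volumes registered to a common
#'   reference, identical shapes.
#' @return An [oct_volume] holding the average; attribute `exclusion_count`
#'   gives, per voxel, how many members were excluded as zero-filled.
#' @export
average_volumes <- function(registered) {
  k <- length(registered)
  if (k == 0L) stopf("average_volumes: empty volume set")
  d <- dim(registered$volumes[[1]]$data)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (v in registered$volumes) {
    x <- v$data
    nz <- x != 0
    acc <- acc + x
    cnt <- cnt + nz
  }
  avg <- ifelse(cnt > 0, acc / cnt, 0)
  out <- with_data(registered$volumes[[1]], avg, id = sprintf("avg_of_%d", k))
  attr(out, "exclusion_count") <- k - cnt
  out
}

#' @noRd
check_metric_inputs <- function(reference, candidate) {
  if (!is.matrix(reference) || !is.matrix(candidate) ||
      !identical(dim(reference), dim(candidate)))
    stopf("metric inputs must be matrices of identical shape")
  invisible(TRUE)
}

#' Jointly min-max scale two images to [0, 1]
#'
#' Scaling uses the joint range so relative contrast between the two images
#' is preserved; a zero joint range (both images constant and equal) leaves
#' the inputs untouched.
#' @noRd
joint_normalize <- function(a, b) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi > lo) {
    a <- (a - lo) / (hi - lo)
    b <- (b - lo) / (hi - lo)
  }
  list(a = a, b = b)
}

#' Mean squared error between two en-face images
#'
#' `MSE = 1/N * sum((I_avg - I_ref)^2)` over all N pixels. Both images are
#' jointly min-max scaled to [0, 1] first (disable with
#' `normalize = FALSE`). Zero iff the images are identical.
#'
#' @param reference_enface,averaged_enface numeric matrices of equal shape.
#' @param normalize jointly scale to [0, 1] before comparing (default TRUE).
#' @return A nonnegative scalar.
#' @export
mse <- function(reference_enface, averaged_enface, normalize = TRUE) {
  check_metric_inputs(reference_enface, averaged_enface)
  if (normalize) {
    n <- joint_normalize(reference_enface, averaged_enface)
    reference_enface <- n$a; averaged_enface <- n$b
  }
  mean((averaged_enface - reference_enface)^2)
}

#' @noRd
gaussian_kernel_1d <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable 'valid' convolution with a symmetric 1D kernel along both axes
#' @noRd
conv2_valid <- function(m, k) {
  n <- length(k)
  nr <- nrow(m) - n + 1L; nc <- ncol(m) - n + 1L
  out <- matrix(0, nr, ncol(m))
  for (i in seq_len(n)) out <- out + k[i] * m[i:(i + nr - 1L), , drop = FALSE]
  res <- matrix(0, nr, nc)
  for (j in seq_len(n)) res <- res + k[j] * out[, j:(j + nc - 1L), drop = FALSE]
  res
}

#' @noRd
local_ssim_maps <- function(a, b, c1, c2, size = 11L, sigma = 1.5) {
  k <- gaussian_kernel_1d(size, sigma)
  mu_a <- conv2_valid(a, k); mu_b <- conv2_valid(b, k)
  s_aa <- conv2_valid(a * a, k) - mu_a^2
  s_bb <- conv2_valid(b * b, k) - mu_b^2
  s_ab <- conv2_valid(a * b, k) - mu_a * mu_b
  lum <- (2 * mu_a * mu_b + c1) / (mu_a^2 + mu_b^2 + c1)
  cs <- (2 * s_ab + c2) / (s_aa + s_bb + c2)
  list(lum = lum, cs = cs)
}

#' Structural similarity between two en-face images
#'
#' `SSIM = (2 mu_r mu_a + c1)(2 sigma_ra + c2) /
#' ((mu_r^2 + mu_a^2 + c1)(sigma_r^2 + sigma_a^2 + c2))`, with
#' `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`, `L = 1` after normalization — small
#' stabilizers against vanishing means/variances. `method = "local"`
#' (default) evaluates the statistic inside an 11-pixel Gaussian window
#' (sigma 1.5) and averages over the image; `method = "global"` evaluates it
#' once from whole-image moments (the literal single-window form, handy for
#' closed-form checks). Equals 1 iff the images are identical.
#'
#' @inheritParams mse
#' @param method `"local"` (Gaussian-windowed mean) or `"global"`.
#' @return A scalar in [-1, 1].
#' @export
ssim <- function(reference_enface, averaged_enface, method = c("local", "global"),
                 normalize = TRUE) {
  method <- match.arg(method)
  check_metric_inputs(reference_enface, averaged_enface)
  if (normalize) {
    n <- joint_normalize(reference_enface, averaged_enface)
    reference_enface <- n$a; averaged_enface <- n$b
  }
  c1 <- 0.01^2; c2 <- 0.03^2
  if (method == "global") {
    mu_r <- mean(reference_enface); mu_a <- mean(averaged_enface)
    n <- length(reference_enface)
    v_r <- sum((reference_enface - mu_r)^2) / n
    v_a <- sum((averaged_enface - mu_a)^2) / n
    cov <- sum((reference_enface - mu_r) * (averaged_enface - mu_a)) / n
    return((2 * mu_r * mu_a + c1) * (2 * cov + c2) /
             ((mu_r^2 + mu_a^2 + c1) * (v_r + v_a + c2)))
  }
  if (any(dim(reference_enface) < 11L))
    stopf("local SSIM needs images of at least 11 pixels per side")
  maps <- local_ssim_maps(reference_enface, averaged_enface, c1, c2)
  mean(maps$lum * maps$cs)
}

#' @noRd
downsample2 <- function(m) box_downsample(m, 2L)

#' Multi-scale structural similarity
#'
#' The standard dyadic multi-scale extension: at each of `scales` scales the
#' Gaussian-windowed contrast/structure term is averaged over the image and
#' the image pair is 2x2 box-downsampled; the luminance term enters only at
#' the coarsest scale. Scale contributions are combined with the
#' conventional exponent weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
#' renormalized to sum 1 when fewer scales fit the image (a warning reports
#' the reduction). Terms are clamped at zero before exponentiation so the
#' result lies in [0, 1]. With `scales = 1` this reduces exactly to
#' [ssim()].
#'
#' @inheritParams mse
#' @param scales number of dyadic scales (default 5; reduced automatically
#'   when a side drops below the 11-pixel window).
#' @return A scalar in [0, 1]; 1 iff the images are identical.
#' @export
ms_ssim <- function(reference_enface, averaged_enface, scales = 5L,
                    normalize = TRUE) {
  check_metric_inputs(reference_enface, averaged_enface)
  if (normalize) {
    n <- joint_normalize(reference_enface, averaged_enface)
    reference_enface <- n$a; averaged_enface <- n$b
  }
  max_scales <- max(1L, floor(log2(min(dim(reference_enface)) / 11)) + 1L)
  if (scales > max_scales) {
    warnf("ms_ssim: image supports %d scales (requested %d); reducing",
          max_scales, scales)
    scales <- max_scales
  }
  w_full <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  w <- w_full[seq_len(scales)]
  w <- w / sum(w)
  c1 <- 0.01^2; c2 <- 0.03^2
  a <- reference_enface; b <- averaged_enface
  val <- 1
  for (j in seq_len(scales)) {
    maps <- local_ssim_maps(a, b, c1, c2)
    if (j < scales) {
      term <- max(mean(maps$cs), 0)
      a <- downsample2(a); b <- downsample2(b)
    } else {
      term <- max(mean(maps$lum * maps$cs), 0)  # full SSIM at coarsest scale
    }
    val <- val * term^w[j]
  }
  val
}

#' Contrast-to-noise ratio of an en-face image
#'
#' `CNR = (mean_fg - mean_bg) / sd_bg` between a caller-supplied foreground
#' (vessel) mask and a background mask; `denominator = "combined"` uses
#' `sqrt(var_fg + var_bg)` instead.
#'
#' @param enface numeric matrix.
#' @param fg_mask,bg_mask disjoint logical matrices of the image's shape,
#'   each with at least one TRUE pixel.
#' @param denominator `"bg"` (default) or `"combined"`.
#' @return A scalar.
#' @export
cnr <- function(enface, fg_mask, bg_mask, denominator = c("bg", "combined")) {
  denominator <- match.arg(denominator)
  if (!identical(dim(enface), dim(fg_mask)) || !identical(dim(enface), dim(bg_mask)))
    stopf("masks must match the image shape")
  fg_mask <- as.logical(fg_mask); bg_mask <- as.logical(bg_mask)
  if (!any(fg_mask) || !any(bg_mask)) stopf("cnr: empty mask")
  if (any(fg_mask & bg_mask)) stopf("cnr: masks must be disjoint")
  fg <- enface[fg_mask]; bg <- enface[bg_mask]
  den <- switch(denominator, bg = sd(bg), combined = sqrt(var(fg) + var(bg)))
  (mean(fg) - mean(bg)) / den
}

#' Evaluation metrics versus number of averaged volumes
#'
#' For k = 1..K the first k volumes of the (quality-ordered) registered
#' target set are averaged and the MSE and MS-SSIM of the averaged en-face
#' projection against the reference en-face projection are evaluated; the
#' k = 1 entry uses a single registered volume unaveraged (the reference
#' itself is the comparison side and is never part of the average). As k
#' grows MSE should fall and MS-SSIM rise — the quantitative signature of
#' successful registration and averaging.
#'
#' @param reference an [oct_volume]; its en-face projection is the
#'   comparison target.
#' @param registered a [volume_set] of at least 2 registered target
#'   volumes, in quality order (best first), excluding the reference.
#' @param trim margin (pixels) cropped from every side of the projections
#'   before evaluation; vacated borders of shifted volumes carry fill
#'   rather than content, and their extent differs per member. Default 8.
#' @return A data frame of class `evaluation_report` with columns `k`,
#'   `mse`, `ms_ssim`.
#' @export
metrics_vs_k <- function(reference, registered, trim = 8L) {
  if (length(registered) < 2L)
    stopf("metrics_vs_k needs at least 2 registered volumes")
  crop <- function(m) {
    if (trim <= 0L || nrow(m) <= 2 * trim + 11 || ncol(m) <= 2 * trim + 11)
      return(m)
    m[(trim + 1):(nrow(m) - trim), (trim + 1):(ncol(m) - trim)]
  }
  ref_ef <- crop(enface_projection(reference))
  k_max <- length(registered)
  out <- data.frame(k = seq_len(k_max), mse = NA_real_, ms_ssim = NA_real_)
  for (k in seq_len(k_max)) {
    avg <- average_volumes(volume_set(registered$volumes[seq_len(k)]))
    ef <- crop(enface_projection(avg))
    out$mse[k] <- mse(ref_ef, ef)
    out$ms_ssim[k] <- suppressWarnings(ms_ssim(ref_ef, ef))
  }
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Plot an evaluation report (metric versus number of averaged volumes)
#'
#' @param report an `evaluation_report` from [metrics_vs_k()].
#' @param path PNG destination.
#' @return `path`, invisibly.
#' @export
plot_metrics_vs_k <- function(report, path) {
  png(path, width = 800, height = 500)
  on.exit(dev.off())
  par(mar = c(4.5, 4.5, 2, 4.5))
  plot(report$k, report$mse, type = "b", col = "darkorange", pch = 16,
       xlab = "number of averaged volumes k", ylab = "MSE",
       main = "Registration quality vs number of averages")
  par(new = TRUE)
  plot(report$k, report$ms_ssim, type = "b", col = "steelblue", pch = 17,
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  axis(4)
  mtext_safe("MS-SSIM", side = 4, line = 3)
  legend("right", legend = c("MSE", "MS-SSIM"), col = c("darkorange", "steelblue"),
         pch = c(16, 17), lty = 1, bty = "n")
  invisible(path)
}

#' @noRd
mtext_safe <- function(text, side, line) graphics::mtext(text, side = side, line = line)
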