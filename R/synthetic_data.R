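# Retina-like phantoms and motion-corrupted acquisitions with ground-truth
# traces. The generator emulates what the registration pipeline needs to see:
# layered axial structure, a branching en-face vessel pattern at two depth
# bands (superficial/deep plexus analogues), multiplicative speckle, and
# per-frame displacement traces with drift, microsaccade jumps, axial shifts,
# small global rotation and optional smooth warps.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Phantom generation parameters
#'
#' @param shape integer (slow, depth, fast) dimensions; default 64 x 96 x 96
#'   keeps full-pipeline runs fast while leaving room for the shifts under
#'   study.
#' @param n_layers number of axial intensity bands (retinal layer analogue).
#' @param vessel_density target en-face area fraction of the vessel pattern,
#'   in (0, 0.5).
#' @param speckle_variance variance of the multiplicative speckle factor
#'   (0 = noise-free).
#' @param seed RNG seed; identical parameters and seed give a bit-identical
#'   phantom.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(shape = c(64L, 96L, 96L), n_layers = 6L,
                           vessel_density = 0.1, speckle_variance = 0.05,
                           seed = 1L) {
  if (length(shape) != 3L || any(shape < 8L))
    stopf("shape must be 3 dimensions, each >= 8")
  if (vessel_density <= 0 || vessel_density >= 0.5)
    stopf("vessel_density must lie in (0, 0.5)")
  if (speckle_variance < 0) stopf("speckle_variance must be >= 0")
  structure(list(shape = as.integer(shape), n_layers = as.integer(n_layers),
                 vessel_density = vessel_density,
                 speckle_variance = speckle_variance, seed = as.integer(seed)),
            class = "phantom_params")
}

#' Multiplicative speckle field with axial correlation
#'
#' OCT speckle decorrelates laterally from A-line to A-line but is
#' correlated along depth over roughly the axial point-spread function, so
#' en-face projections of single volumes stay grainy instead of averaging
#' clean. Gamma noise (mean 1) is drawn per voxel and smoothed along depth
#' with a width-`w` moving average; the raw variance is inflated by `w` so
#' the smoothed field keeps approximately the requested variance.
#' @noRd
speckle_field <- function(dims, variance, w = 9L) {
  ns <- dims[1]; nd <- dims[2]; nf <- dims[3]
  v_raw <- variance * w
  raw <- array(rgamma(ns * nd * nf, shape = 1 / v_raw, rate = 1 / v_raw),
               c(ns, nd, nf))
  m <- matrix(aperm(raw, c(2, 1, 3)), nd, ns * nf)
  sm <- stats::filter(m, rep(1 / w, w), circular = TRUE)
  aperm(array(as.numeric(sm), c(nd, ns, nf)), c(2, 1, 3))
}

#' Smooth random field via separable moving-average smoothing of white noise
#' @noRd
smooth_field <- function(nr, nc, passes = 4L, width = 9L) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  kr <- rep(1 / min(width, nr), min(width, nr))
  kc <- rep(1 / min(width, nc), min(width, nc))
  for (p in seq_len(passes)) {
    f <- apply(f, 2, function(col) as.numeric(stats::filter(col, kr, circular = TRUE)))
    f <- t(apply(f, 1, function(row) as.numeric(stats::filter(row, kc, circular = TRUE))))
  }
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

#' Draw one branching vessel segment into a binary mask
#'
#' A momentum random walk stamped with a 1-pixel-radius disk; returns the
#' updated mask and optionally a branch starting point.
#' @noRd
draw_vessel <- function(mask, start, heading, n_steps, stop_density = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  pos <- start
  for (s in seq_len(n_steps)) {
    heading <- heading + rnorm(1, 0, 0.15)
    pos <- pos + c(sin(heading), cos(heading))
    r <- round(pos[1]); c <- round(pos[2])
    if (r < 1 || r > nr || c < 1 || c > nc) break
    rr <- max(1, r - 1):min(nr, r + 1)
    cc <- max(1, c - 1):min(nc, c + 1)
    # stamp a diamond (radius-1 disk)
    for (i in rr) for (j in cc) if (abs(i - r) + abs(j - c) <= 1) mask[i, j] <- TRUE
    # stop mid-curve once the target area is reached (keeps overshoot at
    # stamp granularity rather than whole-curve granularity)
    if (!is.null(stop_density) && s %% 8L == 0L && mean(mask) >= stop_density)
      break
  }
  list(mask = mask, end = pos, heading = heading)
}

#' @noRd
vessel_mask <- function(nr, nc, density) {
  mask <- matrix(FALSE, nr, nc)
  guard <- 0L
  while (mean(mask) < density && guard < 400L) {
    guard <- guard + 1L
    start <- c(runif(1, 1, nr), runif(1, 1, nc))
    heading <- runif(1, 0, 2 * pi)
    len <- round(runif(1, 0.3, 0.6) * max(nr, nc))
    seg <- draw_vessel(mask, start, heading, len, stop_density = density)
    mask <- seg$mask
    if (runif(1) < 0.35 && mean(mask) < density) {
      # branch from the endpoint at an offset angle
      br <- draw_vessel(mask, seg$end, seg$heading + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
                        round(len / 2), stop_density = density)
      mask <- br$mask
    }
  }
  mask
}

#' Generate a retina-like phantom volume
#'
#' The structural template is a product of three ingredients: an axial
#' profile of `n_layers` smooth intensity bands (layered retina analogue), a
#' smooth multiplicative lateral texture field (gives the en-face projection
#' enough structure for correlation), and a branching vessel pattern
#' embossed at two depth bands (superficial and deep plexus analogues) —
#' darker than surround in OCT mode, brighter in OCTA mode. Multiplicative
#' gamma speckle of the requested variance is applied last. Deterministic
#' per seed.
#'
#' @param params a [phantom_params()].
#' @param modality `"OCT"` or `"OCTA"` (sets vessel contrast polarity).
#' The first ~8% of the depth axis is a structureless dark pre-retinal band
#' (vitreous analogue) carrying pure speckle — a signal-free region for
#' noise measurements.
#'
#' @return An [oct_volume] with attributes `vessel_mask` (en-face union of
#'   both vessel bands), `template` (the noise-free structural array) and
#'   `vitreous_band` (depth index range of the signal-free band).
#' @export
generate_phantom <- function(params, modality = c("OCT", "OCTA")) {
  modality <- match.arg(modality)
  stopifnot(inherits(params, "phantom_params"))
  ns <- params$shape[1]; nd <- params$shape[2]; nf <- params$shape[3]
  with_seed(params$seed, {
    # axial layer profile: n_layers bands of distinct reflectivity, smoothed
    bounds <- sort(c(1, sample(4:(nd - 3), params$n_layers - 1L), nd + 1))
    levels <- runif(params$n_layers, 0.25, 1.0)
    profile <- numeric(nd)
    for (l in seq_len(params$n_layers))
      profile[bounds[l]:(bounds[l + 1] - 1L)] <- levels[l]
    # thin hyperreflective band (RPE analogue) gives the depth profile a
    # sharp landmark; light smoothing keeps interfaces 1-2 px wide
    rpe <- max(1, round(0.78 * nd)) + 0:1
    profile[rpe] <- 1.4
    profile <- as.numeric(stats::filter(profile, rep(1 / 3, 3), circular = TRUE))
    profile <- pmax(profile, 0.1)
    # two-scale lateral texture: slowly varying shading plus granular
    # structure (cellular mosaic analogue, feature scale ~2-3 px — coarse
    # enough to survive bilinear resampling, fine enough to sharpen
    # correlation peaks)
    texture <- 1 + 0.12 * smooth_field(ns, nf) +
      0.12 * smooth_field(ns, nf, passes = 2L, width = 3L)
    texture <- pmax(texture, 0.3)
    # vessel bands: superficial around 30% depth, deep around 65%
    band_sup <- max(1, round(0.28 * nd)):min(nd, round(0.36 * nd))
    band_deep <- max(1, round(0.60 * nd)):min(nd, round(0.70 * nd))
    mask_sup <- vessel_mask(ns, nf, params$vessel_density / 2)
    mask_deep <- vessel_mask(ns, nf, params$vessel_density / 2)
    # grow until the union reaches the target density
    guard <- 0L
    while (mean(mask_sup | mask_deep) < params$vessel_density && guard < 200L) {
      guard <- guard + 1L
      if (guard %% 2L == 0L)
        mask_sup <- vessel_mask_extend(mask_sup, params$vessel_density)
      else
        mask_deep <- vessel_mask_extend(mask_deep, params$vessel_density)
    }
    contrast <- if (modality == "OCT") -0.5 else 0.8
    vitreous <- max(2L, round(0.08 * nd))
    # smooth retinal-curvature analogue: the axial profile is shifted by an
    # elevation surface so B-scans show curved bands (this is what makes
    # lateral shifts observable in a single B-scan)
    elevation <- 3 * smooth_field(ns, nf, passes = 4L, width = 21L)
    template <- array(0, c(ns, nd, nf))
    depth_idx <- seq_len(nd)
    for (s in seq_len(ns)) {
      # (depth, fast) frame: sample the profile at depth - elevation
      shift_row <- elevation[s, ]
      idx <- outer(depth_idx, shift_row, function(d, e) d - e)
      frame <- matrix(approx(depth_idx, profile, xout = as.numeric(idx),
                             rule = 2)$y, nd, nf)
      frame <- frame * matrix(texture[s, ], nd, nf, byrow = TRUE)
      frame[band_sup, ] <- frame[band_sup, ] *
        (1 + contrast * matrix(mask_sup[s, ], length(band_sup), nf, byrow = TRUE))
      frame[band_deep, ] <- frame[band_deep, ] *
        (1 + contrast * matrix(mask_deep[s, ], length(band_deep), nf, byrow = TRUE))
      # vessel shadowing: columns under a superficial vessel are attenuated
      # below the vessel band, as in real OCT B-scans
      below <- depth_idx > max(band_sup)
      shadow_cols <- mask_sup[s, ]
      if (any(shadow_cols))
        frame[below, shadow_cols] <- frame[below, shadow_cols] * 0.65
      # structureless dark pre-retinal band (vitreous analogue): pure
      # speckle over a flat low background, no lateral texture
      frame[seq_len(vitreous), ] <- 0.08
      template[s, , ] <- frame
    }
    data <- template
    if (params$speckle_variance > 0)
      data <- data * speckle_field(dim(data), params$speckle_variance)
    vol <- oct_volume(data, modality = modality,
                      id = sprintf("phantom_seed%d", params$seed))
    attr(vol, "vessel_mask") <- mask_sup | mask_deep
    attr(vol, "vessel_mask_deep") <- mask_deep
    attr(vol, "template") <- template
    attr(vol, "vitreous_band") <- c(1L, vitreous)
    attr(vol, "vessel_bands") <- list(superficial = range(band_sup),
                                      deep = range(band_deep))
    vol
  })
}

#' Short growth segment used while topping the union mask up to the target
#' density; kept short so the overshoot stays within the density tolerance.
#' @noRd
vessel_mask_extend <- function(mask, density) {
  start <- c(runif(1, 1, nrow(mask)), runif(1, 1, ncol(mask)))
  seg <- draw_vessel(mask, start, runif(1, 0, 2 * pi),
                     round(0.2 * max(dim(mask))))
  seg$mask
}

# --- motion traces ----------------------------------------------------------

#' Motion trace presets
#' @noRd
TRACE_PRESETS <- c("drift_only", "saccades", "rotation", "tracked_warp", "combined")

#' Sample a ground-truth motion trace
#'
#' Per-frame integer displacements `(dx, dy, dz)` (fast, slow, depth) over
#' `n_frames`, mimicking involuntary eye motion during a raster acquisition:
#' slow sinusoidal drift (respiratory/cardiac analogue), abrupt microsaccade
#' jumps of 3-10 px along fast that revert after a few frames, smooth axial
#' displacement, optional small global in-plane rotation and optional smooth
#' quadratic en-face warp (motion-tracked rescanning analogue).
#'
#' Presets: `"drift_only"` (transverse drift, |dx| <= 4, |dy| <= 2),
#' `"saccades"` (drift plus 1-3 jumps), `"rotation"` (global rotation only,
#' |alpha| <= 0.8 deg), `"tracked_warp"` (drift plus a <= 4 px quadratic
#' warp), `"combined"` (drift, saccades, axial shifts |dz| <= 6).
#'
#' @param n_frames slow-axis length.
#' @param preset one of the presets above.
#' @param seed RNG seed.
#' @return A list of class `motion_trace`: `dx`, `dy`, `dz` (integer
#'   vectors), `saccade_frames`, `global_rotation_deg`, `warp` (NULL or list
#'   `d_slow`, `d_fast` matrices scaled to en-face shape at corruption
#'   time).
#' @export
motion_trace <- function(n_frames, preset = "combined", seed = 1L) {
  if (!preset %in% TRACE_PRESETS)
    stopf("unknown motion preset '%s' (use one of %s)", preset,
          paste(TRACE_PRESETS, collapse = ", "))
  ns <- as.integer(n_frames)
  with_seed(seed, {
    t <- seq_len(ns) / ns
    drift <- function(amp) {
      round(amp * sin(2 * pi * runif(1, 0.5, 1.5) * t + runif(1, 0, 2 * pi)))
    }
    dx <- integer(ns); dy <- integer(ns); dz <- integer(ns)
    saccades <- integer(0); rot <- 0; warp <- NULL
    if (preset %in% c("drift_only", "saccades", "tracked_warp", "combined")) {
      dx <- drift(runif(1, 2, 4))
      dy <- drift(runif(1, 1, 2))
    }
    if (preset %in% c("saccades", "combined")) {
      n_j <- sample(1:3, 1)
      starts <- sort(sample(5:(ns - 8L), n_j))
      for (s in starts) {
        jump <- sample(3:10, 1) * sample(c(-1L, 1L), 1)
        dur <- sample(2:5, 1)
        frames <- s:min(ns, s + dur - 1L)
        dx[frames] <- dx[frames] + jump
        saccades <- c(saccades, s)
      }
    }
    if (preset == "combined") dz <- drift(runif(1, 3, 6))
    if (preset == "rotation") rot <- runif(1, 0.2, 0.8) * sample(c(-1, 1), 1)
    if (preset == "tracked_warp") {
      amp <- runif(1, 2, 4)
      warp <- list(amp = amp,
                   coef_slow = runif(3, -1, 1), coef_fast = runif(3, -1, 1))
    }
    structure(list(dx = as.integer(dx), dy = as.integer(dy), dz = as.integer(dz),
                   saccade_frames = saccades, global_rotation_deg = rot,
                   warp = warp),
              class = "motion_trace")
  })
}

#' @noRd
zero_trace <- function(n_frames) {
  structure(list(dx = integer(n_frames), dy = integer(n_frames),
                 dz = integer(n_frames), saccade_frames = integer(0),
                 global_rotation_deg = 0, warp = NULL),
            class = "motion_trace")
}

#' @noRd
warp_fields <- function(warp, ns, nf) {
  u <- matrix((seq_len(ns) - (ns + 1) / 2) / (ns / 2), ns, nf)
  v <- matrix((seq_len(nf) - (nf + 1) / 2) / (nf / 2), ns, nf, byrow = TRUE)
  mk <- function(cf) {
    f <- cf[1] * u^2 + cf[2] * v^2 + cf[3] * u * v
    if (max(abs(f)) > 0) f <- f / max(abs(f))
    f
  }
  list(d_slow = warp$amp * mk(warp$coef_slow),
       d_fast = warp$amp * mk(warp$coef_fast))
}

#' Corrupt a volume with a known motion trace
#'
#' Applies, in order: the trace's global in-plane rotation (identically at
#' every depth), its smooth quadratic warp if any, the per-position motion
#' sampling — the frame recorded at slow position `p` images the template at
#' `p - dy[p]`, shifted by integer `(dx[p], dz[p])` with zero fill (so
#' applying the negated trace via [apply_field()] recovers the original
#' exactly wherever the slow mapping is one-to-one and no resampling
#' occurred) — and finally fresh multiplicative speckle. Returns the exact
#' trace applied.
#'
#' @param volume an [oct_volume] (typically a noise-free template).
#' @param trace a [motion_trace()] whose length matches the volume.
#' @param seed RNG seed for the speckle draw.
#' @param speckle_variance variance of the fresh multiplicative speckle
#'   (default 0 = none).
#' @return A list with `volume` (the corrupted acquisition) and `trace`.
#' @export
corrupt <- function(volume, trace, seed = 1L, speckle_variance = 0) {
  ns <- n_slow(volume); nd <- n_depth(volume); nf <- n_fast(volume)
  if (length(trace$dx) != ns)
    stopf("trace length %d does not match volume slow dimension %d",
          length(trace$dx), ns)
  if (max(abs(trace$dx)) > nf / 2 || max(abs(trace$dy)) > ns / 2 ||
      max(abs(trace$dz)) > nd / 2)
    stopf("trace shifts exceed half the volume dimensions")
  arr <- volume$data
  if (trace$global_rotation_deg != 0) {
    rotator <- make_rotator(ns, nf, trace$global_rotation_deg, 1L)
    for (z in seq_len(nd)) arr[, z, ] <- rotator(arr[, z, , drop = TRUE])
  }
  if (!is.null(trace$warp)) {
    w <- warp_fields(trace$warp, ns, nf)
    grid_r <- matrix(seq_len(ns), ns, nf)
    grid_c <- matrix(seq_len(nf), ns, nf, byrow = TRUE)
    src_r <- grid_r - w$d_slow
    src_c <- grid_c - w$d_fast
    for (z in seq_len(nd))
      arr[, z, ] <- matrix(bilinear_sample(arr[, z, , drop = TRUE], src_r, src_c), ns, nf)
  }
  if (any(trace$dx != 0L) || any(trace$dy != 0L) || any(trace$dz != 0L)) {
    # sampling (gather) model of a raster scan under eye motion: the frame
    # recorded at slow position p images the retina at p - dy[p], displaced
    # laterally/axially by (dx[p], dz[p]); every position yields a real,
    # independently speckled frame (no blends, no holes)
    src <- arr
    for (p in seq_len(ns)) {
      i <- min(max(p - trace$dy[p], 1L), ns)
      arr[p, , ] <- shift_matrix(src[i, , ], dr = trace$dz[p], dc = trace$dx[p])
    }
  }
  if (speckle_variance > 0) {
    arr <- with_seed(seed, arr * speckle_field(dim(arr), speckle_variance))
  }
  list(volume = with_data(volume, arr, id = paste0(volume$id, "_corrupt")),
       trace = trace)
}

#' Generate an ensemble of corrupted acquisitions with ground truth
#'
#' Builds one noise-free structural template from `params`, then `n`
#' independently corrupted, independently speckled acquisitions. The first
#' member carries a zero motion trace (the clean, reference-grade
#' acquisition a quality ranking should discover); members 2..n draw fresh
#' traces from the chosen preset. Fully reproducible from `params$seed`.
#'
#' @param params a [phantom_params()]; `speckle_variance` sets the per-member
#'   speckle level.
#' @param n number of acquisitions (>= 2).
#' @param motion_model preset name passed to [motion_trace()].
#' @return A list with `volumes` (a [volume_set]), `traces` (list of
#'   `motion_trace`), and `template` (noise-free [oct_volume]).
#' @export
make_ensemble <- function(params, n, motion_model = "combined") {
  if (n < 2L) stopf("an ensemble needs n >= 2 acquisitions")
  if (!motion_model %in% TRACE_PRESETS)
    stopf("unknown motion preset '%s' (use one of %s)", motion_model,
          paste(TRACE_PRESETS, collapse = ", "))
  clean_params <- params
  clean_params$speckle_variance <- 0
  template <- generate_phantom(clean_params)
  ns <- params$shape[1]
  volumes <- vector("list", n)
  traces <- vector("list", n)
  for (m in seq_len(n)) {
    seed_m <- params$seed + 7919L * m  # distinct sub-seeds per member
    traces[[m]] <- if (m == 1L) zero_trace(ns) else
      motion_trace(ns, motion_model, seed = seed_m)
    res <- corrupt(template, traces[[m]], seed = seed_m + 1L,
                   speckle_variance = params$speckle_variance)
    res$volume$id <- sprintf("acq%02d", m)
    volumes[[m]] <- res$volume
  }
  list(volumes = volume_set(volumes), traces = traces, template = template)
}
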