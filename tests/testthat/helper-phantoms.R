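# Shared fixtures and independent oracles, all generated in code.

# small textured image with blob-scale features, deterministic per seed
textured_image <- function(nr, nc, seed = 1L) {
  octreg3d:::with_seed(seed, {
    f <- matrix(rnorm(nr * nc), nr, nc)
    k <- rep(1 / 3, 3)
    for (p in 1:2) {
      f <- apply(f, 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
      f <- t(apply(f, 1, function(row) as.numeric(stats::filter(row, k, circular = TRUE))))
    }
    f + 2
  })
}

# independent brute-force oracle: the displacement (dx, dy) of target vs
# reference is the circular shift maximizing the Pearson correlation,
# searched exhaustively; ties break toward the smallest (|dy|, |dx|)
oracle_shift <- function(reference, target) {
  nr <- nrow(reference); nc <- ncol(reference)
  best <- NULL
  for (row0 in seq_len(nr) - 1L) {
    for (col0 in seq_len(nc) - 1L) {
      dy <- octreg3d:::wrap_shift(row0, nr)
      dx <- octreg3d:::wrap_shift(col0, nc)
      cc <- cor(as.numeric(reference),
                as.numeric(octreg3d:::circshift_matrix(target, -dy, -dx)))
      if (is.null(best) || cc > best$cc + 1e-12 ||
          (abs(cc - best$cc) <= 1e-12 &&
           (abs(dy) < abs(best$dy) ||
            (abs(dy) == abs(best$dy) && abs(dx) < abs(best$dx))))) {
        best <- list(dx = dx, dy = dy, cc = cc)
      }
    }
  }
  best
}

# small phantom parameter sets used across tests
small_params <- function(seed = 1L, speckle = 0.05) {
  phantom_params(shape = c(48L, 64L, 64L), speckle_variance = speckle, seed = seed)
}

zero_trace_n <- function(n) octreg3d:::zero_trace(n)

# steady-drift trace: fixed amplitude, random phase/frequency
drift_trace <- function(n, seed, amp_dx = 4, amp_dy = 2, amp_dz = 0) {
  octreg3d:::with_seed(seed, {
    t <- seq_len(n) / n
    dr <- function(amp) round(amp * sin(2 * pi * runif(1, 0.5, 1.5) * t + runif(1, 0, 2 * pi)))
    structure(list(dx = as.integer(dr(amp_dx)), dy = as.integer(dr(amp_dy)),
                   dz = as.integer(dr(amp_dz)), saccade_frames = integer(0),
                   global_rotation_deg = 0, warp = NULL),
              class = "motion_trace")
  })
}

rms <- function(a, b) sqrt(mean((a - b)^2))
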