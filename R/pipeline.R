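# Orchestration of the full pipeline (ranking -> preprocessing -> B-scan
# registration -> affine -> averaging -> evaluation), the YAML run
# configuration, and the programmatic entry points behind the CLI.

#' Default run configuration
#'
#' Every numeric parameter of the pipeline with its default: stage toggles
#' (the nonrigid stage only applies to motion-tracked acquisitions, the
#' affine upsample refinement to high-lateral-resolution data), preprocessing
#' parameters (`subvolume_size` 10 frames, `sub_bscan_width` 64 A-lines,
#' motion `threshold_px` 2), coarse subvolume `size` 8, fine `tolerance_px`
#' 4 (midpoint of the empirical 3-5 band), and affine settings (8 strips,
#' +/- 1 degree bracket).
#'
#' @return A nested list; see the YAML written beside every run for the
#'   resolved form.
#' @export
default_config <- function() {
  list(
    input = list(paths = character(0), motion_tracked = FALSE),
    output_dir = "octreg3d_out",
    seed = 1L,
    log_level = "info",
    stages = list(axial_motion = TRUE, transverse = TRUE, nonrigid = FALSE,
                  axial_align = TRUE, motion_removal = TRUE, coarse = TRUE,
                  fine = TRUE, affine = TRUE, average = TRUE, evaluate = TRUE),
    preprocess = list(subvolume_size = 10L, sub_bscan_width = 64L,
                      threshold_px = 2L, nonrigid_grid = 16L),
    coarse = list(size = 8L),
    fine = list(tolerance_px = 4L),
    affine = list(n_strips = 8L, upsample_factor = 1L, max_deg = 1.0)
  )
}

#' @noRd
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stopf("unknown configuration key '%s'", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) && length(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stopf("configuration key '%s' must be a mapping", full)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take their defaults from
#' [default_config()].
#'
#' @param path YAML file path, or a named list already in memory.
#' @return The fully resolved configuration list.
#' @export
load_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(user)) user <- list()
  merge_config(default_config(), user)
}

#' Register one target volume to a reference
#'
#' Runs the per-target chain: intra-volume axial motion correction, rigid
#' transverse alignment, optional nonrigid en-face alignment (motion-tracked
#' data), subvolume/sub-B-scan axial alignment, motion detection (removed
#' frames are blanked and later reconstructed by interpolation of their
#' neighbors' displacements), coarse and fine B-scan registration, field
#' application, and optional strip-wise affine rotation.
#'
#' @param reference,target [oct_volume]s of equal shape.
#' @param config resolved configuration from [load_run_config()] /
#'   [default_config()].
#' @param logger optional logger; defaults to a silent collector.
#' @return A list: `volume` (registered target), `field` (fine-stage
#'   [displacement_field()]), `totals` (data frame of cumulative per-frame
#'   corrections `dx`, `dy`, `dz` indexed by the target's original slow
#'   positions, with `valid` flags), `mask` (motion mask or NULL),
#'   `axial_plan`, `rotation_plan` (or NULL), `applied_transverse`.
#' @export
register_volume <- function(reference, target, config = default_config(),
                            logger = NULL) {
  if (is.null(logger)) logger <- null_logger()
  st <- config$stages
  ns <- n_slow(target)
  amc_pass1 <- integer(ns)
  tgt <- target
  if (isTRUE(st$axial_motion)) {
    tgt <- axial_motion_correct(tgt, logger)
    amc_pass1 <- attr(tgt, "axial_shifts")$pass1
  }
  applied <- c(fast = 0L, slow = 0L)
  if (isTRUE(st$transverse)) {
    tgt <- transverse_align(reference, tgt, logger)
    applied <- attr(tgt, "applied_shift")
  }
  g <- as.integer(applied[["slow"]])
  if (isTRUE(st$nonrigid) && isTRUE(config$input$motion_tracked)) {
    tgt <- nonrigid_enface_align(reference, tgt,
                                 grid = config$preprocess$nonrigid_grid, logger)
  }
  # motion detection runs on the transversely aligned volume, before the
  # axial stage: a saccade frame's lateral offset exceeds the axial tiles'
  # search window, so aligning it axially first would fragment the frame and
  # hide the very offset the detector looks for
  mask <- NULL
  if (isTRUE(st$motion_removal)) {
    mask <- detect_motion(tgt, threshold_px = config$preprocess$threshold_px,
                          logger = logger)
    if (length(mask$removed) > ns / 2)
      # unlike physical deletion, blanked frames are later reconstructed by
      # interpolation, so the pipeline can proceed; fine_register still hard
      # errors if too few frames match
      warnf("motion mask blanks %d of %d frames (> 50%%) in volume '%s'",
            length(mask$removed), ns, target$id)
    if (length(mask$removed)) {
      # blank rather than delete: keeps shapes aligned with the reference,
      # and blank frames are reconstructed by displacement interpolation
      tgt$data[mask$removed, , ] <- 0
      logger$log("motion_removal[%s]: blanked %d frames", target$id,
                 length(mask$removed))
    }
  }
  dz_axial <- integer(ns)
  axial_plan <- NULL
  if (isTRUE(st$axial_align)) {
    ax <- axial_align(reference, tgt,
                      subvolume_size = config$preprocess$subvolume_size,
                      sub_bscan_width = config$preprocess$sub_bscan_width,
                      logger = logger)
    tgt <- ax$volume
    axial_plan <- ax$plan
    dz_axial <- as.integer(round(rowMeans(ax$plan$dz_map)))
  }
  field <- NULL
  reg <- tgt
  if (isTRUE(st$coarse) && isTRUE(st$fine)) {
    coarse <- coarse_register(reference, tgt, size = config$coarse$size,
                              logger = logger)
    field <- fine_register(reference, tgt, coarse,
                           tolerance_px = config$fine$tolerance_px,
                           logger = logger)
    reg <- apply_field(tgt, field)
  }
  rotation_plan <- NULL
  if (isTRUE(st$affine)) {
    rotation_plan <- estimate_strip_rotations(
      reference, reg, n_strips = config$affine$n_strips,
      upsample_factor = config$affine$upsample_factor,
      max_deg = config$affine$max_deg, logger = logger)
    reg <- apply_strip_rotations(reg, rotation_plan)
  }
  # cumulative per-frame corrections, indexed by the target's original slow
  # positions: original frame o sits at p = o + g after the rigid slow shift
  totals <- data.frame(slow_index = seq_len(ns), dx = NA_real_, dy = NA_real_,
                       dz = NA_real_, valid = FALSE)
  for (o in seq_len(ns)) {
    p <- o + g
    if (p < 1L || p > ns) next
    fdx <- if (is.null(field)) 0L else field$dx[p]
    fdy <- if (is.null(field)) 0L else field$dy[p]
    fvalid <- if (is.null(field)) TRUE else field$valid[p]
    totals$dx[o] <- applied[["fast"]] + fdx
    totals$dy[o] <- g + fdy
    totals$dz[o] <- amc_pass1[o] + dz_axial[p]
    totals$valid[o] <- fvalid && !(p %in% (if (is.null(mask)) integer(0) else mask$removed))
  }
  list(volume = reg, field = field, totals = totals, mask = mask,
       axial_plan = axial_plan, rotation_plan = rotation_plan,
       applied_transverse = applied)
}

#' Run the full registration, averaging and evaluation pipeline
#'
#' Loads (or accepts) the input volumes, ranks them and picks the reference,
#' registers every target with [register_volume()], averages the registered
#' set, evaluates metrics versus number of averages, and writes all
#' artifacts to the output directory: the resolved configuration
#' (`config.yaml`), the averaged volume (`averaged.tif` + sidecar),
#' per-volume displacement CSVs and rotation-plan CSVs, the quality ranking
#' (`ranking.csv`), the evaluation curve (`evaluation.csv`, `evaluation.png`)
#' and a structured log of every applied shift (`run.log`).
#'
#' @param config a path to a YAML configuration, a configuration list, or a
#'   list with an element `volumes` (a [volume_set]) to run on in-memory
#'   data.
#' @param volumes optional [volume_set] overriding `config$input$paths`.
#' @return Invisibly, a list with `output_dir`, `reference_index`, `ranking`,
#'   `registered` (volume_set, quality order, reference first), `averaged`,
#'   `report`, and per-target `results`.
#' @export
run_register <- function(config, volumes = NULL) {
  config <- load_run_config(config)
  set.seed(as.integer(config$seed))
  logger <- make_logger(verbose = identical(config$log_level, "debug"))
  if (is.null(volumes)) {
    if (length(config$input$paths) < 2L)
      stopf("run_register needs at least 2 input volumes")
    vols <- lapply(config$input$paths, load_volume)
    volumes <- volume_set(vols)
  }
  if (length(volumes) < 2L)
    stopf("run_register needs at least 2 input volumes")
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  ranking <- rank_volumes(volumes)
  logger$log("ranking: order %s (reference %d)",
             paste(ranking$order, collapse = ","), ranking$reference_index)
  write.csv(cbind(rank = order(ranking$order), ranking$scores),
            file.path(out_dir, "ranking.csv"), row.names = FALSE)

  reference <- volumes$volumes[[ranking$reference_index]]
  ref_prepped <- if (isTRUE(config$stages$axial_motion))
    axial_motion_correct(reference, logger) else reference
  registered <- list(ref_prepped)
  results <- list()
  for (idx in ranking$order[-1]) {
    tgt <- volumes$volumes[[idx]]
    res <- register_volume(ref_prepped, tgt, config, logger)
    results[[tgt$id]] <- res
    registered[[length(registered) + 1L]] <- res$volume
    if (!is.null(res$field))
      write_field_csv(res$field, file.path(out_dir, sprintf("field_%s.csv", tgt$id)))
    if (!is.null(res$rotation_plan))
      write_rotation_csv(res$rotation_plan,
                         file.path(out_dir, sprintf("rotation_%s.csv", tgt$id)))
  }
  reg_set <- volume_set(registered, reference_index = 1L)
  averaged <- NULL
  if (isTRUE(config$stages$average)) {
    averaged <- average_volumes(reg_set)
    save_volume(averaged, file.path(out_dir, "averaged.tif"))
  }
  report <- NULL
  if (isTRUE(config$stages$evaluate) && length(reg_set) >= 3L) {
    # the metric curve compares averaged registered targets against the
    # reference; the reference itself never enters the average
    report <- metrics_vs_k(ref_prepped, volume_set(registered[-1]))
    write.csv(report, file.path(out_dir, "evaluation.csv"), row.names = FALSE)
    plot_metrics_vs_k(report, file.path(out_dir, "evaluation.png"))
  }
  writeLines(logger$lines(), file.path(out_dir, "run.log"))
  invisible(list(output_dir = out_dir, reference_index = ranking$reference_index,
                 ranking = ranking, registered = reg_set, averaged = averaged,
                 report = report, results = results))
}

#' Evaluate a candidate volume against a reference
#'
#' Computes MSE, SSIM and MS-SSIM between the en-face mean projections of
#' the two volumes, plus CNR of each when foreground/background masks are
#' supplied (binary TIFFs or logical matrices).
#'
#' @param reference,candidate [oct_volume]s or paths loadable by
#'   [load_volume()].
#' @param fg_mask,bg_mask optional masks for CNR: logical matrices or paths
#'   to binary TIFFs of the en-face shape.
#' @return A list with `mse`, `ssim`, `ms_ssim`, and (with masks)
#'   `cnr_reference`, `cnr_candidate`.
#' @export
run_evaluate <- function(reference, candidate, fg_mask = NULL, bg_mask = NULL) {
  if (is.character(reference)) reference <- load_volume(reference)
  if (is.character(candidate)) candidate <- load_volume(candidate)
  if (!identical(dim(reference$data), dim(candidate$data)))
    stopf("reference and candidate volumes have different shapes")
  ref_ef <- enface_projection(reference)
  cand_ef <- enface_projection(candidate)
  out <- list(mse = mse(ref_ef, cand_ef),
              ssim = ssim(ref_ef, cand_ef),
              ms_ssim = suppressWarnings(ms_ssim(ref_ef, cand_ef)))
  if (!is.null(fg_mask) || !is.null(bg_mask)) {
    if (is.null(fg_mask) || is.null(bg_mask))
      stopf("CNR needs both a foreground and a background mask")
    read_mask <- function(m) {
      if (is.character(m)) m <- tiff::readTIFF(m)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m > 0.5
    }
    fg <- read_mask(fg_mask); bg <- read_mask(bg_mask)
    out$cnr_reference <- cnr(ref_ef, fg, bg)
    out$cnr_candidate <- cnr(cand_ef, fg, bg)
  }
  out
}

#' Expected correction field implied by a ground-truth motion trace
#'
#' Inverts a [motion_trace()] into the per-frame corrections a perfect
#' registration should report, indexed by the corrupted volume's slow
#' positions: the frame recorded at position `p` images the template at
#' `p - dy[p]` under displacement `(dx[p], dz[p])`, so it needs corrections
#' `(-dx[p], -dy[p], -dz[p])`. Positions whose source index was clamped at
#' the volume edge are NA.
#'
#' When the pipeline's intra-volume axial correction is enabled it also
#' flattens the reference volume's own curvature; a registered target then
#' carries that same flattening on top of the negated trace. Passing the
#' reference's per-frame pass-1 shifts (attribute `axial_shifts` of
#' [axial_motion_correct()]'s output) as `reference_axial` adds them to the
#' expected `dz`.
#'
#' @param trace a `motion_trace`.
#' @param reference_axial optional per-frame axial shifts applied to the
#'   reference, indexed by reference slow position.
#' @return A data frame with columns `slow_index`, `dx`, `dy`, `dz` (NA
#'   where ambiguous).
#' @export
trace_expected_corrections <- function(trace, reference_axial = NULL) {
  ns <- length(trace$dx)
  src <- seq_len(ns) - trace$dy
  clamped <- src < 1L | src > ns
  src <- pmin(pmax(src, 1L), ns)
  dx <- -as.numeric(trace$dx)
  dy <- -as.numeric(trace$dy)
  dz <- -as.numeric(trace$dz) +
    (if (is.null(reference_axial)) 0 else reference_axial[src])
  dx[clamped] <- NA; dy[clamped] <- NA; dz[clamped] <- NA
  data.frame(slow_index = seq_len(ns), dx = dx, dy = dy, dz = dz)
}
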