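# Volume containers and file I/O. The canonical axis order (slow, depth,
# fast) is owned here; every downstream module consumes it.

#' Construct an OCT volume
#'
#' An `oct_volume` wraps a 3D intensity array in the canonical axis order
#' `(slow, depth, fast)`: a fast B-scan (frame) is `data[i, , ]` of shape
#' `(depth, fast)`, and the en-face mean projection is the mean over depth,
#' shape `(slow, fast)`. Physical pixel pitches are carried in micrometers
#' per pixel.
#'
#' @param data 3D numeric array indexed (slow, depth, fast); all dimensions
#'   must be at least 8 and all values finite.
#' @param pitch_slow,pitch_depth,pitch_fast micrometers per pixel along each
#'   axis.
#' @param modality `"OCT"` (structural) or `"OCTA"` (angiography).
#' @param id free-text label used in logs and reports.
#' @return An object of class `oct_volume`.
#' @examples
#' v <- oct_volume(array(runif(8 * 16 * 16), c(8, 16, 16)))
#' dim(v$data)
#' @export
oct_volume <- function(data, pitch_slow = 1, pitch_depth = 1, pitch_fast = 1,
                       modality = c("OCT", "OCTA"), id = "volume") {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array indexed (slow, depth, fast)")
  if (any(dim(data) < 8L))
    stopf("all volume dimensions must be >= 8, got (%s)",
          paste(dim(data), collapse = ", "))
  if (!all(is.finite(data)))
    stopf("volume '%s' contains non-finite intensities", id)
  storage.mode(data) <- "double"
  structure(
    list(data = data,
         pitch_slow = as.numeric(pitch_slow),
         pitch_depth = as.numeric(pitch_depth),
         pitch_fast = as.numeric(pitch_fast),
         modality = modality, id = as.character(id)),
    class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_volume '%s' %s: %d slow x %d depth x %d fast, pitch (%g, %g, %g) um>\n",
              x$id, x$modality, d[1], d[2], d[3],
              x$pitch_slow, x$pitch_depth, x$pitch_fast))
  invisible(x)
}

#' @noRd
n_slow <- function(v) dim(v$data)[1]
#' @noRd
n_depth <- function(v) dim(v$data)[2]
#' @noRd
n_fast <- function(v) dim(v$data)[3]

#' Center index of n frames
#'
#' The center of an n-frame block. With 0-based counting this is index
#' floor(n/2) (the fifth B-scan of a 10-frame block under that convention);
#' in R's 1-based indexing that same physical frame is `floor(n/2) + 1`.
#' @noRd
center_index <- function(n) as.integer(n %/% 2L) + 1L

#' En-face mean projection of a volume
#'
#' Mean over the depth axis; result has shape (slow, fast). A depth range
#' restricts the projection to a slab (e.g. a vascular plexus or a
#' signal-free band supplied by the caller).
#'
#' @param volume an [oct_volume].
#' @param depth_range optional integer `c(from, to)` depth slab (1-based,
#'   inclusive); default uses the full depth axis.
#' @return A numeric matrix of shape (slow, fast).
#' @export
enface_projection <- function(volume, depth_range = NULL) {
  if (is.null(depth_range)) return(apply(volume$data, c(1, 3), mean))
  d <- as.integer(depth_range)
  if (length(d) != 2L || d[1] < 1L || d[2] > n_depth(volume) || d[1] > d[2])
    stopf("depth_range must be c(from, to) within 1..%d", n_depth(volume))
  apply(volume$data[, d[1]:d[2], , drop = FALSE], c(1, 3), mean)
}

#' Extract a fast B-scan frame
#' @param volume an [oct_volume].
#' @param i slow index (1-based).
#' @return Matrix of shape (depth, fast).
#' @export
get_frame <- function(volume, i) {
  volume$data[i, , ]
}

#' Replace the data array of a volume, keeping metadata
#' @noRd
with_data <- function(volume, data, id = volume$id) {
  volume$data <- data
  volume$id <- id
  volume
}

#' Construct a volume set
#'
#' An ordered collection of volumes of identical shape, optionally with a
#' designated reference.
#'
#' @param volumes list of [oct_volume] objects of identical dimensions.
#' @param reference_index optional integer index of the reference volume.
#' @return An object of class `volume_set`.
#' @export
volume_set <- function(volumes, reference_index = NA_integer_) {
  if (!length(volumes)) stopf("a volume set needs at least one volume")
  if (!all(vapply(volumes, inherits, logical(1), "oct_volume")))
    stopf("all members must be oct_volume objects")
  d0 <- dim(volumes[[1]]$data)
  for (v in volumes)
    if (!identical(dim(v$data), d0))
      stopf("all member volumes must share identical (slow, depth, fast) dimensions")
  structure(list(volumes = volumes,
                 reference_index = as.integer(reference_index)),
            class = "volume_set")
}

#' @export
length.volume_set <- function(x) length(x$volumes)

#' @export
print.volume_set <- function(x, ...) {
  d <- dim(x$volumes[[1]]$data)
  cat(sprintf("<volume_set of %d volumes, %d x %d x %d, reference = %s>\n",
              length(x$volumes), d[1], d[2], d[3],
              ifelse(is.na(x$reference_index), "unset", x$reference_index)))
  invisible(x)
}

# --- file formats -----------------------------------------------------------

CANONICAL_AXES <- c("slow", "depth", "fast")

#' @noRd
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Load a volume from disk
#'
#' Two on-disk formats are supported. Multi-page grayscale TIFF: pages are
#' the slow index, page rows depth, page columns fast; an optional JSON
#' sidecar (same basename, `.json`) restores intensity scaling, pitches and
#' modality written by [save_volume()]. Raw binary: a headerless array (C
#' order, last axis fastest) described by a mandatory JSON sidecar with keys
#' `dtype` (`uint8`, `uint16`, `int16`, `int32`, `float32`, `float64`),
#' `shape`, `axis_order` (a permutation of `slow`, `depth`, `fast`) and
#' optionally `pitch_um`, `modality`, `id`. Axes are transposed to the
#' canonical order on load; intensities are cast to floating point.
#'
#' @param path path to a `.tif`/`.tiff` or raw `.bin`/`.raw` file.
#' @param sidecar optional explicit sidecar path; defaults to the file's
#'   basename with a `.json` extension.
#' @return An [oct_volume].
#' @export
load_volume <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (is.null(sidecar)) {
    sc <- sidecar_path(path)
    sidecar <- if (file.exists(sc)) sc else NULL
  }
  meta <- if (!is.null(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  if (ext %in% c("tif", "tiff")) {
    load_volume_tiff(path, meta)
  } else if (ext %in% c("bin", "raw")) {
    if (is.null(meta))
      stopf("raw binary input requires a JSON sidecar (missing for %s)", path)
    load_volume_raw(path, meta)
  } else {
    stopf("unsupported volume format '%s' (use .tif/.tiff or .bin/.raw + sidecar)", ext)
  }
}

#' @noRd
load_volume_tiff <- function(path, meta) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ns <- length(pages)
  d <- dim(pages[[1]])
  arr <- array(0, c(ns, d[1], d[2]))
  for (i in seq_len(ns)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse accidental RGB
    if (!all(is.finite(p)))
      stopf("TIFF page %d of %s contains NaN/Inf intensities", i, path)
    arr[i, , ] <- p
  }
  scale <- 1; offset <- 0
  pitches <- c(1, 1, 1); modality <- "OCT"; id <- tools::file_path_sans_ext(basename(path))
  if (!is.null(meta)) {
    if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$offset)) offset <- meta$offset
    if (!is.null(meta$pitch_um)) pitches <- as.numeric(meta$pitch_um)
    if (!is.null(meta$modality)) modality <- meta$modality
    if (!is.null(meta$id)) id <- meta$id
  }
  arr <- arr * scale + offset
  if (isTRUE(meta$integer_valued)) arr <- round(arr)
  oct_volume(arr, pitches[1], pitches[2], pitches[3], modality = modality, id = id)
}

#' @noRd
raw_dtype_info <- function(dtype) {
  switch(dtype,
    uint8   = list(what = "integer", size = 1L, signed = FALSE),
    uint16  = list(what = "integer", size = 2L, signed = FALSE),
    int16   = list(what = "integer", size = 2L, signed = TRUE),
    int32   = list(what = "integer", size = 4L, signed = TRUE),
    float32 = list(what = "double",  size = 4L, signed = TRUE),
    float64 = list(what = "double",  size = 8L, signed = TRUE),
    stopf("unsupported raw dtype '%s'", dtype))
}

#' @noRd
load_volume_raw <- function(path, meta) {
  for (key in c("dtype", "shape", "axis_order"))
    if (is.null(meta[[key]])) stopf("raw sidecar missing required key '%s'", key)
  info <- raw_dtype_info(meta$dtype)
  shape <- as.integer(meta$shape)
  axes <- as.character(meta$axis_order)
  if (length(shape) != 3L || length(axes) != 3L || !setequal(axes, CANONICAL_AXES))
    stopf("raw sidecar axis_order must be a permutation of (%s)",
          paste(CANONICAL_AXES, collapse = ", "))
  n <- prod(shape)
  vals <- readBin(path, what = info$what, n = n, size = info$size,
                  signed = info$signed, endian = "little")
  if (length(vals) != n)
    stopf("raw file %s holds %d values, sidecar shape implies %d", path, length(vals), n)
  if (!all(is.finite(vals)))
    stopf("raw volume %s contains NaN/Inf at linear index %d",
          path, which(!is.finite(vals))[1])
  # file is C order (last axis fastest); R arrays are column-major
  arr <- aperm(array(vals, dim = rev(shape)), 3:1)
  perm <- match(CANONICAL_AXES, axes)
  arr <- aperm(arr, perm)
  pitches <- if (!is.null(meta$pitch_um)) as.numeric(meta$pitch_um)[match(CANONICAL_AXES, axes)] else c(1, 1, 1)
  oct_volume(arr, pitches[1], pitches[2], pitches[3],
             modality = if (is.null(meta$modality)) "OCT" else meta$modality,
             id = if (is.null(meta$id)) tools::file_path_sans_ext(basename(path)) else meta$id)
}

#' Save a volume to disk
#'
#' TIFF output writes one 32-bit float page per slow index with intensities
#' affinely mapped into [0, 1]; the inverse mapping (a power-of-two scale, so
#' integer-valued data round-trips bit-exactly) plus pitches and modality go
#' into a JSON sidecar next to the file. Raw output writes little-endian
#' float32 (or float64) in canonical axis order, C layout, with the same
#' sidecar. `load_volume(save_volume(v))` reproduces `v` bit-exactly for
#' integer-valued data and to float32 precision otherwise.
#'
#' @param volume an [oct_volume].
#' @param path destination ending in `.tif`/`.tiff` or `.bin`/`.raw`.
#' @param dtype storage type for raw output, `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, dtype = "float32") {
  ext <- tolower(tools::file_ext(path))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stopf("destination directory is not writable: %s", dir)
  meta <- list(pitch_um = c(volume$pitch_slow, volume$pitch_depth, volume$pitch_fast),
               axis_order = CANONICAL_AXES,
               modality = volume$modality, id = volume$id)
  if (ext %in% c("tif", "tiff")) {
    x <- volume$data
    offset <- min(x)
    span <- max(x) - offset
    scale <- if (span > 0) 2^ceiling(log2(span)) else 1
    pages <- lapply(seq_len(dim(x)[1]), function(i) (x[i, , ] - offset) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    meta$scale <- scale; meta$offset <- offset
    # 32-bit TIFF samples are quantized; recording integrality lets the
    # loader round back to the exact integers
    meta$integer_valued <- all(x == round(x))
  } else if (ext %in% c("bin", "raw")) {
    if (!dtype %in% c("float32", "float64")) stopf("raw dtype must be float32 or float64")
    meta$dtype <- dtype
    meta$shape <- dim(volume$data)
    # C order: last (fast) axis fastest
    vals <- as.numeric(aperm(volume$data, 3:1))
    writeBin(vals, path, size = if (dtype == "float32") 4L else 8L, endian = "little")
  } else {
    stopf("unsupported output format '%s'", ext)
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- displacement field CSV -------------------------------------------------

#' Export a displacement field to CSV
#'
#' Columns: `slow_index` (1-based), `dx`, `dy`, `dz`, `valid`, `source`
#' (`matched`, `interpolated` or `extrapolated`).
#'
#' @param field a `displacement_field` (see [fine_register()]).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  df <- as.data.frame(field)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import a displacement field from CSV written by [write_field_csv()]
#'
#' @param path CSV path.
#' @return A `displacement_field`.
#' @export
read_field_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("slow_index", "dx", "dy", "dz", "valid", "source")
  if (!all(need %in% names(df))) stopf("displacement CSV must have columns %s",
                                       paste(need, collapse = ", "))
  displacement_field(dx = df$dx, dy = df$dy, dz = df$dz,
                     valid = as.logical(df$valid), source = df$source)
}
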