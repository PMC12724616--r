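#' Calibrated multichannel image stack
#'
#' Container for a 4-channel 3D fluorescence stack with physical pixel
#' calibration. Data are stored as a `[y, x, z, channel]` array; continuous
#' pixel coordinates are defined so that voxel `i` (1-based) spans
#' `(i-1, i]` with center `i - 0.5`, and physical coordinates are
#' `coordinate_px * calibration`.
#'
#' @param data numeric array `[y, x, z, channel]` (a 2D or 3D array is
#'   promoted with singleton dimensions).
#' @param pixel_xy_um XY pixel size in um (> 0).
#' @param z_step_um z step in um (> 0).
#' @param channel_names channel labels; default `c("dapi","dna5","dna3","rna")`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_xy_um, z_step_um,
                        channel_names = c("dapi", "dna5", "dna3", "rna")) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) abort("`data` must be a [y, x, z, channel] array.")
  if (dim(data)[4] != length(channel_names)) {
    abort(sprintf("Channel count mismatch: array has %d channels, names give %d (%s).",
                  dim(data)[4], length(channel_names),
                  paste(channel_names, collapse = ", ")))
  }
  if (!all(is.finite(data)) || any(data < 0)) {
    abort("Intensities must be finite and >= 0.")
  }
  if (!isTRUE(pixel_xy_um > 0) || !isTRUE(z_step_um > 0)) {
    abort("Calibration (`pixel_xy_um`, `z_step_um`) must be positive.")
  }
  structure(
    list(data = data, pixel_xy_um = pixel_xy_um, z_step_um = z_step_um,
         channel_names = channel_names),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d z, channels: %s | %.3f um/px, %.2f um/z\n",
              d[2], d[1], d[3], paste(x$channel_names, collapse = ","),
              x$pixel_xy_um, x$z_step_um))
  invisible(x)
}

channel_index <- function(stack, channel) {
  if (is.numeric(channel)) return(as.integer(channel))
  i <- match(channel, stack$channel_names)
  if (is.na(i)) {
    abort(sprintf("Unknown channel '%s'; stack has: %s.", channel,
                  paste(stack$channel_names, collapse = ", ")))
  }
  i
}

#' Extract one channel as a 3D array
#' @param stack an [image_stack()].
#' @param channel channel name or index.
#' @return numeric `[y, x, z]` array.
#' @export
get_channel <- function(stack, channel) {
  stack$data[, , , channel_index(stack, channel), drop = TRUE] |>
    (\(a) { if (length(dim(a)) < 3L && !is.null(dim(a))) dim(a) <- c(dim(a), 1L); a })()
}

#' Write an image stack to disk
#'
#' Writes a multi-page 32-bit float TIFF (pages ordered z within channel)
#' plus a JSON sidecar `<path>.json` carrying the pixel calibration, channel
#' names, array dimensions and the intensity scale used to map photon counts
#' into TIFF range. [read_stack()] restores the stack exactly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  scale <- max(stack$data, 1)
  pages <- list()
  for (c_ in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      pages[[length(pages) + 1L]] <- stack$data[, , z, c_] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    pixel_xy_um = stack$pixel_xy_um, z_step_um = stack$z_step_um,
    channel_names = stack$channel_names,
    dim = d, intensity_scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack from disk
#'
#' Reads a multi-page TIFF written by [write_stack()] (JSON sidecar) or any
#' plain multi-page TIFF given explicit calibration overrides and channel
#' names. Calibration must come from the sidecar or the overrides; if
#' neither provides it, this is an error.
#'
#' @param path TIFF path.
#' @param pixel_xy_um,z_step_um calibration overrides (um); take precedence
#'   over sidecar values.
#' @param channel_names expected channel names when no sidecar is present.
#' @param n_channels expected channel count when no sidecar is present;
#'   pages are split as z within channel.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_xy_um = NULL, z_step_um = NULL,
                       channel_names = c("dapi", "dna5", "dna3", "rna"),
                       n_channels = length(channel_names)) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(meta)) {
    d <- as.integer(meta$dim)
    channel_names <- meta$channel_names
    scale <- meta$intensity_scale
  } else {
    if (length(pages) %% n_channels != 0L) {
      abort(sprintf(
        "File has %d pages, not divisible by the expected %d channels (%s).",
        length(pages), n_channels, paste(channel_names, collapse = ", ")
      ))
    }
    d <- c(dim(pages[[1]])[1:2], length(pages) %/% n_channels, n_channels)
    scale <- 1
  }
  if (length(pages) != d[3] * d[4]) {
    abort(sprintf("Expected %d pages (%d z x %d channels), found %d.",
                  d[3] * d[4], d[3], d[4], length(pages)))
  }
  px <- pixel_xy_um %||% meta$pixel_xy_um
  zs <- z_step_um %||% meta$z_step_um
  if (is.null(px) || is.null(zs)) {
    abort("No pixel calibration in metadata; supply `pixel_xy_um` and `z_step_um`.")
  }
  arr <- array(0, dim = d)
  k <- 0L
  for (c_ in seq_len(d[4])) {
    for (z in seq_len(d[3])) {
      k <- k + 1L
      pg <- pages[[k]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # tolerate grey+alpha
      arr[, , z, c_] <- pg * scale
    }
  }
  image_stack(arr, pixel_xy_um = px, z_step_um = zs,
              channel_names = channel_names)
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum over z for one channel, the 2D representation on which
#' the default boundary-distance analysis operates. Calibration is carried
#' as attributes. Idempotent on single-plane input.
#'
#' @param stack an [image_stack()] or a plain 2D matrix (returned as is).
#' @param channel channel name or index.
#' @return 2D matrix with attributes `pixel_xy_um`.
#' @export
max_project <- function(stack, channel = NULL) {
  if (is.matrix(stack)) return(stack)
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(channel)) abort("`channel` is required for a multichannel stack.")
  a <- get_channel(stack, channel)
  proj <- apply(a, c(1, 2), max)
  attr(proj, "pixel_xy_um") <- stack$pixel_xy_um
  proj
}
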