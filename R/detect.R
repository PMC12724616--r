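#' Segment nuclei in a 2D DAPI image
#'
#' Transparent, dependency-light segmentation for smooth (synthetic or
#' well-stained) nuclei: Otsu threshold, hole filling, then a
#' distance-transform watershed to split touching objects. This is a
#' deliberate stand-in with the same input/output contract as learned
#' segmenters used on real data; it is not intended to match them
#' pixel-for-pixel on difficult material.
#'
#' @param dapi 2D matrix (e.g. [max_project()] of the DAPI channel).
#' @param min_area_px minimum object area kept, in pixels.
#' @param exclude_border drop nuclei touching the field border (default
#'   TRUE; distance measurements near crops are unreliable).
#' @param watershed_tolerance height tolerance passed to the watershed.
#' @return A list with `nuclei` (tibble: `label`, `y_px`, `x_px` centroid,
#'   `area_px`, bounding box, `touches_border`) and `labels` (integer label
#'   matrix, 0 = background). A blank image yields zero nuclei, not an error.
#' @export
segment_nuclei <- function(dapi, min_area_px = 100, exclude_border = TRUE,
                           watershed_tolerance = 1) {
  stopifnot(is.matrix(dapi))
  empty <- list(
    nuclei = tibble(label = integer(), y_px = numeric(), x_px = numeric(),
                    area_px = integer(), min_y = integer(), min_x = integer(),
                    max_y = integer(), max_x = integer(),
                    touches_border = logical()),
    labels = matrix(0L, nrow(dapi), ncol(dapi))
  )
  rng <- range(dapi)
  if (diff(rng) <= 0) {
    inform("Blank DAPI image: no nuclei segmented.")
    return(empty)
  }
  norm <- (dapi - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) {
    inform("Otsu threshold left no foreground: no nuclei segmented.")
    return(empty)
  }
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask)))
  dm <- EBImage::imageData(EBImage::distmap(mask))
  labels <- EBImage::imageData(
    EBImage::watershed(EBImage::Image(dm), tolerance = watershed_tolerance)
  )
  labels <- matrix(as.integer(labels), nrow(dapi), ncol(dapi))

  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area_px)
  border_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
  border_labels <- setdiff(border_labels, 0L)
  if (exclude_border) keep <- setdiff(keep, border_labels)
  labels[!(labels %in% keep)] <- 0L

  # relabel sequentially, preserving original order
  new_id <- integer(max(c(labels, 1L)))
  new_id[sort(keep)] <- seq_along(keep)
  labels[labels > 0] <- new_id[labels[labels > 0]]

  if (length(keep) == 0L) return(list(nuclei = empty$nuclei, labels = labels))
  border_new <- new_id[intersect(border_labels, keep)]
  idx <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  nuclei <- tibble(
    label = lab, y = idx[, 1], x = idx[, 2]
  ) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      y_px = mean(.data$y) - 0.5, x_px = mean(.data$x) - 0.5,
      area_px = dplyr::n(),
      min_y = min(.data$y), min_x = min(.data$x),
      max_y = max(.data$y), max_x = max(.data$x),
      .groups = "drop"
    ) |>
    dplyr::mutate(touches_border = .data$label %in% border_new)
  list(nuclei = nuclei, labels = labels)
}

log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  xs <- -r:r
  g <- outer(xs^2, xs^2, `+`)
  k <- (g - 2 * sigma^2) / sigma^4 * exp(-g / (2 * sigma^2))
  k <- -k            # positive response at bright blobs
  k - mean(k)        # zero sum: flat background gives zero response
}

local_maxima <- function(r) {
  ny <- nrow(r); nx <- ncol(r)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- r
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    # plateau tie-break: lexicographically earlier (x, then y) position wins
    earlier <- (dx < 0) || (dx == 0 && dy < 0)
    is_max <- is_max & (if (earlier) r > nb else r >= nb)
  }
  is_max
}

#' Detect diffraction-limited FISH spots
#'
#' Laplacian-of-Gaussian blob detection: the LoG response at scale
#' `sigma_px` is computed, local maxima exceeding `min_snr` times the
#' robust background spread of the response (median absolute deviation
#' scaled by 1.4826) are kept, and each peak is refined to a subpixel
#' centroid by an intensity-weighted mean over a window of half-width
#' `ceiling(sigma_px)` after local background subtraction. In `"3d"` mode
#' detection runs on the max projection and the z position is the
#' intensity-weighted centroid of the z profile under the peak window.
#'
#' @param image an [image_stack()] or a 2D matrix.
#' @param channel channel name/index (required for a stack).
#' @param sigma_px LoG scale in pixels (> 0), matched to the spot PSF width.
#' @param min_snr detection threshold as a multiple of the robust response
#'   spread.
#' @param mode `"2d"` (default, max projection) or `"3d"` (adds `z_px`).
#' @return A spot tibble: `spot_id`, `channel`, `cell_id` (NA until
#'   assigned), `y_px`, `x_px`, optional `z_px`, physical `*_um`
#'   coordinates, `intensity` (peak), `quality` (response / spread),
#'   `registered = TRUE`.
#' @export
detect_spots <- function(image, channel = NULL, sigma_px = 1.3, min_snr = 8,
                         mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (sigma_px <= 0) abort("`sigma_px` must be > 0.")
  is_stack <- inherits(image, "image_stack")
  px <- if (is_stack) image$pixel_xy_um else attr(image, "pixel_xy_um") %||% NA_real_
  zs <- if (is_stack) image$z_step_um else NA_real_
  img2d <- if (is_stack) max_project(image, channel) else image
  vol <- if (is_stack && mode == "3d") get_channel(image, channel) else NULL

  k <- log_kernel(sigma_px)
  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(img2d), k,
                                              boundary = "replicate"))
  spread <- stats::mad(resp, constant = 1.4826)
  if (spread <= 0) spread <- stats::sd(resp)
  # numerical floor: keeps FFT convolution ripple (~1e-13 of the peak) from
  # registering as detections on noise-free images
  spread <- max(spread, 1e-9 * max(abs(resp)), .Machine$double.eps)
  peaks <- local_maxima(resp) & (resp > min_snr * spread)
  idx <- which(peaks, arr.ind = TRUE)
  ch_name <- if (is.null(channel)) NA_character_
             else if (is.character(channel)) channel
             else if (is_stack) image$channel_names[channel] else as.character(channel)
  if (nrow(idx) == 0L) {
    return(tibble(
      spot_id = integer(), channel = character(), cell_id = integer(),
      y_px = numeric(), x_px = numeric(), z_px = numeric(),
      x_um = numeric(), y_um = numeric(), z_um = numeric(),
      intensity = numeric(), quality = numeric(), registered = logical()
    ))
  }
  # order peaks lexicographically (y, then x) for stable ids
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]

  h <- ceiling(sigma_px)
  ny <- nrow(img2d); nx <- ncol(img2d)
  out <- purrr::map(seq_len(nrow(idx)), function(i) {
    iy <- idx[i, 1]; ix <- idx[i, 2]
    y0 <- max(1, iy - h); y1 <- min(ny, iy + h)
    x0 <- max(1, ix - h); x1 <- min(nx, ix + h)
    win <- img2d[y0:y1, x0:x1, drop = FALSE]
    border <- c(win[1, ], win[nrow(win), ], win[, 1], win[, ncol(win)])
    w <- pmax(win - stats::median(border), 0)
    sw <- sum(w)
    if (sw <= 0) { w <- win; sw <- sum(w) }
    yc <- sum(w * (row(win) + y0 - 1 - 0.5)) / sw
    xc <- sum(w * (col(win) + x0 - 1 - 0.5)) / sw
    zc <- NA_real_
    if (!is.null(vol)) {
      prof <- apply(vol[y0:y1, x0:x1, , drop = FALSE], 3, sum)
      prof <- pmax(prof - min(prof), 0)
      zc <- if (sum(prof) > 0) {
        sum(prof * (seq_along(prof) - 0.5)) / sum(prof)
      } else length(prof) / 2
    }
    tibble(
      y_px = yc, x_px = xc, z_px = zc,
      intensity = img2d[iy, ix], quality = resp[iy, ix] / spread
    )
  }) |> dplyr::bind_rows()

  out |>
    dplyr::mutate(
      spot_id = dplyr::row_number(), channel = ch_name, cell_id = NA_integer_,
      x_um = .data$x_px * px, y_um = .data$y_px * px, z_um = .data$z_px * zs,
      registered = TRUE
    ) |>
    dplyr::select("spot_id", "channel", "cell_id", "y_px", "x_px", "z_px",
                  "x_um", "y_um", "z_um", "intensity", "quality", "registered")
}

roll_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

#' Estimate a rigid translation by phase cross-correlation
#'
#' Computes the normalized cross-power spectrum of the two images, locates
#' the correlation peak to integer precision, and (for `upsample > 1`)
#' refines it with an upsampled discrete Fourier transform evaluated by
#' matrix multiplication in a small neighborhood of the peak. The returned
#' shift `s = (dy, dx)` satisfies `moving(y, x) ~ ref(y - dy, x - dx)`, i.e.
#' a feature at position `p` in the reference appears at `p + s` in the
#' moving image.
#'
#' @param ref,moving same-shape 2D matrices (e.g. DAPI from the two
#'   acquisitions).
#' @param upsample subpixel refinement factor; precision ~ 1/upsample px.
#' @return Object of class `registration_result`: `shift_y`, `shift_x`
#'   (subpixel) and `peak_correlation` (Pearson correlation of the overlap
#'   after applying the rounded shift).
#' @export
register_translation <- function(ref, moving, upsample = 20) {
  stopifnot(is.matrix(ref), is.matrix(moving))
  if (!all(dim(ref) == dim(moving))) abort("Images must have the same shape.")
  if (stats::sd(ref) == 0) abort("Degenerate registration input: `ref` is constant.")
  if (stats::sd(moving) == 0) abort("Degenerate registration input: `moving` is constant.")
  ny <- nrow(ref); nx <- ncol(ref)
  R <- fft(ref) * Conj(fft(moving))
  Rn <- R / pmax(Mod(R), .Machine$double.eps)
  cc <- Re(fft(Rn, inverse = TRUE)) / (ny * nx)
  pk <- arrayInd(which.max(cc), dim(cc))
  sy <- pk[1] - 1; sx <- pk[2] - 1
  if (sy > ny / 2) sy <- sy - ny
  if (sx > nx / 2) sx <- sx - nx
  # the correlation peak sits at minus the shift under our convention
  sy <- -sy; sx <- -sx

  if (upsample > 1) {
    # upsampled DFT of the cross-power spectrum around the integer estimate
    half <- 1.5
    ys <- seq(sy - half, sy + half, by = 1 / upsample)
    xs <- seq(sx - half, sx + half, by = 1 / upsample)
    fy <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
    fx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
    Ey <- exp(-2i * pi * outer(ys, fy))
    Ex <- exp(-2i * pi * outer(fx, xs))
    cc_up <- Re(Ey %*% Rn %*% Ex)
    pk <- arrayInd(which.max(cc_up), dim(cc_up))
    sy <- ys[pk[1]]; sx <- xs[pk[2]]
  }
  rolled <- roll_matrix(moving, -round(sy), -round(sx))
  structure(
    list(shift_y = sy, shift_x = sx,
         peak_correlation = stats::cor(as.vector(ref), as.vector(rolled))),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> shift (dy, dx) = (%.3f, %.3f) px, r = %.4f\n",
              x$shift_y, x$shift_x, x$peak_correlation))
  invisible(x)
}

#' Apply an estimated registration to a spot table
#'
#' Translates centroids of spots from the moving acquisition back into the
#' reference frame (subtracting the estimated shift) and recomputes physical
#' coordinates. Spots already flagged `registered` cannot be corrected
#' twice: a second application is an error.
#'
#' @param spots spot tibble from the moving acquisition (`registered` FALSE).
#' @param reg a [register_translation()] result.
#' @param pixel_xy_um XY pixel size used to refresh `x_um`/`y_um`.
#' @return The spot tibble with corrected coordinates, `registered = TRUE`.
#' @export
apply_registration <- function(spots, reg, pixel_xy_um = 0.152) {
  stopifnot(inherits(reg, "registration_result"))
  if (nrow(spots) && any(spots$registered)) {
    abort("Spots are already registered; refusing a second application.")
  }
  spots |>
    dplyr::mutate(
      x_px = .data$x_px - reg$shift_x,
      y_px = .data$y_px - reg$shift_y,
      x_um = .data$x_px * pixel_xy_um,
      y_um = .data$y_px * pixel_xy_um,
      registered = TRUE
    )
}

#' Assign spots to segmented nuclei
#'
#' Looks up the nucleus label at the voxel containing each spot centroid;
#' label 0 (background) or a centroid outside the field leaves the spot
#' unassigned (`cell_id = NA`), which excludes it from all allele analyses.
#'
#' @param spots spot tibble with `y_px`, `x_px`.
#' @param labels integer label matrix from [segment_nuclei()].
#' @return The spot tibble with `cell_id` filled in.
#' @export
assign_spots_to_nuclei <- function(spots, labels) {
  if (nrow(spots) == 0L) return(spots)
  iy <- ceiling(spots$y_px); ix <- ceiling(spots$x_px)
  inside <- iy >= 1 & iy <= nrow(labels) & ix >= 1 & ix <= ncol(labels)
  if (any(!inside)) {
    inform(sprintf("%d spot centroids fall outside the field; left unassigned.",
                   sum(!inside)))
  }
  lab <- rep(NA_integer_, nrow(spots))
  lab[inside] <- labels[cbind(pmax(iy[inside], 1), pmax(ix[inside], 1))]
  lab[!is.na(lab) & lab == 0L] <- NA_integer_
  dplyr::mutate(spots, cell_id = lab)
}
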