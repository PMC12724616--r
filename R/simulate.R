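#' Simulate allele-level ground truth
#'
#' Places non-overlapping spherical nuclei in the field, then draws, for each
#' allele, a pairing state (Bernoulli), a 5'-to-3' boundary displacement
#' (isotropic Gaussian with state-dependent per-axis scale, so the 3D
#' distance is scale times a chi variate with 3 df), an activity state
#' (Bernoulli), and — for active alleles — a nascent-RNA position offset from
#' the 5' boundary anchor. Deterministic for a fixed seed; each cell uses a
#' child random stream derived from the root seed by counter, so increasing
#' `n_cells` leaves earlier cells unchanged.
#'
#' The displacement vector is drawn first and only the allele midpoint is
#' re-sampled when the pair does not fit inside its nucleus, so the
#' distance distribution is exactly the configured mixture.
#'
#' @param config a [simulation_config()].
#' @return An object of class `scene_truth`: a list with `alleles` (one row
#'   per allele: positions in um, `true_distance_um`, `paired`, `active`,
#'   RNA position or `NA`), `cells` (nucleus centers and radii), and the
#'   `config`.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- place_nuclei(config)
  mats <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    set.seed(child_seed(config$seed, i))
    mats[[i]] <- simulate_cell_alleles(
      config,
      center = c(cells$cx_um[i], cells$cy_um[i], cells$cz_um[i]),
      radius = cells$radius_um[i]
    )
  }
  m <- do.call(rbind, mats)
  alleles <- tibble(
    cell_id = rep(seq_len(config$n_cells), each = config$ploidy),
    allele_id = rep(seq_len(config$ploidy), config$n_cells),
    x5_um = m[, 1], y5_um = m[, 2], z5_um = m[, 3],
    x3_um = m[, 4], y3_um = m[, 5], z3_um = m[, 6],
    true_distance_um = m[, 7],
    paired = m[, 8] > 0, active = m[, 9] > 0,
    rna_x_um = m[, 10], rna_y_um = m[, 11], rna_z_um = m[, 12]
  )
  structure(
    list(alleles = alleles, cells = cells, config = config),
    class = "scene_truth"
  )
}

# rejection-pack nucleus centers; sequential so earlier cells are stable
place_nuclei <- function(config) {
  set.seed(config$seed)
  r <- config$nucleus_radius_um
  fx <- config$field_size_px[1] * config$pixel_xy_um
  fy <- config$field_size_px[2] * config$pixel_xy_um
  depth <- config$z_planes * config$z_step_um
  cz <- depth / 2
  max_tries <- 100L * config$n_cells
  cx <- numeric(0); cy <- numeric(0)
  tries <- 0L
  while (length(cx) < config$n_cells) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf(
        "Failed to pack %d nuclei of radius %.2f um into a %.1f x %.1f um field after %d tries.",
        config$n_cells, r, fx, fy, max_tries
      ))
    }
    x <- runif(1, r, fx - r)
    y <- runif(1, r, fy - r)
    if (length(cx) == 0 || all((cx - x)^2 + (cy - y)^2 >= (2 * r)^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
  }
  tibble(
    cell_id = seq_len(config$n_cells),
    cx_um = cx, cy_um = cy, cz_um = cz,
    radius_um = r
  )
}

runif_sphere <- function(radius) {
  # uniform point in a ball
  repeat {
    p <- runif(3, -radius, radius)
    if (sum(p^2) <= radius^2) return(p)
  }
}

# one row per allele: x5 y5 z5 x3 y3 z3 dist paired active rna_x rna_y rna_z
simulate_cell_alleles <- function(config, center, radius) {
  n <- config$ploidy
  m <- matrix(NA_real_, n, 12)
  for (a in seq_len(n)) {
    active <- runif(1) < config$p_active
    p_pair <- if (active) config$p_pair_active else config$p_pair
    paired <- runif(1) < p_pair
    scale <- if (paired) config$paired_scale_um else config$unpaired_scale_um
    disp <- rnorm(3, 0, scale)
    # resample the midpoint only: preserves the displacement law exactly
    for (try in 1:1000) {
      mid <- runif_sphere(radius)
      p5 <- mid - disp / 2
      p3 <- mid + disp / 2
      if (sum(p5^2) <= radius^2 && sum(p3^2) <= radius^2) break
      if (try == 1000) abort("Could not place an allele inside its nucleus.")
    }
    rna <- c(NA_real_, NA_real_, NA_real_)
    if (active) {
      rna <- p5 + center  # degenerate fallback: anchor position
      for (try in 1:1000) {
        cand <- p5 + rnorm(3, 0, config$rna_offset_scale_um)
        if (sum(cand^2) <= radius^2) { rna <- cand + center; break }
      }
    }
    m[a, ] <- c(p5 + center, p3 + center, sqrt(sum(disp^2)),
                paired, active, rna)
  }
  m
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d cells (ploidy %d), %d alleles, %d active\n",
    nrow(x$cells), x$config$ploidy, nrow(x$alleles), sum(x$alleles$active)
  ))
  invisible(x)
}

#' Degrade ground truth to a detected-spot table
#'
#' Emulates the output of spot detection without rendering images: each true
#' spot is retained independently with its channel's detection efficiency,
#' localization noise is added to retained centroids, and RNA-channel
#' coordinates are displaced by the configured inter-acquisition channel
#' shift (the pre-registration state). Pixel coordinates are derived from
#' physical ones via the configured calibration.
#'
#' @param truth a `scene_truth`.
#' @param config a [simulation_config()]; defaults to the one stored in
#'   `truth`.
#' @return A spot table: one row per detected spot with `spot_id`, `channel`
#'   (`dna5`, `dna3`, `rna`), `cell_id`, `allele_id` (ground-truth link),
#'   `x_um`/`y_um`/`z_um`, matching `x_px`/`y_px`/`z_px`, and a `registered`
#'   flag (FALSE for shifted RNA spots).
#' @export
degrade_to_spot_table <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "scene_truth"))
  al <- truth$alleles
  long <- dplyr::bind_rows(
    dplyr::transmute(al, channel = "dna5", cell_id = .data$cell_id,
                     allele_id = .data$allele_id,
                     x_um = .data$x5_um, y_um = .data$y5_um, z_um = .data$z5_um),
    dplyr::transmute(al, channel = "dna3", cell_id = .data$cell_id,
                     allele_id = .data$allele_id,
                     x_um = .data$x3_um, y_um = .data$y3_um, z_um = .data$z3_um),
    al |>
      dplyr::filter(.data$active) |>
      dplyr::transmute(channel = "rna", cell_id = .data$cell_id,
                       allele_id = .data$allele_id,
                       x_um = .data$rna_x_um, y_um = .data$rna_y_um,
                       z_um = .data$rna_z_um)
  )
  set.seed(child_seed(config$seed, 999983L))
  keep <- runif(nrow(long)) < config$detect_eff[long$channel]
  long <- long[keep, , drop = FALSE]
  n <- nrow(long)
  if (config$loc_noise_um > 0 && n > 0) {
    long$x_um <- long$x_um + rnorm(n, 0, config$loc_noise_um)
    long$y_um <- long$y_um + rnorm(n, 0, config$loc_noise_um)
    long$z_um <- long$z_um + rnorm(n, 0, config$loc_noise_um)
  }
  is_rna <- long$channel == "rna"
  long$x_um[is_rna] <- long$x_um[is_rna] +
    config$channel_shift_px[1] * config$pixel_xy_um
  long$y_um[is_rna] <- long$y_um[is_rna] +
    config$channel_shift_px[2] * config$pixel_xy_um
  long |>
    dplyr::mutate(
      spot_id = dplyr::row_number(),
      x_px = .data$x_um / config$pixel_xy_um,
      y_px = .data$y_um / config$pixel_xy_um,
      z_px = .data$z_um / config$z_step_um,
      intensity = config$spot_amplitude,
      quality = NA_real_,
      registered = !is_rna | all(config$channel_shift_px == 0)
    ) |>
    dplyr::select("spot_id", "channel", "cell_id", "allele_id",
                  "x_px", "y_px", "z_px", "x_um", "y_um", "z_um",
                  "intensity", "quality", "registered")
}

#' Render a multichannel image stack from ground truth
#'
#' Produces a calibrated 4-channel 3D stack (`dapi`, `dna5`, `dna3`, `rna`).
#' The DAPI channel contains smooth nuclear disks (per-plane spheres blurred
#' with the PSF); each FISH spot is a 3D Gaussian of s.d. `spot_sigma_px` in
#' XY and `spot_sigma_z_um` axially (pixel anisotropy enters through the
#' z-step conversion) with peak `spot_amplitude` over `background`. Poisson shot noise is applied to every channel, and the RNA
#' channel is rendered displaced by the true channel shift.
#'
#' @inheritParams degrade_to_spot_table
#' @param noise apply Poisson shot noise (default TRUE).
#' @return An [image_stack()].
#' @export
render_stack <- function(truth, config = truth$config, noise = TRUE) {
  stopifnot(inherits(truth, "scene_truth"))
  nx <- config$field_size_px[1]; ny <- config$field_size_px[2]
  nz <- config$z_planes
  dat <- array(0, dim = c(ny, nx, nz, 4))
  px <- config$pixel_xy_um; zs <- config$z_step_um

  # DAPI: filled spheres, blurred per plane
  dapi_amp <- config$spot_amplitude / 2
  zc <- (seq_len(nz) - 0.5) * zs
  for (i in seq_len(nrow(truth$cells))) {
    c_ <- truth$cells[i, ]
    for (z in seq_len(nz)) {
      dz <- zc[z] - c_$cz_um
      if (abs(dz) >= c_$radius_um) next
      rz_px <- sqrt(c_$radius_um^2 - dz^2) / px
      cx <- c_$cx_um / px; cy <- c_$cy_um / px
      x0 <- max(1, floor(cx - rz_px)); x1 <- min(nx, ceiling(cx + rz_px))
      y0 <- max(1, floor(cy - rz_px)); y1 <- min(ny, ceiling(cy + rz_px))
      if (x0 > x1 || y0 > y1) next
      xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
      d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
      dat[y0:y1, x0:x1, z, 1] <- dat[y0:y1, x0:x1, z, 1] +
        dapi_amp * (d2 <= rz_px^2)
    }
  }
  if (config$spot_sigma_px > 0) {
    for (z in seq_len(nz)) {
      dat[, , z, 1] <- as.matrix(EBImage::gblur(
        dat[, , z, 1], sigma = max(config$spot_sigma_px, 0.5)
      ))
    }
  }

  # FISH spots
  al <- truth$alleles
  clip <- 0L
  add_spot <- function(arr, ch, x_um, y_um, z_um, dx_px = 0, dy_px = 0) {
    xc <- x_um / px + dx_px; yc <- y_um / px + dy_px; zc_ <- z_um / zs
    s <- config$spot_sigma_px
    sz <- config$spot_sigma_z_um / zs
    w <- ceiling(4 * s) + 1
    x0 <- floor(xc - w) + 1; x1 <- ceiling(xc + w)
    y0 <- floor(yc - w) + 1; y1 <- ceiling(yc + w)
    if (x1 < 1 || y1 < 1 || x0 > nx || y0 > ny) {
      clip <<- clip + 1L
      return(arr)
    }
    if (x0 < 1 || y0 < 1 || x1 > nx || y1 > ny) clip <<- clip + 1L
    x0 <- max(1, x0); y0 <- max(1, y0); x1 <- min(nx, x1); y1 <- min(ny, y1)
    xs <- (x0:x1) - 0.5; ys <- (y0:y1) - 0.5
    gx <- exp(-(xs - xc)^2 / (2 * s^2))
    gy <- exp(-(ys - yc)^2 / (2 * s^2))
    zcenters <- seq_len(nz) - 0.5
    gz <- exp(-(zcenters - zc_)^2 / (2 * sz^2))
    patch <- outer(gy, gx)
    for (z in which(gz > 1e-6)) {
      arr[y0:y1, x0:x1, z, ch] <- arr[y0:y1, x0:x1, z, ch] +
        config$spot_amplitude * gz[z] * patch
    }
    arr
  }
  for (i in seq_len(nrow(al))) {
    dat <- add_spot(dat, 2, al$x5_um[i], al$y5_um[i], al$z5_um[i])
    dat <- add_spot(dat, 3, al$x3_um[i], al$y3_um[i], al$z3_um[i])
    if (al$active[i]) {
      dat <- add_spot(dat, 4, al$rna_x_um[i], al$rna_y_um[i], al$rna_z_um[i],
                      dx_px = config$channel_shift_px[1],
                      dy_px = config$channel_shift_px[2])
    }
  }
  if (clip > 0) {
    warn(sprintf("%d spot footprints were clipped at the field border.", clip))
  }
  dat <- dat + config$background
  if (noise) {
    set.seed(child_seed(config$seed, 999979L))
    dat[] <- rpois(length(dat), lambda = pmax(dat, 0))
  }
  image_stack(dat,
              pixel_xy_um = config$pixel_xy_um,
              z_step_um = config$z_step_um)
}
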