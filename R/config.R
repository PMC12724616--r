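#' Simulation configuration
#'
#' Builds and validates the parameter set for the synthetic DNA/RNA FISH
#' generator. Defaults describe a field imaged at 152 nm XY pixel size with
#' a 7 um z range sampled every 1 um, populated with diploid nuclei whose
#' 5'/3' TAD boundary separation follows a two-state (paired/unpaired)
#' isotropic-Gaussian displacement mixture. With the default mixture
#' (`p_pair = 0.3`, scales 0.08/0.35 um) the population median 3D boundary
#' distance is ~0.41 um and ~33% of alleles lie within 250 nm, the scale
#' reported for TAD-boundary loci in high-throughput FISH experiments.
#'
#' @param n_cells number of nuclei to place in the field.
#' @param ploidy chromosomal copy number per cell, 2 or 3.
#' @param nucleus_radius_um nuclear radius (um); nuclei are non-overlapping
#'   spheres.
#' @param field_size_px integer `(x, y)` field size in pixels.
#' @param z_planes number of z planes.
#' @param pixel_xy_um XY pixel size in um.
#' @param z_step_um z step in um.
#' @param p_pair probability that an allele is in the paired boundary state.
#' @param paired_scale_um per-axis s.d. (um) of the 5'-to-3' displacement in
#'   the paired state; the 3D distance is then `paired_scale_um` times a
#'   chi-distributed variate with 3 degrees of freedom.
#' @param unpaired_scale_um per-axis displacement s.d. (um) in the unpaired
#'   state.
#' @param p_active per-allele probability of carrying a nascent transcription
#'   site.
#' @param p_pair_active pairing probability for *active* alleles. Defaults to
#'   `p_pair`, i.e. transcriptional activity independent of boundary
#'   proximity; set higher/lower to simulate a coupled alternative.
#' @param rna_offset_scale_um per-axis s.d. (um) of the RNA spot offset from
#'   the 5' boundary anchor.
#' @param detect_eff per-channel detection probability; scalar or named
#'   vector over `c("dna5", "dna3", "rna")`.
#' @param loc_noise_um per-axis localization noise s.d. (um) applied when
#'   degrading ground truth to a spot table.
#' @param channel_shift_px true `(dx, dy)` shift, in pixels, of the RNA
#'   acquisition relative to the DNA acquisition.
#' @param spot_sigma_px rendering PSF s.d. in XY pixels.
#' @param spot_sigma_z_um axial PSF s.d. in um; defaults to three times the
#'   lateral physical width (`3 * spot_sigma_px * pixel_xy_um`), the typical
#'   axial elongation of a confocal PSF, so spots between z planes remain
#'   detectable at a 1 um step.
#' @param spot_amplitude peak spot signal in photons.
#' @param background mean background level in photons.
#' @param seed root random seed; per-cell child streams are derived by
#'   counter so earlier cells are unchanged when `n_cells` grows.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_cells = 10, seed = 1)
#' truth <- simulate_ground_truth(cfg)
simulation_config <- function(n_cells = 20,
                              ploidy = 2,
                              nucleus_radius_um = 3,
                              field_size_px = c(360, 360),
                              z_planes = 8,
                              pixel_xy_um = 0.152,
                              z_step_um = 1.0,
                              p_pair = 0.3,
                              paired_scale_um = 0.08,
                              unpaired_scale_um = 0.35,
                              p_active = 0.3,
                              p_pair_active = NULL,
                              rna_offset_scale_um = 0.2,
                              detect_eff = 1.0,
                              loc_noise_um = 0.0,
                              channel_shift_px = c(0, 0),
                              spot_sigma_px = 1.3,
                              spot_sigma_z_um = NULL,
                              spot_amplitude = 200,
                              background = 10,
                              seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), ploidy = as.integer(ploidy),
    nucleus_radius_um = nucleus_radius_um,
    field_size_px = as.integer(field_size_px), z_planes = as.integer(z_planes),
    pixel_xy_um = pixel_xy_um, z_step_um = z_step_um,
    p_pair = p_pair, paired_scale_um = paired_scale_um,
    unpaired_scale_um = unpaired_scale_um,
    p_active = p_active,
    p_pair_active = p_pair_active %||% p_pair,
    rna_offset_scale_um = rna_offset_scale_um,
    detect_eff = norm_detect_eff(detect_eff),
    loc_noise_um = loc_noise_um,
    channel_shift_px = as.numeric(channel_shift_px),
    spot_sigma_px = spot_sigma_px,
    spot_sigma_z_um = spot_sigma_z_um %||% (3 * spot_sigma_px * pixel_xy_um),
    spot_amplitude = spot_amplitude,
    background = background, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

norm_detect_eff <- function(x) {
  ch <- c("dna5", "dna3", "rna")
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), 3L), ch)
  }
  if (!all(ch %in% names(x))) {
    abort("`detect_eff` must be a scalar or named over c('dna5','dna3','rna').")
  }
  as.numeric(x[ch]) |> stats::setNames(ch)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_pair, cfg$p_active, cfg$p_pair_active, cfg$detect_eff)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  lens <- c(
    nucleus_radius_um = cfg$nucleus_radius_um,
    pixel_xy_um = cfg$pixel_xy_um, z_step_um = cfg$z_step_um
  )
  bad <- names(lens)[!is.finite(lens) | lens <= 0]
  if (length(bad)) abort(paste0("Lengths must be > 0: ", paste(bad, collapse = ", ")))
  if (any(c(cfg$paired_scale_um, cfg$unpaired_scale_um, cfg$rna_offset_scale_um,
            cfg$loc_noise_um) < 0)) {
    abort("Dispersion scales must be >= 0.")
  }
  if (cfg$z_planes < 1L) abort("`z_planes` must be >= 1.")
  if (!cfg$ploidy %in% c(2L, 3L)) abort("`ploidy` must be 2 or 3.")
  if (length(cfg$field_size_px) != 2L || any(cfg$field_size_px < 8L)) {
    abort("`field_size_px` must be two integers >= 8.")
  }
  # packing feasibility: random sequential placement of non-overlapping
  # disks jams near 0.547 coverage; reject configurations beyond it
  fx <- cfg$field_size_px[1] * cfg$pixel_xy_um
  fy <- cfg$field_size_px[2] * cfg$pixel_xy_um
  r <- cfg$nucleus_radius_um
  usable <- max(fx - 2 * r, 0) * max(fy - 2 * r, 0)
  need <- cfg$n_cells * pi * r^2
  if (usable <= 0 || need > 0.54 * usable) {
    abort(sprintf(
      "Field too small: %d nuclei of radius %.2f um need ~%.0f um^2 but only ~%.0f um^2 is usable.",
      cfg$n_cells, r, need, usable
    ))
  }
  structure(cfg, class = "sim_config")
}

# deterministic per-cell child seed derived from the root seed by counter
child_seed <- function(root, i) {
  as.integer((as.numeric(root) %% 65013L * 48271 + i * 16807) %% 2147483629)
}
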