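gauss_spot <- function(ny, nx, yc, xc, sigma = 1.3, amp = 100, bg = 0) {
  ys <- seq_len(ny) - 0.5; xs <- seq_len(nx) - 0.5
  bg + amp * outer(exp(-(ys - yc)^2 / (2 * sigma^2)),
                   exp(-(xs - xc)^2 / (2 * sigma^2)))
}

test_that("segmentation recovers rendered nuclei and honors the border policy", {
  cfg <- simulation_config(n_cells = 2, field_size_px = c(128, 128), seed = 21)
  tr <- simulate_ground_truth(cfg)
  st <- render_stack(tr)
  seg <- segment_nuclei(max_project(st, "dapi"))
  expect_equal(nrow(seg$nuclei), 2)
  # centroids within 1 px of the true centers (projected sphere -> disk)
  truth <- tr$cells
  for (i in 1:2) {
    d <- sqrt((seg$nuclei$x_px - truth$cx_um[i] / 0.152)^2 +
              (seg$nuclei$y_px - truth$cy_um[i] / 0.152)^2)
    expect_lt(min(d), 1)
  }
  # label image and records agree
  expect_setequal(seg$nuclei$label, setdiff(unique(as.vector(seg$labels)), 0L))
  areas <- tabulate(seg$labels[seg$labels > 0])
  expect_equal(sort(areas[areas > 0]), sort(seg$nuclei$area_px))

  # blank image: zero nuclei, no error
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))$nuclei), 0)

  # disk hanging over the field edge is flagged and excluded by default
  img <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if ((i - 32)^2 + (j - 2)^2 < 15^2) img[i, j] <- 1
    if ((i - 20)^2 + (j - 45)^2 < 10^2) img[i, j] <- 1
  }
  seg_def <- segment_nuclei(img, min_area_px = 50)
  expect_equal(nrow(seg_def$nuclei), 1)
  seg_keep <- segment_nuclei(img, min_area_px = 50, exclude_border = FALSE)
  expect_equal(nrow(seg_keep$nuclei), 2)
  expect_equal(sum(seg_keep$nuclei$touches_border), 1)
})

test_that("LoG detection finds isolated spots with subpixel accuracy", {
  img <- gauss_spot(64, 64, 30.3, 41.8)
  sp <- detect_spots(img, sigma_px = 1.3, min_snr = 8)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$y_px - 30.3), 0.5)
  expect_lt(abs(sp$x_px - 41.8), 0.5)

  # two spots 10 sigma apart stay separate
  img2 <- gauss_spot(64, 64, 20, 20) + gauss_spot(64, 64, 20, 33)
  expect_equal(nrow(detect_spots(img2, sigma_px = 1.3, min_snr = 8)), 2)

  expect_error(detect_spots(img, sigma_px = 0), "sigma")
})

test_that("pure-noise fields produce essentially no false positives", {
  n_clean <- 0
  for (s in 1:100) {
    set.seed(s)
    img <- matrix(rpois(64 * 64, 10), 64, 64)
    if (nrow(detect_spots(img, sigma_px = 1.3, min_snr = 8)) == 0) {
      n_clean <- n_clean + 1
    }
  }
  expect_gte(n_clean, 99)
})

test_that("phase correlation recovers integer and subpixel shifts", {
  cfg <- simulation_config(n_cells = 4, field_size_px = c(192, 192), seed = 31)
  ref <- max_project(render_stack(simulate_ground_truth(cfg)), "dapi")

  # identity
  r0 <- register_translation(ref, ref, upsample = 1)
  expect_equal(c(r0$shift_y, r0$shift_x), c(0, 0))
  expect_gt(r0$peak_correlation, 0.999)

  # integer roll is recovered exactly: moving(y, x) = ref(y - 3, x + 2)
  idx_y <- ((seq_len(nrow(ref)) - 1 - 3) %% nrow(ref)) + 1
  idx_x <- ((seq_len(ncol(ref)) - 1 + 2) %% ncol(ref)) + 1
  moving <- ref[idx_y, idx_x]
  ri <- register_translation(ref, moving, upsample = 1)
  expect_identical(c(ri$shift_y, ri$shift_x), c(3, -2))

  # subpixel shift within 1/upsample, and inverse-consistent
  mv <- shift_image(ref, 1.25, -0.5)
  rs <- register_translation(ref, mv, upsample = 20)
  expect_lt(abs(rs$shift_y - 1.25), 1 / 20)
  expect_lt(abs(rs$shift_x - (-0.5)), 1 / 20)
  rb <- register_translation(mv, ref, upsample = 20)
  expect_lt(abs(rs$shift_y + rb$shift_y), 1 / 20)
  expect_lt(abs(rs$shift_x + rb$shift_x), 1 / 20)

  expect_error(register_translation(matrix(1, 8, 8), ref[1:8, 1:8]), "ref")
  expect_error(register_translation(ref[1:8, 1:8], matrix(2, 8, 8)), "moving")
})

test_that("registration round-trip restores shifted RNA coordinates", {
  cfg <- simulation_config(n_cells = 10, seed = 41, channel_shift_px = c(3, -2),
                           field_size_px = c(256, 256))
  tr <- simulate_ground_truth(cfg)
  sp <- degrade_to_spot_table(tr)
  rna <- dplyr::filter(sp, channel == "rna")
  expect_false(any(rna$registered))

  ref <- max_project(render_stack(tr, noise = FALSE), "dapi")
  moving <- shift_image(ref, cfg$channel_shift_px[2], cfg$channel_shift_px[1])
  reg <- register_translation(ref, moving, upsample = 20)
  fixed <- apply_registration(rna, reg, pixel_xy_um = cfg$pixel_xy_um)
  truth_active <- dplyr::filter(tr$alleles, active)
  expect_equal(fixed$x_um,
               truth_active$rna_x_um[match(fixed$allele_id + 10 * fixed$cell_id,
                                           truth_active$allele_id + 10 * truth_active$cell_id)],
               tolerance = 0.01)
  # shift (0,0) is the identity; double application is refused
  reg0 <- register_translation(ref, ref, upsample = 1)
  same <- apply_registration(rna, reg0, pixel_xy_um = cfg$pixel_xy_um)
  expect_equal(same$x_um, rna$x_um)
  expect_error(apply_registration(fixed, reg), "already registered")
})

test_that("spots are assigned to the nucleus under their centroid", {
  labels <- matrix(0L, 32, 32)
  labels[5:15, 5:15] <- 3L
  sp <- make_spots(NA_integer_, "dna5",
                   xs = c(10, 25, 40) * 0.152, ys = c(10, 25, 10) * 0.152)
  out <- assign_spots_to_nuclei(sp, labels)
  expect_equal(out$cell_id, c(3L, NA_integer_, NA_integer_))
})

test_that("full-field detection matches ground truth with high fidelity", {
  # end-to-end: render, segment, detect, assign; recall/precision vs truth
  n_match <- 0; n_truth <- 0; n_det <- 0; sq_err <- c()
  assigned_ok <- 0; assigned_tot <- 0
  for (f in 1:3) {
    cfg <- simulation_config(n_cells = 10, seed = 200 + f,
                             field_size_px = c(256, 256))
    tr <- simulate_ground_truth(cfg)
    st <- render_stack(tr)
    seg <- segment_nuclei(max_project(st, "dapi"))
    for (ch in c("dna5", "dna3")) {
      det <- detect_spots(st, ch, sigma_px = 1.3, min_snr = 8)
      det <- assign_spots_to_nuclei(det, seg$labels)
      tx <- if (ch == "dna5") tr$alleles$x5_um else tr$alleles$x3_um
      ty <- if (ch == "dna5") tr$alleles$y5_um else tr$alleles$y3_um
      n_truth <- n_truth + length(tx); n_det <- n_det + nrow(det)
      used <- rep(FALSE, nrow(det))
      for (i in seq_along(tx)) {
        dd <- sqrt((det$x_px - tx[i] / 0.152)^2 + (det$y_px - ty[i] / 0.152)^2)
        dd[used] <- Inf
        j <- which.min(dd)
        if (length(j) && dd[j] <= 2) {
          used[j] <- TRUE; n_match <- n_match + 1
          sq_err <- c(sq_err, dd[j]^2)
          # assignment fidelity: detected cell label covers the true position
          true_lab <- seg$labels[ceiling(ty[i] / 0.152), ceiling(tx[i] / 0.152)]
          if (true_lab > 0) {
            assigned_tot <- assigned_tot + 1
            if (!is.na(det$cell_id[j]) && det$cell_id[j] == true_lab) {
              assigned_ok <- assigned_ok + 1
            }
          }
        }
      }
    }
  }
  expect_gte(n_match / n_truth, 0.95)   # recall
  expect_gte(n_match / n_det, 0.95)     # precision
  expect_lte(sqrt(mean(sq_err)), 0.5)   # centroid RMSE
  expect_gte(assigned_ok / assigned_tot, 0.99)
})
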