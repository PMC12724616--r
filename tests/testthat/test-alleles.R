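test_that("QC rule follows the ploidy-specific inclusion criteria", {
  cells <- tibble::tribble(
    ~cell_id, ~n_dna5, ~n_dna3, ~n_rna,
    1L, 2L, 2L, 1L,   # diploid pass
    2L, 3L, 2L, 0L,   # dna5 excess
    3L, 2L, 1L, 0L,   # dna3 deficit
    4L, 2L, 2L, 3L    # rna excess (diploid)
  )
  dip <- qc_filter_cells(cells, "diploid")
  expect_equal(dip$qc_pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(dip$qc_reason, c("pass", "dna5_count", "dna3_count", "rna_count"))

  tri <- tibble::tribble(
    ~cell_id, ~n_dna5, ~n_dna3, ~n_rna,
    1L, 3L, 2L, 3L,   # pass: 2 or 3 DNA signals, <= 3 RNA
    2L, 2L, 3L, 0L,   # pass
    3L, 4L, 3L, 0L,   # dna5 out of range
    4L, 3L, 3L, 4L    # rna excess
  ) |> qc_filter_cells("triploid")
  expect_equal(tri$qc_pass, c(TRUE, TRUE, FALSE, FALSE))
  # numeric ploidy is accepted too
  expect_equal(qc_filter_cells(cells, 2)$qc_pass, dip$qc_pass)
})

test_that("closest-neighbor pairing matches the exhaustive assignment", {
  # hand case: one pair at unit distance
  sp <- dplyr::bind_rows(
    make_spots(1L, "dna5", xs = 0, ys = 0),
    make_spots(1L, "dna3", xs = 1, ys = 0, id0 = 10L)
  )
  al <- boundary_distance(pair_boundaries(sp))
  expect_equal(nrow(al), 1)
  expect_equal(al$distance_2d_um, 1)

  # two well-separated alleles
  sp2 <- dplyr::bind_rows(
    make_spots(1L, "dna5", xs = c(0, 10), ys = c(0, 0)),
    make_spots(1L, "dna3", xs = c(0.4, 9.5), ys = c(0, 0), id0 = 10L)
  )
  al2 <- pair_boundaries(sp2)
  expect_equal(al2$spot5_id, c(1L, 2L))
  expect_equal(al2$spot3_id, c(11L, 12L))
  oracle <- brute_force_pairing(cbind(c(0, 10), c(0, 0)),
                                cbind(c(0.4, 9.5), c(0, 0)))
  expect_equal(unname(al2$spot3_id - 10L), unname(oracle[, "i3"]))

  # cardinality: 2 vs 3 spots -> 2 pairs
  sp3 <- dplyr::bind_rows(
    make_spots(1L, "dna5", xs = c(0, 5), ys = c(0, 0)),
    make_spots(1L, "dna3", xs = c(0.3, 5.2, 9), ys = c(0, 0, 0), id0 = 10L)
  )
  expect_equal(nrow(pair_boundaries(sp3)), 2)

  # empty side: empty result, not an error
  sp4 <- make_spots(1L, "dna5", xs = c(0, 1), ys = c(0, 0))
  expect_equal(nrow(suppressMessages(pair_boundaries(sp4))), 0)
})

test_that("greedy pairing equals minimum-total-distance assignment on separated alleles", {
  set.seed(99)
  greedy_total_of <- function(p5, p3) {
    sp <- dplyr::bind_rows(
      make_spots(1L, "dna5", xs = p5[, 1], ys = p5[, 2]),
      make_spots(1L, "dna3", xs = p3[, 1], ys = p3[, 2], id0 = 10L)
    )
    sum(boundary_distance(pair_boundaries(sp))$distance_2d_um)
  }
  oracle_total_of <- function(p5, p3) {
    oracle <- brute_force_pairing(p5, p3)
    sum(sqrt(rowSums(
      (p5[oracle[, "i5"], , drop = FALSE] - p3[oracle[, "i3"], , drop = FALSE])^2
    )))
  }
  # well-separated alleles (inter-allele >> intra-allele): exact agreement
  n_agree <- 0; n_cells <- 100
  for (i in seq_len(n_cells)) {
    centers <- matrix(c(runif(2, 0, 2), runif(2, 6, 8)), ncol = 2, byrow = TRUE)
    p5 <- centers + matrix(rnorm(4, 0, 0.35), ncol = 2)
    p3 <- centers + matrix(rnorm(4, 0, 0.35), ncol = 2)
    if (abs(greedy_total_of(p5, p3) - oracle_total_of(p5, p3)) < 1e-9) {
      n_agree <- n_agree + 1
    }
  }
  expect_gte(n_agree / n_cells, 0.99)
  # unconstrained clouds: greedy total never beats the optimum (sanity)
  for (i in 1:30) {
    p5 <- matrix(runif(6, 0, 6), ncol = 2)
    p3 <- matrix(runif(6, 0, 6), ncol = 2)
    expect_gte(greedy_total_of(p5, p3), oracle_total_of(p5, p3) - 1e-9)
  }
})

test_that("center-to-center distances follow the pixel calibration", {
  mk <- function(dx_px, dy_px, dz_planes) {
    dplyr::bind_rows(
      make_spots(1L, "dna5", xs = 0, ys = 0, zs = 0),
      make_spots(1L, "dna3", xs = dx_px * 0.152, ys = dy_px * 0.152,
                 zs = dz_planes, id0 = 10L)
    ) |> pair_boundaries(mode = "2d") |> boundary_distance()
  }
  # one pixel apart in x: 0.152 um
  expect_equal(mk(1, 0, 0)$distance_2d_um, 0.152)
  # identical centroids: zero
  expect_equal(mk(0, 0, 0)$distance_2d_um, 0)
  # (3,4) px and one z plane: 2D 0.760, 3D sqrt(0.760^2 + 1) ~ 1.256
  al <- mk(3, 4, 1)
  expect_equal(al$distance_2d_um, 5 * 0.152)
  expect_equal(al$distance_3d_um, sqrt(0.76^2 + 1^2), tolerance = 1e-9)
  expect_true(all(al$distance_2d_um <= al$distance_3d_um))
})

test_that("activity calls apply the 1 um rule with closest-wins assignment", {
  mk_allele <- function(cell, x5, x3, id0) {
    dplyr::bind_rows(
      make_spots(cell, "dna5", xs = x5, ys = 0, id0 = id0),
      make_spots(cell, "dna3", xs = x3, ys = 0, id0 = id0 + 1L)
    )
  }
  sp <- dplyr::bind_rows(mk_allele(1L, 0, 0.2, 0L), mk_allele(1L, 5, 5.2, 10L))
  al <- boundary_distance(pair_boundaries(sp))
  expect_equal(nrow(al), 2)

  # RNA 0.5 um from the first 5' spot: that allele active
  rna1 <- make_spots(1L, "rna", xs = -0.5, ys = 0, id0 = 100L)
  out1 <- classify_activity(al, rna1)
  expect_equal(out1$active[order(out1$x5_um)], c(TRUE, FALSE))

  # RNA 1.2 um from every boundary spot: nothing active
  rna2 <- make_spots(1L, "rna", xs = 0, ys = 1.4, id0 = 100L)
  out2 <- classify_activity(al, rna2)
  expect_false(any(out2$active))

  # exactly at the radius: strict inequality keeps it inactive
  rna3 <- make_spots(1L, "rna", xs = -1.0, ys = 0, id0 = 100L)
  expect_false(any(classify_activity(al, rna3)$active))

  # closest-wins: RNA 0.3 um from allele A's 3' and 0.6 um from B's 5'
  spAB <- dplyr::bind_rows(mk_allele(1L, 0, 0.4, 0L), mk_allele(1L, 1.3, 1.7, 10L))
  alAB <- boundary_distance(pair_boundaries(spAB))
  rnaAB <- make_spots(1L, "rna", xs = 0.7, ys = 0, id0 = 100L)
  outAB <- classify_activity(alAB, rnaAB)
  expect_equal(outAB$active[order(outAB$x5_um)], c(TRUE, FALSE))
  expect_equal(outAB$rna_boundary_distance_um[outAB$active], 0.3)

  # each RNA to one allele, each allele to one RNA; surplus unassigned
  rna_many <- make_spots(1L, "rna", xs = c(0.1, 0.15, 5.1), ys = 0, id0 = 100L)
  out_many <- classify_activity(al, rna_many)
  expect_equal(sum(out_many$active), 2)
  # unregistered RNA is rejected
  rna_unreg <- make_spots(1L, "rna", xs = 0.1, ys = 0, id0 = 100L,
                          registered = FALSE)
  expect_error(classify_activity(al, rna_unreg), "registered")
})

test_that("interaction fraction uses a strict threshold and is monotone", {
  got <- interaction_fraction(c(0.10, 0.20, 0.30, 0.50), 0.25)
  expect_equal(got$fraction, 0.5)
  expect_equal(got$n_below, 2L)
  expect_equal(interaction_fraction(rep(0, 5))$fraction, 1)
  # boundary value excluded under the strict convention
  expect_equal(interaction_fraction(c(0.250, 0.10), 0.250)$fraction, 0.5)
  expect_error(interaction_fraction(numeric(0)), "at least one")
  # monotone non-decreasing in the threshold
  set.seed(12)
  d <- runif(200, 0, 1)
  fr <- vapply(seq(0.05, 0.95, by = 0.05),
               function(t) interaction_fraction(d, t)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("expression states bin per-cell transcription-site counts", {
  cells <- tibble::tibble(cell_id = 1:4, n_active = c(0L, 0L, 1L, 2L))
  fr <- expression_state_fractions(cells)
  expect_equal(fr$fraction, c(0.5, 0.25, 0.25, 0))
  expect_equal(sum(fr$fraction), 1)
  all0 <- expression_state_fractions(tibble::tibble(n_active = rep(0L, 7)))
  expect_equal(all0$fraction, c(1, 0, 0, 0))
  many <- expression_state_fractions(tibble::tibble(n_active = c(3L, 5L, 1L)))
  expect_equal(many$fraction[4], 2 / 3)
  expect_error(expression_state_fractions(tibble::tibble(n_active = integer(0))),
               "at least one")
})
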