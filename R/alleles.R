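#' Per-cell FISH signal counts
#'
#' Summarises a spot table into per-cell counts of 5' boundary, 3' boundary
#' and nascent-RNA signals. Unassigned spots (`cell_id` NA) are ignored.
#'
#' @param spots spot tibble with `channel` in `c("dna5","dna3","rna")`.
#' @return Tibble: `cell_id`, `n_dna5`, `n_dna3`, `n_rna`.
#' @export
count_cell_spots <- function(spots) {
  spots |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::count(.data$cell_id, .data$channel) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "n",
                       values_fill = 0L) |>
    (\(d) {
      for (ch in c("dna5", "dna3", "rna")) if (!ch %in% names(d)) d[[ch]] <- 0L
      d
    })() |>
    dplyr::transmute(cell_id = .data$cell_id,
                     n_dna5 = .data$dna5, n_dna3 = .data$dna3,
                     n_rna = .data$rna) |>
    dplyr::arrange(.data$cell_id)
}

#' Ploidy-aware quality-control filter
#'
#' Applies the cell-inclusion rule used for allele analysis: diploid cells
#' pass with exactly two 5' and two 3' DNA signals and at most two RNA
#' signals; triploid cells pass with two or three signals in each DNA
#' channel and at most three RNA signals. Failing cells get a reason code
#' naming the first violated count.
#'
#' @param cells tibble from [count_cell_spots()].
#' @param ploidy_class `"diploid"` or `"triploid"` (or 2/3).
#' @return `cells` with `ploidy_class`, `qc_pass` and `qc_reason` columns.
#' @export
qc_filter_cells <- function(cells, ploidy_class = c("diploid", "triploid")) {
  if (is.numeric(ploidy_class)) {
    ploidy_class <- c("2" = "diploid", "3" = "triploid")[as.character(ploidy_class)]
  }
  ploidy_class <- match.arg(ploidy_class)
  ok_dna <- if (ploidy_class == "diploid") function(n) n == 2L else function(n) n %in% c(2L, 3L)
  max_rna <- if (ploidy_class == "diploid") 2L else 3L
  cells |>
    dplyr::mutate(
      ploidy_class = ploidy_class,
      qc_reason = dplyr::case_when(
        !ok_dna(.data$n_dna5) ~ "dna5_count",
        !ok_dna(.data$n_dna3) ~ "dna3_count",
        .data$n_rna > max_rna ~ "rna_count",
        TRUE ~ "pass"
      ),
      qc_pass = .data$qc_reason == "pass"
    )
}

greedy_pair <- function(p5, p3) {
  # globally-closest greedy matching; ties by (index5, index3) ascending
  n5 <- nrow(p5); n3 <- nrow(p3)
  d <- outer(seq_len(n5), seq_len(n3), function(i, j) {
    sqrt(rowSums((p5[i, , drop = FALSE] - p3[j, , drop = FALSE])^2))
  })
  pairs <- list()
  free5 <- rep(TRUE, n5); free3 <- rep(TRUE, n3)
  for (k in seq_len(min(n5, n3))) {
    dd <- d
    dd[!free5, ] <- Inf; dd[, !free3] <- Inf
    best <- which(dd == min(dd), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    pairs[[k]] <- c(i5 = unname(best[1]), i3 = unname(best[2]),
                    dist = d[best[1], best[2]])
    free5[best[1]] <- FALSE; free3[best[2]] <- FALSE
  }
  do.call(rbind, pairs)
}

#' Pair 5' and 3' TAD boundary signals into alleles
#'
#' Within each QC-passing cell, matches 5' and 3' boundary spots as closest
#' neighbors: the globally closest unmatched (5', 3') pair is selected
#' repeatedly until one channel is exhausted; remaining spots are dropped
#' (and counted in the QC report). For the well-separated alleles that QC
#' enforces this equals the minimum-total-distance bipartite assignment.
#' Matching uses 2D (projected) physical coordinates by default.
#'
#' @param spots spot tibble with assigned `cell_id`s (registered RNA is not
#'   used here).
#' @param mode `"2d"` (match on x/y um) or `"3d"` (include z).
#' @return Allele tibble: `cell_id`, `allele_id`, spot ids and coordinates
#'   of both boundary partners.
#' @export
pair_boundaries <- function(spots, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  cols <- if (mode == "2d") c("x_um", "y_um") else c("x_um", "y_um", "z_um")
  spots <- dplyr::filter(spots, !is.na(.data$cell_id),
                         .data$channel %in% c("dna5", "dna3"))
  empty <- tibble(
    cell_id = integer(), allele_id = integer(),
    spot5_id = integer(), spot3_id = integer(),
    x5_um = numeric(), y5_um = numeric(), z5_um = numeric(),
    x3_um = numeric(), y3_um = numeric(), z3_um = numeric()
  )
  if (nrow(spots) == 0L) {
    inform("No assigned boundary spots; empty allele table.")
    return(empty)
  }
  is5 <- spots$channel == "dna5"
  coords <- as.matrix(spots[, cols])
  idx5 <- split(which(is5), spots$cell_id[is5])
  idx3 <- split(which(!is5), spots$cell_id[!is5])
  cell_ids <- intersect(names(idx5), names(idx3))
  if (length(cell_ids) == 0L) {
    inform("No cell with both 5' and 3' signals; empty allele table.")
    return(empty)
  }
  out <- vector("list", length(cell_ids))
  for (k in seq_along(cell_ids)) {
    i5 <- idx5[[cell_ids[k]]]
    i3 <- idx3[[cell_ids[k]]]
    m <- greedy_pair(coords[i5, , drop = FALSE], coords[i3, , drop = FALSE])
    out[[k]] <- cbind(cell = as.integer(cell_ids[k]),
                      allele = seq_len(nrow(m)),
                      s5 = i5[m[, "i5"]], s3 = i3[m[, "i3"]])
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, "cell"], m[, "allele"]), , drop = FALSE]
  tibble(
    cell_id = m[, "cell"],
    allele_id = m[, "allele"],
    spot5_id = spots$spot_id[m[, "s5"]],
    spot3_id = spots$spot_id[m[, "s3"]],
    x5_um = spots$x_um[m[, "s5"]], y5_um = spots$y_um[m[, "s5"]],
    z5_um = spots$z_um[m[, "s5"]],
    x3_um = spots$x_um[m[, "s3"]], y3_um = spots$y_um[m[, "s3"]],
    z3_um = spots$z_um[m[, "s3"]]
  )
}

#' Center-to-center boundary distances
#'
#' Adds the physical 5'-3' distance to an allele table: `distance_2d_um`
#' from the projected (x, y) centroids and, when z is available,
#' `distance_3d_um` including the axial component. By construction the 2D
#' distance never exceeds the 3D one.
#'
#' @param alleles allele tibble from [pair_boundaries()].
#' @return `alleles` with `distance_2d_um` (and `distance_3d_um`) columns.
#' @export
boundary_distance <- function(alleles) {
  alleles |>
    dplyr::mutate(
      distance_2d_um = sqrt((.data$x3_um - .data$x5_um)^2 +
                            (.data$y3_um - .data$y5_um)^2),
      distance_3d_um = sqrt(.data$distance_2d_um^2 +
                            (.data$z3_um - .data$z5_um)^2)
    )
}

#' Classify allele transcriptional activity
#'
#' An allele is active when a nascent-RNA signal lies within `radius_um`
#' (strictly) of either of its boundary spots. RNA spots are assigned
#' greedily by increasing RNA-to-allele distance (the distance to the
#' nearer of the two boundary spots), each RNA to at most one allele and
#' each allele to at most one RNA; surplus RNA spots stay unassigned.
#' RNA coordinates must already be registered to the DNA frame.
#'
#' @param alleles allele tibble (one cell may hold several alleles).
#' @param rna_spots spot tibble, `channel == "rna"`, registered.
#' @param radius_um activity radius; default 1.0 um.
#' @param mode `"2d"` or `"3d"` distance for the RNA-boundary measurement.
#' @return `alleles` with `active`, `rna_spot_id`, `rna_boundary_distance_um`.
#' @export
classify_activity <- function(alleles, rna_spots, radius_um = 1.0,
                              mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  if (nrow(rna_spots) && !all(rna_spots$registered)) {
    abort("RNA spots must be registered to the DNA frame before activity calls.")
  }
  dist_fun <- function(ax, ay, az, bx, by, bz) {
    d2 <- (ax - bx)^2 + (ay - by)^2
    if (mode == "3d") d2 <- d2 + (az - bz)^2
    sqrt(d2)
  }
  alleles$active <- FALSE
  alleles$rna_spot_id <- NA_integer_
  alleles$rna_boundary_distance_um <- NA_real_
  if (nrow(alleles) == 0L) return(alleles)
  rna_spots <- dplyr::filter(rna_spots, .data$channel == "rna",
                             !is.na(.data$cell_id))
  for (cid in unique(alleles$cell_id)) {
    ai <- which(alleles$cell_id == cid)
    ri <- which(rna_spots$cell_id == cid)
    if (!length(ri)) next
    cand <- tidyr::expand_grid(a = ai, r = ri)
    cand$d <- purrr::map2_dbl(cand$a, cand$r, function(a, r) {
      min(
        dist_fun(alleles$x5_um[a], alleles$y5_um[a], alleles$z5_um[a],
                 rna_spots$x_um[r], rna_spots$y_um[r], rna_spots$z_um[r]),
        dist_fun(alleles$x3_um[a], alleles$y3_um[a], alleles$z3_um[a],
                 rna_spots$x_um[r], rna_spots$y_um[r], rna_spots$z_um[r])
      )
    })
    cand <- cand[cand$d < radius_um, , drop = FALSE]
    cand <- cand[order(cand$d, cand$a, cand$r), , drop = FALSE]
    used_a <- integer(0); used_r <- integer(0)
    for (k in seq_len(nrow(cand))) {
      a <- cand$a[k]; r <- cand$r[k]
      if (a %in% used_a || r %in% used_r) next
      alleles$active[a] <- TRUE
      alleles$rna_spot_id[a] <- rna_spots$spot_id[r]
      alleles$rna_boundary_distance_um[a] <- cand$d[k]
      used_a <- c(used_a, a); used_r <- c(used_r, r)
    }
  }
  alleles
}

#' Boundary interaction fraction
#'
#' Fraction of alleles whose 5'-3' boundary distance falls strictly below a
#' proximity threshold (default 250 nm, the conventional cutoff for a
#' chromatin interaction).
#'
#' @param distances numeric vector of boundary distances (um).
#' @param threshold_um proximity threshold in um.
#' @return Tibble: `n_below`, `n`, `fraction`.
#' @export
interaction_fraction <- function(distances, threshold_um = 0.250) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) abort("`distances` must contain at least one value.")
  n_below <- sum(distances < threshold_um)
  tibble(n_below = n_below, n = length(distances),
         fraction = n_below / length(distances))
}

#' Allelic expression-state fractions
#'
#' Bins the per-cell number of active transcription sites into silent (0),
#' monoallelic (1), biallelic (2) and triallelic-or-more (>=3) states and
#' returns the fraction of cells in each state.
#'
#' @param cells tibble with one row per QC-passing cell.
#' @param n_col name of the column holding the per-cell count of assigned
#'   RNA sites (default `"n_active"`).
#' @return Tibble with `state` (`"0"`, `"1"`, `"2"`, `">=3"`), `n_cells`,
#'   `fraction` (summing to 1).
#' @export
expression_state_fractions <- function(cells, n_col = "n_active") {
  if (nrow(cells) == 0L) abort("`cells` must contain at least one cell.")
  counts <- cells[[n_col]]
  state <- cut(counts, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
               labels = c("0", "1", "2", ">=3"))
  tab <- table(state)
  tibble(
    state = names(tab),
    n_cells = as.integer(tab),
    fraction = as.numeric(tab) / nrow(cells)
  )
}
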