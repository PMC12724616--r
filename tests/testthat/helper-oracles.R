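# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# CDF of the 3D distance |N(0, s^2 I_3)| = s * chi_3
chi3_cdf <- function(d, scale) pchisq((d / scale)^2, df = 3)

mixture_below <- function(threshold, p_pair, paired_scale, unpaired_scale) {
  p_pair * chi3_cdf(threshold, paired_scale) +
    (1 - p_pair) * chi3_cdf(threshold, unpaired_scale)
}

mixture_median <- function(p_pair, paired_scale, unpaired_scale) {
  uniroot(function(d) mixture_below(d, p_pair, paired_scale, unpaired_scale) - 0.5,
          c(1e-6, 10))$root
}

# exhaustive minimum-total-distance bipartite assignment (small sides only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
    }
  }
  out
}

brute_force_pairing <- function(p5, p3) {
  n5 <- nrow(p5); n3 <- nrow(p3)
  k <- min(n5, n3)
  d <- as.matrix(stats::dist(rbind(p5, p3)))[seq_len(n5), n5 + seq_len(n3),
                                             drop = FALSE]
  best <- NULL; best_total <- Inf
  idx5 <- utils::combn(n5, k, simplify = FALSE)
  idx3 <- utils::combn(n3, k, simplify = FALSE)
  for (s5 in idx5) for (s3 in idx3) for (p in all_perms(k)) {
    tot <- sum(d[cbind(s5, s3[p])])
    if (tot < best_total - 1e-12) {
      best_total <- tot
      best <- cbind(i5 = s5, i3 = s3[p])
    }
  }
  best[order(best[, "i5"]), , drop = FALSE]
}

# exhaustive two-sided Mann-Whitney p over all group labelings
mw_exhaustive_p <- function(a, b) {
  comb <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- na * length(b) / 2
  sets <- utils::combn(length(comb), na, simplify = FALSE)
  us <- vapply(sets, function(s) u_of(comb[s], comb[-s]), numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# brute-force two-sample KS D by scanning the pooled step points
ks_d_scan <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# simulate a large population as a series of fields; returns combined
# ground-truth alleles (cell_ids offset to stay unique)
simulate_many <- function(n_cells, seed = 1, cells_per_field = 50,
                          field_size_px = c(512, 512), ...) {
  n_fields <- ceiling(n_cells / cells_per_field)
  out <- vector("list", n_fields)
  offset <- 0L
  remaining <- n_cells
  for (f in seq_len(n_fields)) {
    n_here <- min(cells_per_field, remaining)
    remaining <- remaining - n_here
    cfg <- simulation_config(n_cells = n_here, seed = seed + f,
                             field_size_px = field_size_px, ...)
    tr <- simulate_ground_truth(cfg)
    tr$alleles$cell_id <- tr$alleles$cell_id + offset
    offset <- offset + n_here
    out[[f]] <- tr$alleles
  }
  dplyr::bind_rows(out)
}

# spot table for one synthetic cell laid out by hand
make_spots <- function(cell_id, ch, xs, ys, zs = rep(0, length(xs)),
                       id0 = 0L, registered = TRUE) {
  tibble::tibble(
    spot_id = id0 + seq_along(xs), channel = ch, cell_id = cell_id,
    x_px = xs / 0.152, y_px = ys / 0.152, z_px = zs,
    x_um = xs, y_um = ys, z_um = zs,
    intensity = 100, quality = 10, registered = registered
  )
}
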