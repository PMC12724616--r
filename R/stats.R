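new_fish_test <- function(test, statistic_name, statistic, p_value, group_ns,
                          scheme = "methods", extra = list()) {
  structure(
    c(list(
      test = test, statistic_name = statistic_name, statistic = statistic,
      p_value = p_value, category = categorize_p(p_value, scheme),
      group_ns = group_ns
    ), extra),
    class = "fish_test"
  )
}

#' @export
print.fish_test <- function(x, ...) {
  cat(sprintf("<%s> %s = %.4g, p = %.3g (%s), n = %s\n",
              x$test, x$statistic_name, x$statistic, x$p_value, x$category,
              paste(x$group_ns, collapse = "/")))
  invisible(x)
}

#' @rdname tidy.fish_test
#' @export
#' @exportS3Method generics::glance
glance.fish_test <- function(x, ...) tidy(x)

#' Tidy a hypothesis-test result
#'
#' One-row tibble with the test name, statistic, p-value, significance
#' category and group sizes — the broom-style accessor for every test
#' returned by the statistics layer.
#'
#' @param x a `fish_test` object.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.fish_test <- function(x, ...) {
  tibble(
    test = x$test, statistic_name = x$statistic_name,
    statistic = x$statistic, p_value = x$p_value, category = x$category,
    n1 = x$group_ns[1],
    n2 = if (length(x$group_ns) > 1) x$group_ns[2] else NA_integer_
  )
}

#' Summarise a boundary-distance distribution
#'
#' Median and interquartile range (Q3 - Q1, linear-interpolation quantiles)
#' plus the interaction fraction at the stated threshold — the "median +/-
#' IQR" summary used for single-experiment distance distributions.
#'
#' @param distances numeric vector of distances (um), n >= 1.
#' @param threshold_um interaction threshold (um).
#' @return Tibble: `n`, `median_um`, `q1_um`, `q3_um`, `iqr_um`,
#'   `interaction_fraction`.
#' @export
summarize_distances <- function(distances, threshold_um = 0.250) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) abort("`distances` must contain at least one value.")
  q <- quantile(distances, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    n = length(distances), median_um = q[2], q1_um = q[1], q3_um = q[3],
    iqr_um = q[3] - q[1],
    interaction_fraction = interaction_fraction(distances, threshold_um)$fraction
  )
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two distance distributions. The exact null
#' distribution is used when there are no ties and `n_a * n_b` does not
#' exceed `exact_max`; otherwise the tie-corrected normal approximation
#' with continuity correction. The statistic U counts (a, b) pairs with
#' a > b.
#'
#' @param a,b numeric vectors, each n >= 1.
#' @param exact_max largest `n_a * n_b` for which the exact distribution is
#'   used (no ties).
#' @param scheme significance-category scheme, see [categorize_p()].
#' @return A `fish_test` (see [tidy.fish_test()]).
#' @export
mann_whitney <- function(a, b, exact_max = 400, scheme = "methods") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && length(a) * length(b) <= exact_max
  res <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  new_fish_test("mann_whitney", "U", unname(res$statistic), res$p.value,
                c(length(a), length(b)), scheme,
                extra = list(exact = use_exact))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two empirical distance distributions via the maximum ECDF
#' difference D with the asymptotic p-value.
#'
#' @inheritParams mann_whitney
#' @return A `fish_test`.
#' @export
ks_test <- function(a, b, scheme = "methods") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  new_fish_test("ks", "D", unname(res$statistic), res$p.value,
                c(length(a), length(b)), scheme)
}

#' Kruskal-Wallis test with Dunn-Bonferroni post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H over all groups, followed by pairwise
#' Dunn z tests on mean ranks with Bonferroni adjustment (raw p multiplied
#' by the number of pairwise comparisons, capped at 1).
#'
#' @param data data frame with one observation per row.
#' @param value,group column names (strings) of the measurement and the
#'   grouping factor.
#' @param scheme significance-category scheme.
#' @return List with `kruskal` (a `fish_test`) and `pairwise` (tibble:
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`, `category`).
#' @export
kruskal_dunn <- function(data, value, group, scheme = "methods") {
  x <- data[[value]]; g <- factor(data[[group]])
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) abort("Need at least two groups.")
  if (any(table(g) == 0L)) abort("Every group must be non-empty.")
  kw <- kruskal.test(x, g)
  kw_res <- new_fish_test("kruskal_wallis", "H", unname(kw$statistic),
                          kw$p.value, as.integer(table(g)), scheme)

  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  pw <- purrr::map(seq_len(m), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- if (se > 0) (mean_ranks[[g1]] - mean_ranks[[g2]]) / se else 0
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = g1, group2 = g2, z = z, p_value = p,
           p_adjusted = min(1, p * m))
  }) |> dplyr::bind_rows() |>
    dplyr::mutate(category = categorize_p(.data$p_adjusted, scheme))
  list(kruskal = kw_res, pairwise = pw)
}

#' Two-way ANOVA on per-experiment medians
#'
#' Compares experiment-level median distances across a condition-by-locus
#' design: each replicate experiment contributes one median per cell of the
#' design, a fixed-effects two-way ANOVA is fitted, and the condition
#' contrast within each locus is tested with Bonferroni adjustment across
#' loci. Mirrors the "mean of medians" aggregation used for multi-experiment
#' dot plots.
#'
#' @param data data frame with one row per experiment: a median column plus
#'   two factor columns.
#' @param value,condition,locus column names (strings).
#' @param scheme significance-category scheme.
#' @return List with `anova` (tidy ANOVA table), `contrasts` (tibble of
#'   per-locus condition contrasts with adjusted p and category) and
#'   `means` (per-cell mean of medians, sd, sem, n).
#' @export
compare_experiment_means <- function(data, value = "median_um",
                                     condition = "condition", locus = "locus",
                                     scheme = "methods") {
  d <- tibble(
    y = data[[value]],
    condition = factor(data[[condition]]),
    locus = factor(data[[locus]])
  )
  cell_n <- dplyr::count(d, .data$condition, .data$locus)
  if (any(cell_n$n < 2L)) {
    abort(paste0(
      "Each condition x locus cell needs >= 2 experiments for the ",
      "mean-of-medians ANOVA; use a distribution-level test (mann_whitney) instead."
    ))
  }
  multi_locus <- nlevels(d$locus) > 1L
  if (diff(range(d$y)) == 0) {
    # no variation at all: every contrast is null by construction
    means <- d |>
      dplyr::group_by(.data$condition, .data$locus) |>
      dplyr::summarise(n_experiments = dplyr::n(),
                       mean_of_medians_um = mean(.data$y),
                       sd_um = 0, sem_um = 0, .groups = "drop")
    ctr <- tidyr::expand_grid(locus = levels(d$locus)) |>
      dplyr::mutate(contrast = paste(levels(d$condition)[1], "-",
                                     levels(d$condition)[2]),
                    estimate = 0, p_value = 1,
                    category = categorize_p(1, scheme))
    an_tbl <- tibble(term = c("condition", "locus"), df = NA_integer_,
                     sumsq = 0, statistic = 0, p_value = 1)
    return(list(anova = an_tbl, contrasts = ctr, means = means))
  }
  fml <- if (multi_locus) y ~ condition * locus else y ~ condition
  fit <- aov(fml, data = d)
  an <- as.data.frame(summary(fit)[[1]])
  an_tbl <- tibble(
    term = trimws(rownames(an)), df = an$Df, sumsq = an$`Sum Sq`,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  emm <- emmeans::emmeans(fit, if (multi_locus) ~ condition | locus else ~ condition)
  ctr <- summary(emmeans::contrast(emm, method = "pairwise",
                                   adjust = "bonferroni"))
  ctr_tbl <- as_tibble(ctr) |>
    dplyr::rename(p_value = "p.value") |>
    dplyr::mutate(
      p_value = pmin(1, .data$p_value * if (multi_locus) nlevels(d$locus) else 1),
      category = categorize_p(.data$p_value, scheme)
    )
  means <- d |>
    dplyr::group_by(.data$condition, .data$locus) |>
    dplyr::summarise(
      n_experiments = dplyr::n(),
      mean_of_medians_um = mean(.data$y),
      sd_um = sd(.data$y),
      sem_um = sd(.data$y) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  list(anova = an_tbl, contrasts = ctr_tbl, means = means)
}

#' Within-nucleus allele-distance correlation
#'
#' Tests whether the boundary distances of the two alleles of the same
#' nucleus covary. Because allele identity within a nucleus is arbitrary,
#' the pair order is randomized per nucleus under the given seed; Pearson r
#' and Spearman rho are both reported.
#'
#' @param alleles allele tibble with `cell_id` and a distance column; only
#'   nuclei with exactly two alleles are used.
#' @param value distance column name.
#' @param seed seed for the per-nucleus order randomization.
#' @param scheme significance-category scheme.
#' @return Tibble with one row per method (`pearson`, `spearman`):
#'   `estimate`, `p_value`, `category`, `n_pairs`.
#' @export
allele_pair_correlation <- function(alleles, value = "distance_2d_um",
                                    seed = 1L, scheme = "methods") {
  pairs <- alleles |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::filter(dplyr::n() == 2L) |>
    dplyr::summarise(d1 = .data[[value]][1], d2 = .data[[value]][2],
                     .groups = "drop")
  if (nrow(pairs) < 3L) abort("Need at least 3 two-allele nuclei.")
  set.seed(seed)
  flip <- runif(nrow(pairs)) < 0.5
  tmp <- pairs$d1[flip]
  pairs$d1[flip] <- pairs$d2[flip]
  pairs$d2[flip] <- tmp
  purrr::map(c("pearson", "spearman"), function(m) {
    ct <- suppressWarnings(cor.test(pairs$d1, pairs$d2, method = m))
    tibble(method = m, estimate = unname(ct$estimate), p_value = ct$p.value,
           category = categorize_p(ct$p.value, scheme), n_pairs = nrow(pairs))
  }) |> dplyr::bind_rows()
}

#' Significance categories for p-values
#'
#' Maps p-values to star categories. The default `"methods"` scheme is
#' `*** p < 0.001`, `** p < 0.01`, `* p < 0.05`, `ns p >= 0.05`. The
#' `"fig2"` scheme used for very large allele samples is
#' `*** p < 1e-100`, `** 1e-100 <= p < 1e-20`, `* 1e-20 <= p < 0.01`,
#' `ns` otherwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param scheme `"methods"` (default) or `"fig2"`.
#' @return Character vector of labels.
#' @export
categorize_p <- function(p, scheme = c("methods", "fig2")) {
  scheme <- match.arg(scheme)
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  if (scheme == "methods") {
    dplyr::case_when(
      p < 0.001 ~ "***",
      p < 0.01 ~ "**",
      p < 0.05 ~ "*",
      TRUE ~ "ns"
    )
  } else {
    dplyr::case_when(
      p < 1e-100 ~ "***",
      p < 1e-20 ~ "**",
      p < 0.01 ~ "*",
      TRUE ~ "ns"
    )
  }
}
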