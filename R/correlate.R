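#' 2-D conductance histogram of a population
#'
#' Counts the members of a population on the grid of one conductance pair;
#' the remaining conductances are marginalised (each model contributes one
#' count at its (level, level) cell regardless of its other conductances).
#'
#' @param pop A record tibble with `lvl_<conductance>` columns.
#' @param pair Character vector of two distinct conductance names.
#' @param grid The `conductance_grid`.
#' @return A `cond_hist2d`: an integer matrix (rows = levels of `pair[1]`,
#'   columns = levels of `pair[2]`, in grid level order) with attributes
#'   `pair`, `n` and `population`.
#' @export
#' @examples
#' db <- make_planted_db(1000, seed = 2)
#' h <- histogram2d(db, c("CaS", "KCa"))
#' sum(h) == nrow(db)
histogram2d <- function(pop, pair, grid = db_grid(pop) %||% conductance_grid()) {
  stopifnot(length(pair) == 2, pair[1] != pair[2])
  for (nm in pair) {
    if (!nm %in% grid$conductances) {
      abort(paste0("unknown conductance '", nm, "'"))
    }
  }
  la <- length(grid$levels[[pair[1]]])
  lb <- length(grid$levels[[pair[2]]])
  a <- factor(pop[[paste0("lvl_", pair[1])]], levels = seq_len(la))
  b <- factor(pop[[paste0("lvl_", pair[2])]], levels = seq_len(lb))
  counts <- unclass(table(a, b))
  dimnames(counts) <- list(
    signif(grid$levels[[pair[1]]], 6),
    signif(grid$levels[[pair[2]]], 6)
  )
  structure(counts, pair = pair, n = nrow(pop),
            population = attr(pop, "population_label"),
            class = c("cond_hist2d", "matrix", "array"))
}

#' Raw chi-squared statistic of independence
#'
#' \eqn{\chi^2 = \sum_{ij} (O_{ij} - E_{ij})^2 / E_{ij}} with expected
#' counts from the product of marginals, \eqn{E_{ij} = r_i c_j / N}. Cells
#' whose row or column marginal is zero are dropped from the sum (their
#' expectation is undefined). The raw statistic is used deliberately —
#' no p-value, no scaling by N — so that, at a fixed cutoff, relationships
#' backed by more models pass more easily; this compensates for the sparse
#' sampling of the conductance space.
#'
#' @param counts A `cond_hist2d` or plain non-negative count matrix.
#' @return The statistic (>= 0), or an error for an empty histogram.
#' @export
chi2_independence <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("chi-squared statistic undefined for an empty histogram")
  r <- rowSums(counts)
  cc <- colSums(counts)
  keep_r <- r > 0
  keep_c <- cc > 0
  o <- counts[keep_r, keep_c, drop = FALSE]
  e <- outer(r[keep_r], cc[keep_c]) / n
  sum((o - e)^2 / e)
}

#' Spearman rank correlation of a conductance pair in a population
#'
#' Rank correlation with midranks for ties (ties are pervasive on a
#' 6-level grid). Computed on the grid level indices; since Spearman
#' correlation is invariant under any strictly monotone relabelling, this
#' is identical to computing it on the conductance values themselves.
#'
#' @param pop Record tibble with `lvl_*` columns.
#' @param pair Two conductance names.
#' @return rho in `[-1, 1]`, or `NA` when the population has fewer than
#'   two members or either conductance is constant within it (an
#'   undefined-rho result never counts as a correlation).
#' @export
spearman_rho <- function(pop, pair) {
  x <- pop[[paste0("lvl_", pair[1])]]
  y <- pop[[paste0("lvl_", pair[2])]]
  if (length(x) < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Independence and difference matrices
#'
#' The independence matrix is the 2-D distribution expected if the two
#' conductances varied independently within the population: the outer
#' product of the two normalised 1-D marginal histograms, scaled back to
#' model counts. The difference matrix is the observed minus expected
#' distribution, in percent of the population, per cell — the graphical
#' complement to the chi-squared statistic for judging whether an apparent
#' relationship ("ramp" types in particular) is explained by independent
#' variation.
#'
#' @param counts A `cond_hist2d` or count matrix.
#' @return A list with `expected` (model counts, sums to N) and
#'   `difference` (percent of population, sums to ~0).
#' @export
independence_difference <- function(counts) {
  n <- sum(counts)
  if (n == 0) abort("independence matrix undefined for an empty histogram")
  expected <- outer(rowSums(counts) / n, colSums(counts) / n) * n
  difference <- 100 * (unclass(counts) - expected) / n
  list(expected = expected, difference = difference)
}

#' Edge-concentration flag
#'
#' Statistically passing relationships driven by a majority of models at
#' zero conductance (level-1 row/column mass) tend to be false positives
#' of the linearity criteria. This heuristic flags a histogram when the
#' fraction of models in the first row or first column exceeds the
#' threshold; flagged results are reported for review, never silently
#' excluded.
#'
#' @param counts A `cond_hist2d` or count matrix.
#' @param fraction Flagging threshold on the level-1 mass fraction.
#' @return Logical.
#' @export
flag_edge_concentration <- function(counts, fraction = 0.5) {
  n <- sum(counts)
  if (n == 0) return(FALSE)
  edge <- sum(counts[1, ]) + sum(counts[, 1]) - counts[1, 1]
  edge / n >= fraction
}

#' Screen every conductance pair of a population for linear dependence
#'
#' For each unordered conductance pair: builds the 2-D grid histogram,
#' computes the raw chi-squared independence statistic and the Spearman
#' rank correlation, and flags the pair as a correlation when both
#' criteria hold strictly (`chi2 > chi2_cutoff` and `|rho| > rho_cutoff`).
#' The slope sign of a correlation is the sign of rho. Pairs with
#' undefined rho (constant conductance) never pass. Small populations are
#' screened anyway, with a low-N warning (sparse populations carry little
#' information and the raw-statistic cutoff makes them conservative).
#'
#' @param pop Record tibble (`lvl_*` columns).
#' @param grid The `conductance_grid`.
#' @param chi2_cutoff,rho_cutoff Correlation criteria (defaults 500
#'   and 0.2, strict).
#' @param edge_fraction Threshold for [flag_edge_concentration()].
#' @param low_n_warn Population size below which a warning is emitted.
#' @param population Label recorded in the result.
#' @return A `correlation_scan` tibble, one row per pair, in
#'   lexicographic pair order: `population`, `cond_a`, `cond_b`, `n`,
#'   `chi2`, `rho`, `passes_chi2`, `passes_rho`, `is_correlation`,
#'   `slope_sign` (`"+"`, `"-"`, or `NA`), `flagged_edge`.
#' @export
#' @examples
#' pl <- data.frame(type = "b", cond_a = "CaS", cond_b = "KCa",
#'                  sign = 1, width = 2, adherence = 0.9)
#' db <- make_planted_db(20000, type_weights = c(b = 1), planted = pl, seed = 3)
#' scan <- scan_correlations(db)
#' scan[scan$is_correlation, c("cond_a", "cond_b", "chi2", "rho")]
scan_correlations <- function(pop, grid = db_grid(pop) %||% conductance_grid(),
                              chi2_cutoff = 500, rho_cutoff = 0.2,
                              edge_fraction = 0.5, low_n_warn = 1000,
                              population = NA_character_) {
  if (nrow(pop) == 0) abort("cannot scan an empty population")
  if (nrow(pop) < low_n_warn) {
    warn(paste0("scan_correlations: population ",
                if (!is.na(population)) paste0("'", population, "' "),
                "has only ", nrow(pop), " models (< ", low_n_warn,
                "); statistics are computed but carry little information"))
  }
  pairs <- conductance_pairs(grid)
  res <- purrr::pmap(pairs, function(cond_a, cond_b) {
    pair <- c(cond_a, cond_b)
    h <- histogram2d(pop, pair, grid)
    chi2 <- chi2_independence(h)
    rho <- spearman_rho(pop, pair)
    p_chi <- chi2 > chi2_cutoff
    p_rho <- !is.na(rho) && abs(rho) > rho_cutoff
    tibble(
      population = population, cond_a = cond_a, cond_b = cond_b,
      n = nrow(pop), chi2 = chi2, rho = rho,
      passes_chi2 = p_chi, passes_rho = p_rho,
      is_correlation = p_chi && p_rho,
      slope_sign = dplyr::if_else(p_chi && p_rho,
                                  dplyr::if_else(rho > 0, "+", "-"),
                                  NA_character_),
      flagged_edge = flag_edge_concentration(h, edge_fraction)
    )
  })
  out <- dplyr::bind_rows(res)
  structure(out, class = unique(c("correlation_scan", class(out))),
            cutoffs = c(chi2 = chi2_cutoff, rho = rho_cutoff))
}

#' Scan a set of populations
#'
#' Applies [scan_correlations()] to each population of a
#' [build_populations()] table, skipping empty populations (recorded with
#' zero rows).
#'
#' @param populations Tibble with `population` and `data` columns.
#' @param grid The `conductance_grid`.
#' @param ... Passed to [scan_correlations()].
#' @return A combined `correlation_scan` tibble.
#' @export
scan_populations <- function(populations, grid = conductance_grid(), ...) {
  res <- purrr::map2(populations$data, populations$population,
                     function(d, label) {
                       if (nrow(d) == 0) return(NULL)
                       scan_correlations(d, grid, population = label, ...)
                     })
  out <- dplyr::bind_rows(res)
  structure(out, class = unique(c("correlation_scan", class(out))))
}

#' @export
tidy.correlation_scan <- function(x, ...) {
  as_tibble(x)
}

#' Scan-level summary statistics
#'
#' One-row summary of a correlation scan: pairs tested, correlations
#' found, sign balance, how many involve a calcium conductance, and how
#' many carry the edge-concentration review flag.
#'
#' @param x A `correlation_scan`.
#' @param calcium_conductances Names counted as calcium conductances.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.correlation_scan <- function(x, calcium_conductances = c("CaT", "CaS"),
                                    ...) {
  corr <- dplyr::filter(as_tibble(x), .data$is_correlation)
  tibble(
    n_tests = nrow(x),
    n_populations = dplyr::n_distinct(x$population),
    n_correlations = nrow(corr),
    n_positive = sum(corr$slope_sign == "+"),
    n_negative = sum(corr$slope_sign == "-"),
    n_calcium = sum(corr$cond_a %in% calcium_conductances |
                      corr$cond_b %in% calcium_conductances),
    n_flagged = sum(x$flagged_edge & x$is_correlation)
  )
}

#' Pair-by-population sign summary
#'
#' Reshapes a multi-population scan into the summary layout used to
#' compare activity types: one row per conductance pair, one column per
#' population, entries `"+"`, `"-"` or `""`.
#'
#' @param scan A `correlation_scan` covering one or more populations.
#' @return A tibble with `cond_a`, `cond_b` and one character column per
#'   population.
#' @export
correlation_sign_matrix <- function(scan) {
  x <- as_tibble(scan)
  x$sign <- dplyr::coalesce(x$slope_sign, "")
  tidyr::pivot_wider(x[, c("cond_a", "cond_b", "population", "sign")],
                     names_from = "population", values_from = "sign",
                     values_fill = "")
}
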