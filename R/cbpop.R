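#' Build a correlation mask from a population's conductance histogram
#'
#' The shape of an observed correlation is captured by thresholding the
#' raw 2-D conductance histogram of the source population: a grid cell is
#' inside the mask when it holds at least `threshold` (default 3%,
#' inclusive) of the population's models. The mask is later applied to the
#' whole database, irrespective of activity type, to build a
#' correlation-based population.
#'
#' @param pop Source population (record tibble with `lvl_*` columns).
#' @param pair Two conductance names.
#' @param grid The `conductance_grid`.
#' @param threshold Minimum fraction of the population per cell.
#' @return A `correlation_mask`: list with `pair`, `cells` (logical
#'   matrix), `threshold`, `n_source`. An empty mask triggers a warning
#'   here and an error on use.
#' @export
#' @examples
#' pl <- data.frame(type = "b", cond_a = "CaS", cond_b = "KCa",
#'                  sign = 1, width = 2, adherence = 0.9)
#' db <- make_planted_db(20000, type_weights = c(b = 1), planted = pl, seed = 3)
#' m <- correlation_mask(db, c("CaS", "KCa"))
#' sum(m$cells)
correlation_mask <- function(pop, pair, grid = db_grid(pop) %||% conductance_grid(),
                             threshold = 0.03) {
  if (nrow(pop) == 0) abort("cannot build a mask from an empty population")
  h <- histogram2d(pop, pair, grid)
  cells <- unclass(h) / sum(h) >= threshold
  if (!any(cells)) {
    warn(paste0("correlation mask for ", pair[1], "/", pair[2],
                " is empty at threshold ", threshold))
  }
  structure(list(pair = pair, cells = cells, threshold = threshold,
                 n_source = nrow(pop)),
            class = "correlation_mask")
}

#' @export
print.correlation_mask <- function(x, ...) {
  cat("<correlation_mask>", paste(x$pair, collapse = "/"), "-",
      sum(x$cells), "of", length(x$cells), "cells (threshold",
      x$threshold, ")\n")
  invisible(x)
}

new_mask <- function(pair, cells, threshold = NA_real_, n_source = NA_integer_) {
  structure(list(pair = pair, cells = cells, threshold = threshold,
                 n_source = n_source),
            class = "correlation_mask")
}

#' Select a correlation-based population
#'
#' Scans the entire database — regardless of activity type — for models
#' whose conductance pairs fall inside every given mask (conjunction
#' across masks). The result is the correlation-based population cb_i for
#' the activity type the masks were derived from.
#'
#' @param db A `model_db` (or record tibble with `lvl_*` columns).
#' @param masks A `correlation_mask` or list of them. Empty masks are
#'   refused.
#' @return The selected records. A possibly-empty result (e.g. disjoint
#'   masks on the same pair) is returned with a warning.
#' @export
select_cb_population <- function(db, masks) {
  if (inherits(masks, "correlation_mask")) masks <- list(masks)
  if (length(masks) == 0) abort("need at least one mask")
  keep <- rep(TRUE, nrow(db))
  for (m in masks) {
    stopifnot(inherits(m, "correlation_mask"))
    if (!any(m$cells)) {
      abort(paste0("refusing empty mask on ", paste(m$pair, collapse = "/")))
    }
    i <- db[[paste0("lvl_", m$pair[1])]]
    j <- db[[paste0("lvl_", m$pair[2])]]
    keep <- keep & m$cells[cbind(i, j)]
  }
  out <- db[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("correlation-based population is empty")
  }
  out
}

#' Enrichment of a target activity type in a correlation-based population
#'
#' %Success of a population is the percentage of its models belonging to
#' the target type; the success factor is
#' \deqn{f_{Success} = \frac{\%Success_{cb}}{\%Success_{original}}
#'   = \frac{N(cb \cap type_i)/N(cb)}{N(O \cap type_i)/N(O)}}
#' the multiplicative change in the likelihood of the target type caused
#' by imposing the correlation(s). `f > 1` means the correlation supports
#' the activity type.
#'
#' @param db The original database.
#' @param cb The correlation-based population (subset of `db` rows,
#'   matched by `model_id`).
#' @param type Either a predicate function applied to a record tibble
#'   (returning a logical vector), or a character activity-class label
#'   matched against `activity_class`.
#' @return A one-row tibble: `n_db`, `n_cb`, `n_type_db`, `n_type_cb`,
#'   `pct_success_cb`, `pct_success_original`, `f_success`.
#' @export
#' @examples
#' db <- make_planted_db(5000, seed = 4)
#' success_report(db, db, "burster")$f_success  # full database: exactly 1
success_report <- function(db, cb, type) {
  if (nrow(cb) == 0) abort("success undefined for an empty population")
  in_type <- function(x) {
    if (is.function(type)) type(x) else x$activity_class == type
  }
  t_db <- sum(in_type(db), na.rm = TRUE)
  t_cb <- sum(in_type(cb), na.rm = TRUE)
  if (t_db == 0) abort("target type has no members in the database")
  pct_cb <- 100 * t_cb / nrow(cb)
  pct_o <- 100 * t_db / nrow(db)
  tibble(
    n_db = nrow(db), n_cb = nrow(cb),
    n_type_db = t_db, n_type_cb = t_cb,
    pct_success_cb = pct_cb, pct_success_original = pct_o,
    f_success = pct_cb / pct_o
  )
}

#' Random control masks
#'
#' The null control for mask-based enrichment: each control mask selects a
#' uniformly random conductance pair and a uniformly random set of
#' distinct grid cells. Matching the cell count of the observed
#' correlation mask is the minimal fair control; the cell count used is
#' recorded in each mask. On a database whose conductances are independent
#' of the activity label, the expected success factor of such masks is 1.
#'
#' @param n_masks Number of masks.
#' @param cells_per_mask Cells per mask (in `[1, n_levels^2]`).
#' @param grid The `conductance_grid`.
#' @param seed RNG seed (reproducible; caller's RNG state restored).
#' @return A list of `correlation_mask` objects.
#' @export
random_control_masks <- function(n_masks, cells_per_mask,
                                 grid = conductance_grid(), seed = 1L) {
  L <- unique(lengths(grid$levels))
  stopifnot(length(L) == 1, cells_per_mask >= 1, cells_per_mask <= L^2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  pairs <- conductance_pairs(grid)
  lapply(seq_len(n_masks), function(i) {
    pr <- pairs[sample.int(nrow(pairs), 1), ]
    cells <- matrix(FALSE, L, L)
    cells[sample.int(L^2, cells_per_mask)] <- TRUE
    new_mask(c(pr$cond_a, pr$cond_b), cells)
  })
}

#' Ideal linear-correlation mask
#'
#' A diagonal band of the given width and slope sign — the idealised shape
#' of a perfect linear correlation on the grid. Applied to random pairs
#' and activity types it provides a shape-specific control: on an
#' independent database it produces no systematic enrichment.
#'
#' @param pair Two conductance names.
#' @param grid The `conductance_grid`.
#' @param width Band half-width in cells (1 = the main diagonal;
#'   `n_levels` = the full grid).
#' @param sign `+1` (rising) or `-1` (falling band).
#' @return A `correlation_mask`.
#' @export
ideal_linear_mask <- function(pair, grid = conductance_grid(), width = 1,
                              sign = 1) {
  L <- unique(lengths(grid$levels))
  stopifnot(length(L) == 1, L >= 2, width >= 1)
  cells <- matrix(FALSE, L, L)
  b <- band_cells(L, sign, width)
  cells[b] <- TRUE
  new_mask(pair, cells)
}
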