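#' Conductance grid definition
#'
#' A conductance grid assigns each maximal conductance a small set of
#' equidistant levels (from zero up to a physiological maximum); the model
#' database is the Cartesian product of those levels. The default grid is
#' the shipped 8-conductance, 6-level STG grid (6^8 = 1,679,616 models).
#'
#' @param levels Named list of numeric level vectors, one per conductance,
#'   each non-empty and strictly increasing. Defaults to the grid in the
#'   shipped kinetics configuration.
#' @return An object of class `conductance_grid`.
#' @export
#' @examples
#' g <- conductance_grid()
#' grid_size(g)   # 1679616
conductance_grid <- function(levels = read_kinetics()$grid) {
  stopifnot(is.list(levels), length(levels) >= 1, !is.null(names(levels)))
  for (nm in names(levels)) {
    lv <- levels[[nm]]
    if (length(lv) < 1 || any(!is.finite(lv)) || any(lv < 0) ||
        (length(lv) > 1 && any(diff(lv) <= 0))) {
      abort(paste0("grid levels for ", nm,
                   " must be non-negative and strictly increasing"))
    }
  }
  structure(
    list(conductances = names(levels), levels = lapply(levels, as.numeric)),
    class = "conductance_grid"
  )
}

#' @rdname conductance_grid
#' @export
grid_size <- function(grid) {
  stopifnot(inherits(grid, "conductance_grid"))
  prod(lengths(grid$levels))
}

#' @export
print.conductance_grid <- function(x, ...) {
  cat("<conductance_grid>", length(x$conductances), "conductances,",
      paste(lengths(x$levels), collapse = "x"), "=",
      format(grid_size(x), big.mark = ","), "points\n")
  invisible(x)
}

#' Enumerate all grid points
#'
#' Expands the full Cartesian product of conductance levels in lexicographic
#' grid order (first conductance varying fastest). Level indices are 1-based
#' integers; level 1 is always the lowest value of that conductance (zero on
#' the default grid).
#'
#' @param grid A `conductance_grid`.
#' @param gbar If `TRUE` (default) also attach the maximal-conductance value
#'   columns (`g_<name>`, mS/cm^2) alongside the index columns (`lvl_<name>`).
#' @return A tibble with one row per grid point and a `model_id` key
#'   (1..grid_size, in enumeration order).
#' @export
#' @examples
#' enumerate_grid(conductance_grid(list(a = c(0, 1, 2), b = c(0, 5, 10))))
enumerate_grid <- function(grid, gbar = TRUE) {
  stopifnot(inherits(grid, "conductance_grid"))
  idx <- do.call(expand.grid, c(lapply(grid$levels, seq_along),
                                KEEP.OUT.ATTRS = FALSE))
  names(idx) <- paste0("lvl_", grid$conductances)
  out <- as_tibble(idx)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  if (gbar) {
    for (nm in grid$conductances) {
      out[[paste0("g_", nm)]] <- grid$levels[[nm]][out[[paste0("lvl_", nm)]]]
    }
  }
  dplyr::bind_cols(tibble(model_id = seq_len(nrow(out))), out)
}

#' Convert level indices to maximal conductances
#'
#' @param grid A `conductance_grid`.
#' @param lvl Named list/vector of 1-based level indices (one per
#'   conductance) or a tibble of `lvl_<name>` columns.
#' @return Named numeric vector (or tibble of `g_<name>` columns) of
#'   maximal conductances, mS/cm^2.
#' @export
grid_gbar <- function(grid, lvl) {
  stopifnot(inherits(grid, "conductance_grid"))
  if (is.data.frame(lvl)) {
    out <- lvl[0]
    for (nm in grid$conductances) {
      out[[paste0("g_", nm)]] <- grid$levels[[nm]][lvl[[paste0("lvl_", nm)]]]
    }
    return(as_tibble(out))
  }
  vapply(grid$conductances, function(nm) grid$levels[[nm]][[lvl[[nm]]]],
         numeric(1))
}

#' All unordered conductance pairs of a grid
#'
#' @param grid A `conductance_grid` (default: the 8-conductance grid, giving
#'   the 28 pairs screened by [scan_correlations()]).
#' @return A tibble with character columns `cond_a`, `cond_b`.
#' @export
conductance_pairs <- function(grid = conductance_grid()) {
  nm <- if (inherits(grid, "conductance_grid")) grid$conductances else grid
  cmb <- utils::combn(nm, 2)
  tibble(cond_a = cmb[1, ], cond_b = cmb[2, ])
}
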