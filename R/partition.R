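#' Model database container
#'
#' A model database is a tibble with one record per model: the grid level
#' indices (`lvl_<conductance>`), the maximal conductances
#' (`g_<conductance>`, mS/cm^2) and the activity descriptor columns
#' produced by [classify_trace()] (at minimum `activity_class`). The grid
#' definition and provenance (kinetics name/version, generator, seed)
#' travel in attributes and survive the TSV round-trip via a YAML sidecar.
#'
#' @param x A data frame of records with a unique `model_id` column.
#' @param grid The `conductance_grid` the records live on.
#' @param kinetics Optional `channel_kinetics` used to build the records
#'   (only its name/version are stored).
#' @param provenance Optional list of extra provenance fields.
#' @return A tibble of class `model_db`.
#' @export
model_db <- function(x, grid, kinetics = NULL, provenance = list()) {
  stopifnot(is.data.frame(x), inherits(grid, "conductance_grid"))
  if (!"model_id" %in% names(x)) abort("model databases need a model_id column")
  if (anyDuplicated(x$model_id)) abort("model_id must be unique")
  if (nrow(x) > grid_size(grid)) {
    abort("more records than grid points")
  }
  if (!is.null(kinetics)) {
    provenance$kinetics <- list(name = kinetics$name,
                                schema_version = kinetics$schema_version)
  }
  out <- as_tibble(x)
  structure(out, grid = grid, provenance = provenance,
            class = unique(c("model_db", class(out))))
}

#' @rdname model_db
#' @param db A `model_db`.
#' @export
db_grid <- function(db) attr(db, "grid")

DB_SCHEMA_VERSION <- 1L

descriptor_columns <- function() {
  c("activity_class", "quality", "n_maxima", "n_spikes", "n_bursts",
    "spike_frequency", "spike_height", "burst_period", "burst_duration",
    "duty_cycle", "spikes_per_burst", "slow_wave_peak",
    "slow_wave_amplitude", "slope_average", "slope_initial",
    "slope_central")
}

#' Write / read a model database
#'
#' The records go to a TSV file and the grid definition, provenance and
#' schema version to a `<path>.meta.yaml` sidecar; reading restores both
#' losslessly. A schema-version mismatch, or a TSV column that is neither
#' a grid column nor a known descriptor column, is an explicit error.
#'
#' @param db A `model_db`.
#' @param path TSV file path.
#' @return `write_model_db` returns `path` invisibly; `read_model_db`
#'   returns the `model_db`.
#' @export
write_model_db <- function(db, path) {
  stopifnot(inherits(db, "model_db"))
  grid <- db_grid(db)
  readr::write_tsv(as_tibble(db), path)
  meta <- list(
    schema_version = DB_SCHEMA_VERSION,
    grid = lapply(grid$levels, as.numeric),
    provenance = attr(db, "provenance") %||% list()
  )
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 17L)
  invisible(path)
}

#' @rdname write_model_db
#' @export
read_model_db <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(meta_path)) {
    abort(paste0("missing database sidecar ", meta_path))
  }
  meta <- yaml::read_yaml(meta_path)
  if (!identical(as.integer(meta$schema_version), DB_SCHEMA_VERSION)) {
    abort(paste0("database schema version mismatch: file has ",
                 meta$schema_version, ", package expects ",
                 DB_SCHEMA_VERSION))
  }
  grid <- conductance_grid(meta$grid)
  recs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  known <- c("model_id", paste0("lvl_", grid$conductances),
             paste0("g_", grid$conductances), descriptor_columns())
  unknown <- setdiff(names(recs), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown database columns: ",
                 paste(unknown, collapse = ", ")))
  }
  model_db(recs, grid = grid, provenance = meta$provenance)
}

#' Read a whitespace-delimited model-database dump
#'
#' Parses an external database dump (one model per line, fields separated
#' by whitespace) given a column map from package field names to 1-based
#' source column positions. The map must cover the eight conductances
#' (`g_<name>`); any descriptor fields present (e.g. `activity_class`,
#' `duty_cycle`) are taken from the stored descriptive statistics rather
#' than recomputed from traces. Rows with too few fields or non-numeric
#' values in numeric fields are collected in `attr(, "rejects")` (with
#' line numbers and reasons), never silently dropped.
#'
#' @param path Dump file path.
#' @param column_map Named integer vector: names are package field names,
#'   values source column positions.
#' @param grid The `conductance_grid` whose levels the conductance values
#'   are matched against (nearest level, for the `lvl_*` index columns).
#' @return A `model_db`; rejected lines in `attr(, "rejects")`.
#' @export
read_supplementary_dump <- function(path, column_map,
                                    grid = conductance_grid()) {
  stopifnot(is.numeric(column_map), !is.null(names(column_map)))
  gcols <- paste0("g_", grid$conductances)
  if (!all(gcols %in% names(column_map))) {
    abort(paste0("column map must cover ", paste(gcols, collapse = ", ")))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  need <- max(column_map)
  ok <- lengths(toks) >= need
  rejects <- tibble(line = which(!ok),
                    reason = rep("too few fields", sum(!ok)))
  toks <- toks[ok]
  fields <- lapply(column_map, function(j) {
    vapply(toks, `[[`, character(1), j)
  })
  out <- tibble(.rows = length(toks))
  bad <- logical(length(toks))
  for (nm in names(fields)) {
    if (nm == "activity_class") {
      out[[nm]] <- fields[[nm]]
    } else {
      val <- suppressWarnings(as.numeric(fields[[nm]]))
      bad <- bad | is.na(val)
      out[[nm]] <- val
    }
  }
  if (any(bad)) {
    rejects <- dplyr::bind_rows(rejects,
      tibble(line = which(ok)[bad], reason = "non-numeric field"))
    out <- out[!bad, , drop = FALSE]
  }
  for (nm in grid$conductances) {
    lv <- grid$levels[[nm]]
    out[[paste0("lvl_", nm)]] <- vapply(out[[paste0("g_", nm)]],
                                        function(g) which.min(abs(lv - g)),
                                        integer(1))
  }
  out <- dplyr::bind_cols(tibble(model_id = seq_len(nrow(out))), out)
  db <- model_db(out, grid = grid,
                 provenance = list(source = path,
                                   column_map = as.list(column_map)))
  attr(db, "rejects") <- rejects
  db
}

#' Partition a population by one activity metric
#'
#' Splits the records of one activity class into bins of a single metric.
#' Bins are left-closed, right-open, with open outer bins (`< first edge`
#' and `>= last edge`), so a model sitting exactly on an edge falls in the
#' upper bin. The resulting populations are disjoint and cover every
#' record of the class with a defined metric value.
#'
#' @param db A `model_db` (or any record tibble).
#' @param metric Metric column name, e.g. `"duty_cycle"`.
#' @param edges Strictly increasing bin edges, in metric units.
#' @param class Restrict to this `activity_class` first (`NULL`: no
#'   restriction).
#' @return A tibble with one row per population: `population` (label),
#'   `metric`, `lo`, `hi`, `n`, and the member records in the `data`
#'   list-column.
#' @export
#' @examples
#' db <- make_planted_db(500, seed = 1)
#' db$duty_cycle <- runif(nrow(db))
#' partition_models(db, "duty_cycle", c(0.25, 0.5, 0.75))
partition_models <- function(db, metric, edges, class = NULL) {
  stopifnot(metric %in% names(db), length(edges) >= 1,
            !is.unsorted(edges, strictly = TRUE))
  sub <- if (is.null(class)) db else
    dplyr::filter(db, .data$activity_class == class)
  sub <- dplyr::filter(sub, !is.na(.data[[metric]]))
  breaks <- c(-Inf, edges, Inf)
  lab <- c(paste0("<", edges[1]),
           if (length(edges) > 1) {
             paste0(edges[-length(edges)], "-", edges[-1])
           },
           paste0(">=", edges[length(edges)]))
  bin <- cut(sub[[metric]], breaks = breaks, labels = lab, right = FALSE)
  members <- lapply(lab, function(l) sub[bin == l, , drop = FALSE])
  tibble(
    population = paste0(metric, " ", lab),
    metric = metric,
    lo = breaks[-length(breaks)],
    hi = breaks[-1],
    n = vapply(members, nrow, integer(1)),
    data = members
  )
}

#' Select models satisfying a conjunction of metric ranges
#'
#' Each criterion is a closed range `[lo, hi]` on one metric; a model is
#' selected when it satisfies every criterion (so adding a criterion can
#' never grow the population). An empty criteria set selects the whole
#' database.
#'
#' @param db A record tibble.
#' @param criteria Named list: `list(duty_cycle = c(0.2, 0.5), ...)`, or a
#'   data frame with columns `metric`, `lo`, `hi`.
#' @return The selected records (same columns as `db`).
#' @export
select_by_criteria <- function(db, criteria) {
  if (is.data.frame(criteria)) {
    criteria <- setNames(Map(c, criteria$lo, criteria$hi), criteria$metric)
  }
  out <- db
  for (metric in names(criteria)) {
    rng <- criteria[[metric]]
    if (length(rng) != 2 || rng[1] > rng[2]) {
      abort(paste0("criterion on ", metric, " must be a non-empty range"))
    }
    if (!metric %in% names(out)) {
      abort(paste0("criterion metric not in database: ", metric))
    }
    out <- dplyr::filter(out, !is.na(.data[[metric]]),
                         .data[[metric]] >= rng[1],
                         .data[[metric]] <= rng[2])
  }
  out
}

#' Default partition schemes
#'
#' Reads the shipped "reference mode" scheme configuration: the
#' single-metric binning schemes (spike frequency, duty cycle, three
#' rise-phase slope variants, plus the disabled-by-default spike-height
#' and spikes-per-burst schemes), the pacemaker multi-criteria ranges and
#' the correlation-screen cutoffs.
#'
#' @param path Scheme YAML path (shipped default).
#' @return The configuration as a named list.
#' @export
default_schemes <- function(path = system.file("extdata",
                                               "schemes-default.yaml",
                                               package = "condcorr",
                                               mustWork = TRUE)) {
  yaml::read_yaml(path)
}

#' Enumerate the activity-defined sub-populations of a database
#'
#' Builds the full set of sub-populations screened for correlations:
#' the six tier-2 activity classes; the periodic spikers binned by spike
#' frequency; the periodic bursters binned by duty cycle and by each of
#' the three rise-phase slope measures; and the pacemaker-criteria
#' populations (each criterion alone and every pairwise conjunction,
#' applied to periodic bursters). With the shipped scheme configuration
#' this enumerates 6 + 5 + 6 + 3 x 5 + 5 + 10 = 47 sub-populations;
#' populations may be empty for small databases but are always listed.
#'
#' @param db A `model_db` with descriptor columns.
#' @param schemes A scheme configuration ([default_schemes()]).
#' @return A tibble: `population`, `tier` (`"class"`, `"metric"`,
#'   `"pacemaker"`), `n`, `data` list-column.
#' @export
build_populations <- function(db, schemes = default_schemes()) {
  classes <- c("silent", "periodic_spiking", "irregular_spiking",
               "periodic_bursting", "irregular_bursting",
               "one_spike_bursting")
  tier2 <- tibble(
    population = classes,
    tier = "class",
    n = vapply(classes, function(cl) sum(db$activity_class == cl,
                                         na.rm = TRUE), integer(1)),
    data = lapply(classes, function(cl) {
      db[!is.na(db$activity_class) & db$activity_class == cl, , drop = FALSE]
    })
  )
  metric_pops <- list()
  for (metric in names(schemes$single_metric)) {
    sch <- schemes$single_metric[[metric]]
    if (isFALSE(sch$enabled %||% TRUE)) next
    part <- partition_models(db, metric, as.numeric(sch$edges),
                             class = sch$class)
    part$tier <- "metric"
    metric_pops[[metric]] <- part[, c("population", "tier", "n", "data")]
  }
  pc <- schemes$pacemaker_criteria
  pb <- db[!is.na(db$activity_class) &
             db$activity_class == "periodic_bursting", , drop = FALSE]
  singles <- lapply(names(pc), function(m) {
    select_by_criteria(pb, setNames(list(as.numeric(pc[[m]])), m))
  })
  pairs <- utils::combn(names(pc), 2, simplify = FALSE)
  pairs_data <- lapply(pairs, function(ms) {
    select_by_criteria(pb, setNames(lapply(ms, function(m)
      as.numeric(pc[[m]])), ms))
  })
  pace <- tibble(
    population = c(paste0("pacemaker:", names(pc)),
                   vapply(pairs, paste, character(1), collapse = "+")),
    tier = "pacemaker",
    n = vapply(c(singles, pairs_data), nrow, integer(1)),
    data = c(singles, pairs_data)
  )
  pace$population[seq_along(pairs) + length(pc)] <-
    paste0("pacemaker:", pace$population[seq_along(pairs) + length(pc)])
  dplyr::bind_rows(c(list(tier2), metric_pops, list(pace)))
}
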