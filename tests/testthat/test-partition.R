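toy_db <- function(n = 9, seed = 1) {
  g <- conductance_grid(list(a = c(0, 1, 2), b = c(0, 1, 2)))
  set.seed(seed)
  db <- enumerate_grid(g)[seq_len(n), ]
  db$activity_class <- rep(c("periodic_bursting", "periodic_spiking",
                             "silent"), length.out = n)
  db$duty_cycle <- seq(0.01, 0.65, length.out = n)
  model_db(db, grid = g, provenance = list(note = "toy"))
}

test_that("model databases round-trip through the TSV store", {
  db <- toy_db()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_db(db, path)
  back <- read_model_db(path)
  expect_equal(as.data.frame(back), as.data.frame(db))
  expect_equal(db_grid(back)$levels, db_grid(db)$levels)
  expect_equal(attr(back, "provenance")$note, "toy")
})

test_that("an empty database round-trips", {
  db <- toy_db(9)[0, ]
  db <- model_db(db, grid = conductance_grid(list(a = c(0, 1, 2),
                                                  b = c(0, 1, 2))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_db(db, path)
  expect_equal(nrow(read_model_db(path)), 0)
})

test_that("unknown columns and schema mismatches are explicit errors", {
  db <- toy_db()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model_db(db, path)
  recs <- readr::read_tsv(path, show_col_types = FALSE)
  recs$mystery_column <- 1
  readr::write_tsv(recs, path)
  expect_error(read_model_db(path), "mystery_column")
  meta_path <- paste0(path, ".meta.yaml")
  meta <- yaml::read_yaml(meta_path)
  meta$schema_version <- 99L
  yaml::write_yaml(meta, meta_path)
  expect_error(read_model_db(path), "schema version mismatch")
})

test_that("supplementary dumps parse via the column map, rejecting bad rows", {
  grid <- conductance_grid()
  gnames <- grid$conductances
  lines <- c(
    "1 100 2.5 4 30 10 50 0.02 0.01 bursting 0.25",
    "2 0 5 6 10 25 125 0.05 0.03 spiking 0.10",
    "3 300 7.5 8 0 15 75 0 0 silent 0.00",
    "4 200 2.5",                       # truncated row
    "5 100 2.5 4 30 10 xx 0.02 0.01 bursting 0.25"  # non-numeric field
  )
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, path)
  cmap <- c(g_Na = 2, g_CaT = 3, g_CaS = 4, g_A = 5, g_KCa = 6, g_Kd = 7,
            g_H = 8, g_leak = 9, activity_class = 10, duty_cycle = 11)
  db <- read_supplementary_dump(path, cmap, grid)
  expect_equal(nrow(db), 3)
  expect_equal(db$g_Na, c(100, 0, 300))
  expect_equal(db$lvl_Na, c(2L, 1L, 4L))
  rej <- attr(db, "rejects")
  expect_equal(sort(rej$line), c(4, 5))
  # permuting the source columns while fixing the map gives the same parse
  lines2 <- vapply(strsplit(lines[1:3], " "), function(x)
    paste(x[c(11, 1:10)], collapse = " "), character(1))
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines2, path2)
  cmap2 <- cmap + 1
  cmap2["duty_cycle"] <- 1   # old column 11 moved to the front
  db2 <- read_supplementary_dump(path2, cmap2, grid)
  expect_equal(db2$g_Na, db$g_Na)
  expect_equal(db2$duty_cycle, db$duty_cycle)
})

test_that("partitions are left-closed, disjoint, and cover the class", {
  db <- toy_db(9)
  part <- partition_models(db, "duty_cycle", c(0.05, 0.1, 0.2, 0.4, 0.6),
                           class = "periodic_bursting")
  expect_equal(nrow(part), 6)
  nb <- sum(db$activity_class == "periodic_bursting")
  expect_equal(sum(part$n), nb)
  ids <- unlist(lapply(part$data, function(d) d$model_id))
  expect_equal(sort(ids),
               sort(db$model_id[db$activity_class == "periodic_bursting"]))
  # a model exactly on an edge falls in the upper bin
  db2 <- toy_db(9)
  db2$duty_cycle[1] <- 0.05
  p2 <- partition_models(db2, "duty_cycle", c(0.05, 0.1),
                         class = "periodic_bursting")
  expect_true(1 %in% p2$data[[2]]$model_id)
  expect_false(1 %in% p2$data[[1]]$model_id)
})

test_that("metric partitions of the wrong class are empty, not wrong", {
  db <- toy_db(9)
  db$spike_frequency <- NA_real_
  part <- partition_models(db, "spike_frequency", c(10, 25),
                           class = "periodic_bursting")
  expect_equal(sum(part$n), 0)
})

test_that("criteria selection is a conjunction of closed ranges", {
  db <- toy_db(9)
  db$slow_wave_amplitude <- seq(5, 45, length.out = 9)
  db$slow_wave_peak <- seq(-60, -20, length.out = 9)
  a <- select_by_criteria(db, list(slow_wave_amplitude = c(10, 30)))
  ab <- select_by_criteria(db, list(slow_wave_amplitude = c(10, 30),
                                    slow_wave_peak = c(-45, -30)))
  expect_true(all(ab$model_id %in% a$model_id))
  expect_lte(nrow(ab), nrow(a))
  # boundary inclusion: amplitude exactly 10 or 30 is kept
  db$slow_wave_amplitude[1:2] <- c(10, 30)
  sel <- select_by_criteria(db, list(slow_wave_amplitude = c(10, 30)))
  expect_true(all(c(1, 2) %in% sel$model_id))
  # empty criteria set selects everything
  expect_equal(nrow(select_by_criteria(db, list())), nrow(db))
  expect_error(select_by_criteria(db, list(duty_cycle = c(2, 1))), "range")
})

test_that("planted criterion membership is recovered exactly", {
  set.seed(4)
  n <- 200
  db <- tibble::tibble(
    model_id = 1:n,
    activity_class = "periodic_bursting",
    slow_wave_amplitude = runif(n, 0, 40),
    slow_wave_peak = runif(n, -60, -10),
    duty_cycle = runif(n, 0, 0.8),
    burst_period = runif(n, 200, 3000),
    spikes_per_burst = sample(1:40, n, replace = TRUE)
  )
  crit <- list(slow_wave_amplitude = c(10, 30), slow_wave_peak = c(-45, -20),
               duty_cycle = c(0.2, 0.5), burst_period = c(1000, 2000),
               spikes_per_burst = c(4, 30))
  sel <- select_by_criteria(db, crit)
  manual <- db$model_id[
    db$slow_wave_amplitude >= 10 & db$slow_wave_amplitude <= 30 &
      db$slow_wave_peak >= -45 & db$slow_wave_peak <= -20 &
      db$duty_cycle >= 0.2 & db$duty_cycle <= 0.5 &
      db$burst_period >= 1000 & db$burst_period <= 2000 &
      db$spikes_per_burst >= 4 & db$spikes_per_burst <= 30
  ]
  expect_equal(sel$model_id, manual)
})

test_that("the default scheme set enumerates 47 sub-populations", {
  set.seed(8)
  n <- 2000
  classes <- c("silent", "periodic_spiking", "irregular_spiking",
               "periodic_bursting", "irregular_bursting",
               "one_spike_bursting")
  db <- make_planted_db(n, type_weights = setNames(rep(1, 6), classes),
                        seed = 12)
  db$spike_frequency <- ifelse(db$activity_class == "periodic_spiking",
                               runif(n, 0, 100), NA)
  db$duty_cycle <- ifelse(db$activity_class == "periodic_bursting",
                          runif(n, 0, 0.8), NA)
  for (m in c("slope_average", "slope_initial", "slope_central")) {
    db[[m]] <- ifelse(db$activity_class == "periodic_bursting",
                      runif(n, 0, 0.2), NA)
  }
  db$slow_wave_amplitude <- runif(n, 0, 40)
  db$slow_wave_peak <- runif(n, -60, -10)
  db$burst_period <- runif(n, 200, 3000)
  db$spikes_per_burst <- sample(1:40, n, replace = TRUE)
  pops <- build_populations(db)
  expect_equal(nrow(pops), 47)
  expect_equal(sum(pops$tier == "class"), 6)
  expect_equal(sum(pops$tier == "metric"), 26)   # 5 + 6 + 3 x 5
  expect_equal(sum(pops$tier == "pacemaker"), 15)
  # disjoint cover within each single-metric scheme
  duty <- pops[grepl("^duty_cycle", pops$population), ]
  ids <- unlist(lapply(duty$data, function(d) d$model_id))
  expect_false(any(duplicated(ids)))
  expect_equal(length(ids),
               sum(db$activity_class == "periodic_bursting"))
})
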