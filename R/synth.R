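#' Specification for an analytic voltage-trace fixture
#'
#' Describes a piecewise-linear waveform of known activity class and
#' metrics, used to test the classifier independently of the ODE
#' integrator. Knot times that must be detected exactly (spike apexes,
#' between-burst minima) are snapped to the sampling grid, so constructed
#' timing is exact up to one sample interval; the realised (post-snapping)
#' parameters are attached to the generated trace.
#'
#' @param class One of `"silent"`, `"periodic_spiking"`,
#'   `"irregular_spiking"`, `"periodic_bursting"`, `"irregular_bursting"`,
#'   `"one_spike_bursting"`.
#' @param frequency Spike frequency, Hz (spiking classes).
#' @param burst_period Burst period, ms (bursting classes).
#' @param duty_cycle Burst duration / burst period, in (0, 1) (bursting
#'   classes with more than one spike per burst).
#' @param spikes_per_burst Spikes per burst (>= 2 for plain bursters).
#' @param spike_peak Spike apex voltage, mV (> -30).
#' @param trough Between-burst (or baseline) minimum, mV (< -30).
#' @param intra_valley Voltage between spikes inside a burst, mV.
#' @param rise_slopes `NULL` for a linear rise phase, or `c(s1, s2)` mV/ms
#'   for a two-segment rise whose break sits at the first quarter of the
#'   rise span (so the initial slope is `s1` and the central slope
#'   essentially `s2`).
#' @param jitter Relative timing jitter for the irregular classes.
#' @param dt Sampling interval, ms.
#' @param duration Trace duration, ms (default: about 11 cycles).
#' @param baseline Voltage of a silent trace (and the inter-spike valley of
#'   spiking traces), mV.
#' @param seed RNG seed for jittered classes.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(class, frequency = NULL, burst_period = NULL,
                       duty_cycle = NULL, spikes_per_burst = 3,
                       spike_peak = 10, trough = -65, intra_valley = -40,
                       rise_slopes = NULL, jitter = 0.15, dt = 0.5,
                       duration = NULL, baseline = -60, seed = NULL) {
  classes <- c("silent", "periodic_spiking", "irregular_spiking",
               "periodic_bursting", "irregular_bursting", "one_spike_bursting")
  class <- match.arg(class, classes)
  if (class %in% c("periodic_spiking", "irregular_spiking") &&
      is.null(frequency)) {
    abort("spiking specs need a frequency")
  }
  if (class %in% c("periodic_bursting", "irregular_bursting") &&
      (is.null(burst_period) || is.null(duty_cycle))) {
    abort("bursting specs need burst_period and duty_cycle")
  }
  if (class == "one_spike_bursting" && is.null(burst_period)) {
    abort("one-spike bursting specs need burst_period")
  }
  if (!is.null(duty_cycle) && (duty_cycle <= 0 || duty_cycle >= 1)) {
    abort("duty cycle must lie strictly between 0 and 1")
  }
  if (spike_peak <= -30 || trough >= -30) {
    abort("spike peak must exceed -30 mV and trough must lie below it")
  }
  structure(
    list(class = class, frequency = frequency, burst_period = burst_period,
         duty_cycle = duty_cycle, spikes_per_burst = spikes_per_burst,
         spike_peak = spike_peak, trough = trough,
         intra_valley = intra_valley, rise_slopes = rise_slopes,
         jitter = jitter, dt = dt, duration = duration,
         baseline = baseline, seed = seed),
    class = "trace_spec"
  )
}

snap <- function(t, dt) round(t / dt) * dt

# piecewise-linear waveform sampled on the dt grid
sample_knots <- function(kt, kv, dt, duration) {
  o <- order(kt)
  kt <- kt[o]
  kv <- kv[o]
  keep <- !duplicated(kt)
  tt <- seq(0, duration, by = dt)
  vv <- stats::approx(kt[keep], kv[keep], xout = tt, rule = 2)$y
  new_voltage_trace(tt, vv, ca = NULL, dt = dt)
}

local_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Generate an analytic voltage trace from a fixture specification
#'
#' Builds the piecewise-linear waveform described by a [trace_spec()]. The
#' realised parameters after grid snapping (class, frequency, burst period,
#' duty cycle, rise-phase slopes, slow-wave peak and amplitude) are
#' attached as `attr(trace, "realized")`, so tests can compare classifier
#' output against the construction without re-deriving it.
#'
#' @param spec A [trace_spec()].
#' @return A `voltage_trace` tibble (`ca` is `NA`: fixtures carry no
#'   calcium pool).
#' @export
#' @examples
#' tr <- make_trace(trace_spec("periodic_spiking", frequency = 20))
#' classify_trace(tr)$activity_class
make_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  dt <- spec$dt
  w <- snap(max(2 * dt, 2), dt)   # spike half-width, ms
  if (spec$class == "silent") {
    dur <- spec$duration %||% 2000
    tr <- sample_knots(c(0, dur), rep(spec$baseline, 2), dt, dur)
    attr(tr, "realized") <- list(class = "silent")
    return(tr)
  }
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))

  if (spec$class %in% c("periodic_spiking", "irregular_spiking")) {
    p <- snap(1000 / spec$frequency, dt)
    ncyc <- ceiling((spec$duration %||% (12 * p)) / p)
    isis <- rep(p, ncyc)
    if (spec$class == "irregular_spiking") {
      isis <- snap(p * runif(ncyc, 1 - spec$jitter, 1 + spec$jitter), dt)
    }
    apex <- snap(cumsum(c(w + dt, isis)), dt)
    kt <- 0
    kv <- spec$baseline
    for (a in apex) {
      kt <- c(kt, a - w, a, a + w)
      kv <- c(kv, spec$baseline, spec$spike_peak, spec$baseline)
    }
    tr <- sample_knots(kt, kv, dt, max(apex) + w)
    attr(tr, "realized") <- list(
      class = spec$class, frequency = 1000 / mean(diff(apex)),
      spike_peak = spec$spike_peak,
      spike_height = spec$spike_peak - spec$baseline
    )
    return(tr)
  }

  # ---- bursting classes -------------------------------------------------
  p <- snap(spec$burst_period, dt)
  one_spike <- spec$class == "one_spike_bursting"
  k <- if (one_spike) 1L else as.integer(spec$spikes_per_burst)
  if (!one_spike && k < 2) {
    abort("plain bursting fixtures need at least two spikes per burst")
  }
  isi_in <- if (k == 1) 0 else snap(spec$duty_cycle * p / (k - 1), dt)
  d <- isi_in * max(k - 1, 0)
  if (k > 1 && isi_in >= 0.7 * (p - d)) {
    abort("spec contradiction: intra-burst ISI would qualify as inter-burst")
  }
  nb <- ceiling((spec$duration %||% (10 * p)) / p)
  starts <- snap(cumsum(c(2 * w, rep(p, nb - 1))), dt)
  if (spec$class == "irregular_bursting") {
    starts <- snap(starts + c(0, p * spec$jitter * runif(nb - 1, -1, 1)), dt)
  }
  # between-burst minimum voltage (one-spike traces dip lower after the
  # sub-threshold bump so the bump is not the gap minimum)
  v_min <- if (one_spike) spec$trough - 2 else spec$trough
  kt <- 0
  kv <- v_min
  rise <- list(average = NULL, initial = NULL, central = NULL)
  for (b in seq_len(nb)) {
    a0 <- starts[b]
    apexes <- a0 + (0:(k - 1)) * isi_in
    kt <- c(kt, a0 - w)
    kv <- c(kv, -30)
    for (j in seq_len(k)) {
      kt <- c(kt, apexes[j])
      kv <- c(kv, spec$spike_peak)
      if (j < k) {
        kt <- c(kt, (apexes[j] + apexes[j + 1]) / 2)
        kv <- c(kv, spec$intra_valley)
      }
    }
    if (b == nb) {
      # closing downstroke so the final apex is a strict maximum
      kt <- c(kt, apexes[k] + w)
      kv <- c(kv, -30)
      break
    }
    gap_b <- starts[b + 1] - apexes[k]
    t5 <- starts[b + 1] - w              # threshold crossing, on-grid
    if (one_spike) {
      t_fall <- snap(apexes[k] + 0.15 * gap_b, dt)
      t_bump <- snap(t_fall + 0.15 * gap_b, dt)
      t1 <- snap(t_bump + 0.15 * gap_b, dt)
      kt <- c(kt, t_fall, t_bump, t1)
      kv <- c(kv, spec$trough, -45, v_min)
    } else if (is.null(spec$rise_slopes)) {
      t1 <- snap(apexes[k] + 0.15 * gap_b, dt)
      kt <- c(kt, t1)
      kv <- c(kv, v_min)
    } else {
      s1 <- spec$rise_slopes[1]
      s2 <- spec$rise_slopes[2]
      t_rise <- (-30 - v_min) / (0.25 * s1 + 0.75 * s2)
      t1 <- snap(t5 - t_rise, dt)
      if (t1 <= apexes[k] + w) abort("rise slopes too shallow for the burst gap")
      kt <- c(kt, t1)
      kv <- c(kv, v_min)
    }
    # rise-phase shape between the minimum (t1) and the crossing (t5)
    tr_span <- t5 - t1
    if (is.null(spec$rise_slopes) || one_spike) {
      s_lin <- (-30 - v_min) / tr_span
      rise$average <- c(rise$average, s_lin)
      rise$initial <- c(rise$initial, s_lin)
      rise$central <- c(rise$central, s_lin)
    } else {
      tq <- t1 + 0.25 * tr_span          # break knot; need not be on-grid
      vq <- v_min + spec$rise_slopes[1] * 0.25 * tr_span
      kt <- c(kt, tq)
      kv <- c(kv, vq)
      s2r <- (-30 - vq) / (0.75 * tr_span)
      v4 <- vq + s2r * 0.5 * tr_span
      rise$initial <- c(rise$initial, spec$rise_slopes[1])
      rise$central <- c(rise$central, s2r)
      rise$average <- c(rise$average, (v4 - v_min) / (0.75 * tr_span))
    }
  }
  tr <- sample_knots(kt, kv, dt, max(starts) + d + w)
  attr(tr, "realized") <- list(
    class = spec$class,
    burst_period = mean(diff(starts)),
    burst_duration = d,
    duty_cycle = d / mean(diff(starts)),
    spikes_per_burst = k,
    slow_wave_peak = spec$spike_peak,
    slow_wave_amplitude = spec$spike_peak - v_min,
    slope_average = mean(rise$average),
    slope_initial = mean(rise$initial),
    slope_central = mean(rise$central)
  )
  tr
}

#' A parameterised family of classifier fixtures
#'
#' Builds a spread of [trace_spec()]s covering all six activity classes:
#' silent baselines, periodic spikers across 2-100 Hz, jittered irregular
#' spikers, periodic bursters across a period x duty-cycle x spike-count
#' grid, jittered irregular bursters, and one-spike bursters. Used by the
#' classifier-recovery checks.
#'
#' @param seed Seed for the jittered members.
#' @return A list of `trace_spec` objects (length > 100).
#' @export
fixture_family <- function(seed = 1L) {
  specs <- list()
  for (b in c(-80, -70, -60, -50, -40)) {
    specs <- c(specs, list(trace_spec("silent", baseline = b)))
  }
  for (f in seq(2, 98, length.out = 25)) {
    specs <- c(specs, list(trace_spec("periodic_spiking", frequency = f)))
  }
  for (i in seq_len(12)) {
    specs <- c(specs, list(trace_spec("irregular_spiking",
                                      frequency = 5 + 6 * i,
                                      seed = seed + i)))
  }
  for (p in c(800, 1200, 1800, 2600)) {
    for (dc in c(0.1, 0.2, 0.25, 0.35, 0.5)) {
      for (k in c(3L, 6L)) {
        specs <- c(specs, list(trace_spec("periodic_bursting",
                                          burst_period = p, duty_cycle = dc,
                                          spikes_per_burst = k)))
      }
    }
  }
  for (i in seq_len(10)) {
    specs <- c(specs, list(trace_spec("irregular_bursting",
                                      burst_period = 900 + 150 * i,
                                      duty_cycle = 0.25, jitter = 0.05,
                                      seed = seed + 100 + i)))
  }
  for (p in seq(600, 2400, length.out = 8)) {
    specs <- c(specs, list(trace_spec("one_spike_bursting", burst_period = p)))
  }
  specs
}

#' Generate a surrogate model database with planted conductance structure
#'
#' Draws `n_models` records on an `n_levels`-per-conductance grid. Each
#' record gets an activity-type label from `type_weights`; conductance
#' levels are uniform and independent, except for planted pair rules: for
#' records of the rule's type, with probability `adherence` the pair's
#' grid cell is drawn uniformly from a diagonal band of the given sign and
#' width (the minimal generator of the near-linear band structure the
#' correlation screen is designed to detect), otherwise kept uniform.
#'
#' @param n_models Number of records.
#' @param grid A `conductance_grid` (all conductances must share a level
#'   count so bands are square).
#' @param type_weights Named numeric vector of activity-type mixture
#'   weights (normalised internally).
#' @param planted A data frame with columns `type`, `cond_a`, `cond_b`,
#'   `sign` (+1/-1), `width` (band half-width in cells, >= 1), `adherence`
#'   (probability in `[0, 1]`); or `NULL` for a fully independent database.
#' @param seed RNG seed; the generator is reproducible and restores the
#'   caller's RNG state.
#' @return A `model_db` tibble with `model_id`, `lvl_*`, `g_*` and
#'   `activity_class` columns; the generating specification is stored in
#'   `attr(, "provenance")$planted_spec`.
#' @export
#' @examples
#' pl <- data.frame(type = "burster", cond_a = "CaS", cond_b = "KCa",
#'                  sign = 1, width = 1, adherence = 0.9)
#' db <- make_planted_db(2000, planted = pl, seed = 1)
make_planted_db <- function(n_models, grid = conductance_grid(),
                            type_weights = c(burster = 0.3, spiker = 0.4,
                                             silent = 0.3),
                            planted = NULL, seed = 1L) {
  stopifnot(inherits(grid, "conductance_grid"), n_models >= 1)
  L <- unique(lengths(grid$levels))
  if (length(L) != 1) abort("planted databases need a uniform level count")
  conds <- grid$conductances
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  w <- type_weights / sum(type_weights)
  type <- sample(names(w), n_models, replace = TRUE, prob = w)
  lvl <- matrix(sample.int(L, n_models * length(conds), replace = TRUE),
                nrow = n_models)
  colnames(lvl) <- paste0("lvl_", conds)
  if (!is.null(planted)) {
    need <- c("type", "cond_a", "cond_b", "sign", "width", "adherence")
    if (!all(need %in% names(planted))) {
      abort(paste0("planted spec needs columns ", paste(need, collapse = ", ")))
    }
    for (r in seq_len(nrow(planted))) {
      pr <- planted[r, ]
      if (!all(c(pr$cond_a, pr$cond_b) %in% conds)) {
        abort("planted pair names a conductance not in the grid")
      }
      band <- band_cells(L, pr$sign, pr$width)
      rows <- which(type == pr$type & runif(n_models) < pr$adherence)
      if (length(rows) > 0) {
        pick <- band[sample.int(nrow(band), length(rows), replace = TRUE), ,
                     drop = FALSE]
        lvl[rows, paste0("lvl_", pr$cond_a)] <- pick[, 1]
        lvl[rows, paste0("lvl_", pr$cond_b)] <- pick[, 2]
      }
    }
  }
  db <- as_tibble(as.data.frame(lvl))
  for (nm in conds) {
    db[[paste0("g_", nm)]] <- grid$levels[[nm]][db[[paste0("lvl_", nm)]]]
  }
  db <- dplyr::bind_cols(tibble(model_id = seq_len(n_models)), db,
                         tibble(activity_class = type))
  model_db(db, grid = grid,
           provenance = list(generator = "make_planted_db", seed = seed,
                             planted_spec = planted))
}

# grid cells of a diagonal band: |i - j| < width (positive slope) or
# |i + j - (L + 1)| < width (negative slope)
band_cells <- function(L, sign, width) {
  cells <- expand.grid(i = seq_len(L), j = seq_len(L))
  keep <- if (sign >= 0) abs(cells$i - cells$j) < width
          else abs(cells$i + cells$j - (L + 1)) < width
  as.matrix(cells[keep, , drop = FALSE])
}

#' Simulate and classify a reduced conductance grid
#'
#' Down-scales the shipped 6-level grid to `levels` equidistant values per
#' conductance (always spanning zero to the physiological maximum) and runs
#' the full simulate-and-classify pipeline over the resulting Cartesian
#' product. With `levels = 3` this is the 3^8 = 6,561-model reduced
#' database; with `levels = 1` it is the single all-zero (silent) model.
#'
#' @param levels Levels per conductance.
#' @param kin A `channel_kinetics`.
#' @param config A [sim_config()].
#' @param ... Passed to [run_grid()] (e.g. `checkpoint`).
#' @return A `model_db` tibble.
#' @export
make_reduced_grid_db <- function(levels = 3, kin = read_kinetics(),
                                 config = sim_config(), ...) {
  stopifnot(levels >= 1)
  lv <- lapply(kin$grid, function(x) {
    if (levels == 1) min(x) else seq(min(x), max(x), length.out = levels)
  })
  run_grid(conductance_grid(lv), kin, config, ...)
}
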