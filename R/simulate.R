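#' Simulation configuration
#'
#' Integration settings for the exponential-Euler simulator. Defaults:
#' 0.05 ms steps, 10 s of simulated time with the first 4 s discarded as
#' transient (slow bursters need several seconds to settle onto their
#' attractor), initial voltage -50 mV with gating at steady state for that
#' voltage and calcium at rest.
#'
#' @param dt Integration step, ms.
#' @param duration Total simulated time, ms.
#' @param transient Initial span discarded before analysis, ms.
#' @param v_init Initial membrane voltage, mV.
#' @param record_every Record one sample every this many steps (1 = every
#'   step).
#' @param i_inject Constant injected current density, uA/cm^2 (0 for the
#'   database; non-zero only for closed-form integrator checks).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.05, duration = 10000, transient = 4000,
                       v_init = -50, record_every = 1L, i_inject = 0) {
  stopifnot(dt > 0, duration > 0, transient >= 0, transient < duration,
            record_every >= 1)
  structure(
    list(dt = dt, duration = duration, transient = transient,
         v_init = v_init, record_every = as.integer(record_every),
         i_inject = i_inject),
    class = "sim_config"
  )
}

#' Simulate one model neuron
#'
#' Integrates the single-compartment membrane equation
#' \deqn{C_m \frac{dV}{dt} = -\sum_i \bar g_i m_i^{p_i} h_i^{q_i} (V - E_i) + I_{inject}}
#' together with first-order gating kinetics and the intracellular calcium
#' pool, using the exponential-Euler scheme (gates and voltage updated
#' against their instantaneous steady states; exact for the passive
#' membrane). The calcium reversal is recomputed each step from the Nernst
#' relation. Deterministic: identical inputs give identical traces.
#'
#' @param gbar Named numeric vector (or single-row data frame with `g_<name>`
#'   or bare-name columns) of maximal conductances, mS/cm^2, covering every
#'   channel in `kin`.
#' @param kin A `channel_kinetics` object.
#' @param config A [sim_config()].
#' @return A `voltage_trace`: tibble with columns `time` (ms), `v` (mV),
#'   `ca` (uM) covering `(transient, duration]`, with the step size in
#'   `attr(, "dt")` and the configuration in `attr(, "config")`.
#' @export
#' @examples
#' kin <- read_kinetics()
#' g <- c(Na = 0, CaT = 0, CaS = 0, A = 0, KCa = 0, Kd = 0, H = 0, leak = 0.05)
#' tr <- simulate_neuron(g, kin, sim_config(duration = 200, transient = 0))
simulate_neuron <- function(gbar, kin, config = sim_config()) {
  stopifnot(inherits(kin, "channel_kinetics"), inherits(config, "sim_config"))
  if (is.data.frame(gbar)) {
    stopifnot(nrow(gbar) == 1)
    nms <- sub("^g_", "", names(gbar))
    gbar <- setNames(as.numeric(gbar[1, ]), nms)
  }
  if (any(!is.finite(gbar)) || any(gbar < 0)) {
    abort("maximal conductances must be finite and non-negative")
  }
  chan <- kinetics_matrix(kin, gbar)
  mem <- kin$membrane
  cal <- kin$calcium
  res <- .simulate_cpp(
    chan,
    c(mem$capacitance, mem$area, mem$v_range[[1]], mem$v_range[[2]]),
    c(cal$tau, cal$f, cal$rest, cal$external, cal$nernst_prefactor),
    c(config$dt, config$duration, config$transient, config$record_every,
      config$v_init, config$i_inject)
  )
  new_voltage_trace(res$time, res$v, res$ca,
                    dt = config$dt * config$record_every, config = config)
}

new_voltage_trace <- function(time, v, ca = NULL, dt, config = NULL) {
  out <- tibble(time = time, v = v,
                ca = if (is.null(ca)) NA_real_ else ca)
  structure(out, dt = dt, config = config,
            class = c("voltage_trace", class(out)))
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace>", nrow(x), "samples, dt =", attr(x, "dt"), "ms,",
      "t in [", min(x$time), ",", max(x$time), "] ms\n")
  NextMethod()
}

#' Simulate and classify a grid of model neurons
#'
#' Runs [simulate_neuron()] followed by [classify_trace()] for every point
#' of a conductance grid, producing a model database: one record per grid
#' point carrying the level indices, the maximal conductances and the full
#' activity descriptor. Records are independent, so results do not depend
#' on execution order or chunking; a text checkpoint makes long runs
#' resumable.
#'
#' @param grid A `conductance_grid`.
#' @param kin A `channel_kinetics` object.
#' @param config A [sim_config()].
#' @param classifier A [classifier_config()].
#' @param checkpoint Optional path to a TSV checkpoint. Completed records
#'   are appended as they finish; re-running with the same path resumes
#'   after the last complete record. A checkpoint whose columns do not
#'   match the expected schema is a hard error.
#' @param checkpoint_every Flush frequency, records.
#' @param progress Print a progress line every this many records
#'   (`Inf` = silent).
#' @return A `model_db` tibble (see [model_db()]).
#' @export
run_grid <- function(grid, kin, config = sim_config(),
                     classifier = classifier_config(),
                     checkpoint = NULL, checkpoint_every = 200L,
                     progress = Inf) {
  stopifnot(inherits(grid, "conductance_grid"))
  points <- enumerate_grid(grid, gbar = TRUE)
  n <- nrow(points)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- readr::read_tsv(checkpoint, show_col_types = FALSE,
                            progress = FALSE)
    need <- c("model_id", paste0("lvl_", grid$conductances), "activity_class")
    if (!all(need %in% names(done))) {
      abort(paste0("corrupt checkpoint '", checkpoint,
                   "': missing columns ",
                   paste(setdiff(need, names(done)), collapse = ", ")))
    }
  }
  todo <- if (is.null(done)) points else
    points[!points$model_id %in% done$model_id, , drop = FALSE]
  gcols <- paste0("g_", grid$conductances)
  rows <- vector("list", nrow(todo))
  pending <- list()
  for (i in seq_len(nrow(todo))) {
    pt <- todo[i, , drop = FALSE]
    gb <- setNames(as.numeric(pt[1, gcols]), grid$conductances)
    tr <- simulate_neuron(gb, kin, config)
    desc <- classify_trace(tr, classifier)
    rec <- dplyr::bind_cols(pt, desc)
    rows[[i]] <- rec
    if (!is.null(checkpoint)) {
      pending[[length(pending) + 1]] <- rec
      if (length(pending) >= checkpoint_every || i == nrow(todo)) {
        chunk <- dplyr::bind_rows(pending)
        readr::write_tsv(chunk, checkpoint, append = file.exists(checkpoint),
                         col_names = !file.exists(checkpoint))
        pending <- list()
      }
    }
    if (is.finite(progress) && i %% progress == 0) {
      message("run_grid: ", i, "/", nrow(todo), " records")
    }
  }
  new <- dplyr::bind_rows(rows)
  db <- if (is.null(done)) new else
    dplyr::arrange(dplyr::bind_rows(done, new), .data$model_id)
  model_db(db, grid = grid, kinetics = kin)
}
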