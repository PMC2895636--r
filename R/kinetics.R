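#' Read a channel-kinetics configuration
#'
#' Loads the structured YAML description of a single-compartment
#' conductance-based model: membrane constants, the intracellular calcium
#' pool, every ion channel's gating kinetics, and the conductance grid used
#' to build model databases. The package ships a transcription of the
#' classic stomatogastric (STG) model-database kinetics (Prinz, Billimoria &
#' Marder 2003, J Neurophysiol; kinetics lineage Liu et al. 1998 and
#' Huguenard & McCormick 1992) as its default.
#'
#' Each ionic current is \eqn{I = \bar g\, m^p h^q (V - E)} with maximal
#' conductance \eqn{\bar g} in mS/cm^2 and gating variables relaxing towards
#' voltage- (and for the calcium-dependent potassium current, calcium-)
#' dependent steady states with voltage-dependent time constants. Calcium
#' currents use a Nernst reversal recomputed from the instantaneous
#' intracellular concentration.
#'
#' @param path Path to a kinetics YAML file; the shipped STG configuration
#'   by default.
#' @return An object of class `channel_kinetics`: a named list with elements
#'   `name`, `schema_version`, `status`, `membrane`, `calcium`, `channels`
#'   (named list, one entry per channel) and `grid` (named list of maximal
#'   conductance levels per channel, mS/cm^2).
#' @export
#' @examples
#' kin <- read_kinetics()
#' names(kin$channels)
read_kinetics <- function(path = default_kinetics_path()) {
  raw <- yaml::read_yaml(path)
  for (f in c("schema_version", "membrane", "calcium", "channels")) {
    if (is.null(raw[[f]])) abort(paste0("kinetics file missing field '", f, "'"))
  }
  chans <- raw$channels
  names(chans) <- vapply(chans, function(ch) ch$name, character(1))
  kin <- structure(
    list(
      name = raw$name %||% "unnamed",
      schema_version = raw$schema_version,
      status = raw$status %||% "unspecified",
      membrane = raw$membrane,
      calcium = raw$calcium,
      channels = chans,
      grid = raw$grid
    ),
    class = "channel_kinetics"
  )
  validate_kinetics(kin)
  kin
}

#' @rdname read_kinetics
#' @export
default_kinetics_path <- function() {
  system.file("extdata", "kinetics-stg.yaml", package = "condcorr", mustWork = TRUE)
}

#' Write a channel-kinetics configuration
#'
#' Serialises a `channel_kinetics` object back to YAML. Reading the result
#' reproduces the object exactly (numeric values survive bit-exactly because
#' YAML serialisation keeps full precision).
#'
#' @param kin A `channel_kinetics` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinetics <- function(kin, path) {
  stopifnot(inherits(kin, "channel_kinetics"))
  out <- list(
    schema_version = kin$schema_version,
    name = kin$name,
    status = kin$status,
    membrane = kin$membrane,
    calcium = kin$calcium,
    channels = unname(kin$channels),
    grid = kin$grid
  )
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

validate_kinetics <- function(kin) {
  mem <- kin$membrane
  cal <- kin$calcium
  if (!all(c("capacitance", "area", "v_range") %in% names(mem))) {
    abort("membrane config needs capacitance, area, v_range")
  }
  if (mem$capacitance <= 0 || mem$area <= 0) abort("membrane constants must be positive")
  for (f in c("tau", "f", "rest", "external", "nernst_prefactor")) {
    if (is.null(cal[[f]]) || cal[[f]] <= 0) {
      abort(paste0("calcium pool parameter '", f, "' missing or non-positive"))
    }
  }
  for (ch in kin$channels) {
    if (is.null(ch$name) || is.null(ch$reversal) || is.null(ch$p) || is.null(ch$q)) {
      abort("each channel needs name, reversal, p, q")
    }
    if (ch$p < 0 || ch$q < 0) abort(paste0("negative gating exponent in ", ch$name))
    if (ch$p > 0 && is.null(ch$m_inf)) {
      abort(paste0("channel ", ch$name, " has p > 0 but no m_inf"))
    }
    if (ch$q > 0 && is.null(ch$h_inf)) {
      abort(paste0("channel ", ch$name, " has q > 0 but no h_inf"))
    }
  }
  invisible(kin)
}

#' @export
print.channel_kinetics <- function(x, ...) {
  cat("<channel_kinetics>", x$name, "(schema", x$schema_version, ",", x$status, ")\n")
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  cat("  grid levels:", paste(lengths(x$grid), collapse = "/"), "\n")
  invisible(x)
}

# ---- gating functional forms -------------------------------------------

kinetics_form_code <- function(form) {
  match(form, c("constant", "logistic", "logistic_ca", "sigmoid", "biexp", "prodsig")) - 1L
}

# Evaluate one gating functional form at voltage v (mV) and calcium ca (uM).
# Mirrors the integrator's C++ evaluation; this R version is the public,
# testable surface.
eval_gating_form <- function(spec, v, ca) {
  switch(spec$form,
    constant = rep(spec$a, length(v)),
    logistic = 1 / (1 + exp((v - spec$vhalf) / spec$k)),
    logistic_ca = (ca / (ca + spec$ca_half)) / (1 + exp((v - spec$vhalf) / spec$k)),
    sigmoid = spec$a + spec$b / (1 + exp((v - spec$vhalf) / spec$k)),
    biexp = spec$a + spec$b /
      (exp((v - spec$vhalf1) / spec$k1) + exp((v - spec$vhalf2) / spec$k2)),
    prodsig = spec$s / (1 + exp((v - spec$vhalf1) / spec$k1)) *
      (spec$c + 1 / (1 + exp((v - spec$vhalf2) / spec$k2))),
    abort(paste0("unknown gating form '", spec$form, "'"))
  )
}

#' Evaluate steady-state gating and time constants for one channel
#'
#' Returns the steady-state activation/inactivation and their time constants
#' at the given voltage and intracellular calcium concentration. Channels
#' without an inactivation gate (q = 0) report `h_inf = 1` and `tau_h = NA`;
#' ungated channels (leak) report `m_inf = 1` as well. Voltages are clamped
#' to the configured table range before evaluation.
#'
#' @param kin A `channel_kinetics` object.
#' @param channel Channel name, e.g. `"Na"`.
#' @param v Membrane voltage(s), mV. Must be finite.
#' @param ca Intracellular calcium, uM (> 0); the resting concentration by
#'   default. Only the calcium-dependent potassium current uses it.
#' @return A tibble with columns `v`, `ca`, `m_inf`, `h_inf`, `tau_m`,
#'   `tau_h`.
#' @export
#' @examples
#' kin <- read_kinetics()
#' evaluate_gating(kin, "Na", v = c(-80, -25.5, 0))
evaluate_gating <- function(kin, channel, v, ca = kin$calcium$rest) {
  stopifnot(inherits(kin, "channel_kinetics"))
  ch <- kin$channels[[channel]]
  if (is.null(ch)) abort(paste0("unknown channel '", channel, "'"))
  if (any(!is.finite(v)) || any(!is.finite(ca)) || any(ca <= 0)) {
    abort(paste0("non-finite voltage or non-positive calcium for channel ", channel))
  }
  vr <- kin$membrane$v_range
  vc <- pmin(pmax(v, vr[[1]]), vr[[2]])
  m_inf <- if (ch$p > 0) eval_gating_form(ch$m_inf, vc, ca) else rep(1, length(vc))
  tau_m <- if (ch$p > 0) eval_gating_form(ch$tau_m, vc, ca) else rep(NA_real_, length(vc))
  h_inf <- if (ch$q > 0) eval_gating_form(ch$h_inf, vc, ca) else rep(1, length(vc))
  tau_h <- if (ch$q > 0) eval_gating_form(ch$tau_h, vc, ca) else rep(NA_real_, length(vc))
  tibble(v = v, ca = ca, m_inf = m_inf, h_inf = h_inf, tau_m = tau_m, tau_h = tau_h)
}

#' Nernst reversal potential for calcium
#'
#' Computes \eqn{E_{Ca} = k \ln([Ca]_{out} / [Ca]_{in})}, with the prefactor
#' \eqn{k = RT/2F} in mV. Used every integration step to couple the two
#' calcium currents to the intracellular pool.
#'
#' @param ca_in Intracellular concentration, uM (> 0).
#' @param ca_out Extracellular concentration, uM; default from the shipped
#'   configuration (3 mM).
#' @param prefactor RT/2F in mV (natural log form).
#' @return Reversal potential(s), mV.
#' @export
#' @examples
#' nernst_calcium(0.05)   # resting concentration -> strongly positive
#' nernst_calcium(3000)   # equal concentrations -> 0
nernst_calcium <- function(ca_in, ca_out = 3000, prefactor = 12.2) {
  if (any(!is.finite(ca_in)) || any(ca_in <= 0)) {
    abort("intracellular calcium must be finite and positive")
  }
  prefactor * log(ca_out / ca_in)
}

# Encode a kinetics object + maximal-conductance vector into the numeric
# matrix consumed by the C++ integrator.
kinetics_matrix <- function(kin, gbar) {
  chans <- kin$channels
  nm <- names(chans)
  if (!all(nm %in% names(gbar))) {
    abort(paste0("gbar missing channels: ",
                 paste(setdiff(nm, names(gbar)), collapse = ", ")))
  }
  encode <- function(spec) {
    out <- numeric(7)
    if (is.null(spec)) {
      out[1] <- -1
      return(out)
    }
    out[1] <- kinetics_form_code(spec$form)
    pars <- switch(spec$form,
      constant = spec$a,
      logistic = c(spec$vhalf, spec$k),
      logistic_ca = c(spec$vhalf, spec$k, spec$ca_half),
      sigmoid = c(spec$a, spec$b, spec$vhalf, spec$k),
      biexp = c(spec$a, spec$b, spec$vhalf1, spec$k1, spec$vhalf2, spec$k2),
      prodsig = c(spec$s, spec$vhalf1, spec$k1, spec$c, spec$vhalf2, spec$k2)
    )
    out[seq_along(pars) + 1] <- pars
    out
  }
  mat <- matrix(0, nrow = length(chans), ncol = 33)
  for (i in seq_along(chans)) {
    ch <- chans[[i]]
    is_ca <- identical(ch$reversal, "calcium")
    mat[i, 1] <- gbar[[ch$name]]
    mat[i, 2] <- as.numeric(is_ca)
    mat[i, 3] <- if (is_ca) NA_real_ else ch$reversal
    mat[i, 4] <- ch$p
    mat[i, 5] <- ch$q
    mat[i, 6:12] <- encode(if (ch$p > 0) ch$m_inf else NULL)
    mat[i, 13:19] <- encode(if (ch$p > 0) ch$tau_m else NULL)
    mat[i, 20:26] <- encode(if (ch$q > 0) ch$h_inf else NULL)
    mat[i, 27:33] <- encode(if (ch$q > 0) ch$tau_h else NULL)
  }
  mat
}
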