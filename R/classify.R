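#' Classifier thresholds
#'
#' The three thresholds of the activity taxonomy, with the reference values
#' as immutable defaults: any voltage maximum above -30 mV is a spike
#' (strict inequality); a train is periodic when every inter-event interval
#' is within 1% of the mean interval (inclusive); an inter-spike interval is
#' an inter-burst interval when it is within 30% of the largest inter-spike
#' interval of the trace (inclusive, i.e. ISI >= 0.7 * max ISI).
#'
#' @param spike_threshold Spike detection threshold, mV.
#' @param periodicity_tol Relative tolerance of the periodicity test.
#' @param burst_isi_frac Relative deviation from the maximum ISI below which
#'   an ISI counts as inter-burst.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(spike_threshold = -30, periodicity_tol = 0.01,
                              burst_isi_frac = 0.3) {
  stopifnot(periodicity_tol > 0, burst_isi_frac > 0, burst_isi_frac < 1)
  structure(
    list(spike_threshold = spike_threshold,
         periodicity_tol = periodicity_tol,
         burst_isi_frac = burst_isi_frac),
    class = "classifier_config"
  )
}

#' Detect membrane-voltage maxima
#'
#' Strict local maxima of the sampled trace: samples larger than both
#' neighbours. Constant or monotone traces have none (the definition of a
#' silent model). Plateau samples (exact ties with a neighbour) are not
#' maxima; on simulated traces ties do not occur at double precision.
#'
#' @param trace A data frame with numeric `time` (ms) and `v` (mV) columns.
#' @return A tibble with columns `time`, `v`, one row per maximum, in time
#'   order.
#' @export
detect_maxima <- function(trace) {
  v <- trace$v
  stopifnot(is.numeric(v), all(is.finite(v)))
  n <- length(v)
  if (n < 3) return(tibble(time = numeric(), v = numeric()))
  i <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  tibble(time = trace$time[i], v = v[i])
}

#' Select the maxima that are spikes
#'
#' A maximum is a spike when its voltage strictly exceeds the spike
#' threshold; all other maxima are sub-threshold slow-wave activity.
#'
#' @param maxima Output of [detect_maxima()].
#' @param threshold Spike threshold, mV (default -30).
#' @return The subset of `maxima` rows with `v > threshold`.
#' @export
detect_spikes <- function(maxima, threshold = -30) {
  dplyr::filter(maxima, .data$v > threshold)
}

#' Periodicity test on a sequence of event times
#'
#' TRUE when every inter-event interval deviates from the mean interval by
#' at most `tol` of the mean (inclusive). Requires at least three events.
#'
#' @param times Event times, ms, increasing.
#' @param tol Relative tolerance (default 1%).
#' @return Logical scalar; `NA` with fewer than three events.
#' @export
is_periodic <- function(times, tol = 0.01) {
  if (length(times) < 3) return(NA)
  iv <- diff(times)
  m <- mean(iv)
  if (m <= 0) return(FALSE)
  all(abs(iv - m) <= tol * m)
}

#' Segment spikes into bursts
#'
#' Applies the maximum-ISI rule: the largest inter-spike interval of the
#' trace sets the scale, and every ISI within `frac` of it (ISI >=
#' (1-frac) * max ISI) is an inter-burst interval. Bursts are the maximal
#' runs of spikes between inter-burst intervals; single-spike bursts are
#' allowed.
#'
#' @param spike_times Spike times, ms, increasing; at least two.
#' @param frac Relative deviation defining inter-burst ISIs (default 30%).
#' @return A tibble with columns `burst`, `t_start`, `t_end`, `n_spikes`,
#'   and a `spikes` list-column of the member spike times.
#' @export
#' @examples
#' st <- c(0, 20, 40, 540, 560, 580, 1080, 1100, 1120)
#' segment_bursts(st)   # three 3-spike bursts
segment_bursts <- function(spike_times, frac = 0.3) {
  stopifnot(length(spike_times) >= 2, !is.unsorted(spike_times))
  isi <- diff(spike_times)
  inter <- isi >= (1 - frac) * max(isi)
  burst_id <- cumsum(c(1L, as.integer(inter)))
  grp <- split(spike_times, burst_id)
  tibble(
    burst = seq_along(grp),
    t_start = vapply(grp, min, numeric(1), USE.NAMES = FALSE),
    t_end = vapply(grp, max, numeric(1), USE.NAMES = FALSE),
    n_spikes = lengths(grp, use.names = FALSE),
    spikes = unname(grp)
  )
}

#' Burst timing metrics
#'
#' Burst period is measured between consecutive burst starts; burst
#' duration is first-spike to last-spike time within a burst (zero for a
#' one-spike burst); duty cycle is mean duration over mean period.
#'
#' @param bursts Output of [segment_bursts()]; at least two bursts.
#' @return A one-row tibble: `burst_period`, `burst_duration` (ms),
#'   `duty_cycle`, `spikes_per_burst`.
#' @export
burst_metrics <- function(bursts) {
  if (nrow(bursts) < 2) {
    abort("burst metrics need at least two bursts")
  }
  period <- mean(diff(bursts$t_start))
  duration <- mean(bursts$t_end - bursts$t_start)
  tibble(
    burst_period = period,
    burst_duration = duration,
    duty_cycle = duration / period,
    spikes_per_burst = mean(bursts$n_spikes)
  )
}

# Linear interpolation of the trace voltage at arbitrary times.
trace_v_at <- function(trace, t) {
  stats::approx(trace$time, trace$v, xout = t, rule = 2)$y
}

#' Rise-phase slopes of the slow wave
#'
#' For each between-burst gap: point 1 is the inter-burst voltage minimum,
#' point 5 the next upward crossing of the spike threshold (interpolated);
#' points 2-4 divide the time span from 1 to 5 into four equal sections.
#' The average slope runs from point 1 to point 4 (the 4-to-5 section is
#' omitted to avoid the steep upstroke of the first spike of the next
#' burst), the initial slope from 1 to 2, and the central slope from 2
#' to 4. Gaps in which the threshold is never re-crossed are skipped with
#' a warning. Slopes are averaged over gaps.
#'
#' @param trace Data frame with `time`, `v`.
#' @param bursts Output of [segment_bursts()].
#' @param threshold Spike threshold, mV.
#' @return One-row tibble: `slope_average`, `slope_initial`,
#'   `slope_central` (mV/ms).
#' @export
rise_phase_slopes <- function(trace, bursts, threshold = -30) {
  n <- nrow(bursts)
  if (n < 2) abort("rise-phase slopes need at least two bursts")
  sa <- si <- sc <- numeric(0)
  skipped <- 0L
  for (k in seq_len(n - 1)) {
    lo <- bursts$t_end[k]
    hi <- bursts$t_start[k + 1]
    win <- trace$time > lo & trace$time <= hi
    if (!any(win)) next
    tw <- trace$time[win]
    vw <- trace$v[win]
    i1 <- which.min(vw)
    t1 <- tw[i1]; v1 <- vw[i1]
    # first upward threshold crossing after point 1
    after <- seq(i1, length(vw))
    cross <- which(vw[after] > threshold)
    if (length(cross) == 0 || cross[1] == 1) {
      skipped <- skipped + 1L
      next
    }
    j <- after[cross[1]]
    # interpolate the crossing time between samples j-1 and j
    t5 <- tw[j - 1] + (threshold - vw[j - 1]) / (vw[j] - vw[j - 1]) *
      (tw[j] - tw[j - 1])
    tt <- t1 + (t5 - t1) * (1:3) / 4
    v2 <- trace_v_at(trace, tt[1])
    v4 <- trace_v_at(trace, tt[3])
    sa <- c(sa, (v4 - v1) / (tt[3] - t1))
    si <- c(si, (v2 - v1) / (tt[1] - t1))
    sc <- c(sc, (v4 - v2) / (tt[3] - tt[1]))
  }
  if (skipped > 0) {
    warn(paste0("rise_phase_slopes: ", skipped,
                " between-burst gap(s) without a threshold crossing skipped"))
  }
  if (length(sa) == 0) {
    return(tibble(slope_average = NA_real_, slope_initial = NA_real_,
                  slope_central = NA_real_))
  }
  tibble(slope_average = mean(sa), slope_initial = mean(si),
         slope_central = mean(sc))
}

#' Slow-wave peak and amplitude
#'
#' The slow-wave peak of a burst is approximated by the last voltage
#' maximum inside the burst; the amplitude is that peak minus the
#' between-burst minimum that follows. Both are averaged over bursts.
#'
#' @param trace Data frame with `time`, `v`.
#' @param maxima Output of [detect_maxima()].
#' @param bursts Output of [segment_bursts()].
#' @return One-row tibble: `slow_wave_peak`, `slow_wave_amplitude` (mV).
#' @export
slow_wave_metrics <- function(trace, maxima, bursts) {
  n <- nrow(bursts)
  if (n < 2) abort("slow-wave metrics need at least two bursts")
  peaks <- vapply(seq_len(n), function(k) {
    mk <- maxima$v[maxima$time >= bursts$t_start[k] &
                     maxima$time <= bursts$t_end[k]]
    if (length(mk) == 0) NA_real_ else mk[length(mk)]
  }, numeric(1))
  amps <- vapply(seq_len(n - 1), function(k) {
    win <- trace$time > bursts$t_end[k] & trace$time < bursts$t_start[k + 1]
    if (!any(win) || is.na(peaks[k])) return(NA_real_)
    peaks[k] - min(trace$v[win])
  }, numeric(1))
  tibble(slow_wave_peak = mean(peaks, na.rm = TRUE),
         slow_wave_amplitude = mean(amps, na.rm = TRUE))
}

empty_descriptor <- function() {
  tibble(
    activity_class = NA_character_, quality = "ok",
    n_maxima = 0L, n_spikes = 0L, n_bursts = NA_integer_,
    spike_frequency = NA_real_, spike_height = NA_real_,
    burst_period = NA_real_, burst_duration = NA_real_,
    duty_cycle = NA_real_, spikes_per_burst = NA_real_,
    slow_wave_peak = NA_real_, slow_wave_amplitude = NA_real_,
    slope_average = NA_real_, slope_initial = NA_real_,
    slope_central = NA_real_
  )
}

#' Classify the intrinsic activity of a voltage trace
#'
#' Assigns exactly one of the six activity classes — `silent`,
#' `periodic_spiking`, `irregular_spiking`, `periodic_bursting`,
#' `irregular_bursting`, `one_spike_bursting` — and populates every
#' applicable scalar metric. The decision flow:
#'
#' 1. No voltage maxima, or no supra-threshold maxima: `silent` (the number
#'    of sub-threshold maxima is retained in `n_maxima`).
#' 2. With spikes, the maximum-ISI rule ([segment_bursts()]) splits the
#'    trace into bursts. If every ISI qualifies as inter-burst (a single
#'    interval scale), the trace is tonic spiking — unless sub-threshold
#'    slow-wave maxima sit between the spikes, in which case each spike is
#'    its own burst: `one_spike_bursting`.
#' 3. Spikers are `periodic_spiking` when all inter-maximum intervals are
#'    within the periodicity tolerance of their mean, else
#'    `irregular_spiking`. Bursters are `periodic_bursting` when the
#'    burst-start intervals pass the same test (the mirror of the spiking
#'    rule), else `irregular_bursting`.
#'
#' Degenerate traces (a single spike in the window, or too few bursts for
#' timing metrics) keep their class but are marked `quality = "low_event"`;
#' they are never silently dropped.
#'
#' @param trace A data frame with `time` (ms) and `v` (mV); typically a
#'   `voltage_trace` already restricted to post-transient time.
#' @param config A [classifier_config()].
#' @return A one-row tibble: `activity_class`, `quality`, counts
#'   (`n_maxima`, `n_spikes`, `n_bursts`), spiker metrics
#'   (`spike_frequency` Hz, `spike_height` mV), burst metrics
#'   (`burst_period`, `burst_duration` ms, `duty_cycle`,
#'   `spikes_per_burst`), slow-wave metrics (`slow_wave_peak`,
#'   `slow_wave_amplitude` mV) and rise-phase slopes (mV/ms).
#' @export
classify_trace <- function(trace, config = classifier_config()) {
  stopifnot(all(c("time", "v") %in% names(trace)))
  if (!all(is.finite(trace$v))) {
    out <- empty_descriptor()
    out$activity_class <- "silent"
    out$quality <- "unclassifiable"
    return(out)
  }
  thr <- config$spike_threshold
  out <- empty_descriptor()
  maxima <- detect_maxima(trace)
  out$n_maxima <- nrow(maxima)
  spikes <- detect_spikes(maxima, thr)
  out$n_spikes <- nrow(spikes)

  if (nrow(maxima) == 0 || nrow(spikes) == 0) {
    out$activity_class <- "silent"
    return(out)
  }
  if (nrow(spikes) == 1) {
    out$activity_class <- "irregular_spiking"
    out$quality <- "low_event"
    return(out)
  }

  st <- spikes$time
  isi <- diff(st)
  inter <- isi >= (1 - config$burst_isi_frac) * max(isi)

  spiker_metrics <- function(out) {
    out$spike_frequency <- 1000 * (length(st) - 1) / (st[length(st)] - st[1])
    gaps <- vapply(seq_len(length(st) - 1), function(k) {
      win <- trace$time > st[k] & trace$time < st[k + 1]
      if (!any(win)) NA_real_ else min(trace$v[win])
    }, numeric(1))
    out$spike_height <- mean(spikes$v) - mean(gaps, na.rm = TRUE)
    out
  }

  if (all(inter)) {
    # one interval scale: tonic spiking, unless sub-threshold maxima sit
    # between the spikes (slow-wave structure -> one-spike bursting)
    sub <- maxima$v <= thr & maxima$time > st[1] & maxima$time < st[length(st)]
    if (any(sub)) {
      bursts <- tibble(burst = seq_along(st), t_start = st, t_end = st,
                       n_spikes = 1L, spikes = as.list(st))
      out$activity_class <- "one_spike_bursting"
      out$n_bursts <- nrow(bursts)
      out$burst_period <- mean(diff(st))
      out$burst_duration <- 0
      out$duty_cycle <- 0
      out$spikes_per_burst <- 1
      out <- fill_burst_shape(out, trace, maxima, bursts, thr)
      return(out)
    }
    per <- is_periodic(maxima$time, config$periodicity_tol)
    out$activity_class <- if (isTRUE(per)) "periodic_spiking" else "irregular_spiking"
    if (is.na(per)) out$quality <- "low_event"
    return(spiker_metrics(out))
  }

  # bursting
  bursts <- segment_bursts(st, config$burst_isi_frac)
  out$n_bursts <- nrow(bursts)
  if (all(bursts$n_spikes == 1L)) {
    out$activity_class <- "one_spike_bursting"
  } else {
    per <- is_periodic(bursts$t_start, config$periodicity_tol)
    out$activity_class <- if (isTRUE(per)) "periodic_bursting" else "irregular_bursting"
    if (is.na(per)) out$quality <- "low_event"
  }
  if (nrow(bursts) >= 2) {
    bm <- burst_metrics(bursts)
    out[names(bm)] <- bm
    out <- fill_burst_shape(out, trace, maxima, bursts, thr)
  } else {
    out$quality <- "low_event"
  }
  out
}

fill_burst_shape <- function(out, trace, maxima, bursts, thr) {
  sw <- slow_wave_metrics(trace, maxima, bursts)
  out[names(sw)] <- sw
  sl <- rise_phase_slopes(trace, bursts, thr)
  out[names(sl)] <- sl
  out
}
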